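a_o: 0.647
h_o: 0.04
l_o: 15.0
phi_e: 0.34
phi_m: 0.33
phi_c: 0.33
beta_theta: 0.056
beta_z: 0.067
beta_d: 0.877
alpha_0o: 0.521853446346304
c_e: 89.709999999999994
c1_m: 261.399999999999977
c2_m: 0.24
c1_c: 234.900000000000006
c2_c: 4.08
G_theta_e: 1.9
G_z_e: 1.62
G_m: 1.2
G_c: 1.25
eta: 1.0
K_ratio: 0.35
delta: 0.0
xi: 0.0
T_max: 250.0
C_B: 0.8326
C_S: 0.4163
lambda_M: 1.1
lambda_0: 0.4
Q_ratio: 1.0
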