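# gnreq — mechanobiologically equilibrated growth and remodeling of the aorta

Thoracic aortic aneurysms arise from many interacting risk factors —
compromised elastic fibers, aberrant collagen remodeling, lost smooth muscle
contractility, dysfunctional mechanosensing or mechanoregulation of matrix,
superimposed hypertension and aging. Because these co-exist in patients and
in mouse models, their individual contributions are hard to isolate
experimentally. `gnreq` is for vascular-biomechanics researchers who want to
study such insults *in isolation and in combination* in silico: it implements
a rate-independent, mechanobiologically equilibrated constrained-mixture
model of a cylindrical murine thoracic-aorta segment and a catalog of
"numerical knockout" simulations on it.

## Model at a glance

The wall is a constrained mixture of elastin-dominated matrix (neo-Hookean,
prestretched via a deposition stretch tensor **G**ᵉ, degradable but not
produced), four collagen fiber families and passive smooth muscle
(exponential fiber energies `c1/(4c2)(exp(c2(λ²−1)²)−1)`, each deposited at
its deposition stretch `G`), and shear-regulated active tone. Growth and
remodeling states satisfy, at every material point,

- mechanical equilibrium of the pressurized membrane, and
- mechanobiological equilibrium — production balances removal:

  `((1−δ)σ_v − σ_o)/σ_o − (K_τw/K_σ)·((1−ξ)τ_w/τ_wo − 1) = 0`,

with `σ_v = tr(σ)/3` the stress stimulus, `τ_w/τ_wo = (a_o/a)³` the wall
shear ratio at constant flow, `δ`, `ξ` the mechanosensing/endothelial
dysfunction fractions, and evolved mass fractions `φ_h = φ_o ρ/J`,
`ρ_m = ρ_c^η`. The equilibrated limit collapses the hereditary integrals of
the full constrained-mixture theory: every fiber family sits at its
deposition stretch, and stress, stored energy `W = Σ φ_h Ŵ`, and the
small-on-large circumferential stiffness `c_θθθθ` are rules of mixtures over
the evolved composition. Localized insults enter through Gaussian-like
axial profiles `θ(z) = θ_end + (θ_central − θ_end)·exp(−|(z−l_o/2)/z_od|^νz)`.

Two solvers expose the model: `solve_uniform()` (0-D uniform cylinder) and
`solve_scenario()` (axisymmetric nonlinear membrane finite elements with
follower pressure, a consistent complex-step tangent, and fold-capable
continuation).

## Worked example

```r
library(gnreq)

pars <- mouse_dta_parameters()          # murine DTA baseline (kPa, mm)
baseline <- homeostatic_baseline(pars)
baseline
#> Homeostatic baseline: P_o = 16.337 kPa (122.5 mmHg), sigma_o = 168.20 kPa, tau_wo = 1
#>   W_o = 67.73 kPa, c_tttt,o = 1423.1 kPa

mesh <- build_mesh(pars)                # 20 quadratic membrane elements
res <- run_scenario(scenario_spec("elastin_integrity", "severe"),
                    pars, baseline = baseline, mesh = mesh)
summarize_result(res)
#>                      label max_diameter_ratio central_W central_W_change
#> 1 elastin_integrity:severe            55.4635   44.6721         -34.0455
#>   central_ctttt central_ctttt_fold lesion_length converged
#> 1       2199.15            1.54537          3.75      TRUE
```

A severe (62%) localized loss of elastic fiber integrity dilates the central
segment by ~55%, drops the central stored energy density by ~34% from its
homeostatic 67.7 kPa, and stiffens the wall circumferentially by ~1.5-fold
over a lesion ~3.8 mm long — the signature changes of an aneurysmal wall.
`knockout_catalog()` enumerates all insult × severity × risk-factor
combinations; `scan_delta_instability()` bisects the mechanosensing level
beyond which no equilibrated solution exists; `simulate_equibiaxial()` runs
virtual biaxial tests on remodeled compositions; `write_vtk()` /
`write_metrics_csv()` export surfaces and summaries.

A thin command-line front end ships at `inst/cli/gnr.R`:

```sh
Rscript inst/cli/gnr.R run --scenario elastin_integrity:severe --hypertension --aging
Rscript inst/cli/gnr.R sweep --param delta --grid 0:0.2:0.01
```

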