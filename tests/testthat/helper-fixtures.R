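# Shared fixtures: the baseline parameterization and derived homeostatic
# state are deterministic and cheap; computed once per test run.
pars_fix <- mouse_dta_parameters()
base_fix <- homeostatic_baseline(pars_fix)

# Small meshes for finite-element tests keep the suite fast; scenario-level
# checks use the standard 20-element mesh.
mesh20 <- build_mesh(pars_fix, n_elem = 20)
mesh6 <- build_mesh(pars_fix, n_elem = 6)

# Random admissible perturbation of the reference geometry (smooth bulge plus
# axial jitter away from the clamped ends).
perturbed_dof <- function(mesh, amp_r = 0.05, amp_z = 0.02, seed = 1) {
  set.seed(seed)
  u <- reference_dof(mesh)
  n <- mesh$n_nodes
  s <- seq(0, pi, length.out = n)
  u[1:n] <- u[1:n] * (1 + amp_r * sin(s) * runif(1, 0.5, 1))
  interior <- (n + 2):(2 * n - 1)
  u[interior] <- u[interior] +
    amp_z * (mesh$l_o / n) * rnorm(length(interior))
  u
}
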