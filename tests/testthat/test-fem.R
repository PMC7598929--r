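test_that("mesh construction matches the reference discretization", {
  m <- build_mesh(pars_fix)
  expect_equal(m$n_elem, 20)
  expect_equal(m$n_nodes, 41)
  expect_equal(max(m$z_nodes), 15)
  expect_equal(min(diff(m$z_nodes)), max(diff(m$z_nodes)))
  expect_error(build_mesh(pars_fix, n_elem = 3), "at least 4")
  # refinement x2 nests the coarse nodes
  m2 <- build_mesh(pars_fix, n_elem = 40)
  expect_true(all(m$z_nodes %in% m2$z_nodes))
})

test_that("baseline configuration is a discrete equilibrium", {
  u0 <- reference_dof(mesh20)
  loc <- gnreq:::resolve_local(pars_fix)
  asm <- assemble_residual(mesh20, u0, loc, pars_fix, base_fix$P_o, base_fix)
  free <- gnreq:::free_dof_index(mesh20)
  expect_lt(max(abs(asm$R[free])), 1e-9)
  expect_equal(asm$rho, rep(1, mesh20$n_gp), tolerance = 1e-10)
})

test_that("global axial balance holds for arbitrary admissible states", {
  u <- perturbed_dof(mesh6, seed = 7)
  loc <- gnreq:::resolve_local(pars_fix, list(c_e = 70))
  asm <- assemble_residual(mesh6, u, loc, pars_fix, base_fix$P_o, base_fix)
  # internal axial forces are self-equilibrated; the net axial residual over
  # all nodes equals the net axial follower-pressure force on the surface
  n <- mesh6$n_nodes
  kin <- gnreq:::gp_kinematics(mesh6, u)
  wj <- rep(mesh6$w, mesh6$n_elem) * mesh6$jac
  f_ext_z <- -2 * pi * base_fix$P_o * sum(wj * kin$r * kin$drds)
  expect_equal(sum(asm$R[n + seq_len(n)]), -f_ext_z, tolerance = 1e-8)
})

test_that("analytic tangent agrees with the numeric (FD) tangent", {
  u <- perturbed_dof(mesh6, seed = 1)
  loc <- gnreq:::resolve_local(pars_fix)
  free <- gnreq:::free_dof_index(mesh6)
  asm <- assemble_residual(mesh6, u, loc, pars_fix, base_fix$P_o, base_fix)
  Ka <- tangent(mesh6, u, loc, pars_fix, base_fix$P_o, base_fix,
                rho = asm$rho, mode = "analytic")
  Kn <- tangent(mesh6, u, loc, pars_fix, base_fix$P_o, base_fix,
                rho = asm$rho, mode = "numeric")
  rel <- max(abs(Ka[free, free] - Kn[free, free])) /
    max(abs(Ka[free, free]))
  expect_lt(rel, 1e-4)
})

test_that("uniform-field membrane solve equals the 0-D solution pointwise", {
  ov <- list(c_e = 0.8 * pars_fix$c_e, delta = 0.03)
  st0 <- solve_uniform(pars_fix, overrides = ov, baseline = base_fix)
  loc <- gnreq:::resolve_local(pars_fix, ov)
  res <- solve_scenario(mesh20, loc, base_fix$P_o, pars_fix,
                        baseline = base_fix, label = "uniform check")
  expect_true(res$converged)
  gp <- res$gp_table
  expect_lt(max(abs(gp$lam_theta - st0$lam_theta)) / st0$lam_theta, 1e-6)
  expect_lt(max(abs(gp$lam_z - 1)), 1e-6)
  expect_lt(max(abs(gp$rho_c - st0$rho_c_ratio)) / st0$rho_c_ratio, 1e-6)
  expect_lt(max(abs(gp$W - st0$W)) / st0$W, 1e-6)
})

test_that("local constitutive update matches the uniform solver", {
  ov <- list(c_e = 0.38 * pars_fix$c_e)
  st0 <- solve_uniform(pars_fix, overrides = ov, baseline = base_fix)
  stl <- local_constitutive_update(st0$lam_theta, st0$lam_z, pars_fix,
                                   overrides = ov, baseline = base_fix)
  expect_equal(stl$rho_c_ratio, st0$rho_c_ratio, tolerance = 1e-8)
  expect_equal(stl$W, st0$W, tolerance = 1e-8)
  # an insulted point deposits compensatory collagen
  expect_gt(stl$rho_c_ratio, 1)
})

test_that("quadratic convergence is observed near the solution", {
  sp <- scenario_spec("elastin_integrity", "severe")
  res <- run_scenario(sp, pars_fix, baseline = base_fix, mesh = mesh20)
  expect_true(res$converged)
  lg <- res$steps[[length(res$steps)]]$newton_log
  if (length(lg) >= 3) {
    # the last contraction should be far better than linear
    expect_lt(lg[length(lg)] / lg[length(lg) - 1], 1e-3)
  }
})

test_that("tangent eigenvalues decay toward zero near the instability", {
  # a localized mechanosensing lesion approaching its critical magnitude has
  # an increasingly ill-conditioned tangent (rows equilibrated so mechanical
  # and mechanobiological equations share a scale)
  mesh <- mesh20
  z <- mesh$gp_z
  w <- exp(-abs((z - 7.5) / 3)^5)
  loc_b <- gnreq:::resolve_local(pars_fix)
  r_scale <- 2 * pi * mesh$a_o * mesh$h_o * base_fix$sigma_o
  smallest_ev <- function(delta_c) {
    loc <- loc_b
    loc$delta <- delta_c * w
    loc$K_ratio <- pars_fix$K_ratio * (1 - w)
    res <- solve_scenario(mesh, loc, base_fix$P_o, pars_fix,
                          baseline = base_fix,
                          config = fem_solve_config(arc_length = FALSE))
    expect_true(res$converged)
    asm <- gnreq:::assemble_coupled(mesh, res$u, res$rho, loc, pars_fix,
                                    base_fix$P_o, base_fix)
    Kb <- gnreq:::tangent_coupled(mesh, res$u, res$rho, loc, pars_fix,
                                  base_fix$P_o, base_fix, asm$kin)
    free <- gnreq:::free_dof_index(mesh)
    ng <- mesh$n_gp
    K <- rbind(cbind(Kb$Kuu[free, free], Kb$Kur[free, ]),
               cbind(Kb$Kru[, free], diag(Kb$Krr, ng)))
    K <- K * c(rep(1 / r_scale, length(free)), rep(1, ng))
    min(abs(Re(eigen(K, only.values = TRUE)$values)))
  }
  ev <- vapply(c(0.05, 0.15, 0.21), smallest_ev, numeric(1))
  expect_true(all(diff(ev) < 0))
  expect_lt(ev[3], 0.75 * ev[1])
})
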