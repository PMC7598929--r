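test_that("homeostatic baseline is an exact fixed point with derived P_o", {
  expect_equal(base_fix$P_o, 16.33690, tolerance = 1e-6)
  expect_equal(base_fix$sigma_o, 168.20482, tolerance = 1e-6)
  expect_equal(base_fix$tau_wo, 1)
  # both residuals vanish at the reference state
  expect_lt(abs(mechanobiological_residual(base_fix$state, pars_fix,
                                           base_fix)), 1e-12)
  s <- mixture_stress(base_fix$state, pars_fix)
  # Laplace consistency of the derived pressure (mid-wall membrane value)
  expect_equal(base_fix$P_o * pars_fix$a_o / pars_fix$h_o,
               s["theta", "theta"], tolerance = 1e-9)
  # thin-wall check: sigma_tt - sigma_rr = P (a/h + 1/2), within membrane terms
  expect_equal(s["theta", "theta"] - s["r", "r"],
               base_fix$P_o * (pars_fix$a_o / pars_fix$h_o + 0.5),
               tolerance = 1e-9)
})

test_that("mechanobiological residual reflects sensing dysfunction", {
  # at the baseline deformation, a mechanosensing deficit delta shifts the
  # residual to exactly -delta (shear deviation is zero there)
  for (d in c(0.05, 0.185)) {
    st <- base_fix$state
    st$loc <- gnreq:::resolve_local(pars_fix, list(delta = d))
    expect_equal(mechanobiological_residual(st, pars_fix, base_fix), -d,
                 tolerance = 1e-12)
  }
  # shear term enters through the gain ratio only
  st <- base_fix$state
  st$tau_ratio <- 0.9
  st$loc <- gnreq:::resolve_local(pars_fix, list(K_ratio = 0.35))
  expect_equal(mechanobiological_residual(st, pars_fix, base_fix),
               -0.35 * (0.9 - 1), tolerance = 1e-12)
})

test_that("mass coupling is the turnover power law", {
  expect_equal(mass_coupling(1, 3.7), 1)
  expect_equal(mass_coupling(2, 1), 2)
  expect_equal(mass_coupling(2, 1.05), 2.0705298, tolerance = 1e-6)
  expect_error(mass_coupling(-1, 1), "positive")
})

test_that("uniform solve returns the identity at baseline inputs", {
  st <- solve_uniform(pars_fix, baseline = base_fix)
  expect_equal(st$lam_theta, 1, tolerance = 1e-9)
  expect_equal(st$rho_c_ratio, 1, tolerance = 1e-9)
  expect_equal(st$J, 1, tolerance = 1e-9)
  expect_equal(st$W, 67.73162, tolerance = 1e-4)
})

test_that("hypertension drives near-ideal mechano-adaptation", {
  st <- solve_uniform(pars_fix, P = 1.5 * base_fix$P_o, baseline = base_fix)
  thick_ratio <- st$J / (st$lam_theta * st$lam_z)
  expect_equal(thick_ratio, 1.5, tolerance = 0.1)        # ~1.5x thickening
  expect_equal(st$lam_theta, 1, tolerance = 0.1)         # caliber preserved
  expect_gt(st$rho_c_ratio, 1)                           # collagen deposition
})

test_that("uniform elastin loss dilates the vessel and loses stored energy", {
  st <- solve_uniform(pars_fix, overrides = list(c_e = 0.7 * pars_fix$c_e),
                      baseline = base_fix)
  expect_gt(st$lam_theta, 1)
  expect_lt(st$W, 67.8)
  expect_lt(st$tau_ratio, 1)
})

test_that("equilibria are independent of the continuation path", {
  ov <- list(c_e = 0.5 * pars_fix$c_e, delta = 0.05)
  st10 <- solve_uniform(pars_fix, P = 1.3 * base_fix$P_o, overrides = ov,
                        config = uniform_solve_config(continuation_steps = 10),
                        baseline = base_fix)
  st50 <- solve_uniform(pars_fix, P = 1.3 * base_fix$P_o, overrides = ov,
                        config = uniform_solve_config(continuation_steps = 50),
                        baseline = base_fix)
  expect_equal(st10$lam_theta, st50$lam_theta, tolerance = 1e-6)
  expect_equal(st10$rho_c_ratio, st50$rho_c_ratio, tolerance = 1e-6)
})

test_that("mass-volume consistency holds at solved states", {
  for (ov in list(list(c_e = 40), list(delta = 0.08), list(eta = 1.05))) {
    st <- solve_uniform(pars_fix, overrides = ov, baseline = base_fix)
    expect_equal(st$J,
                 pars_fix$phi_e + pars_fix$phi_m * st$rho_m_ratio +
                   pars_fix$phi_c * st$rho_c_ratio, tolerance = 1e-10)
    expect_equal(st$rho_m_ratio, mass_coupling(st$rho_c_ratio, st$loc$eta),
                 tolerance = 1e-12)
    expect_equal(st$tau_ratio,
                 wall_shear_ratio(st$lam_theta * pars_fix$a_o, pars_fix$a_o),
                 tolerance = 1e-12)
  }
})

test_that("force-controlled axial mode holds the axial force", {
  st <- solve_uniform(pars_fix, P = 1.2 * base_fix$P_o,
                      config = uniform_solve_config(axial_mode = "force-controlled"),
                      baseline = base_fix)
  expect_false(isTRUE(all.equal(st$lam_z, 1)))
  pr0 <- gnreq:::point_response(1, 1, 1, gnreq:::resolve_local(pars_fix),
                                pars_fix, base_fix$P_o)
  f0 <- gnreq:::axial_force_kernel(pr0, 1, 1, pars_fix, base_fix$P_o)
  prh <- gnreq:::point_response(st$lam_theta, st$lam_z, st$rho_c_ratio,
                                st$loc, pars_fix, st$P)
  fh <- gnreq:::axial_force_kernel(prh, st$lam_theta, st$lam_z, pars_fix,
                                   st$P)
  expect_equal(fh, f0, tolerance = 1e-6 * abs(f0))
})

test_that("uniform-mode mechanosensing scan finds a critical delta", {
  # shear feedback stabilizes the uniform vessel, so its critical level is
  # far above the localized one; a low scan ceiling reports the
  # not-critical flag
  sc_low <- scan_delta_instability(pars_fix, delta_max = 0.2,
                                   resolution = 0.005, mode = "uniform")
  expect_false(sc_low$critical)
  expect_equal(sc_low$delta_critical, 0.2)
  sc <- scan_delta_instability(pars_fix, delta_max = 0.9,
                               resolution = 0.005, mode = "uniform")
  expect_true(sc$critical)
  expect_gt(sc$delta_critical, 0.2)
  expect_lt(sc$delta_critical, 0.9)
  # dilatation grows monotonically with delta below the critical value
  d_grid <- c(0.3, 0.6, 0.9) * sc$delta_critical
  lam <- vapply(d_grid, function(d)
    solve_uniform(pars_fix, overrides = list(delta = d),
                  baseline = base_fix)$lam_theta, numeric(1))
  expect_true(all(diff(lam) > 0))
})
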