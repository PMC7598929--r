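test_that("constituent energies match closed-form values and limits", {
  # elastin at its deposition stretches (independent arithmetic: 149.8135)
  expect_equal(elastin_stored_energy(89.71, c(1.90, 1.62, 1 / (1.90 * 1.62))),
               149.81351, tolerance = 1e-6)
  expect_equal(elastin_stored_energy(123, c(1, 1, 1)), 0)
  # linearity in c_e, including the damaged-modulus case
  expect_equal(elastin_stored_energy(0.38 * 89.71, c(1.90, 1.62, 0.3249)),
               0.38 * elastin_stored_energy(89.71, c(1.90, 1.62, 0.3249)))
  expect_error(elastin_stored_energy(89.71, c(1, -1, 1)), "invalid deformation")

  # collagen and passive muscle at their deposition stretches
  expect_equal(fiber_stored_energy(1.25, 234.9, 4.08), 37.943747,
               tolerance = 1e-6)
  expect_equal(fiber_stored_energy(1.20, 261.4, 0.24), 12.950291,
               tolerance = 1e-6)
  expect_equal(fiber_stored_energy(1.0, 500, 3), 0)
  # c2 -> 0 analytic limit
  expect_equal(fiber_stored_energy(1.3, 100, 0), 100 * (1.3^2 - 1)^2 / 4)
  expect_equal(fiber_stored_energy(1.3, 100, 1e-9),
               fiber_stored_energy(1.3, 100, 0), tolerance = 1e-6)
})

test_that("fiber stress matches lam * dW/dlam and is odd about lam = 1", {
  expect_equal(fiber_cauchy_stress(1.25, 234.9, 4.08), 750.7107,
               tolerance = 1e-6)
  expect_equal(fiber_cauchy_stress(1, 99, 9), 0)
  # central finite-difference oracle on the energy
  for (lam in c(0.9, 1.05, 1.2, 1.3)) {
    h <- 1e-6
    fd <- lam * (fiber_stored_energy(lam + h, 234.9, 4.08) -
                   fiber_stored_energy(lam - h, 234.9, 4.08)) / (2 * h)
    expect_equal(fiber_cauchy_stress(lam, 234.9, 4.08), fd,
                 tolerance = 1e-6)
  }
  expect_lt(fiber_cauchy_stress(0.9, 234.9, 4.08), 0)
})

test_that("equilibrated active stress reproduces tone values and knockout", {
  p <- mouse_dta_parameters()
  # C_B chosen so the basal tone is T_max/2
  expect_equal(equilibrated_active_stress(1, 0, p) /
                 (1 - ((p$lambda_M - 1) / (p$lambda_M - p$lambda_0))^2),
               125.00945, tolerance = 1e-6)
  expect_equal(equilibrated_active_stress(0.33, 0, p), 40.411217,
               tolerance = 1e-6)
  p0 <- mixture_parameters(T_max = 0)
  expect_equal(equilibrated_active_stress(0.33, -0.5, p0), 0)
  p_bad <- mouse_dta_parameters()
  p_bad$lambda_0 <- p_bad$lambda_M
  expect_error(equilibrated_active_stress(0.3, 0, p_bad), "lambda_M")
})

test_that("wall shear ratio follows the inverse-cube law exactly", {
  a_o <- 0.647
  expect_equal(wall_shear_ratio(1.1 * a_o, a_o), 0.7513148, tolerance = 1e-6)
  expect_equal(wall_shear_ratio(a_o, a_o), 1)
  expect_equal(wall_shear_ratio(a_o, a_o, Q_ratio = 2), 2)
  a <- seq(0.5, 2, by = 0.25) * a_o
  expect_equal(wall_shear_ratio(a, a_o, 1.3) * (a / a_o)^3,
               rep(1.3, length(a)))
  # strictly decreasing in the current radius
  expect_true(all(diff(wall_shear_ratio(a, a_o)) < 0))
})

test_that("stress stimulus is the mean stress, rotation invariant", {
  expect_equal(stress_stimulus(diag(c(-3, -3, -3))), -3)
  s <- diag(c(272, 257, -6))
  expect_equal(stress_stimulus(s), sum(c(272, 257, -6)) / 3)
  th <- 0.7
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(stress_stimulus(Q %*% s %*% t(Q)), stress_stimulus(s))
  expect_error(stress_stimulus(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
               "symmetric")
})

test_that("diagonal collagen reorients toward circumferential with stretch", {
  a0 <- 29.9 * pi / 180
  expect_equal(collagen_angle(1.3, 1.3, a0), a0)
  expect_equal(collagen_angle(1.2, 1.0, a0) * 180 / pi, 34.606863,
               tolerance = 1e-6)
  lt <- seq(0.8, 1.8, by = 0.1)
  ang <- collagen_angle(lt, 1, a0)
  expect_true(all(diff(ang) > 0))
  expect_equal(collagen_angle(1.5, 1, pi / 2), pi / 2)
})

test_that("mixture stress at baseline satisfies the membrane conditions", {
  st <- base_fix$state
  s <- mixture_stress(st, pars_fix)
  expect_equal(s, t(s))
  # radial condition fixes the multiplier
  expect_equal(s["r", "r"], -base_fix$P_o / 2, tolerance = 1e-10)
  # mid-wall Laplace: sigma_tt = P a/h by construction of P_o
  expect_equal(s["theta", "theta"],
               base_fix$P_o * pars_fix$a_o / pars_fix$h_o,
               tolerance = 1e-8)
  expect_equal(stress_stimulus(s), base_fix$sigma_o)
})

test_that("passive stress equals the energy derivative (frozen composition)", {
  # (2/J) F dW/dC F^T oracle via central differences of the stored energy of
  # a state at frozen composition, under diagonal elastic perturbations
  states <- list(
    base_fix$state,
    local_constitutive_update(1.2, 1.05, pars_fix, baseline = base_fix),
    local_constitutive_update(1.35, 0.98, pars_fix,
                              overrides = list(c_e = 60, delta = 0.05),
                              baseline = base_fix))
  for (st in states) {
    loc <- st$loc
    energy <- function(mu_t, mu_z, mu_r) {
      # per unit current volume of the unperturbed state, times the relative
      # volume (so this is energy per reference-of-perturbation volume)
      J <- st$J
      phi_e <- pars_fix$phi_e / J
      phi_m <- pars_fix$phi_m * st$rho_m_ratio / J
      phi_c <- pars_fix$phi_c * st$rho_c_ratio / J
      le <- c(pars_fix$G_theta_e * st$lam_theta * mu_t,
              pars_fix$G_z_e * st$lam_z * mu_z,
              pars_fix$G_r_e * (J / (st$lam_theta * st$lam_z)) * mu_r)
      a <- st$alpha_0h
      lam_d <- sqrt(mu_t^2 * sin(a)^2 + mu_z^2 * cos(a)^2)
      phi_e * loc$c_e / 2 * (sum(le^2) - 3) +
        phi_c * (pars_fix$beta_theta * fiber_stored_energy(loc$G_c * mu_t, loc$c1_c, loc$c2_c) +
                   pars_fix$beta_z * fiber_stored_energy(loc$G_c * mu_z, loc$c1_c, loc$c2_c) +
                   pars_fix$beta_d * fiber_stored_energy(loc$G_c * lam_d, loc$c1_c, loc$c2_c)) +
        phi_m * fiber_stored_energy(loc$G_m * mu_t, loc$c1_m, loc$c2_m)
    }
    s <- mixture_stress(st, pars_fix)
    p_mult <- s["r", "r"]  # -P/2; extra_r = sigma_rr + p
    h <- 1e-5
    # sigma_extra_ii = mu_i dW/dmu_i at mu = 1 (J_pert = 1 handled per axis)
    fd_t <- (energy(1 + h, 1, 1) - energy(1 - h, 1, 1)) / (2 * h)
    fd_z <- (energy(1, 1 + h, 1) - energy(1, 1 - h, 1)) / (2 * h)
    fd_r <- (energy(1, 1, 1 + h) - energy(1, 1, 1 - h)) / (2 * h)
    # remove the active part (not derivable from the stored energy)
    act <- equilibrated_active_stress(pars_fix$phi_m * st$rho_m_ratio / st$J,
                                      (1 - loc$xi) * st$tau_ratio - 1,
                                      modifyList(pars_fix,
                                                 list(T_max = loc$T_max)))
    # reconstruct total stresses: sigma_ii = extra_i (+ active) - p with the
    # multiplier p = extra_r + P/2 from the membrane radial condition
    p_h <- fd_r + st$P / 2
    expect_equal(s["theta", "theta"], fd_t + act - p_h, tolerance = 2e-5 * abs(fd_t))
    expect_equal(s["z", "z"], fd_z - p_h, tolerance = 2e-5 * max(abs(fd_z), 1))
    expect_equal(s["r", "r"], fd_r - p_h, tolerance = 1e-8)
  }
})

test_that("stored energy density: anchors, zeros, and damage linearity", {
  expect_equal(base_fix$state$W, 67.73162, tolerance = 1e-5)
  # all deposition stretches = 1 stores nothing at the reference state
  p1 <- mixture_parameters(G_theta_e = 1, G_z_e = 1, G_m = 1, G_c = 1)
  # an unstressed reference wall stores no energy
  st1 <- gnreq:::new_point_state(1, 1, 1, gnreq:::resolve_local(p1), p1, 0)
  expect_equal(st1$W, 0)
  # elastin damage d reduces W by exactly d * phi_e * What_e at fixed state
  d <- 0.4
  st_dam <- gnreq:::new_point_state(1, 1, 1,
                                    gnreq:::resolve_local(pars_fix,
                                                          list(c_e = (1 - d) * pars_fix$c_e)),
                                    pars_fix, base_fix$P_o)
  expect_equal(base_fix$state$W - st_dam$W,
               d * pars_fix$phi_e * 149.81351, tolerance = 1e-5)
})

test_that("circumferential stiffness matches its finite-difference oracle", {
  # d(J sigma_tt_passive)/d(eps) at frozen composition, the Kirchhoff-stress
  # derivative under a circumferential stretch increment
  kirchhoff_fd <- function(st, h = 1e-5) {
    loc <- st$loc
    sig_t <- function(mu_t) {
      J <- st$J
      phi_e <- pars_fix$phi_e / J
      phi_m <- pars_fix$phi_m * st$rho_m_ratio / J
      phi_c <- pars_fix$phi_c * st$rho_c_ratio / J
      a <- st$alpha_0h
      lam_d <- sqrt(mu_t^2 * sin(a)^2 + cos(a)^2)
      m_t2 <- mu_t^2 * sin(a)^2 / lam_d^2
      s_e <- loc$c_e * (pars_fix$G_theta_e * st$lam_theta * mu_t)^2
      s_c <- pars_fix$beta_theta *
        fiber_cauchy_stress(loc$G_c * mu_t, loc$c1_c, loc$c2_c) +
        pars_fix$beta_d * fiber_cauchy_stress(loc$G_c * lam_d, loc$c1_c, loc$c2_c) * m_t2
      s_m <- fiber_cauchy_stress(loc$G_m * mu_t, loc$c1_m, loc$c2_m)
      Jp <- mu_t  # det of diag(mu_t, 1, 1)
      (phi_e * s_e + phi_c * s_c + phi_m * s_m) / Jp * Jp  # Cauchy * J_pert
    }
    (sig_t(1 + h) - sig_t(1 - h)) / (2 * h)
  }
  expect_equal(base_fix$state$c_tttt, 1423.0611, tolerance = 1e-4)
  states <- list(base_fix$state,
                 local_constitutive_update(1.25, 1.1, pars_fix,
                                           baseline = base_fix),
                 local_constitutive_update(1.5, 1.0, pars_fix,
                                           overrides = list(c_e = 40),
                                           baseline = base_fix))
  for (st in states)
    expect_equal(material_stiffness_ctttt(st, pars_fix), kirchhoff_fd(st),
                 tolerance = 1e-4)
  # with all fiber fractions zero the elastin neo-Hookean closed form remains
  p_e <- mixture_parameters(phi_e = 1 - 2e-9, phi_m = 1e-9, phi_c = 1e-9)
  st_e <- gnreq:::new_point_state(1, 1, 1, gnreq:::resolve_local(p_e), p_e,
                                  homeostatic_baseline(p_e)$P_o)
  expect_equal(st_e$c_tttt, 2 * p_e$c_e * p_e$G_theta_e^2,
               tolerance = 1e-6)
})

test_that("stiffness linearization matches the oracle on random states", {
  set.seed(42)
  for (i in 1:25) {
    lam_t <- runif(1, 0.9, 1.6)
    lam_z <- runif(1, 0.9, 1.3)
    ov <- list(c_e = runif(1, 30, 90), delta = runif(1, 0, 0.1))
    st <- try(local_constitutive_update(lam_t, lam_z, pars_fix,
                                        overrides = ov, baseline = base_fix),
              silent = TRUE)
    if (inherits(st, "try-error")) next  # no local equilibrium there
    expect_gt(st$W, 0)
    s <- mixture_stress(st, pars_fix)
    expect_equal(s, t(s))
    expect_true(st$rho_c_ratio > 0 && st$rho_m_ratio > 0)
    expect_equal(st$J,
                 pars_fix$phi_e + pars_fix$phi_m * st$rho_m_ratio +
                   pars_fix$phi_c * st$rho_c_ratio,
                 tolerance = 1e-12)
  }
})
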