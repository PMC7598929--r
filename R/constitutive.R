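#' @title Constituent energies, stresses, and stiffness of the equilibrated mixture
#' @description
#' The wall is a constrained mixture of elastin-dominated matrix (neo-Hookean,
#' deposited with a fixed isochoric prestretch), four collagen fiber families
#' (circumferential, axial, two symmetric diagonals) and circumferential
#' smooth muscle (exponential fiber energies, each deposited at its deposition
#' stretch), plus shear-regulated active muscle tone.  At mechanobiological
#' equilibrium, turnover keeps every fiber family at its deposition stretch,
#' so mixture stress and energy become rules of mixtures over the *evolved*
#' mass fractions, while elastin (never produced in maturity) follows the
#' mixture deformation from the original homeostatic state.
#' @name constitutive
NULL

# ---------------------------------------------------------------------------
# Elementary constituent responses.  The private kernels are polymorphic over
# complex input (used for complex-step linearization); the exported wrappers
# validate real arguments.

fiber_energy_kernel <- function(lam, c1, c2) {
  e2 <- (lam^2 - 1)^2
  if (all(c2 != 0)) return(c1 / (4 * c2) * (exp(c2 * e2) - 1))
  n <- max(length(lam), length(c1), length(c2))
  lam <- rep_len(lam, n); c1 <- rep_len(c1, n)
  c2 <- rep_len(c2, n); e2 <- rep_len(e2, n)
  out <- lam * 0                       # preserves complex type
  z <- c2 == 0                         # analytic c2 -> 0 limit
  out[z] <- c1[z] * e2[z] / 4
  out[!z] <- c1[!z] / (4 * c2[!z]) * (exp(c2[!z] * e2[!z]) - 1)
  out
}

fiber_stress_kernel <- function(lam, c1, c2) {
  # Cauchy stress of an incompressible fiber: lam * dW/dlam
  c1 * lam^2 * (lam^2 - 1) * exp(c2 * (lam^2 - 1)^2)
}

# d(sigma_fiber)/d(lam) -- used by the analytic stiffness
fiber_stiffness_kernel <- function(lam, c1, c2) {
  # k = lam^2 W'' - lam W' evaluated at lam (frozen-composition tangent term)
  E <- exp(c2 * (lam^2 - 1)^2)
  Wp <- c1 * lam * (lam^2 - 1) * E
  Wpp <- c1 * E * ((3 * lam^2 - 1) + 4 * c2 * lam^2 * (lam^2 - 1)^2)
  lam^2 * Wpp - lam * Wp
}

#' Stored energy of the elastin-dominated matrix
#'
#' Neo-Hookean energy per unit current constituent volume,
#' `W = c_e/2 * (lam1^2 + lam2^2 + lam3^2 - 3)`, evaluated at the three
#' principal elastin stretches (mixture stretches times the elastin
#' deposition stretches).  Linear in `c_e`.
#'
#' @param c_e elastin shear modulus (kPa); a locally damaged value may be
#'   passed directly.
#' @param stretches numeric vector of the 3 principal elastin stretches.
#' @return energy density (kPa).
#' @export
#' @examples
#' elastin_stored_energy(89.71, c(1.90, 1.62, 1 / (1.90 * 1.62)))  # ~149.8
elastin_stored_energy <- function(c_e, stretches) {
  if (length(stretches) != 3L) stop("need exactly 3 principal stretches")
  if (any(!is.finite(stretches)) || any(stretches <= 0))
    stop("invalid deformation: elastin principal stretches must be positive")
  c_e / 2 * (sum(stretches^2) - 3)
}

#' Stored energy of a fiber family
#'
#' Exponential fiber energy `c1/(4 c2) * (exp(c2 (lam^2-1)^2) - 1)`; the
#' `c2 = 0` limit is the quadratic `c1 (lam^2-1)^2 / 4`.  Non-negative and
#' even in `(lam^2 - 1)`.
#'
#' @param lam fiber stretch (> 0), measured from the fiber's natural
#'   configuration.
#' @param c1 fiber modulus (kPa).
#' @param c2 dimensionless exponential constant.
#' @return energy density (kPa).
#' @export
fiber_stored_energy <- function(lam, c1, c2) {
  if (any(!is.finite(lam)) || any(lam <= 0)) stop("fiber stretch must be positive")
  fiber_energy_kernel(lam, c1, c2)
}

#' Uniaxial Cauchy stress of a fiber family
#'
#' `sigma = c1 lam^2 (lam^2 - 1) exp(c2 (lam^2-1)^2)`, i.e. `lam * dW/dlam`
#' for an incompressible fiber.  Its sign is the sign of `lam - 1`.
#'
#' @inheritParams fiber_stored_energy
#' @return fiber Cauchy stress contribution (kPa).
#' @export
fiber_cauchy_stress <- function(lam, c1, c2) {
  if (any(!is.finite(lam)) || any(lam <= 0)) stop("fiber stretch must be positive")
  fiber_stress_kernel(lam, c1, c2)
}

active_tone_kernel <- function(d_tau, T_max, C_B, C_S) {
  T_max * (1 - exp(-(C_B - C_S * d_tau)^2))
}

#' Equilibrated circumferential active stress of smooth muscle
#'
#' At mechanobiological equilibrium the active reference length has fully
#' adapted (`lam_theta_act = 1`), leaving
#' `sigma_act = phi_m * T(d_tau) * (1 - ((lambda_M - 1)/(lambda_M - lambda_0))^2)`
#' with the shear-mediated tone
#' `T(d_tau) = T_max (1 - exp(-(C_B - C_S d_tau)^2))`.
#'
#' @param phi_m_current evolved smooth muscle mass fraction (per current
#'   volume), in `[0, 1]`.
#' @param d_tau wall shear stress deviation `Delta tau_w` from homeostasis.
#' @param pars a [mixture_parameters()] object (uses `T_max`, `C_B`, `C_S`,
#'   `lambda_M`, `lambda_0`).
#' @return circumferential active Cauchy stress (kPa).
#' @export
equilibrated_active_stress <- function(phi_m_current, d_tau, pars) {
  if (any(phi_m_current < 0) || any(phi_m_current > 1))
    stop("phi_m_current must lie in [0, 1]")
  if (pars$lambda_M == pars$lambda_0)
    stop("invalid parameters: lambda_M must differ from lambda_0")
  parab <- 1 - ((pars$lambda_M - 1) / (pars$lambda_M - pars$lambda_0))^2
  phi_m_current * active_tone_kernel(d_tau, pars$T_max, pars$C_B, pars$C_S) * parab
}

#' Flow-induced wall shear stress ratio
#'
#' For constant (Poiseuille-like) flow, `tau_wh / tau_wo =
#' Q_ratio * (a_o / a_current)^3`: shear falls with the cube of the luminal
#' radius, so `wall_shear_ratio * (a/a_o)^3 = Q_ratio` exactly.
#'
#' @param a_current current luminal radius (mm).
#' @param a_o reference luminal radius (mm).
#' @param Q_ratio flow ratio `Q_h / Q_o`.
#' @return dimensionless shear ratio `tau_wh / tau_wo`.
#' @export
wall_shear_ratio <- function(a_current, a_o, Q_ratio = 1) {
  if (any(a_current <= 0) || any(a_o <= 0)) stop("radii must be positive")
  Q_ratio * (a_o / a_current)^3
}

#' Intramural stress stimulus
#'
#' The mechanobiological stimulus is the mean Cauchy stress
#' `sigma_v = tr(sigma)/3`, invariant under rotations of `sigma`.
#'
#' @param sigma symmetric 3x3 Cauchy stress (kPa).
#' @return mean stress (kPa).
#' @export
stress_stimulus <- function(sigma) {
  if (!is.matrix(sigma) || any(dim(sigma) != 3L))
    stop("sigma must be a 3x3 matrix")
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("sigma must be symmetric")
  sum(diag(sigma)) / 3
}

#' Deposition angle of remodeled diagonal collagen
#'
#' Newly synthesized diagonal collagen reorients with the in-plane
#' deformation, `tan(alpha_0h) = (lam_theta / lam_z) * tan(alpha_0o)`, with
#' the angle measured from the *axial* direction, so increasing
#' circumferential-to-axial stretch rotates fibers toward circumferential.
#' The two symmetric families remain mirror images about the axis.
#'
#' @param lam_theta,lam_z circumferential and axial mixture stretches from the
#'   original homeostatic configuration.
#' @param alpha_0o reference angle from the axial direction (rad); `pi/2` is
#'   treated as fixed circumferential.
#' @return evolved deposition angle `alpha_0h` (rad).
#' @export
collagen_angle <- function(lam_theta, lam_z, alpha_0o) {
  if (any(Re(lam_theta) <= 0) || any(Re(lam_z) <= 0))
    stop("stretches must be positive")
  if (isTRUE(all(alpha_0o == pi / 2))) return(rep(pi / 2, length(lam_theta)))
  atan(lam_theta / lam_z * tan(alpha_0o))
}

# ---------------------------------------------------------------------------
# Local parameter resolution.  `overrides` replaces any modifiable entry of
# the baseline parameter set; values may be vectors (one per material point).

local_overridable <- function() {
  c("c_e", "c1_c", "c2_c", "c1_m", "c2_m", "T_max", "delta", "xi", "eta",
    "K_ratio", "G_c", "G_m", "Q_ratio")
}

resolve_local <- function(pars, overrides = list()) {
  bad <- setdiff(names(overrides), local_overridable())
  if (length(bad))
    stop("cannot override parameter locally: ", bad[[1L]], call. = FALSE)
  loc <- pars[local_overridable()]
  for (nm in names(overrides)) loc[[nm]] <- overrides[[nm]]
  loc
}

# ---------------------------------------------------------------------------
# Mixture point response at mechanobiological equilibrium.
#
# Inputs may be vectors over material points and may be complex (for
# complex-step differentiation); no non-analytic operation is used.
#   lam_t, lam_z : mixture stretches from the original homeostatic state
#   rho_c        : referential collagen density ratio rho_Rh^c / rho_o^c
#   loc          : resolved local parameters (resolve_local)
#   pars         : baseline gnr_parameters (reference c_e for elastin damage)
#   P            : transmural pressure (kPa)
# Returns extra (constituent) stresses, multiplier, stimulus, energy, and the
# kinematic bookkeeping.  sigma_rr is fixed at -P/2 (mid-wall membrane value)
# through the Lagrange multiplier p.
point_response <- function(lam_t, lam_z, rho_c, loc, pars, P) {
  # Elastin damage is a loss of load-bearing integrity at preserved volume:
  # the local modulus loc$c_e falls but the elastin-dominated matrix keeps
  # occupying its reference volume fraction in J.
  g_e <- loc$c_e / pars$c_e                 # elastin integrity fraction
  rho_m <- rho_c^loc$eta
  J <- pars$phi_e + pars$phi_m * rho_m + pars$phi_c * rho_c
  lam_r <- J / (lam_t * lam_z)

  phi_e_h <- pars$phi_e / J
  phi_m_h <- pars$phi_m * rho_m / J
  phi_c_h <- pars$phi_c * rho_c / J

  # elastin (uses the undamaged modulus; damage is carried by g_e)
  le_t <- pars$G_theta_e * lam_t
  le_z <- pars$G_z_e * lam_z
  le_r <- pars$G_r_e * lam_r
  se_t <- loc$c_e * le_t^2
  se_z <- loc$c_e * le_z^2
  se_r <- loc$c_e * le_r^2

  # collagen families, equilibrated at the (possibly insulted) deposition
  # stretch; diagonal families at the evolved angle alpha_0h
  alpha <- atan(lam_t / lam_z * tan(pars$alpha_0o))
  s2 <- sin(alpha)^2
  c2a <- cos(alpha)^2
  sc <- fiber_stress_kernel(loc$G_c, loc$c1_c, loc$c2_c)
  sm <- fiber_stress_kernel(loc$G_m, loc$c1_m, loc$c2_m)

  # shear and active tone (local deformed radius a_h = lam_t * a_o)
  tau_ratio <- loc$Q_ratio / lam_t^3
  d_tau <- (1 - loc$xi) * tau_ratio - 1
  parab <- 1 - ((pars$lambda_M - 1) / (pars$lambda_M - pars$lambda_0))^2
  Tact <- active_tone_kernel(d_tau, loc$T_max, pars$C_B, pars$C_S)
  s_act <- phi_m_h * Tact * parab

  extra_t <- phi_e_h * se_t + phi_c_h * (pars$beta_theta + pars$beta_d * s2) * sc +
    phi_m_h * sm + s_act
  extra_z <- phi_e_h * se_z + phi_c_h * (pars$beta_z + pars$beta_d * c2a) * sc
  extra_r <- phi_e_h * se_r

  p <- extra_r + P / 2                       # sigma_rr = -P/2 at mid-wall
  sigma_v <- (extra_t + extra_z + extra_r) / 3 - p

  # stored energy per unit current volume (rule of mixtures)
  We <- loc$c_e / 2 * (le_t^2 + le_z^2 + le_r^2 - 3)
  Wc <- fiber_energy_kernel(loc$G_c, loc$c1_c, loc$c2_c)
  Wm <- fiber_energy_kernel(loc$G_m, loc$c1_m, loc$c2_m)
  W <- phi_e_h * We + phi_c_h * Wc + phi_m_h * Wm

  list(extra_t = extra_t, extra_z = extra_z, extra_r = extra_r,
       p = p, sigma_v = sigma_v, W = W,
       J = J, lam_r = lam_r, alpha = alpha,
       g_e = g_e, rho_m = rho_m,
       phi_e_h = phi_e_h, phi_m_h = phi_m_h, phi_c_h = phi_c_h,
       tau_ratio = tau_ratio, d_tau = d_tau, s_act = s_act,
       sc = sc, sm = sm, s2 = s2)
}

# ---------------------------------------------------------------------------
# Equilibrated point state object

new_point_state <- function(lam_t, lam_z, rho_c, loc, pars, P) {
  pr <- point_response(lam_t, lam_z, rho_c, loc, pars, P)
  sigma <- diag(c(pr$extra_t - pr$p, pr$extra_z - pr$p, pr$extra_r - pr$p))
  dimnames(sigma) <- list(c("theta", "z", "r"), c("theta", "z", "r"))
  st <- list(lam_theta = lam_t, lam_z = lam_z, J = pr$J,
             rho_c_ratio = rho_c, rho_m_ratio = pr$rho_m,
             rho_e_ratio = 1, elastin_integrity = pr$g_e,
             alpha_0h = pr$alpha, sigma = sigma, sigma_v = pr$sigma_v,
             W = pr$W, tau_ratio = pr$tau_ratio, P = P,
             loc = loc)
  st$c_tttt <- stiffness_from_response(pr, loc, pars, include_active = FALSE)
  class(st) <- "gnr_point_state"
  st
}

#' @export
print.gnr_point_state <- function(x, ...) {
  cat("Equilibrated material point state\n")
  cat(sprintf("  lam_theta = %.4f, lam_z = %.4f, J = %.4f\n",
              x$lam_theta, x$lam_z, x$J))
  cat(sprintf("  rho ratios: e = %.4f, m = %.4f, c = %.4f\n",
              x$rho_e_ratio, x$rho_m_ratio, x$rho_c_ratio))
  cat(sprintf("  alpha_0h = %.2f deg, tau_wh/tau_wo = %.4f\n",
              x$alpha_0h * 180 / pi, x$tau_ratio))
  cat(sprintf("  sigma_v = %.2f kPa, W = %.2f kPa, c_tttt = %.1f kPa\n",
              x$sigma_v, x$W, x$c_tttt))
  invisible(x)
}

#' Mixture Cauchy stress at an equilibrated state
#'
#' Rule-of-mixtures Cauchy stress
#' `sigma = sum_a phi_h^a sigma_hat^a + phi_h^m sigma_act - p I`, with evolved
#' mass fractions `phi_h^a = phi_o^a rho^a / J`, collagen assembled over the
#' four families (diagonals at the evolved angle), and the Lagrange
#' multiplier fixed by the membrane radial condition `sigma_rr = -P/2` at
#' mid-wall.  Axes are (circumferential, axial, radial).
#'
#' @param state a `gnr_point_state` (from [solve_uniform()] or
#'   [local_constitutive_update()]).
#' @param pars baseline parameters.
#' @param P transmural pressure (kPa); defaults to the pressure stored in the
#'   state.
#' @return symmetric 3x3 Cauchy stress matrix (kPa).
#' @export
mixture_stress <- function(state, pars, P = state$P) {
  pr <- point_response(state$lam_theta, state$lam_z, state$rho_c_ratio,
                       state$loc, pars, P)
  comps <- c(pr$extra_t - pr$p, pr$extra_z - pr$p, pr$extra_r - pr$p)
  if (any(!is.finite(comps)))
    stop("non-finite stress for state: lam_theta = ", state$lam_theta,
         ", lam_z = ", state$lam_z, ", rho_c = ", state$rho_c_ratio)
  sigma <- diag(comps)
  dimnames(sigma) <- list(c("theta", "z", "r"), c("theta", "z", "r"))
  sigma
}

#' Stored energy density of the mixture
#'
#' `W = sum_a phi_h^a What^a`, per unit *current* volume, with fiber
#' constituents at their deposition stretches (equilibrated turnover) and
#' elastin at the mixture deformation from the original homeostatic state.
#'
#' @inheritParams mixture_stress
#' @return energy density (kPa).
#' @export
stored_energy_density <- function(state, pars) {
  pr <- point_response(state$lam_theta, state$lam_z, state$rho_c_ratio,
                       state$loc, pars, state$P)
  pr$W
}

stiffness_from_response <- function(pr, loc, pars, include_active = FALSE) {
  kc <- fiber_stiffness_kernel(loc$G_c, loc$c1_c, loc$c2_c)
  km <- fiber_stiffness_kernel(loc$G_m, loc$c1_m, loc$c2_m)
  fiber_term <- pr$phi_c_h * (pars$beta_theta + pars$beta_d * pr$s2^2) * kc +
    pr$phi_m_h * km
  passive_t <- pr$extra_t - pr$s_act
  ct <- 2 * passive_t + fiber_term
  if (include_active) ct <- ct + 2 * pr$s_act
  ct
}

#' Circumferential material stiffness of the mixture
#'
#' Small-on-large linearization of the mixture response about the current
#' loaded state at *frozen composition*: the circumferential-circumferential
#' component of the spatial elasticity tensor,
#' `c_tttt = 2 sigma_theta^passive + sum_fam phi_h k(G) m_theta^4` with
#' `k(lam) = lam^2 W'' - lam W'` per fiber family (fibers sit at their
#' deposition stretches at equilibrium) and the elastin part reducing to its
#' neo-Hookean closed form.  Equivalently the derivative of the Kirchhoff
#' stress with respect to an imposed circumferential stretch increment at
#' frozen composition.  Active tone is excluded by default (it enters the
#' stress state, not the stiffness map); `include_active` adds its geometric
#' `2 sigma_act` term.
#'
#' @inheritParams mixture_stress
#' @param include_active include the active-stress geometric term.
#' @return stiffness component (kPa).
#' @export
material_stiffness_ctttt <- function(state, pars, include_active = FALSE) {
  pr <- point_response(state$lam_theta, state$lam_z, state$rho_c_ratio,
                       state$loc, pars, state$P)
  ct <- stiffness_from_response(pr, state$loc, pars, include_active)
  if (!is.finite(ct) || ct <= 0)
    stop("singular or invalid linearization at this state")
  ct
}
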