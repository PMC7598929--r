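#' @title Coupled mechanical and mechanobiological equilibrium at a point
#' @description
#' The rate-independent growth-and-remodeling solve: at every accepted state,
#' mass production balances removal (`Upsilon = 1`), which reduces to the
#' scalar residual `Delta sigma - K_ratio * Delta tau_w = 0` with
#' `Delta sigma = ((1 - delta) sigma_v - sigma_o)/sigma_o` and
#' `Delta tau_w = (1 - xi) tau_wh/tau_wo - 1`.  Only the gain *ratio*
#' `K_tauw/K_sigma` enters; removal-rate constants of the transient theory do
#' not appear anywhere in the equilibrated solution.
#' @name local_equilibrium
NULL

#' Solver settings for uniform (0-D) equilibrated solves
#'
#' @param newton_tol dimensionless residual tolerance.
#' @param max_iter maximum Newton iterations per continuation step.
#' @param continuation_steps number of quasi-static increments from the
#'   baseline to the full insult/load (10, with step halving on divergence).
#' @param max_halvings maximum continuation step halvings before declaring
#'   that no equilibrium exists.
#' @param axial_mode `"fixed-ends"` (axial stretch held at 1, as when axial
#'   displacements are fixed at both ends) or `"force-controlled"` (axial
#'   stretch free, total axial force held at its baseline value).
#' @return a `gnr_solve_config` list.
#' @export
uniform_solve_config <- function(newton_tol = 1e-10, max_iter = 50,
                                 continuation_steps = 10, max_halvings = 5,
                                 axial_mode = c("fixed-ends", "force-controlled")) {
  stopifnot(newton_tol > 0, continuation_steps >= 1)
  structure(list(newton_tol = newton_tol, max_iter = max_iter,
                 continuation_steps = continuation_steps,
                 max_halvings = max_halvings,
                 axial_mode = match.arg(axial_mode)),
            class = "gnr_solve_config")
}

#' Smooth-muscle-to-collagen mass coupling
#'
#' Equilibrated referential densities inherit the turnover-rate ratio of the
#' transient theory as the power law `rho_m_ratio = rho_c_ratio^eta`.
#'
#' @param rho_c_ratio referential collagen density ratio (> 0).
#' @param eta smooth-muscle-to-collagen turnover ratio.
#' @return smooth muscle referential density ratio.
#' @export
mass_coupling <- function(rho_c_ratio, eta) {
  if (any(rho_c_ratio <= 0)) stop("rho_c_ratio must be positive")
  rho_c_ratio^eta
}

#' Original homeostatic baseline state
#'
#' Constructs the reference in vivo state (mixture stretches 1, density
#' ratios 1, constituents at their deposition stretches), derives the
#' homeostatic pressure `P_o` as the value that equilibrates the baseline
#' constitutive stress through the mid-wall Laplace relation
#' `P_o = (sigma_hat_tt - sigma_hat_rr) / (a_o/h_o + 1/2)` (the 1/2 comes
#' from the radial condition `sigma_rr = -P/2`), and records the stimulus
#' setpoints `sigma_o = tr(sigma)/3` and `tau_wo` (ratio 1).  This state is an
#' exact root of both the mechanical and the mechanobiological residuals.
#'
#' @param pars a [mixture_parameters()] object.
#' @return list with elements `state` (a `gnr_point_state`), `P_o` (kPa),
#'   `sigma_o` (kPa), and `tau_wo` (= 1), of class `gnr_baseline`.
#' @export
homeostatic_baseline <- function(pars) {
  validate_parameters(pars)
  loc <- resolve_local(pars)
  pr <- point_response(1, 1, 1, loc, pars, P = 0)
  P_o <- (pr$extra_t - pr$extra_r) / (pars$a_o / pars$h_o + 0.5)
  if (!is.finite(P_o) || P_o <= 0)
    stop("configuration error: baseline parameters admit no positive homeostatic pressure")
  state <- new_point_state(1, 1, 1, loc, pars, P_o)
  structure(list(state = state, P_o = P_o, sigma_o = state$sigma_v,
                 tau_wo = 1), class = "gnr_baseline")
}

#' @export
print.gnr_baseline <- function(x, ...) {
  cat(sprintf("Homeostatic baseline: P_o = %.3f kPa (%.1f mmHg), sigma_o = %.2f kPa, tau_wo = %g\n",
              x$P_o, x$P_o / 0.133322, x$sigma_o, x$tau_wo))
  cat(sprintf("  W_o = %.2f kPa, c_tttt,o = %.1f kPa\n", x$state$W, x$state$c_tttt))
  invisible(x)
}

#' Mechanobiological equilibrium residual
#'
#' `Delta sigma - K_ratio * Delta tau_w`, zero at mechanobiological
#' equilibrium, with the dysfunction fractions `delta` (intramural
#' mechanosensing) and `xi` (endothelial shear sensing) attenuating the
#' sensed stimuli.
#'
#' @param state a `gnr_point_state`.
#' @param pars baseline parameters.
#' @param baseline a [homeostatic_baseline()] object (recomputed if omitted).
#' @return dimensionless scalar residual.
#' @export
mechanobiological_residual <- function(state, pars,
                                       baseline = homeostatic_baseline(pars)) {
  if (baseline$sigma_o == 0) stop("configuration error: sigma_o is zero")
  loc <- state$loc
  d_sig <- ((1 - loc$delta) * state$sigma_v - baseline$sigma_o) / baseline$sigma_o
  d_tau <- (1 - loc$xi) * state$tau_ratio / baseline$tau_wo - 1
  d_sig - loc$K_ratio * d_tau
}

# ---------------------------------------------------------------------------
# Vectorized residual kernels shared by the 0-D and FEM solvers.

mb_residual_kernel <- function(pr, loc, sigma_o) {
  ((1 - loc$delta) * pr$sigma_v - sigma_o) / sigma_o -
    loc$K_ratio * pr$d_tau
}

# Circumferential (Laplace) equilibrium of the uniform cylinder:
# sigma_tt - sigma_rr = P a_h / h_h with a_h = lam_t a_o, h_h = J h_o/(lam_t lam_z)
mech_residual_kernel <- function(pr, lam_t, lam_z, pars, P, sigma_o) {
  (pr$extra_t - pr$extra_r - P / 2 -
     P * lam_t^2 * lam_z * pars$a_o / (pr$J * pars$h_o)) / sigma_o
}

axial_force_kernel <- function(pr, lam_t, lam_z, pars, P) {
  # total axial force carried by the wall (per 2*pi), at mid-wall radius
  (pr$extra_z - pr$p) * (pr$J * pars$h_o / (lam_t * lam_z)) * (lam_t * pars$a_o)
}

no_equilibrium <- function(msg) {
  stop(structure(class = c("gnr_no_equilibrium", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Solve the uniform (0-D) equilibrated growth-and-remodeling problem
#'
#' Newton solve for the circumferential stretch and referential collagen
#' density of a uniform cylindrical segment under pressure `P`, satisfying
#' simultaneously (i) circumferential (Laplace) mechanical equilibrium with
#' wall thickness `h = J h_o/(lam_theta lam_z)` and (ii) the
#' mechanobiological residual, with smooth muscle mass slaved by
#' [mass_coupling()], elastin mass fixed at its (possibly damaged) survival
#' fraction, the volume ratio from mass--volume consistency, wall shear from
#' the deformed luminal radius, and diagonal collagen at the evolved angle.
#' The insult and pressure are ramped quasi-statically over
#' `config$continuation_steps` increments with step halving on divergence;
#' exhaustion of halvings signals a classed `gnr_no_equilibrium` error
#' (a mechanobiological static instability).
#'
#' @param pars baseline parameters.
#' @param P target transmural pressure (kPa); default: derived `P_o`.
#' @param Q_ratio flow ratio.
#' @param overrides named list of local parameter values encoding the insult
#'   (e.g. `list(c_e = 34.1)`, `list(delta = 0.1)`); see
#'   [mixture_parameters()] names.
#' @param config a [uniform_solve_config()].
#' @param baseline precomputed [homeostatic_baseline()] (optional).
#' @return converged `gnr_point_state` (with `P` and local parameters
#'   attached).
#' @export
#' @examples
#' pars <- mouse_dta_parameters()
#' st <- solve_uniform(pars)          # homeostatic fixed point
#' st$lam_theta                       # 1
solve_uniform <- function(pars, P = NULL, Q_ratio = 1, overrides = list(),
                          config = uniform_solve_config(),
                          baseline = homeostatic_baseline(pars)) {
  if (is.null(P)) P <- baseline$P_o
  if (!is.null(overrides$Q_ratio)) Q_ratio <- overrides$Q_ratio
  overrides$Q_ratio <- Q_ratio
  loc_target <- resolve_local(pars, overrides)
  loc_base <- resolve_local(pars)
  sigma_o <- baseline$sigma_o
  axial_free <- config$axial_mode == "force-controlled"
  f_z_o <- NULL
  if (axial_free) {
    pr0 <- point_response(1, 1, 1, loc_base, pars, baseline$P_o)
    f_z_o <- axial_force_kernel(pr0, 1, 1, pars, baseline$P_o)
  }

  blend <- function(t) {
    loc <- loc_base
    for (nm in names(loc)) loc[[nm]] <- loc_base[[nm]] + t * (loc_target[[nm]] - loc_base[[nm]])
    list(loc = loc, P = baseline$P_o + t * (P - baseline$P_o))
  }

  resid <- function(x, loc, Pt) {
    lam_t <- x[1L]; rho_c <- x[2L]
    lam_z <- if (axial_free) x[3L] else 1
    if (!all(is.finite(x)) || lam_t <= 0.05 || lam_t > 50 ||
        rho_c <= 1e-8 || rho_c > 1e4 || lam_z <= 0.05)
      return(rep(NA_real_, length(x)))
    pr <- point_response(lam_t, lam_z, rho_c, loc, pars, Pt)
    out <- c(mech_residual_kernel(pr, lam_t, lam_z, pars, Pt, sigma_o),
             mb_residual_kernel(pr, loc, sigma_o))
    if (axial_free)
      out <- c(out, (axial_force_kernel(pr, lam_t, lam_z, pars, Pt) - f_z_o) /
                 (abs(f_z_o) + 1e-12))
    out
  }

  newton <- function(x, loc, Pt) {
    for (it in seq_len(config$max_iter)) {
      r <- resid(x, loc, Pt)
      if (any(!is.finite(r))) return(NULL)
      if (max(abs(r)) < config$newton_tol) return(x)
      n <- length(x)
      Jm <- matrix(0, n, n)
      for (j in seq_len(n)) {
        hstep <- 1e-7 * max(1, abs(x[j]))
        xp <- x; xp[j] <- xp[j] + hstep
        rp <- resid(xp, loc, Pt)
        if (any(!is.finite(rp))) return(NULL)
        Jm[, j] <- (rp - r) / hstep
      }
      dx <- tryCatch(solve(Jm, -r), error = function(e) NULL)
      if (is.null(dx) || any(!is.finite(dx))) return(NULL)
      # damp very large updates to stay in the admissible region
      scale <- max(1, max(abs(dx)) / 0.5)
      x <- x + dx / scale
    }
    r <- resid(x, loc, Pt)
    if (all(is.finite(r)) && max(abs(r)) < config$newton_tol) x else NULL
  }

  x <- c(1, 1, if (axial_free) 1)
  t_now <- 0
  dt0 <- 1 / config$continuation_steps
  dt <- dt0
  halvings <- 0L                      # consecutive failures at the current front
  while (t_now < 1 - 1e-12) {
    t_try <- min(1, t_now + dt)
    b <- blend(t_try)
    sol <- newton(x, b$loc, b$P)
    if (is.null(sol)) {
      halvings <- halvings + 1L
      dt <- dt / 2
      if (halvings > config$max_halvings)
        no_equilibrium(sprintf(
          "no mechanobiologically equilibrated solution beyond continuation fraction %.3f",
          t_now))
      next
    }
    x <- sol
    t_now <- t_try
    halvings <- 0L
    dt <- min(dt * 2, dt0)            # recover the nominal step after success
  }
  lam_z <- if (axial_free) x[3L] else 1
  st <- new_point_state(x[1L], lam_z, x[2L], blend(1)$loc, pars, P)
  if (min(st$rho_c_ratio, st$rho_m_ratio, st$rho_e_ratio) < 0)
    stop("model breakdown: negative constituent mass")
  st
}

#' Critical mechanosensing dysfunction by bisection
#'
#' Scans the mechanosensing parameter `delta` for the largest value that
#' still admits a converged mechanobiologically equilibrated solution;
#' beyond it, dilatation is unbounded (a mechanobiological static
#' instability).  The default probes a localized axisymmetric lesion
#' (the membrane finite-element solve with the standard insult profile on
#' `delta`, end value 0); `mode = "uniform"` scans the uniform 0-D problem
#' instead.
#'
#' @param pars baseline parameters.
#' @param delta_max upper end of the scan.
#' @param resolution bisection resolution (must be <= 0.005).
#' @param mode `"fem"` (localized lesion) or `"uniform"`.
#' @param n_elem mesh resolution for the FEM probe.
#' @param nu_z,z_od insult profile decay exponent and deviation (mm).
#' @param config solver settings (a [uniform_solve_config()]; for the FEM
#'   probe its tolerances are mapped onto [fem_solve_config()]).
#' @return list with `delta_critical` (largest converged value, reported on
#'   the resolution grid), `critical` (logical: FALSE when no failure was
#'   found below `delta_max`), and `probes` (data.frame of tested values).
#' @export
scan_delta_instability <- function(pars, delta_max = 0.25, resolution = 0.005,
                                   mode = c("fem", "uniform"),
                                   n_elem = 20, nu_z = 5, z_od = 3,
                                   config = NULL) {
  stopifnot(resolution <= 0.005, resolution > 0, delta_max > 0)
  mode <- match.arg(mode)
  baseline <- homeostatic_baseline(pars)
  probe <- if (mode == "uniform") {
    cfg <- if (is.null(config)) uniform_solve_config(max_halvings = 3) else config
    function(delta) {
      tryCatch({
        solve_uniform(pars, overrides = list(delta = delta), config = cfg,
                      baseline = baseline)
        TRUE
      }, gnr_no_equilibrium = function(e) FALSE)
    }
  } else {
    # plain Newton--Raphson load stepping: the instability threshold is the
    # largest delta whose equilibrated solve still converges without
    # path-following
    cfg <- if (is.null(config))
      fem_solve_config(max_halvings = 3, arc_length = FALSE) else config
    mesh <- build_mesh(pars, n_elem = n_elem)
    function(delta) {
      spec <- scenario_spec("mechanosensing", severity = "custom",
                            value = delta, nu_z = nu_z, z_od = z_od)
      res <- run_scenario(spec, pars, config = cfg, mesh = mesh,
                          baseline = baseline)
      isTRUE(res$converged)
    }
  }

  probes <- data.frame(delta = numeric(0), converged = logical(0))
  note <- function(d, ok) probes <<- rbind(probes, data.frame(delta = d, converged = ok))

  if (probe(delta_max)) {
    note(delta_max, TRUE)
    return(list(delta_critical = delta_max, critical = FALSE, probes = probes))
  }
  note(delta_max, FALSE)
  lo <- 0; hi <- delta_max
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    ok <- probe(mid)
    note(mid, ok)
    if (ok) lo <- mid else hi <- mid
  }
  list(delta_critical = round(lo / resolution) * resolution,
       critical = TRUE, probes = probes)
}
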