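#' @title Spatial insult fields
#' @description
#' Gaussian-like axial (and optionally circumferential) profiles that assign
#' any controlled parameter its local value along the segment, used to
#' prescribe localized losses of cell or matrix function while keeping the
#' end regions at their baseline values.
#' @name insult_fields
NULL

#' Specify a spatial insult profile for one parameter
#'
#' The axisymmetric profile is
#' `theta(z) = theta_end + (theta_central - theta_end) *
#' exp(-|(z - l_o/2)/z_od|^nu_z)`; the asymmetric variant multiplies a second
#' circumferential factor with apex at `theta_o = pi`.  The field is
#' continuous, bounded between the end and central/apex values, and symmetric
#' about the lesion center.
#'
#' @param parameter_name which parameter entry the field modulates (one of
#'   the locally overridable names, e.g. `"c_e"`, `"delta"`, `"K_ratio"`).
#' @param theta_end parameter value near the ends (defaults to the baseline
#'   value in scenario builders).
#' @param theta_central parameter value at the lesion center / apex.
#' @param nu_z axial decay exponent (> 0).
#' @param z_od axial deviation (mm), in `(0, l_o/2]`.
#' @param nu_theta,theta_od circumferential decay exponent and deviation
#'   (rad), used only when `symmetric = FALSE`.
#' @param symmetric axisymmetric (`TRUE`) or axially-and-circumferentially
#'   localized (`FALSE`).
#' @param l_o segment length (mm).
#' @return an `insult_field_spec` object.
#' @export
insult_field_spec <- function(parameter_name, theta_end, theta_central,
                              nu_z = 5, z_od = 3,
                              nu_theta = 5, theta_od = pi / 3,
                              symmetric = TRUE, l_o = 15) {
  stopifnot(nu_z > 0, z_od > 0, z_od <= l_o / 2)
  if (!symmetric) stopifnot(nu_theta > 0, theta_od > 0, theta_od <= pi)
  structure(list(parameter_name = parameter_name, theta_end = theta_end,
                 theta_central = theta_central, nu_z = nu_z, z_od = z_od,
                 nu_theta = nu_theta, theta_od = theta_od,
                 symmetric = symmetric, l_o = l_o),
            class = "insult_field_spec")
}

#' Evaluate the axisymmetric insult profile
#'
#' @param z_o reference axial coordinate(s), in `[0, l_o]`.
#' @param spec an [insult_field_spec()].
#' @return local parameter value(s).
#' @export
axisymmetric_field <- function(z_o, spec) {
  stopifnot(inherits(spec, "insult_field_spec"))
  if (any(z_o < -1e-9) || any(z_o > spec$l_o + 1e-9))
    stop("z_o must lie in [0, l_o]")
  w <- exp(-abs((z_o - spec$l_o / 2) / spec$z_od)^spec$nu_z)
  spec$theta_end + (spec$theta_central - spec$theta_end) * w
}

#' Evaluate the asymmetric insult profile
#'
#' Product of axial and circumferential Gaussian-like factors with apex at
#' `(l_o/2, pi)`.  When `spec$symmetric` is `TRUE` the circumferential factor
#' is dropped and the field is independent of `theta_o`.
#'
#' @param z_o reference axial coordinate(s) (mm).
#' @param theta_o reference azimuth(s), in `[0, 2*pi]`.
#' @param spec an [insult_field_spec()].
#' @return local parameter value(s).
#' @export
asymmetric_field <- function(z_o, theta_o, spec) {
  stopifnot(inherits(spec, "insult_field_spec"))
  if (any(theta_o < -1e-9) || any(theta_o > 2 * pi + 1e-9))
    stop("theta_o must lie in [0, 2*pi]")
  wz <- exp(-abs((z_o - spec$l_o / 2) / spec$z_od)^spec$nu_z)
  if (spec$symmetric) {
    v <- spec$theta_end + (spec$theta_central - spec$theta_end) * wz
    return(rep_len(v, max(length(z_o), length(theta_o))))
  }
  wt <- exp(-abs((theta_o - pi) / spec$theta_od)^spec$nu_theta)
  spec$theta_end + (spec$theta_central - spec$theta_end) * wz * wt
}

#' End-region regularization profiles
#'
#' Shear-mediated matrix turnover is confined to the non-aneurysmal end
#' segments: localized scenarios therefore carry a gain-ratio field with the
#' baseline value at the ends and zero at the lesion center, together with a
#' smooth-muscle-to-collagen turnover-ratio field whose end value keeps the
#' ends homeostatic.  In the equilibrated model an insult-free end with
#' baseline parameters is exactly homeostatic, so the defaults are the
#' baseline `K_ratio` and `eta = 1` at the ends; non-default end values can
#' be solved for against the 0-D homeostatic residual via
#' `solve_end = TRUE`.
#'
#' @param pars baseline parameters.
#' @param K_end,K_central end/central values of the shear-to-intramural gain
#'   ratio (defaults: baseline and 0).
#' @param eta_end,eta_central end/central values of the turnover ratio.
#' @param nu_z,z_od shared profile shape parameters.
#' @param solve_end verify/solve the end values so that the 0-D equilibrium
#'   at `z = 0` reproduces the baseline state (root of the homeostatic
#'   residual); with baseline end parameters this is an identity.
#' @return list with `K_ratio` and `eta` [insult_field_spec()]s.
#' @export
end_region_profiles <- function(pars, K_end = pars$K_ratio, K_central = 0,
                                eta_end = pars$eta, eta_central = pars$eta,
                                nu_z = 5, z_od = 3, solve_end = FALSE) {
  if (solve_end) {
    baseline <- homeostatic_baseline(pars)
    st <- solve_uniform(pars, overrides = list(K_ratio = K_end, eta = eta_end),
                        baseline = baseline)
    if (abs(st$lam_theta - 1) > 1e-8 || abs(st$rho_c_ratio - 1) > 1e-8)
      stop("end values do not keep the end region homeostatic")
  }
  list(K_ratio = insult_field_spec("K_ratio", K_end, K_central,
                                   nu_z = nu_z, z_od = z_od, l_o = pars$l_o),
       eta = insult_field_spec("eta", eta_end, eta_central,
                               nu_z = nu_z, z_od = z_od, l_o = pars$l_o))
}
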