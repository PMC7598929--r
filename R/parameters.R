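#' Constitutive and geometric parameters of the aortic mixture
#'
#' Constructs the full parameter set of the constrained-mixture wall model:
#' reference geometry, homeostatic mass fractions, collagen fiber-family
#' fractions and orientation, material constants, deposition (pre-)stretches,
#' turnover couplings, mechanosensing/endothelial dysfunction fractions, and
#' vasoactive constants.  The defaults reproduce the literature baseline for a
#' non-aneurysmal descending thoracic aorta of a wild-type male mouse
#' (homogenized through the wall thickness), which [mouse_dta_parameters()]
#' returns unchanged.
#'
#' Units are kPa and mm throughout; angles are stored in radians.
#'
#' @param a_o reference luminal radius (mm).
#' @param h_o reference wall thickness (mm).
#' @param l_o reference segment length (mm).
#' @param phi_e,phi_m,phi_c homeostatic mass fractions of elastin-dominated
#'   matrix, smooth muscle, and collagen-dominated matrix (must sum to 1).
#' @param beta_theta,beta_z,beta_d collagen family fractions (circumferential,
#'   axial, both symmetric diagonal families together; must sum to 1).
#' @param alpha_0o reference diagonal fiber angle, measured from the axial
#'   direction (rad).
#' @param c_e elastin shear modulus (kPa).
#' @param c1_m,c2_m,c1_c,c2_c fiber material constants for passive smooth
#'   muscle and collagen (kPa, dimensionless).
#' @param G_theta_e,G_z_e elastin deposition stretches (circumferential,
#'   axial); the radial one is `1/(G_theta_e * G_z_e)` (isochoric deposition).
#' @param G_m,G_c smooth muscle / collagen fiber deposition stretches.
#' @param eta smooth-muscle-to-collagen turnover ratio (referential densities
#'   couple as `rho_m = rho_c^eta`).
#' @param K_ratio shear-to-intramural gain ratio `K_tauw / K_sigma`.
#' @param delta mechanosensing dysfunction fraction in `[0, 1]` (fraction of
#'   intramural stress *not* transduced).
#' @param xi endothelial dysfunction fraction in `[0, 1]`.
#' @param T_max,C_B,C_S,lambda_M,lambda_0 vasoactive constants: maximum active
#'   stress (kPa), shear-tone shape constants (`C_S` defaults to `C_B/2`), and
#'   stretches of maximal / minimal contraction.
#' @param Q_ratio flow ratio `Q_h / Q_o` (cardiac output held constant: 1).
#'
#' @return An object of class `gnr_parameters` (a validated named list with
#'   the derived radial elastin deposition stretch `G_r_e`).
#' @seealso [mouse_dta_parameters()], [homeostatic_baseline()],
#'   [read_gnr_config()]
#' @export
#' @examples
#' pars <- mixture_parameters()
#' pars$a_o       # 0.647 mm
#' pars$G_r_e    # 1 / (1.90 * 1.62)
mixture_parameters <- function(a_o = 0.647, h_o = 0.040, l_o = 15,
                               phi_e = 0.34, phi_m = 0.33, phi_c = 0.33,
                               beta_theta = 0.056, beta_z = 0.067,
                               beta_d = 0.877,
                               alpha_0o = 29.9 * pi / 180,
                               c_e = 89.71,
                               c1_m = 261.4, c2_m = 0.24,
                               c1_c = 234.9, c2_c = 4.08,
                               G_theta_e = 1.90, G_z_e = 1.62,
                               G_m = 1.20, G_c = 1.25,
                               eta = 1, K_ratio = 0.35,
                               delta = 0, xi = 0,
                               T_max = 250, C_B = 0.8326, C_S = NULL,
                               lambda_M = 1.1, lambda_0 = 0.4,
                               Q_ratio = 1) {
  if (is.null(C_S)) C_S <- C_B / 2
  pars <- list(a_o = a_o, h_o = h_o, l_o = l_o,
               phi_e = phi_e, phi_m = phi_m, phi_c = phi_c,
               beta_theta = beta_theta, beta_z = beta_z, beta_d = beta_d,
               alpha_0o = alpha_0o,
               c_e = c_e, c1_m = c1_m, c2_m = c2_m, c1_c = c1_c, c2_c = c2_c,
               G_theta_e = G_theta_e, G_z_e = G_z_e,
               G_r_e = 1 / (G_theta_e * G_z_e),
               G_m = G_m, G_c = G_c,
               eta = eta, K_ratio = K_ratio, delta = delta, xi = xi,
               T_max = T_max, C_B = C_B, C_S = C_S,
               lambda_M = lambda_M, lambda_0 = lambda_0,
               Q_ratio = Q_ratio)
  class(pars) <- "gnr_parameters"
  validate_parameters(pars)
  pars
}

#' Baseline murine descending thoracic aorta parameters
#'
#' The canonical baseline parameterization used throughout the package and its
#' tests: a non-aneurysmal mouse descending thoracic aorta with
#' `a_o = 0.647` mm, `h_o = 0.040` mm, `l_o = 15` mm, equal-thirds mass
#' fractions (0.34/0.33/0.33), and the biaxially identified material constants
#' and deposition stretches.  Identical to `mixture_parameters()` with default
#' arguments; provided as a named entry point for scripts and tests.
#'
#' @return A `gnr_parameters` object.
#' @export
mouse_dta_parameters <- function() mixture_parameters()

validate_parameters <- function(pars) {
  stopifnot(inherits(pars, "gnr_parameters"))
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  chk(abs(pars$phi_e + pars$phi_m + pars$phi_c - 1) < 1e-9,
      "mass fractions phi_e + phi_m + phi_c must sum to 1")
  chk(abs(pars$beta_theta + pars$beta_z + pars$beta_d - 1) < 1e-9,
      "collagen family fractions beta_theta + beta_z + beta_d must sum to 1")
  chk(abs(pars$G_r_e * pars$G_theta_e * pars$G_z_e - 1) < 1e-9,
      "elastin deposition must be isochoric: G_r_e = 1/(G_theta_e * G_z_e)")
  chk(pars$delta >= 0 && pars$delta <= 1, "delta must lie in [0, 1]")
  chk(pars$xi >= 0 && pars$xi <= 1, "xi must lie in [0, 1]")
  chk(pars$lambda_0 < 1 && pars$lambda_M > 1,
      "active stretch limits must satisfy lambda_0 < 1 < lambda_M")
  for (nm in c("a_o", "h_o", "l_o"))
    chk(pars[[nm]] > 0, paste(nm, "must be positive"))
  for (nm in c("c_e", "c1_m", "c2_m", "c1_c", "c2_c", "T_max"))
    chk(pars[[nm]] >= 0, paste(nm, "must be non-negative"))
  for (nm in c("G_theta_e", "G_z_e", "G_m", "G_c", "Q_ratio"))
    chk(pars[[nm]] > 0, paste(nm, "must be positive"))
  invisible(pars)
}

#' @export
print.gnr_parameters <- function(x, ...) {
  cat("Constrained-mixture wall parameters (kPa, mm, rad)\n")
  cat(sprintf("  geometry: a_o = %.3f mm, h_o = %.3f mm, l_o = %.1f mm\n",
              x$a_o, x$h_o, x$l_o))
  cat(sprintf("  fractions: phi = (%.2f e, %.2f m, %.2f c); beta = (%.3f, %.3f, %.3f)\n",
              x$phi_e, x$phi_m, x$phi_c, x$beta_theta, x$beta_z, x$beta_d))
  cat(sprintf("  fiber angle alpha_0o = %.1f deg\n", x$alpha_0o * 180 / pi))
  cat(sprintf("  moduli: c_e = %.2f; muscle (%.1f, %.2f); collagen (%.1f, %.2f)\n",
              x$c_e, x$c1_m, x$c2_m, x$c1_c, x$c2_c))
  cat(sprintf("  deposition stretches: G_e = (%.2f, %.2f, %.4f), G_m = %.2f, G_c = %.2f\n",
              x$G_theta_e, x$G_z_e, x$G_r_e, x$G_m, x$G_c))
  cat(sprintf("  turnover: eta = %g, K_tauw/K_sigma = %g, delta = %g, xi = %g\n",
              x$eta, x$K_ratio, x$delta, x$xi))
  cat(sprintf("  tone: T_max = %g kPa, C_B = %g, C_S = %g, lambda_M = %g, lambda_0 = %g\n",
              x$T_max, x$C_B, x$C_S, x$lambda_M, x$lambda_0))
  invisible(x)
}

# Names that a flat key-value config file may carry (C_S optional, G_r_e derived).
config_keys <- function() {
  c("a_o", "h_o", "l_o", "phi_e", "phi_m", "phi_c",
    "beta_theta", "beta_z", "beta_d", "alpha_0o",
    "c_e", "c1_m", "c2_m", "c1_c", "c2_c",
    "G_theta_e", "G_z_e", "G_m", "G_c",
    "eta", "K_ratio", "delta", "xi",
    "T_max", "C_B", "C_S", "lambda_M", "lambda_0", "Q_ratio")
}

#' Read / write a flat parameter configuration file
#'
#' Flat YAML key-value files mirror the constructor arguments of
#' [mixture_parameters()] (angles in radians).  Unknown keys raise an error
#' naming the offending key; missing keys fall back to the baseline defaults.
#' A bundled fixture reproducing the baseline exactly ships at
#' `system.file("extdata", "mouse_dta_baseline.yaml", package = "gnreq")`.
#'
#' @param path file path.
#' @param pars a `gnr_parameters` object (for writing).
#' @return `read_gnr_config()` returns a `gnr_parameters` object;
#'   `write_gnr_config()` returns `path` invisibly.
#' @export
read_gnr_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a flat key-value mapping")
  bad <- setdiff(names(raw), c(config_keys(), "G_r_e"))
  if (length(bad))
    stop("unknown configuration key: ", bad[[1L]], call. = FALSE)
  raw$G_r_e <- NULL
  for (nm in names(raw)) {
    if (!is.numeric(raw[[nm]]) || length(raw[[nm]]) != 1L)
      stop("configuration key must be a single number: ", nm, call. = FALSE)
  }
  do.call(mixture_parameters, raw)
}

#' @rdname read_gnr_config
#' @export
write_gnr_config <- function(pars, path) {
  validate_parameters(pars)
  out <- pars[config_keys()]
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}
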