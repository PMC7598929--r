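#' @title Derived metrics, virtual mechanical tests, and file output
#' @name postprocess_io
NULL

#' Summary metrics of a scenario result
#'
#' Maximal local diameter increase (percent of baseline diameter, from the
#' deformed radius), central stored energy density and circumferential
#' material stiffness (absolute, percent change, and fold change against the
#' homeostatic values), lesion length (full width at half maximum of the
#' diameter excess over the end regions), and the convergence flag.  For an
#' unconverged continuation the metrics describe the last converged state.
#'
#' @param result a `gnr_result` or `gnr_uniform_result`.
#' @return one-row data.frame of class `gnr_summary`.
#' @export
summarize_result <- function(result) UseMethod("summarize_result")

#' @export
summarize_result.gnr_result <- function(result) {
  mesh <- result$mesh
  n <- mesh$n_nodes
  r <- result$u[seq_len(n)]
  dmax <- 100 * (max(r) / mesh$a_o - 1)
  central <- probe_state(result, mesh$l_o / 2)
  W_o <- result$baseline$state$W
  ct_o <- result$baseline$state$c_tttt
  # FWHM of the diameter excess over the proximal end value
  excess <- r - r[1L]
  lesion <- NA_real_
  if (max(excess) > 1e-6 * mesh$a_o) {
    half <- max(excess) / 2
    above <- excess >= half
    zs <- mesh$z_nodes
    lesion <- diff(range(zs[above]))
    lesion <- min(lesion, mesh$l_o)
  }
  structure(data.frame(
    label = result$label,
    max_diameter_ratio = dmax,
    central_W = central$W,
    central_W_change = 100 * (central$W / W_o - 1),
    central_ctttt = central$c_tttt,
    central_ctttt_fold = central$c_tttt / ct_o,
    lesion_length = lesion,
    converged = result$converged,
    stringsAsFactors = FALSE), class = c("gnr_summary", "data.frame"))
}

#' @export
summarize_result.gnr_uniform_result <- function(result) {
  W_o <- result$baseline$state$W
  ct_o <- result$baseline$state$c_tttt
  st <- result$state
  if (is.null(st)) {
    return(structure(data.frame(label = result$label,
                                max_diameter_ratio = NA_real_,
                                central_W = NA_real_,
                                central_W_change = NA_real_,
                                central_ctttt = NA_real_,
                                central_ctttt_fold = NA_real_,
                                lesion_length = NA_real_, converged = FALSE,
                                stringsAsFactors = FALSE),
                     class = c("gnr_summary", "data.frame")))
  }
  structure(data.frame(
    label = result$label,
    max_diameter_ratio = 100 * (st$lam_theta - 1),
    central_W = st$W,
    central_W_change = 100 * (st$W / W_o - 1),
    central_ctttt = st$c_tttt,
    central_ctttt_fold = st$c_tttt / ct_o,
    lesion_length = NA_real_,
    converged = result$converged,
    stringsAsFactors = FALSE), class = c("gnr_summary", "data.frame"))
}

# ---------------------------------------------------------------------------
# Frozen-composition elastic response used by the virtual biaxial tests:
# an additional isochoric elastic deformation diag(mu_r, mu_t, mu_z) applied
# to a converged equilibrated state, with mass fractions, fiber angle, and
# constituent natural configurations frozen, and plane stress (sigma_rr = 0).

frozen_passive_stress <- function(mu_t, mu_z, state, pars) {
  mu_r <- 1 / (mu_t * mu_z)
  loc <- state$loc
  g_e <- loc$c_e / pars$c_e
  J <- state$J
  phi_e_h <- pars$phi_e * g_e / J
  phi_m_h <- pars$phi_m * state$rho_m_ratio / J
  phi_c_h <- pars$phi_c * state$rho_c_ratio / J
  # elastin follows the total deformation from its natural configuration
  le_t <- pars$G_theta_e * state$lam_theta * mu_t
  le_z <- pars$G_z_e * state$lam_z * mu_z
  le_r <- pars$G_r_e * (J / (state$lam_theta * state$lam_z)) * mu_r
  se <- pars$c_e * c(le_t^2, le_z^2, le_r^2)
  # fiber families: deposition stretch times relative stretch along the
  # (convecting) family direction, frozen at the equilibrated angle
  a <- state$alpha_0h
  s2 <- sin(a)^2; c2a <- cos(a)^2
  lam_d <- sqrt(mu_t^2 * s2 + mu_z^2 * c2a)
  m_t2 <- mu_t^2 * s2 / lam_d^2
  m_z2 <- mu_z^2 * c2a / lam_d^2
  f <- function(lam) fiber_stress_kernel(lam, loc$c1_c, loc$c2_c)
  s_c_t <- pars$beta_theta * f(loc$G_c * mu_t) +
    pars$beta_d * f(loc$G_c * lam_d) * m_t2
  s_c_z <- pars$beta_z * f(loc$G_c * mu_z) +
    pars$beta_d * f(loc$G_c * lam_d) * m_z2
  s_m_t <- fiber_stress_kernel(loc$G_m * mu_t, loc$c1_m, loc$c2_m)
  extra_t <- phi_e_h * se[1] + phi_c_h * s_c_t + phi_m_h * s_m_t
  extra_z <- phi_e_h * se[2] + phi_c_h * s_c_z
  extra_r <- phi_e_h * se[3]
  c(theta = extra_t - extra_r, z = extra_z - extra_r)   # p = extra_r (plane stress)
}

#' Simulated equibiaxial stress-stretch test
#'
#' Post-processing virtual experiment on the remodeled composition of a
#' converged state: the passive mixture (active tone off), at frozen mass
#' fractions and fiber angle, is first unloaded to its traction-free
#' configuration and then stretched equibiaxially; circumferential and axial
#' Cauchy stresses are reported against the applied stretch.
#'
#' @param state a `gnr_point_state` (e.g. from [probe_state()] at the lesion
#'   apex).
#' @param pars baseline parameters.
#' @param stretch monotone grid of equibiaxial stretches (> 0) measured from
#'   the traction-free configuration.
#' @return data.frame with columns `stretch`, `sigma_theta`, `sigma_z` (kPa)
#'   and attributes `mu_free` (traction-free pre-stretches).
#' @export
simulate_equibiaxial <- function(state, pars, stretch = seq(1, 1.3, by = 0.01)) {
  if (any(stretch <= 0)) stop("stretches must be positive")
  mu <- c(0.8, 0.8)
  for (it in 1:100) {
    r0 <- frozen_passive_stress(mu[1], mu[2], state, pars)
    if (max(abs(r0)) < 1e-10) break
    Jm <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- 1e-7
      mp <- mu; mp[j] <- mp[j] + h
      Jm[, j] <- (frozen_passive_stress(mp[1], mp[2], state, pars) - r0) / h
    }
    d <- solve(Jm, -r0)
    d <- pmin(pmax(d, -0.2), 0.2)
    mu <- pmax(mu + d, 0.05)
  }
  if (max(abs(frozen_passive_stress(mu[1], mu[2], state, pars))) > 1e-6)
    stop("traction-free configuration did not converge")
  out <- t(vapply(stretch, function(s) {
    frozen_passive_stress(mu[1] * s, mu[2] * s, state, pars)
  }, numeric(2)))
  res <- data.frame(stretch = stretch, sigma_theta = out[, 1],
                    sigma_z = out[, 2])
  attr(res, "mu_free") <- mu
  res
}

# ---------------------------------------------------------------------------
# File output

fmt9 <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 9, format = "g") else as.character(x)
}

#' Write a scenario result as a legacy-ASCII VTK polydata surface
#'
#' Revolves the final deformed meridian into a quadrilateral surface mesh
#' (`n_theta` circumferential divisions) and attaches point-data arrays for
#' stored energy density, circumferential material stiffness, volume ratio,
#' and the local diameter ratio.
#'
#' @param result a `gnr_result`.
#' @param path output file path.
#' @param n_theta circumferential tessellation (>= 8).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(result, path, n_theta = 36) {
  stopifnot(inherits(result, "gnr_result"), n_theta >= 8)
  mesh <- result$mesh
  n <- mesh$n_nodes
  r <- result$u[seq_len(n)]
  z <- result$u[n + seq_len(n)]
  # nodal fields interpolated from the Gauss point table
  gp <- result$gp_table
  nodal <- function(v) stats::approx(gp$z_o, v, xout = mesh$z_nodes,
                                     rule = 2)$y
  W <- nodal(gp$W); ct <- nodal(gp$c_tttt); Jv <- nodal(gp$J)
  drat <- r / mesh$a_o
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(r[i] * cos(th), r[i] * sin(th), z[i])
  }))
  quad <- function(i, j) {
    jn <- j %% n_theta + 1L
    c((i - 1L) * n_theta + j - 1L, (i - 1L) * n_theta + jn - 1L,
      i * n_theta + jn - 1L, i * n_theta + j - 1L)
  }
  polys <- do.call(rbind, lapply(seq_len(n - 1L), function(i) {
    t(vapply(seq_len(n_theta), function(j) quad(i, j), numeric(4)))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("equilibrated growth-and-remodeling result: ", result$label)
  wl("ASCII")
  wl("DATASET POLYDATA")
  wl(sprintf("POINTS %d float", nrow(pts)))
  writeLines(apply(pts, 1, function(p) paste(fmt9(p), collapse = " ")), con)
  wl(sprintf("POLYGONS %d %d", nrow(polys), 5L * nrow(polys)))
  writeLines(apply(polys, 1, function(q)
    paste(c(4L, q), collapse = " ")), con)
  wl(sprintf("POINT_DATA %d", nrow(pts)))
  arr <- function(name, v) {
    wl(sprintf("SCALARS %s float 1", name))
    wl("LOOKUP_TABLE default")
    writeLines(fmt9(rep(v, each = n_theta)), con)
  }
  arr("stored_energy_kPa", W)
  arr("c_tttt_kPa", ct)
  arr("volume_ratio", Jv)
  arr("diameter_ratio", drat)
  invisible(path)
}

#' Write summary metrics to CSV
#'
#' One row per scenario/step, header row, 9 significant digits,
#' locale-independent.
#'
#' @param metrics a data.frame (e.g. rbind of [summarize_result()] rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  out <- as.data.frame(lapply(metrics, function(col) {
    if (is.numeric(col)) fmt9(col) else col
  }), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read summary metrics back from CSV
#'
#' @param path CSV written by [write_metrics_csv()].
#' @return data.frame with numeric columns restored.
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
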