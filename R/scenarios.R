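#' @title Numerical knockout catalog and scenario runner
#' @description
#' Maps named in silico "knockouts" -- localized losses of elastic fiber
#' integrity, collagen cross-linking, smooth muscle contractility,
#' mechanosensing, or mechanoregulation, plus increased collagen turnover --
#' with optional superimposed hypertension (1.5x pressure) and aging
#' (uniform 30% elastin loss) onto parameter fields and runs them through the
#' membrane finite-element or uniform solvers.
#' @name scenarios
NULL

insult_defs <- function(pars) {
  list(
    elastin_integrity = list(param = "c_e", base = pars$c_e,
                             mild = 0.68 * pars$c_e, severe = 34.1),
    collagen_crosslinking = list(param = "c1_c", base = pars$c1_c,
                                 mild = 0.91 * pars$c1_c, severe = 181),
    contractility = list(param = "T_max", base = pars$T_max,
                         mild = 0.40 * pars$T_max, severe = 0),
    mechanosensing = list(param = "delta", base = pars$delta,
                          mild = 0.075, severe = 0.185),
    mechanoregulation = list(param = "G_c", base = pars$G_c,
                             mild = 0.996 * pars$G_c, severe = 1.235),
    collagen_degradation = list(param = "eta", base = pars$eta,
                                mild = 1.05, severe = 1.125)
  )
}

#' Specify one knockout scenario
#'
#' @param insult one of `"elastin_integrity"`, `"collagen_crosslinking"`,
#'   `"contractility"`, `"mechanosensing"`, `"mechanoregulation"`,
#'   `"collagen_degradation"`.
#' @param severity `"mild"`, `"severe"`, or `"custom"` (then give `value`).
#' @param value central parameter value for `severity = "custom"`.
#' @param hypertension `FALSE`, `TRUE` (1.5x pressure), or a numeric pressure
#'   multiplier.
#' @param aging `FALSE`, `TRUE` (uniform 30% elastin loss), or a numeric loss
#'   fraction; composes multiplicatively with localized elastin damage.
#' @param geometry `"axisymmetric"` (localized lesion, membrane FEM),
#'   `"uniform"` (0-D; the insult applied uniformly, shear gain kept at
#'   baseline), or `"asymmetric"` (field specification only; not solved).
#' @param nu_z,z_od axial profile decay exponent and deviation (mm).
#' @param nu_theta,theta_od circumferential profile parameters (asymmetric
#'   fields only).
#' @param T_max_uniform optional uniform contractility override (kPa), e.g.
#'   a protective basal tone superimposed on a matrix insult.
#' @param label optional label.
#' @return a `gnr_scenario` object.
#' @export
scenario_spec <- function(insult, severity = c("mild", "severe", "custom"),
                          value = NULL, hypertension = FALSE, aging = FALSE,
                          geometry = c("axisymmetric", "uniform", "asymmetric"),
                          nu_z = 5, z_od = 3, nu_theta = 5, theta_od = pi / 3,
                          T_max_uniform = NULL, label = NULL) {
  insult <- match.arg(insult, names(insult_defs(mixture_parameters())))
  severity <- match.arg(severity)
  geometry <- match.arg(geometry)
  if (severity == "custom" && is.null(value))
    stop("custom severity requires a value")
  p_mult <- if (isTRUE(hypertension)) 1.5 else if (is.numeric(hypertension))
    hypertension else 1
  age_loss <- if (isTRUE(aging)) 0.30 else if (is.numeric(aging)) aging else 0
  if (is.null(label))
    label <- paste0(insult, ":", if (severity == "custom")
      format(value) else severity,
      if (p_mult != 1) "+hypertension" else "",
      if (age_loss > 0) "+aging" else "",
      if (geometry != "axisymmetric") paste0(" [", geometry, "]") else "")
  structure(list(insult = insult, severity = severity, value = value,
                 p_mult = p_mult, age_loss = age_loss, geometry = geometry,
                 nu_z = nu_z, z_od = z_od, nu_theta = nu_theta,
                 theta_od = theta_od, T_max_uniform = T_max_uniform,
                 label = label),
            class = "gnr_scenario")
}

central_value <- function(spec, pars) {
  def <- insult_defs(pars)[[spec$insult]]
  v <- switch(spec$severity, mild = def$mild, severe = def$severe,
              custom = spec$value)
  list(param = def$param, base = def$base, central = v)
}

#' Build the insult field specifications for a scenario
#'
#' Returns the spatial field specs the scenario implies: the insulted
#' parameter (end value at baseline), the gain-ratio field (baseline at the
#' ends, zero at the lesion center: shear-mediated turnover confined to the
#' non-aneurysmal segments), and the turnover-ratio field.
#'
#' @param spec a [scenario_spec()].
#' @param pars baseline parameters.
#' @return named list of [insult_field_spec()] objects.
#' @export
build_insult_fields <- function(spec, pars) {
  cv <- central_value(spec, pars)
  sym <- spec$geometry != "asymmetric"
  ends <- end_region_profiles(pars, nu_z = spec$nu_z, z_od = spec$z_od)
  fields <- list(
    insult = insult_field_spec(cv$param, cv$base, cv$central,
                               nu_z = spec$nu_z, z_od = spec$z_od,
                               nu_theta = spec$nu_theta,
                               theta_od = spec$theta_od,
                               symmetric = sym, l_o = pars$l_o),
    K_ratio = ends$K_ratio)
  if (cv$param != "eta") fields$eta <- ends$eta
  fields
}

#' The knockout catalog
#'
#' Deterministically ordered list of scenarios: the five localized insults at
#' mild and severe severity crossed with risk factors (none, hypertension,
#' aging, both) on the axisymmetric geometry (40 cases), the increased
#' collagen-turnover cases, uniform-insult variants, and the asymmetric
#' field-only specifications.
#'
#' @param pars baseline parameters.
#' @return named list of `gnr_scenario` objects; `attr(, "core")` marks the
#'   40 five-insult axisymmetric cases.
#' @export
knockout_catalog <- function(pars = mouse_dta_parameters()) {
  five <- c("elastin_integrity", "collagen_crosslinking", "contractility",
            "mechanosensing", "mechanoregulation")
  specs <- list()
  for (ins in five)
    for (sev in c("mild", "severe"))
      for (risk in c("none", "hypertension", "aging", "both"))
        specs[[length(specs) + 1L]] <-
          scenario_spec(ins, sev,
                        hypertension = risk %in% c("hypertension", "both"),
                        aging = risk %in% c("aging", "both"))
  n_core <- length(specs)
  # increased collagen degradation relative to production (turnover ratio)
  for (sev in c("mild", "severe"))
    for (risk in c("none", "hypertension", "aging", "both"))
      specs[[length(specs) + 1L]] <-
        scenario_spec("collagen_degradation", sev,
                      hypertension = risk %in% c("hypertension", "both"),
                      aging = risk %in% c("aging", "both"))
  # uniform-insult variants
  specs[[length(specs) + 1L]] <-
    scenario_spec("elastin_integrity", "custom", value = 0.70 * pars$c_e,
                  geometry = "uniform", label = "uniform elastin loss 30%")
  specs[[length(specs) + 1L]] <-
    scenario_spec("collagen_crosslinking", "custom", value = 0.80 * pars$c1_c,
                  geometry = "uniform", label = "uniform cross-linking loss 20%")
  specs[[length(specs) + 1L]] <-
    scenario_spec("contractility", "custom", value = 0.20 * pars$T_max,
                  geometry = "uniform", label = "uniform contractility loss 80%")
  specs[[length(specs) + 1L]] <-
    scenario_spec("mechanosensing", "custom", value = 0.12,
                  geometry = "uniform", label = "uniform mechanosensing loss 12%")
  # asymmetric lesions: apex values; field specifications only
  asym <- list(c("elastin_integrity", 20.2), c("collagen_crosslinking", 111),
               c("mechanosensing", 0.4), c("mechanoregulation", 1.22))
  for (a in asym)
    specs[[length(specs) + 1L]] <-
      scenario_spec(a[[1]], "custom", value = as.numeric(a[[2]]),
                    geometry = "asymmetric")
  names(specs) <- vapply(specs, `[[`, "", "label")
  attr(specs, "core") <- seq_len(n_core)
  specs
}

#' Run one knockout scenario
#'
#' Builds the parameter fields (insult profile, end-region gain profile,
#' risk factors), runs the quasi-static continuation, and returns the
#' result.  Uniform scenarios run the 0-D solver; asymmetric specifications
#' are field-only and raise an error if a solve is requested.
#'
#' @param spec a [scenario_spec()].
#' @param pars baseline parameters.
#' @param config a [fem_solve_config()] (axisymmetric) or
#'   [uniform_solve_config()] (uniform); defaults chosen per geometry.
#' @param mesh optional prebuilt mesh (axisymmetric).
#' @param baseline optional precomputed [homeostatic_baseline()].
#' @param n_elem mesh resolution when no mesh is given.
#' @return a `gnr_result` (axisymmetric) or `gnr_uniform_result` (uniform).
#' @export
run_scenario <- function(spec, pars, config = NULL, mesh = NULL,
                         baseline = homeostatic_baseline(pars), n_elem = 20) {
  stopifnot(inherits(spec, "gnr_scenario"))
  if (spec$geometry == "asymmetric")
    stop("asymmetric lesions are specified as fields only (see ",
         "build_insult_fields); solving them is out of scope", call. = FALSE)
  P_target <- baseline$P_o * spec$p_mult
  age_f <- 1 - spec$age_loss
  cv <- central_value(spec, pars)

  if (spec$geometry == "uniform") {
    cfg <- config %||% uniform_solve_config()
    ov <- list()
    ov[[cv$param]] <- cv$central
    if (cv$param == "c_e") ov$c_e <- ov$c_e * age_f
    else if (age_f < 1) ov$c_e <- pars$c_e * age_f
    if (!is.null(spec$T_max_uniform)) ov$T_max <- spec$T_max_uniform
    st <- tryCatch(
      solve_uniform(pars, P = P_target, overrides = ov, config = cfg,
                    baseline = baseline),
      gnr_no_equilibrium = function(e) e)
    conv <- inherits(st, "gnr_point_state")
    return(structure(list(state = if (conv) st else NULL,
                          converged = conv, P_final = P_target,
                          pars = pars, baseline = baseline,
                          label = spec$label),
                     class = "gnr_uniform_result"))
  }

  cfg <- config %||% fem_solve_config()
  if (is.null(mesh)) mesh <- build_mesh(pars, n_elem = n_elem)
  fields <- build_insult_fields(spec, pars)
  z <- mesh$gp_z
  ov <- list()
  ov[[cv$param]] <- axisymmetric_field(z, fields$insult)
  ov$K_ratio <- axisymmetric_field(z, fields$K_ratio)
  if (!is.null(fields$eta)) ov$eta <- axisymmetric_field(z, fields$eta)
  if (!is.null(spec$T_max_uniform)) ov$T_max <- spec$T_max_uniform
  ov_insult <- ov                             # localized insult alone
  if (cv$param == "c_e") ov$c_e <- ov$c_e * age_f
  else if (age_f < 1) ov$c_e <- rep(pars$c_e * age_f, length(z))
  loc_insult <- resolve_local(pars, ov_insult)
  loc_target <- resolve_local(pars, ov)

  # simultaneous quasi-static ramp of insult and risk factors
  res <- solve_scenario(mesh, loc_target, P_target, pars, config = cfg,
                        baseline = baseline, label = spec$label)
  if (res$converged || (spec$p_mult == 1 && age_f >= 1)) return(res)

  # staged path (equilibrated states are path-independent): localized insult
  # first, then uniform aging, then pressure
  r1 <- solve_scenario(mesh, loc_insult, baseline$P_o, pars, config = cfg,
                       baseline = baseline, label = spec$label)
  if (!r1$converged) return(if (r1$t_reached > res$t_reached) r1 else res)
  r2 <- r1
  if (age_f < 1) {
    r2 <- solve_scenario(mesh, loc_target, baseline$P_o, pars, config = cfg,
                         baseline = baseline, label = spec$label,
                         init = r1, loc_start = loc_insult,
                         P_start = baseline$P_o)
    if (!r2$converged) return(res)
  }
  if (spec$p_mult != 1) {
    r3 <- solve_scenario(mesh, loc_target, P_target, pars, config = cfg,
                         baseline = baseline, label = spec$label,
                         init = r2, loc_start = loc_target,
                         P_start = baseline$P_o)
    if (!r3$converged) return(res)
    return(r3)
  }
  r2
}

#' Sweep a control parameter over a grid
#'
#' Re-runs a base scenario with one control varied -- the central insult
#' value (`"value"`, e.g. a grid of mechanosensing `delta`) or a lesion
#' profile parameter (`"z_od"`, `"nu_z"`) -- and tabulates summary metrics.
#'
#' @param parameter `"value"`, `"z_od"`, or `"nu_z"`.
#' @param grid monotone numeric grid.
#' @param base_spec the scenario to modify (a [scenario_spec()]).
#' @param pars baseline parameters.
#' @param config,mesh,baseline passed to [run_scenario()].
#' @return data.frame with one row per grid point: `value`,
#'   `max_diameter_ratio` (%), `central_W` (kPa), `central_ctttt` (kPa),
#'   `lesion_length` (mm), `converged`.
#' @export
sweep_parameter <- function(parameter = c("value", "z_od", "nu_z"), grid,
                            base_spec, pars, config = NULL, mesh = NULL,
                            baseline = homeostatic_baseline(pars)) {
  parameter <- match.arg(parameter)
  if (!length(grid))
    return(data.frame(value = numeric(0), max_diameter_ratio = numeric(0),
                      central_W = numeric(0), central_ctttt = numeric(0),
                      lesion_length = numeric(0), converged = logical(0)))
  if (is.unsorted(grid) && is.unsorted(rev(grid)))
    stop("grid must be monotone")
  if (is.null(mesh) && base_spec$geometry == "axisymmetric")
    mesh <- build_mesh(pars)
  rows <- lapply(grid, function(v) {
    sp <- base_spec
    if (parameter == "value") { sp$severity <- "custom"; sp$value <- v }
    else sp[[parameter]] <- v
    res <- run_scenario(sp, pars, config = config, mesh = mesh,
                        baseline = baseline)
    m <- summarize_result(res)
    data.frame(value = v, max_diameter_ratio = m$max_diameter_ratio,
               central_W = m$central_W, central_ctttt = m$central_ctttt,
               lesion_length = m$lesion_length, converged = m$converged)
  })
  do.call(rbind, rows)
}
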