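#' @title Axisymmetric nonlinear membrane finite elements
#' @description
#' Localized lesions are solved on an axisymmetric nonlinear membrane
#' reduction of the cylindrical segment: 1-D quadratic elements along the
#' axis describe the meridian `(r(z_o), z(z_o))`, follower pressure acts on
#' the deformed surface, and at every Gauss point the *local*
#' mechanobiological equilibrium is solved for the referential collagen
#' density (internal-variable style) at fixed deformation, with wall shear
#' evaluated pointwise from the local deformed radius.  The consistent
#' tangent carries the implicit dependence of the local mass solve, the
#' shear-radius feedback, the evolving fiber angle, and the follower load.
#' @name fem_axisymmetric
NULL

#' Solver settings for the membrane finite-element continuation
#'
#' @param newton_tol relative residual tolerance of the global Newton loop
#'   (measured against the baseline membrane force scale).
#' @param max_iter maximum global Newton iterations per step.
#' @param continuation_steps quasi-static increments of the insult/load.
#' @param max_halvings continuation step halvings before declaring no
#'   equilibrium.
#' @param tangent_mode `"analytic"` (consistent linearization) or
#'   `"numeric"` (column-wise finite difference of the residual).
#' @param arc_length follow the equilibrium path with a Riks-type arc-length
#'   predictor--corrector when plain load stepping stalls at a fold
#'   (snap-through of the membrane).  Disable to reproduce plain
#'   Newton--Raphson load stepping, whose first failure defines the
#'   mechanobiological instability threshold.
#' @return a `gnr_fem_config` list.
#' @export
fem_solve_config <- function(newton_tol = 1e-10, max_iter = 30,
                             continuation_steps = 10, max_halvings = 5,
                             tangent_mode = c("analytic", "numeric"),
                             arc_length = TRUE) {
  structure(list(newton_tol = newton_tol, max_iter = max_iter,
                 continuation_steps = continuation_steps,
                 max_halvings = max_halvings,
                 tangent_mode = match.arg(tangent_mode),
                 arc_length = arc_length),
            class = "gnr_fem_config")
}

#' Build the axisymmetric membrane mesh
#'
#' Uniform reference mesh of the cylinder midsurface: `n_elem` quadratic
#' (3-node) elements along the axis, `2 n_elem + 1` nodes, 3-point Gauss
#' integration per element.
#'
#' @param pars baseline parameters (geometry).
#' @param n_elem number of elements (>= 4; default 20).
#' @param gauss_order Gauss points per element (3).
#' @return a `gnr_mesh` object.
#' @export
build_mesh <- function(pars, n_elem = 20, gauss_order = 3) {
  if (n_elem < 4) stop("n_elem must be at least 4")
  if (gauss_order != 3) stop("only 3-point Gauss integration is supported")
  n_nodes <- 2L * n_elem + 1L
  z_nodes <- seq(0, pars$l_o, length.out = n_nodes)
  conn <- t(vapply(seq_len(n_elem),
                   function(e) c(2L * e - 1L, 2L * e, 2L * e + 1L),
                   integer(3)))
  s <- sqrt(3 / 5)
  xi <- c(-s, 0, s)
  w <- c(5, 8, 5) / 9
  # quadratic shape functions at the Gauss points: rows gp, cols node
  N <- cbind(xi * (xi - 1) / 2, 1 - xi^2, xi * (xi + 1) / 2)
  dN <- cbind(xi - 0.5, -2 * xi, xi + 0.5)
  h_e <- pars$l_o / n_elem
  jac <- h_e / 2
  gp_z <- as.vector(vapply(seq_len(n_elem), function(e) {
    z_nodes[conn[e, ]] %*% t(N)    # 3 gp per element
  }, numeric(3)))
  structure(list(n_elem = n_elem, n_nodes = n_nodes, z_nodes = z_nodes,
                 conn = conn, a_o = pars$a_o, h_o = pars$h_o, l_o = pars$l_o,
                 xi = xi, w = w, N = N, dN = dN, jac = jac, gp_z = gp_z,
                 n_gp = 3L * n_elem),
            class = "gnr_mesh")
}

#' Reference degrees of freedom of a mesh
#'
#' Nodal coordinates `(r_1..r_n, z_1..z_n)` of the undeformed midsurface.
#'
#' @param mesh a [build_mesh()] object.
#' @return numeric vector of length `2 * n_nodes`.
#' @export
reference_dof <- function(mesh) c(rep(mesh$a_o, mesh$n_nodes), mesh$z_nodes)

free_dof_index <- function(mesh) {
  n <- mesh$n_nodes
  # axial displacement fixed at proximal and distal ends; radially free
  setdiff(seq_len(2L * n), c(n + 1L, 2L * n))
}

# Kinematics at all Gauss points for a given dof vector.
gp_kinematics <- function(mesh, u) {
  n <- mesh$n_nodes
  r <- u[seq_len(n)]
  z <- u[n + seq_len(n)]
  ne <- mesh$n_elem
  idx <- t(mesh$conn)                               # 3 x ne node ids
  r_el <- matrix(r[idx], nrow = 3)
  z_el <- matrix(z[idx], nrow = 3)
  r_gp <- as.vector(mesh$N %*% r_el)                # 3 gp x ne, column-major
  drds <- as.vector(mesh$dN %*% r_el) / mesh$jac
  dzds <- as.vector(mesh$dN %*% z_el) / mesh$jac
  lam_s <- sqrt(drds^2 + dzds^2)
  list(r = r_gp, drds = drds, dzds = dzds,
       lam_t = r_gp / mesh$a_o, lam_s = lam_s)
}

# Vectorized local mechanobiological solve for rho_c at fixed deformation:
# capped Newton (complex-step derivative) started from the previous converged
# density, with a per-point expanding-bracket root fallback.  Failure of the
# fallback means no local equilibrium root exists near the continuation path
# (the stimulus saturates away from its setpoint), which the caller treats by
# halving the continuation step.
solve_rho_gp <- function(lam_t, lam_s, loc, pars, P, sigma_o, rho0,
                         tol = 1e-12, max_iter = 60) {
  gfun <- function(r) {
    pr <- point_response(lam_t, lam_s, r, loc, pars, P)
    mb_residual_kernel(pr, loc, sigma_o)
  }
  n <- length(lam_t)
  rho <- pmax(rep_len(rho0, n), 1e-8)
  h <- 1e-30
  g <- NULL
  for (it in seq_len(max_iter)) {
    G <- gfun(rho + (0+1i) * h)
    g <- Re(G)
    if (any(!is.finite(g))) { g[!is.finite(g)] <- 1; break }
    if (max(abs(g)) < tol) return(rho)
    dg <- Im(G) / h
    d <- -g / dg
    d[!is.finite(d)] <- 0
    cap <- 0.5 * pmax(rho, 1)
    d <- pmin(pmax(d, -cap), cap)
    rho <- pmax(rho + d, 1e-8)
  }
  # per-point fallback for the stragglers: bracketed root nearest to rho0
  stray <- which(abs(g) >= tol | !is.finite(g))
  loc_i <- function(i) lapply(loc, function(v) if (length(v) > 1L) v[i] else v)
  for (i in stray) {
    li <- loc_i(i)
    gi <- function(r) {
      pr <- point_response(lam_t[i], lam_s[i], r, li, pars, P)
      Re(mb_residual_kernel(pr, li, sigma_o))
    }
    r0 <- max(rep_len(rho0, n)[i], 1e-6)
    g0 <- gi(r0)
    if (!is.finite(g0)) return(NULL)
    if (abs(g0) < tol) { rho[i] <- r0; next }
    found <- FALSE
    for (f in 2^(1:8)) {
      for (rb in c(r0 / f, r0 * f)) {
        gb <- gi(rb)
        if (is.finite(gb) && g0 * gb < 0) {
          iv <- sort(c(r0, rb))
          sol <- tryCatch(
            stats::uniroot(gi, lower = iv[1], upper = iv[2], tol = 1e-14),
            error = function(e) NULL)
          if (!is.null(sol) && abs(gi(sol$root)) < 1e-9) {
            rho[i] <- sol$root
            found <- TRUE
          }
        }
        if (found) break
      }
      if (found) break
    }
    if (!found) return(NULL)
  }
  # polish to full tolerance
  for (it in 1:10) {
    G <- gfun(rho + (0+1i) * h)
    g <- Re(G)
    if (any(!is.finite(g))) return(NULL)
    if (max(abs(g)) < tol) return(rho)
    d <- -g / (Im(G) / h)
    d[!is.finite(d)] <- 0
    cap <- 0.1 * pmax(rho, 1)
    rho <- pmax(rho + pmin(pmax(d, -cap), cap), 1e-8)
  }
  if (max(abs(g)) < 1e-9) rho else NULL
}

#' Local constitutive update at a Gauss point
#'
#' Given the membrane stretches from the nodal geometry, solves the local
#' mechanobiological residual for the referential collagen density at fixed
#' deformation (internal-variable style), with wall shear from the local
#' deformed radius, and returns the full equilibrated point state.
#'
#' @param lam_theta,lam_z membrane stretches at the point.
#' @param pars baseline parameters.
#' @param overrides named list of local parameter values (the insult).
#' @param P transmural pressure (kPa; default the derived `P_o`).
#' @param baseline precomputed [homeostatic_baseline()].
#' @param rho_init starting guess for the collagen density ratio.
#' @return a `gnr_point_state`.
#' @export
local_constitutive_update <- function(lam_theta, lam_z, pars,
                                      overrides = list(), P = NULL,
                                      baseline = homeostatic_baseline(pars),
                                      rho_init = 1) {
  if (is.null(P)) P <- baseline$P_o
  loc <- resolve_local(pars, overrides)
  rho <- solve_rho_gp(lam_theta, lam_z, loc, pars, P, baseline$sigma_o,
                      rho_init)
  if (is.null(rho))
    stop(structure(class = c("gnr_no_equilibrium", "error", "condition"),
                   list(message = "local mechanobiological solve did not converge",
                        call = NULL)))
  new_point_state(lam_theta, lam_z, rho, loc, pars, P)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Membrane point functions: a1 multiplies (x' . dx') in the internal virtual
# work, b multiplies the radial variation dr.
membrane_forces <- function(lam_t, lam_s, rho, loc, pars, P) {
  pr <- point_response(lam_t, lam_s, rho, loc, pars, P)
  list(a1 = pars$h_o * pr$J * (pr$extra_z - pr$p) / lam_s^2,
       b  = pars$h_o * pr$J * (pr$extra_t - pr$p) / (lam_t * pars$a_o),
       G  = NULL, pr = pr)
}

# Point-level partial derivatives of (a1, b) with respect to (lam_t, lam_s),
# carrying the implicit dependence of the local mass solve, via complex-step
# differentiation (machine precision) and the implicit function theorem.
membrane_forces_d <- function(lam_t, lam_s, rho, loc, pars, P, sigma_o) {
  h <- 1e-30
  ih <- (0+1i) * h
  eval_all <- function(lt, ls, rc) {
    pr <- point_response(lt, ls, rc, loc, pars, P)
    list(a1 = pars$h_o * pr$J * (pr$extra_z - pr$p) / ls^2,
         b  = pars$h_o * pr$J * (pr$extra_t - pr$p) / (lt * pars$a_o),
         G  = mb_residual_kernel(pr, loc, sigma_o))
  }
  f0 <- eval_all(lam_t, lam_s, rho)
  ft <- eval_all(lam_t + ih, lam_s, rho)
  fs <- eval_all(lam_t, lam_s + ih, rho)
  fr <- eval_all(lam_t, lam_s, rho + ih)
  im <- function(z) Im(z) / h
  G_rho <- im(fr$G)
  drho_t <- -im(ft$G) / G_rho
  drho_s <- -im(fs$G) / G_rho
  list(a1 = Re(f0$a1), b = Re(f0$b),
       a1_t = im(ft$a1) + im(fr$a1) * drho_t,
       a1_s = im(fs$a1) + im(fr$a1) * drho_s,
       b_t  = im(ft$b) + im(fr$b) * drho_t,
       b_s  = im(fs$b) + im(fr$b) * drho_s)
}

#' Assemble the global membrane residual
#'
#' Virtual-work residual of the membrane stress resultants plus follower
#' pressure on the deformed surface, with the local mechanobiological
#' equilibrium solved at every Gauss point.  Axial displacements are fixed
#' at the two ends (rows retained; constraints applied by the solver).
#'
#' @param mesh a [build_mesh()] object.
#' @param u nodal dof vector (see [reference_dof()]).
#' @param loc resolved local parameters at the Gauss points (named list of
#'   scalars or per-Gauss-point vectors; see `mixture_parameters()` names).
#' @param pars baseline parameters.
#' @param P transmural pressure (kPa).
#' @param baseline a [homeostatic_baseline()] object.
#' @param rho_init per-Gauss-point starting guess for the local solve.
#' @return list with `R` (residual vector, length `2 n_nodes`), `rho`
#'   (converged local densities), and `kin` (Gauss point kinematics); `NULL`
#'   if the configuration is inadmissible or a local solve fails.
#' @export
assemble_residual <- function(mesh, u, loc, pars, P,
                              baseline = homeostatic_baseline(pars),
                              rho_init = rep(1, mesh$n_gp)) {
  kin <- gp_kinematics(mesh, u)
  if (any(!is.finite(kin$lam_t)) || any(kin$lam_t < 0.05) ||
      any(kin$lam_s < 0.05) || any(kin$lam_t > 60))
    return(NULL)
  rho <- solve_rho_gp(kin$lam_t, kin$lam_s, loc, pars, P, baseline$sigma_o,
                      rho_init)
  if (is.null(rho)) return(NULL)
  mf <- membrane_forces(kin$lam_t, kin$lam_s, rho, loc, pars, P)
  a1 <- mf$a1; b <- mf$b
  n <- mesh$n_nodes
  R <- numeric(2L * n)
  two_pi <- 2 * pi
  for (e in seq_len(mesh$n_elem)) {
    ids <- mesh$conn[e, ]
    gsel <- (e - 1L) * 3L + 1:3
    for (g in 1:3) {
      k <- gsel[g]
      wj <- mesh$w[g] * mesh$jac
      Ni <- mesh$N[g, ]
      dNi <- mesh$dN[g, ] / mesh$jac
      # internal
      R[ids] <- R[ids] + two_pi * mesh$a_o * wj *
        (a1[k] * kin$drds[k] * dNi + b[k] * Ni)
      R[n + ids] <- R[n + ids] + two_pi * mesh$a_o * wj *
        (a1[k] * kin$dzds[k] * dNi)
      # follower pressure (external), on the deformed surface
      R[ids] <- R[ids] - two_pi * P * wj * kin$r[k] * kin$dzds[k] * Ni
      R[n + ids] <- R[n + ids] + two_pi * P * wj * kin$r[k] * kin$drds[k] * Ni
    }
  }
  list(R = R, rho = rho, kin = kin)
}

#' Assemble the global tangent
#'
#' Consistent linearization of [assemble_residual()]: either the analytic
#' mode (element-level chain rule with machine-precision point derivatives,
#' implicit differentiation through the local mass solve, and exact follower
#' pressure linearization) or a column-wise finite difference of the global
#' residual.
#'
#' @inheritParams assemble_residual
#' @param rho converged local densities at `u` (from [assemble_residual()]).
#' @param mode `"analytic"` or `"numeric"`.
#' @return dense tangent matrix (`2 n_nodes` square, unconstrained).
#' @export
tangent <- function(mesh, u, loc, pars, P,
                    baseline = homeostatic_baseline(pars),
                    rho = NULL, mode = c("analytic", "numeric")) {
  mode <- match.arg(mode)
  n <- mesh$n_nodes
  if (mode == "numeric") {
    base <- assemble_residual(mesh, u, loc, pars, P, baseline,
                              rho_init = rho %||% rep(1, mesh$n_gp))
    if (is.null(base)) stop("residual not assemblable at this state")
    K <- matrix(0, 2L * n, 2L * n)
    hstep <- 1e-7
    for (j in seq_len(2L * n)) {
      up <- u; up[j] <- up[j] + hstep
      rj <- assemble_residual(mesh, up, loc, pars, P, baseline,
                              rho_init = base$rho)
      if (is.null(rj)) stop("residual not assemblable during finite differencing")
      K[, j] <- (rj$R - base$R) / hstep
    }
    return(K)
  }
  kin <- gp_kinematics(mesh, u)
  if (is.null(rho)) {
    rho <- solve_rho_gp(kin$lam_t, kin$lam_s, loc, pars, P, baseline$sigma_o,
                        rep(1, mesh$n_gp))
    if (is.null(rho)) stop("local solve failed; tangent unavailable")
  }
  d <- membrane_forces_d(kin$lam_t, kin$lam_s, rho, loc, pars, P,
                         baseline$sigma_o)
  K <- matrix(0, 2L * n, 2L * n)
  two_pi <- 2 * pi
  for (e in seq_len(mesh$n_elem)) {
    ids <- mesh$conn[e, ]
    for (g in 1:3) {
      k <- (e - 1L) * 3L + g
      wj <- mesh$w[g] * mesh$jac
      Ni <- mesh$N[g, ]
      dNi <- mesh$dN[g, ] / mesh$jac
      rp <- kin$drds[k]; zp <- kin$dzds[k]; rg <- kin$r[k]
      ls <- kin$lam_s[k]
      # variations: dlam_t = N_j dr / a_o ; dlam_s = (rp dN_j dr + zp dN_j dz)/ls
      dlt_r <- Ni / mesh$a_o
      dls_r <- rp * dNi / ls
      dls_z <- zp * dNi / ls
      da1_r <- d$a1_t[k] * dlt_r + d$a1_s[k] * dls_r
      da1_z <- d$a1_s[k] * dls_z
      db_r <- d$b_t[k] * dlt_r + d$b_s[k] * dls_r
      db_z <- d$b_s[k] * dls_z
      cf <- two_pi * mesh$a_o * wj
      # internal part
      K[ids, ids] <- K[ids, ids] + cf *
        (outer(rp * dNi, da1_r) + d$a1[k] * outer(dNi, dNi) +
           outer(Ni, db_r))
      K[ids, n + ids] <- K[ids, n + ids] + cf *
        (outer(rp * dNi, da1_z) + outer(Ni, db_z))
      K[n + ids, ids] <- K[n + ids, ids] + cf *
        (outer(zp * dNi, da1_r))
      K[n + ids, n + ids] <- K[n + ids, n + ids] + cf *
        (outer(zp * dNi, da1_z) + d$a1[k] * outer(dNi, dNi))
      # follower pressure, exact linearization
      pf <- two_pi * P * wj
      K[ids, ids] <- K[ids, ids] - pf * zp * outer(Ni, Ni)
      K[ids, n + ids] <- K[ids, n + ids] - pf * rg * outer(Ni, dNi)
      K[n + ids, ids] <- K[n + ids, ids] +
        pf * (rp * outer(Ni, Ni) + rg * outer(Ni, dNi))
    }
  }
  K
}

# ---------------------------------------------------------------------------
# Monolithic assembly: the continuation solver advances geometry and the
# referential collagen densities together (unknowns (u, rho)), which remains
# regular where the pointwise mass solve alone has a limit point (the local
# stimulus saturating at its setpoint) while the coupled equilibrium path
# continues.  The condensed forms above are retained as the verification API.

assemble_coupled <- function(mesh, u, rho, loc, pars, P, baseline) {
  kin <- gp_kinematics(mesh, u)
  if (any(!is.finite(kin$lam_t)) || any(kin$lam_t < 0.05) ||
      any(kin$lam_s < 0.05) || any(kin$lam_t > 60) || any(rho <= 0))
    return(NULL)
  pr <- point_response(kin$lam_t, kin$lam_s, rho, loc, pars, P)
  g <- mb_residual_kernel(pr, loc, baseline$sigma_o)
  a1 <- pars$h_o * pr$J * (pr$extra_z - pr$p) / kin$lam_s^2
  b <- pars$h_o * pr$J * (pr$extra_t - pr$p) / (kin$lam_t * pars$a_o)
  if (any(!is.finite(g)) || any(!is.finite(a1)) || any(!is.finite(b)))
    return(NULL)
  n <- mesh$n_nodes
  R <- numeric(2L * n)
  two_pi <- 2 * pi
  for (e in seq_len(mesh$n_elem)) {
    ids <- mesh$conn[e, ]
    for (gq in 1:3) {
      k <- (e - 1L) * 3L + gq
      wj <- mesh$w[gq] * mesh$jac
      Ni <- mesh$N[gq, ]
      dNi <- mesh$dN[gq, ] / mesh$jac
      R[ids] <- R[ids] + two_pi * mesh$a_o * wj *
        (a1[k] * kin$drds[k] * dNi + b[k] * Ni)
      R[n + ids] <- R[n + ids] + two_pi * mesh$a_o * wj *
        (a1[k] * kin$dzds[k] * dNi)
      R[ids] <- R[ids] - two_pi * P * wj * kin$r[k] * kin$dzds[k] * Ni
      R[n + ids] <- R[n + ids] + two_pi * P * wj * kin$r[k] * kin$drds[k] * Ni
    }
  }
  list(R = R, g = g, kin = kin)
}

tangent_coupled <- function(mesh, u, rho, loc, pars, P, baseline, kin) {
  h <- 1e-30
  ih <- (0+1i) * h
  fab <- function(lt, ls, rc) {
    pr <- point_response(lt, ls, rc, loc, pars, P)
    list(a1 = pars$h_o * pr$J * (pr$extra_z - pr$p) / ls^2,
         b  = pars$h_o * pr$J * (pr$extra_t - pr$p) / (lt * pars$a_o),
         g  = mb_residual_kernel(pr, loc, baseline$sigma_o))
  }
  im <- function(z) Im(z) / h
  ft <- fab(kin$lam_t + ih, kin$lam_s, rho)
  fs <- fab(kin$lam_t, kin$lam_s + ih, rho)
  fr <- fab(kin$lam_t, kin$lam_s, rho + ih)
  f0 <- fab(kin$lam_t, kin$lam_s, rho)
  n <- mesh$n_nodes
  ng <- mesh$n_gp
  Kuu <- matrix(0, 2L * n, 2L * n)
  Kur <- matrix(0, 2L * n, ng)
  Kru <- matrix(0, ng, 2L * n)
  two_pi <- 2 * pi
  for (e in seq_len(mesh$n_elem)) {
    ids <- mesh$conn[e, ]
    for (gq in 1:3) {
      k <- (e - 1L) * 3L + gq
      wj <- mesh$w[gq] * mesh$jac
      Ni <- mesh$N[gq, ]
      dNi <- mesh$dN[gq, ] / mesh$jac
      rp <- kin$drds[k]; zp <- kin$dzds[k]; rg <- kin$r[k]
      ls <- kin$lam_s[k]
      dlt_r <- Ni / mesh$a_o
      dls_r <- rp * dNi / ls
      dls_z <- zp * dNi / ls
      da1_r <- im(ft$a1)[k] * dlt_r + im(fs$a1)[k] * dls_r
      da1_z <- im(fs$a1)[k] * dls_z
      db_r <- im(ft$b)[k] * dlt_r + im(fs$b)[k] * dls_r
      db_z <- im(fs$b)[k] * dls_z
      cf <- two_pi * mesh$a_o * wj
      Kuu[ids, ids] <- Kuu[ids, ids] + cf *
        (outer(rp * dNi, da1_r) + Re(f0$a1)[k] * outer(dNi, dNi) +
           outer(Ni, db_r))
      Kuu[ids, n + ids] <- Kuu[ids, n + ids] + cf *
        (outer(rp * dNi, da1_z) + outer(Ni, db_z))
      Kuu[n + ids, ids] <- Kuu[n + ids, ids] + cf * outer(zp * dNi, da1_r)
      Kuu[n + ids, n + ids] <- Kuu[n + ids, n + ids] + cf *
        (outer(zp * dNi, da1_z) + Re(f0$a1)[k] * outer(dNi, dNi))
      pf <- two_pi * P * wj
      Kuu[ids, ids] <- Kuu[ids, ids] - pf * zp * outer(Ni, Ni)
      Kuu[ids, n + ids] <- Kuu[ids, n + ids] - pf * rg * outer(Ni, dNi)
      Kuu[n + ids, ids] <- Kuu[n + ids, ids] +
        pf * (rp * outer(Ni, Ni) + rg * outer(Ni, dNi))
      # coupling blocks
      Kur[ids, k] <- Kur[ids, k] + cf *
        (im(fr$a1)[k] * rp * dNi + im(fr$b)[k] * Ni)
      Kur[n + ids, k] <- Kur[n + ids, k] + cf * im(fr$a1)[k] * zp * dNi
      Kru[k, ids] <- Kru[k, ids] + im(ft$g)[k] * dlt_r + im(fs$g)[k] * dls_r
      Kru[k, n + ids] <- Kru[k, n + ids] + im(fs$g)[k] * dls_z
    }
  }
  list(Kuu = Kuu, Kur = Kur, Kru = Kru, Krr = im(fr$g))
}

# Field-wise predictor: solves the uniform (0-D) equilibrium problem at each
# node's local parameters and assembles the resulting radius and density
# fields as an initial guess for the full-load membrane Newton solve.  This
# lands inside the Newton basin of the final equilibrium when quasi-static
# continuation snaps through an intermediate fold.
fieldwise_predictor <- function(mesh, loc, P, pars, baseline) {
  at_node <- function(v) {
    if (length(v) == 1L) rep(v, mesh$n_nodes)
    else stats::approx(mesh$gp_z, v, xout = mesh$z_nodes, rule = 2)$y
  }
  loc_n <- lapply(loc, at_node)
  cfg0 <- uniform_solve_config(continuation_steps = 20, max_halvings = 6)
  lam <- rep(NA_real_, mesh$n_nodes)
  for (i in seq_len(mesh$n_nodes)) {
    ov <- lapply(loc_n, `[[`, i)
    st <- tryCatch(
      solve_uniform(pars, P = P, Q_ratio = ov$Q_ratio, overrides = ov,
                    config = cfg0, baseline = baseline),
      gnr_no_equilibrium = function(e) NULL, error = function(e) NULL)
    if (!is.null(st)) lam[i] <- st$lam_theta
  }
  if (all(is.na(lam))) return(NULL)
  if (anyNA(lam)) {
    ok <- which(!is.na(lam))
    lam <- stats::approx(mesh$z_nodes[ok], lam[ok], xout = mesh$z_nodes,
                         rule = 2)$y
  }
  u <- reference_dof(mesh)
  u[seq_len(mesh$n_nodes)] <- lam * mesh$a_o
  kin <- gp_kinematics(mesh, u)
  rho <- solve_rho_gp(kin$lam_t, kin$lam_s, loc, pars, P, baseline$sigma_o,
                      rep(1, mesh$n_gp))
  if (is.null(rho)) rho <- rep(1.2, mesh$n_gp)
  list(u = u, rho = rho)
}

# Riks-type (orthogonal-plane) arc-length continuation of the coupled
# equilibrium path R(u, rho; t) = 0, g(u, rho; t) = 0 in the continuation
# parameter t.  Geometry is scaled by the reference radius in the path norm.
# Returns the furthest state along the path; converged = TRUE only if t = 1
# is reached and a plain Newton polish at t = 1 succeeds.
arc_length_continue <- function(mesh, blend, free, u, rho, t0,
                                pars, baseline, config, r_scale, tol) {
  ng <- mesh$n_gp
  nf <- length(free)
  a_o <- mesh$a_o
  res_at <- function(u, rho, t) {
    b <- blend(t)
    assemble_coupled(mesh, u, rho, b$loc, pars, b$P, baseline)
  }
  sys_at <- function(u, rho, t, asm) {
    b <- blend(t)
    Kb <- tangent_coupled(mesh, u, rho, b$loc, pars, b$P, baseline, asm$kin)
    ht <- 1e-6
    asm2 <- res_at(u, rho, t + ht)               # blend is linear in t
    if (is.null(asm2)) return(NULL)
    Rt <- c((asm2$R[free] - asm$R[free]) / ht, (asm2$g - asm$g) / ht)
    list(K = rbind(cbind(Kb$Kuu[free, free, drop = FALSE],
                         Kb$Kur[free, , drop = FALSE]),
                   cbind(Kb$Kru[, free, drop = FALSE], diag(Kb$Krr, ng))),
         Rt = Rt)
  }
  merit <- function(asm) max(max(abs(asm$R[free])) / r_scale, max(abs(asm$g)))
  polish <- function(u, rho, t) {
    for (it in seq_len(config$max_iter)) {
      asm <- res_at(u, rho, t)
      if (is.null(asm)) return(NULL)
      if (max(abs(asm$R[free])) < tol && max(abs(asm$g)) < 1e-10)
        return(list(u = u, rho = rho))
      sy <- sys_at(u, rho, t, asm)
      if (is.null(sy)) return(NULL)
      dx <- tryCatch(solve(sy$K, -c(asm$R[free], asm$g)),
                     error = function(e) NULL)
      if (is.null(dx) || any(!is.finite(dx))) return(NULL)
      sc <- max(1, max(abs(dx[seq_len(nf)])) / (0.5 * a_o),
                max(abs(dx[nf + seq_len(ng)]) / (0.5 * pmax(rho, 1))))
      u[free] <- u[free] + dx[seq_len(nf)] / sc
      rho <- pmax(rho + dx[nf + seq_len(ng)] / sc, 1e-8)
    }
    NULL
  }
  # initial path tangent at the current point
  asm <- res_at(u, rho, t0)
  if (is.null(asm)) return(list(u = u, rho = rho, t = t0, converged = FALSE,
                                steps = list()))
  sy <- sys_at(u, rho, t0, asm)
  if (is.null(sy)) return(list(u = u, rho = rho, t = t0, converged = FALSE,
                               steps = list()))
  dxdt <- tryCatch(solve(sy$K, -sy$Rt), error = function(e) NULL)
  if (is.null(dxdt) || any(!is.finite(dxdt)))
    return(list(u = u, rho = rho, t = t0, converged = FALSE, steps = list()))
  v <- c(dxdt[seq_len(nf)] / a_o, dxdt[nf + seq_len(ng)], 1)
  v <- v / sqrt(sum(v^2))
  dt0 <- 1 / config$continuation_steps
  dl <- min(dt0 / max(abs(v[nf + ng + 1L]), 1e-3), 1)
  t <- t0
  best <- list(u = u, rho = rho, t = t0)
  steps <- list()
  fails <- 0L
  for (step in 1:400) {
    # predictor
    u_p <- u; u_p[free] <- u[free] + dl * v[seq_len(nf)] * a_o
    rho_p <- pmax(rho + dl * v[nf + seq_len(ng)], 1e-8)
    t_p <- t + dl * v[nf + ng + 1L]
    ok <- FALSE
    u_c <- u_p; rho_c <- rho_p; t_c <- t_p
    for (it in 1:15) {
      asm <- res_at(u_c, rho_c, t_c)
      if (is.null(asm)) break
      con <- sum(v * c((u_c[free] - u_p[free]) / a_o, rho_c - rho_p,
                       t_c - t_p))
      if (max(abs(asm$R[free])) < tol && max(abs(asm$g)) < 1e-10 &&
          abs(con) < 1e-10) { ok <- TRUE; break }
      sy <- sys_at(u_c, rho_c, t_c, asm)
      if (is.null(sy)) break
      A <- rbind(cbind(sy$K, sy$Rt),
                 c(v[seq_len(nf)] / a_o, v[nf + seq_len(ng)],
                   v[nf + ng + 1L]))
      dx <- tryCatch(solve(A, -c(asm$R[free], asm$g, con)),
                     error = function(e) NULL)
      if (is.null(dx) || any(!is.finite(dx))) break
      sc <- max(1, max(abs(dx[seq_len(nf)])) / (0.5 * a_o),
                max(abs(dx[nf + seq_len(ng)]) / (0.5 * pmax(rho_c, 1))))
      u_c[free] <- u_c[free] + dx[seq_len(nf)] / sc
      rho_c <- pmax(rho_c + dx[nf + seq_len(ng)] / sc, 1e-8)
      t_c <- t_c + dx[nf + ng + 1L] / sc
    }
    if (!ok) {
      fails <- fails + 1L
      dl <- dl / 2
      if (fails > 30L || dl < 1e-5) break
      next
    }
    v_new <- c((u_c[free] - u[free]) / a_o, rho_c - rho, t_c - t)
    nv <- sqrt(sum(v_new^2))
    if (nv > 0) {
      v_new <- v_new / nv
      if (sum(v_new * v) > 0) v <- v_new   # keep direction continuity
    }
    u <- u_c; rho <- rho_c; t <- t_c
    steps[[length(steps) + 1L]] <- list(t = t, u = u, rho = rho,
                                        newton_log = numeric(0))
    if (t > best$t) best <- list(u = u, rho = rho, t = t)
    if (t >= 1 - 1e-10) {
      pol <- polish(u, rho, 1)
      if (!is.null(pol))
        return(list(u = pol$u, rho = pol$rho, t = 1, converged = TRUE,
                    steps = steps))
      break
    }
    if (t >= 1 - dl * abs(v[nf + ng + 1L])) {
      # try to land exactly on t = 1 from here
      pol <- polish(u, rho, 1)
      if (!is.null(pol)) {
        steps[[length(steps) + 1L]] <- list(t = 1, u = pol$u, rho = pol$rho,
                                            newton_log = numeric(0))
        return(list(u = pol$u, rho = pol$rho, t = 1, converged = TRUE,
                    steps = steps))
      }
    }
    if (t < best$t - 0.4) break        # path recedes: no equilibrium at t = 1
    dl <- min(dl * 1.4, 1)
  }
  list(u = best$u, rho = best$rho, t = best$t, converged = FALSE,
       steps = steps)
}

#' Solve a localized growth-and-remodeling scenario on the membrane mesh
#'
#' Quasi-static continuation over insult magnitude and pressure with a global
#' Newton solve at every step and the local mechanobiological equilibrium
#' enforced at every Gauss point.  On divergence the continuation step is
#' halved (up to `config$max_halvings`); exhaustion returns the last
#' converged state flagged as unconverged (mechanobiological static
#' instability).
#'
#' @param mesh a [build_mesh()] object.
#' @param loc_target resolved local parameters at full insult (named list of
#'   per-Gauss-point vectors or scalars).
#' @param P_target target pressure (kPa).
#' @param pars baseline parameters.
#' @param config a [fem_solve_config()].
#' @param baseline a [homeostatic_baseline()].
#' @param label scenario label carried into the result.
#' @param init optional starting point for staged continuation: a previous
#'   `gnr_result` (or list with `u` and `rho`) whose state corresponds to
#'   `loc_start` / `P_start`.
#' @param loc_start,P_start parameters and pressure at the start of the
#'   continuation (defaults: the insult-free baseline at `P_o`); equilibrated
#'   states are path-independent, so staged ramps (insult first, then risk
#'   factors) may be chained through `init`.
#' @return a `gnr_result` object: per-step nodal geometry, final Gauss point
#'   states, convergence log, and metadata.
#' @export
solve_scenario <- function(mesh, loc_target, P_target, pars,
                           config = fem_solve_config(),
                           baseline = homeostatic_baseline(pars),
                           label = "scenario", init = NULL,
                           loc_start = NULL, P_start = NULL) {
  loc_base <- if (is.null(loc_start)) resolve_local(pars) else loc_start
  P_base <- if (is.null(P_start)) baseline$P_o else P_start
  blend <- function(t) {
    loc <- loc_base
    for (nm in names(loc))
      loc[[nm]] <- loc_base[[nm]] + t * (loc_target[[nm]] - loc_base[[nm]])
    list(loc = loc, P = P_base + t * (P_target - P_base))
  }
  n <- mesh$n_nodes
  free <- free_dof_index(mesh)
  u <- if (is.null(init)) reference_dof(mesh) else init$u
  rho <- if (is.null(init)) rep(1, mesh$n_gp) else init$rho
  r_scale <- 2 * pi * mesh$a_o * mesh$h_o * baseline$sigma_o
  tol <- config$newton_tol * r_scale

  ng <- mesh$n_gp
  merit <- function(asm) max(max(abs(asm$R[free])) / r_scale, max(abs(asm$g)))
  newton_step <- function(u, rho, loc, P) {
    log_norm <- numeric(0)
    asm <- assemble_coupled(mesh, u, rho, loc, pars, P, baseline)
    if (is.null(asm)) return(NULL)
    for (it in seq_len(config$max_iter)) {
      m0 <- merit(asm)
      log_norm <- c(log_norm, m0)
      if (max(abs(asm$R[free])) < tol && max(abs(asm$g)) < 1e-10)
        return(list(u = u, rho = rho, log = log_norm))
      Kb <- tangent_coupled(mesh, u, rho, loc, pars, P, baseline, asm$kin)
      K <- rbind(cbind(Kb$Kuu[free, free, drop = FALSE],
                       Kb$Kur[free, , drop = FALSE]),
                 cbind(Kb$Kru[, free, drop = FALSE], diag(Kb$Krr, ng)))
      dx <- tryCatch(solve(K, -c(asm$R[free], asm$g)),
                     error = function(e) NULL)
      if (is.null(dx) || any(!is.finite(dx))) return(NULL)
      du <- dx[seq_along(free)]
      dr <- dx[length(free) + seq_len(ng)]
      # joint damping: at most half a radius geometrically and a 50% change
      # of any local density within a full step
      sc <- max(1, max(abs(du)) / (0.5 * mesh$a_o),
                max(abs(dr) / (0.5 * pmax(rho, 1))))
      # backtracking line search on the residual merit
      accepted <- FALSE
      step <- 1 / sc
      for (ls in 1:7) {
        u_t <- u; u_t[free] <- u[free] + step * du
        rho_t <- pmax(rho + step * dr, 1e-8)
        asm_t <- assemble_coupled(mesh, u_t, rho_t, loc, pars, P, baseline)
        if (!is.null(asm_t) && is.finite(merit(asm_t)) &&
            (merit(asm_t) < (1 - 0.2 * step) * m0 || merit(asm_t) < 1e-13)) {
          u <- u_t; rho <- rho_t; asm <- asm_t; accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) return(NULL)
    }
    NULL
  }

  steps <- list()
  t_now <- 0
  dt0 <- 1 / config$continuation_steps
  dt <- dt0
  halvings <- 0L                      # consecutive failures at the current front
  failures <- 0L                      # total failed attempts (effort budget)
  converged <- TRUE
  while (t_now < 1 - 1e-12) {
    t_try <- min(1, t_now + dt)
    b <- blend(t_try)
    sol <- newton_step(u, rho, b$loc, b$P)
    if (is.null(sol)) {
      halvings <- halvings + 1L
      failures <- failures + 1L
      dt <- dt / 2
      if (halvings > config$max_halvings || failures > 3L * config$max_halvings) {
        converged <- FALSE
        break
      }
      next
    }
    u <- sol$u; rho <- sol$rho
    t_now <- t_try
    halvings <- 0L
    dt <- min(dt * 2, dt0)            # recover the nominal step after success
    steps[[length(steps) + 1L]] <-
      list(t = t_now, u = u, rho = rho, newton_log = sol$log)
  }

  if (!converged && config$arc_length) {
    # quasi-static stepping snapped through a fold; try to land directly on
    # the full-load equilibrium from the field-wise 0-D predictor
    bf <- blend(1)
    pred <- fieldwise_predictor(mesh, bf$loc, bf$P, pars, baseline)
    if (!is.null(pred)) {
      sol <- newton_step(pred$u, pred$rho, bf$loc, bf$P)
      if (!is.null(sol)) {
        u <- sol$u; rho <- sol$rho; t_now <- 1; converged <- TRUE
        steps[[length(steps) + 1L]] <-
          list(t = 1, u = u, rho = rho, newton_log = sol$log)
      }
    }
  }
  if (!converged && config$arc_length) {
    # Riks-type arc-length path following from the last converged state:
    # traverses snap-through folds of the membrane where load stepping stalls
    # although an equilibrium at full load exists.
    arc <- arc_length_continue(mesh, blend, free, u, rho, t_now,
                               pars, baseline, config, r_scale, tol)
    u <- arc$u; rho <- arc$rho; t_now <- arc$t
    converged <- arc$converged
    if (length(arc$steps))
      steps <- c(steps, arc$steps)
  }
  t_reached <- t_now
  b <- blend(t_reached)
  kin <- gp_kinematics(mesh, u)
  pr <- point_response(kin$lam_t, kin$lam_s, rho, b$loc, pars, b$P)
  ct <- stiffness_from_response(pr, b$loc, pars, include_active = FALSE)
  gp_table <- data.frame(z_o = mesh$gp_z, r = kin$r,
                         lam_theta = kin$lam_t, lam_z = kin$lam_s,
                         rho_c = rho, rho_m = Re(pr$rho_m), J = Re(pr$J),
                         W = Re(pr$W), c_tttt = Re(ct),
                         sigma_v = Re(pr$sigma_v),
                         tau_ratio = Re(pr$tau_ratio),
                         alpha_0h = Re(pr$alpha))
  structure(list(mesh = mesh, steps = steps, converged = converged,
                 t_reached = t_reached, u = u, rho = rho,
                 loc_final = b$loc, P_final = b$P,
                 gp_table = gp_table, baseline = baseline, pars = pars,
                 label = label),
            class = "gnr_result")
}

#' @export
print.gnr_result <- function(x, ...) {
  dmax <- 100 * (max(x$u[seq_len(x$mesh$n_nodes)]) / x$mesh$a_o - 1)
  cat(sprintf("G&R scenario '%s': %s (continuation fraction %.3f)\n",
              x$label,
              if (x$converged) "converged" else "no equilibrium (instability)",
              x$t_reached))
  cat(sprintf("  max local diameter increase: %.1f%%\n", dmax))
  invisible(x)
}

#' Interpolated equilibrated state at an axial station
#'
#' Evaluates the membrane stretches at reference coordinate `z` from the
#' finite-element interpolation of the final converged geometry and performs
#' the local constitutive update there.
#'
#' @param result a `gnr_result`.
#' @param z reference axial coordinate (mm).
#' @return a `gnr_point_state`.
#' @export
probe_state <- function(result, z) {
  mesh <- result$mesh
  stopifnot(z >= 0, z <= mesh$l_o)
  h_e <- mesh$l_o / mesh$n_elem
  e <- min(mesh$n_elem, max(1L, ceiling(z / h_e)))
  z0 <- (e - 1) * h_e
  xi <- 2 * (z - z0) / h_e - 1
  N <- c(xi * (xi - 1) / 2, 1 - xi^2, xi * (xi + 1) / 2)
  dN <- c(xi - 0.5, -2 * xi, xi + 0.5) / mesh$jac
  ids <- mesh$conn[e, ]
  n <- mesh$n_nodes
  r <- sum(N * result$u[ids])
  drds <- sum(dN * result$u[ids])
  dzds <- sum(dN * result$u[n + ids])
  lam_t <- r / mesh$a_o
  lam_s <- sqrt(drds^2 + dzds^2)
  # local parameters at z by the same interpolation rule as the fields
  loc <- lapply(result$loc_final, function(v) {
    if (length(v) == 1L) return(v)
    stats::approx(mesh$gp_z, v, xout = z, rule = 2)$y
  })
  rho0 <- stats::approx(mesh$gp_z, result$rho, xout = z, rule = 2)$y
  pars <- result$pars
  locr <- resolve_local(pars, loc[local_overridable()])
  # polish the interpolated density against the local residual where the
  # root is regular; keep the interpolated value otherwise (near a local
  # fold the converged field itself is the best value available)
  rho <- solve_rho_gp(lam_t, lam_s, locr, pars, result$P_final,
                      result$baseline$sigma_o, rho0)
  if (is.null(rho) || abs(rho - rho0) > 0.2 * max(1, rho0)) rho <- rho0
  new_point_state(lam_t, lam_s, rho, locr, pars, result$P_final)
}
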