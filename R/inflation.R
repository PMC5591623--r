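#' Inflate the residually-stressed artery to a given lumen pressure
#'
#' Solves the plane-strain boundary-value problem for the intact
#' two-layer wall under lumen pressure `p_lumen`, composing the total
#' deformation directly from the stress-free open sector (a single
#' incompressible map with the same closing factor).  The deformed
#' inner radius is the root of
#' \deqn{\int_{r_i}^{r_o} (\sigma_{\theta\theta} - \sigma_{rr})
#'   \frac{dr}{r} = p,}
#' with \eqn{\sigma_{rr}(r_i) = -p} and \eqn{\sigma_{rr}(r_o) = 0}.
#' At `p_lumen = 0` this reduces exactly to [solve_unloaded()].
#'
#' @param sector an [open_sector()] (its `alpha` sets the residual
#'   stress).
#' @param materials a [wall_materials()].
#' @param p_lumen lumen pressure, kPa (non-negative).
#' @param n_nodes output grid size.
#' @param panels,order composite quadrature per layer.
#' @return Object of class `loaded_solution`: list with `annulus`
#'   (deformed geometry carrying `p_lumen`), `state` (a `wall_state`),
#'   `p_norm` (pressure over the media matrix stiffness) and `info`.
#' @export
solve_loaded <- function(sector, materials, p_lumen, n_nodes = 401,
                         panels = 10, order = 10) {
  stopifnot(inherits(sector, "open_sector"),
            inherits(materials, "wall_materials"))
  if (p_lumen < 0) stop("lumen pressure must be non-negative")
  f <- function(a)
    .forward_residual(sector, a, materials, panels, order) - p_lumen
  lower <- 0.01 * sector$R_i
  upper <- sector$R_o
  expands <- 0L
  while (f(upper) < 0 && expands < 3L) {
    upper <- 2 * upper
    expands <- expands + 1L
  }
  sol <- .safe_root(f, lower, upper, tol_x = 1e-13,
                    what = "solve_loaded")
  a <- sol$root
  k <- k_factor(sector$alpha)
  r_m <- sqrt((sector$R_m^2 - sector$R_i^2) / k + a^2)
  r_o <- sqrt((sector$R_o^2 - sector$R_i^2) / k + a^2)
  annulus <- closed_annulus(a, r_m, r_o, p_lumen = p_lumen)
  grid <- .profile_grid(a, r_m, r_o, n_nodes)
  state <- .compute_profile(k, sector$R_i, a, grid, materials,
                            s_rr_inner = -p_lumen)
  structure(
    list(annulus = annulus, state = state,
         p_norm = p_lumen / materials$media$c,
         info = list(iterations = sol$iter, residual = sol$f_root,
                     bracket = c(lower, upper),
                     bracket_expansions = expands)),
    class = "loaded_solution")
}

#' @export
print.loaded_solution <- function(x, ...) {
  cat(sprintf(
    "Loaded artery: p = %g kPa (p/c = %.4g), r_i = %.4f mm\n",
    x$annulus$p_lumen, x$p_norm, x$annulus$r_i))
  invisible(x)
}

#' Pressure-radius response of the intact artery
#'
#' Sweeps [solve_loaded()] over a grid of lumen pressures and tabulates
#' the deformed inner radius and the dimensionless pressure.
#'
#' @inheritParams solve_loaded
#' @param p_grid non-negative, strictly increasing pressures, kPa.
#' @return Data frame with columns `p_kPa`, `r_i_mm`, `p_norm`, one row
#'   per pressure in input order.
#' @export
pressure_radius_curve <- function(sector, materials, p_grid,
                                  n_nodes = 201) {
  stopifnot(is.numeric(p_grid), length(p_grid) >= 1)
  if (any(p_grid < 0)) stop("pressures must be non-negative")
  if (is.unsorted(p_grid, strictly = TRUE) && length(p_grid) > 1)
    stop("pressure grid must be strictly increasing")
  rows <- lapply(p_grid, function(p) {
    sol <- tryCatch(
      solve_loaded(sector, materials, p, n_nodes),
      error = function(e) stop(sprintf(
        "inflation failed at p = %g kPa: %s", p, conditionMessage(e)),
        call. = FALSE))
    data.frame(p_kPa = p, r_i_mm = sol$annulus$r_i, p_norm = sol$p_norm)
  })
  do.call(rbind, rows)
}

# max principal stress over a shear-free wall state: the stress tensor
# is diagonal in (r, theta, z), so no eigendecomposition is needed.
.max_principal <- function(state) {
  s <- pmax(state$sigma_rr_kPa, state$sigma_tt_kPa, state$sigma_zz_kPa)
  i <- which.max(s)
  list(value = s[i], r = state$r_mm[i])
}

#' Approximate tear-initiation pressure of the intact wall
#'
#' Estimates the smallest lumen pressure at which the maximum principal
#' Cauchy stress anywhere in the intact, axisymmetric wall reaches the
#' cohesive strength `T_c` (the initiation criterion
#' \eqn{\sigma_{mp} \ge T_c}).  This is a deliberately low-fidelity
#' surrogate for the critical pressure of a dissection: it ignores the
#' tear geometry, the stress concentration at its tips, and inner-wall
#' buckling, so its value is meaningful for trends across opening
#' angles rather than as an absolute strength prediction.
#'
#' @inheritParams solve_loaded
#' @param T_c cohesive strength threshold, kPa.
#' @param tol bisection tolerance on the pressure as a fraction of the
#'   media matrix stiffness.
#' @param n_nodes grid size used when scanning the wall stress.
#' @return List with `p_c` (kPa), `p_norm` (`p_c` over the media
#'   stiffness), `location_mm` (radius where the criterion is first
#'   met) and `flag` (`"ok"` or `"already_initiated"`).
#' @export
initiation_pressure <- function(sector, materials, T_c,
                                tol = 1e-6, n_nodes = 201) {
  stopifnot(T_c > 0)
  c_m <- materials$media$c
  g <- function(p) {
    st <- solve_loaded(sector, materials, p, n_nodes)$state
    .max_principal(st)
  }
  g0 <- g(0)
  if (g0$value >= T_c)
    return(list(p_c = 0, p_norm = 0, location_mm = g0$r,
                flag = "already_initiated"))
  # the inflation problem can have a limit pressure (no equilibrium
  # beyond it); treat infeasible pressures as the top of the bracket
  g_try <- function(p) tryCatch(g(p), error = function(e) NULL)
  hi <- 5 * c_m
  g_hi <- g_try(hi)
  halvings <- 0L
  while (is.null(g_hi) && halvings < 40L) {
    hi <- hi / 2
    g_hi <- g_try(hi)
    halvings <- halvings + 1L
  }
  if (is.null(g_hi))
    stop("inflation failed at every bracket pressure")
  expands <- 0L
  while (g_hi$value < T_c && expands < 3L) {
    g2 <- g_try(2 * hi)
    if (is.null(g2)) {
      # approach the stability limit from below
      lo_f <- hi; hi_inf <- 2 * hi
      for (i in 1:30) {
        mid <- (lo_f + hi_inf) / 2
        gm <- g_try(mid)
        if (is.null(gm)) hi_inf <- mid
        else { lo_f <- mid; g_hi <- gm; hi <- mid }
      }
      break
    }
    hi <- 2 * hi
    g_hi <- g2
    expands <- expands + 1L
  }
  if (g_hi$value < T_c)
    stop(sprintf(
      paste0("no initiation up to p = %g kPa: max principal stress ",
             "%.4g kPa stays below T_c = %g kPa"), hi, g_hi$value, T_c))
  lo <- 0
  while (hi - lo > tol * c_m) {
    mid <- (lo + hi) / 2
    if (g(mid)$value >= T_c) hi <- mid else lo <- mid
  }
  at <- g(hi)
  list(p_c = hi, p_norm = hi / c_m, location_mm = at$r, flag = "ok")
}
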