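#' @importFrom stats uniroot optimize rnorm runif setNames
#' @importFrom utils modifyList
NULL

# Gauss-Legendre nodes/weights on [a, b]; thin cache over pracma since
# the solvers request the same orders repeatedly.
.gauss_cache <- new.env(parent = emptyenv())
.gauss_ref <- function(n) {
  key <- as.character(n)
  g <- .gauss_cache[[key]]
  if (is.null(g)) {
    g <- pracma::gaussLegendre(n, -1, 1)
    .gauss_cache[[key]] <- g
  }
  g
}
.gauss_on <- function(a, b, n) {
  g <- .gauss_ref(n)
  list(x = (b - a) / 2 * g$x + (a + b) / 2, w = (b - a) / 2 * g$w)
}

# Composite Gauss-Legendre rule: `panels` equal panels of `order`
# points each.  Stiff fibre exponentials (k2 up to ~30) defeat a
# single high-order panel; a composite rule keeps the residual at
# quadrature accuracy across the admissible parameter range.
.gauss_composite <- function(a, b, panels, order) {
  g <- .gauss_ref(order)
  edges <- seq(a, b, length.out = panels + 1L)
  lo <- edges[-(panels + 1L)]
  h2 <- (edges[2L] - edges[1L]) / 2
  mid <- lo + h2
  list(x = as.vector(outer(h2 * g$x, mid, `+`)),
       w = rep(h2 * g$w, times = panels))
}

# Safeguarded bracketed root solve.  The HGO exponential can overflow
# to +Inf at extreme bracket endpoints; the sign is still meaningful,
# so non-finite values are clamped to huge signed numbers and the
# bracketing logic proceeds unchanged.  Raw Newton is deliberately
# avoided: it can escape the physical branch.
.safe_root <- function(f, lower, upper, tol_x, what = "root") {
  clamp <- function(v) {
    if (is.nan(v)) stop(what, ": residual evaluated to NaN")
    if (!is.finite(v)) v <- sign(v) * 1e300
    v
  }
  f_s <- function(x) clamp(f(x))
  fl <- f_s(lower); fu <- f_s(upper)
  if (fl == 0) return(list(root = lower, f_root = 0, iter = 0L))
  if (fu == 0) return(list(root = upper, f_root = 0, iter = 0L))
  if (sign(fl) == sign(fu))
    stop(sprintf(
      "%s: no sign change in bracket [%g, %g] (f = %g, %g)",
      what, lower, upper, fl, fu))
  sol <- uniroot(f_s, c(lower, upper), f.lower = fl, f.upper = fu,
                 tol = tol_x, maxiter = 1000L)
  # Guarded Newton polish: for stiff fibre parameters the residual
  # slope can exceed 1e8 kPa/mm, so the x-converged uniroot solution
  # can still carry a visible residual.  Accept only improving steps.
  x <- sol$root
  fx <- f(x)
  h <- 1e-7 * max(abs(x), 1)
  for (i in 1:5) {
    if (fx == 0) break
    fp <- (f_s(x + h) - f_s(x - h)) / (2 * h)
    if (!is.finite(fp) || fp == 0) break
    xn <- x - fx / fp
    if (!is.finite(xn) || xn <= 0) break
    fn <- f(xn)
    if (!is.finite(fn) || abs(fn) >= abs(fx)) break
    x <- xn
    fx <- fn
  }
  list(root = x, f_root = fx, iter = sol$iter)
}

# Deformed radius at which the fibre families of `layer` switch on
# (lam_t cos(beta) = 1, i.e. I4 = 1).  The tension-only switch puts a
# derivative kink in every stress integrand there; making it an
# explicit quadrature breakpoint restores spectral convergence.
# lam_t^2 = k^2 r^2 / (k r^2 - k r_i^2 + R_i^2) crosses a level at
# most once inside the wall, with the closed form below.
.engagement_radius <- function(k, R_i, r_i_ref, layer) {
  if (layer$k1 <= 0) return(numeric(0))
  cb <- cos(layer$beta * pi / 180)
  if (cb <= 1e-12) return(numeric(0))
  L2 <- 1 / cb^2
  den <- k * (k - L2)
  if (den == 0) return(numeric(0))
  rc2 <- L2 * (R_i^2 - k * r_i_ref^2) / den
  if (!is.finite(rc2) || rc2 <= 0) return(numeric(0))
  sqrt(rc2)
}

# Integrate f over [a, b] with composite Gauss, splitting at interior
# breakpoints and allocating panels proportionally to piece width.
.integrate_split <- function(f, a, b, breaks, panels, order) {
  pts <- c(a, breaks[breaks > a & breaks < b], b)
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    np <- max(2L, ceiling(panels * (pts[i + 1L] - pts[i]) / (b - a)))
    g <- .gauss_composite(pts[i], pts[i + 1L], np, order)
    total <- total + sum(g$w * f(g$x))
  }
  total
}

# Forward integrand: equilibrium condition written in the reference
# variable R (dr/r = R dR / (k r^2)), avoiding inversion of the map.
.forward_residual <- function(sector, r_i, materials, panels = 10,
                              order = 10) {
  k <- k_factor(sector$alpha)
  seg <- list(c(sector$R_i, sector$R_m), c(sector$R_m, sector$R_o))
  lay <- list(materials$media, materials$adventitia)
  total <- 0
  for (j in 1:2) {
    layer <- lay[[j]]
    f <- function(R) {
      r <- sqrt((R^2 - sector$R_i^2) / k + r_i^2)
      lam_t <- k * r / R
      .stress_diff_raw(1 / lam_t, lam_t, layer) * R / (k * r^2)
    }
    rc <- .engagement_radius(k, sector$R_i, r_i, layer)
    Rc <- if (length(rc) && k * (rc^2 - r_i^2) + sector$R_i^2 > 0)
      sqrt(k * (rc^2 - r_i^2) + sector$R_i^2) else numeric(0)
    total <- total +
      .integrate_split(f, seg[[j]][1], seg[[j]][2], Rc, panels, order)
  }
  total
}

# Inverse integrand: same condition written directly in r.
.inverse_residual <- function(annulus, R_i, alpha, materials,
                              panels = 10, order = 10) {
  k <- k_factor(alpha)
  seg <- list(c(annulus$r_i, annulus$r_m), c(annulus$r_m, annulus$r_o))
  lay <- list(materials$media, materials$adventitia)
  total <- 0
  for (j in 1:2) {
    layer <- lay[[j]]
    f <- function(r) {
      R <- sqrt(k * (r^2 - annulus$r_i^2) + R_i^2)
      lam_t <- k * r / R
      .stress_diff_raw(1 / lam_t, lam_t, layer) / r
    }
    rc <- .engagement_radius(k, R_i, annulus$r_i, layer)
    total <- total +
      .integrate_split(f, seg[[j]][1], seg[[j]][2], rc, panels, order)
  }
  total
}

#' Equilibrium integral residual of the closing problem
#'
#' The traction-free closed state satisfies
#' \deqn{\int_{r_i}^{r_o} (\sigma_{\theta\theta} - \sigma_{rr})
#'   \frac{dr}{r} = 0.}
#' For a given open sector and a candidate closed inner radius this
#' function returns the value of that integral (kPa), computed by a
#' change of variable to the reference radius and integrated per layer
#' with composite Gauss-Legendre quadrature (the layer interface is
#' always a panel boundary).  The closed inner radius of the unloaded
#' artery is the root of this residual.
#'
#' @param sector an [open_sector()].
#' @param r_i_candidate candidate closed inner radius, mm.
#' @param materials a [wall_materials()].
#' @param panels,order composite-quadrature panels per layer and Gauss
#'   order per panel.
#' @return Integral value, kPa.
#' @export
wall_residual <- function(sector, r_i_candidate, materials,
                          panels = 10, order = 10) {
  stopifnot(inherits(sector, "open_sector"),
            inherits(materials, "wall_materials"))
  if (!is.finite(r_i_candidate) || r_i_candidate <= 0)
    stop("candidate inner radius makes the radial map degenerate")
  .forward_residual(sector, r_i_candidate, materials, panels, order)
}

# Node allocation: n_nodes unique radii, interface always a node, at
# least two nodes per layer; interface row is duplicated (one row per
# layer) so the hoop-stress jump is representable.
.profile_grid <- function(r_i, r_m, r_o, n_nodes) {
  stopifnot(n_nodes >= 11)
  frac <- (r_m - r_i) / (r_o - r_i)
  m <- 1L + min(max(2L, round((n_nodes - 1L) * frac)), n_nodes - 3L)
  list(media = seq(r_i, r_m, length.out = m),
       adventitia = seq(r_m, r_o, length.out = n_nodes - m + 1L))
}

# Cumulative radial-stress profile across both layers.  Integration of
# (s_tt - s_rr)/r runs interval-by-interval with composite Gauss
# quadrature on a sub-divided grid, so accuracy is quadrature-limited
# rather than set by the output grid density (stiff fibre exponentials
# need narrow panels even when few output nodes are requested).
# lam_t(r) needs the reference map, parameterised by (k, R_i, r_i_ref).
.compute_profile <- function(k, R_i, r_i_ref, grid, materials,
                             s_rr_inner, n_gauss_int = 8,
                             n_sub = 4L) {
  lay <- list(materials$media, materials$adventitia)
  names(lay) <- c("media", "adventitia")
  g <- .gauss_ref(n_gauss_int)
  s_start <- s_rr_inner
  out <- vector("list", 2L)
  for (j in 1:2) {
    r <- grid[[j]]
    m <- length(r)
    # refined integration grid: n_sub equal pieces per output interval
    sub <- vapply(seq_len(n_sub) - 1L,
                  function(s) r[-m] + (r[-1L] - r[-m]) * s / n_sub,
                  numeric(m - 1L))
    rf <- sort(c(as.vector(sub), r[m]))
    a <- rf[-length(rf)]; b <- rf[-1L]
    h2 <- (b - a) / 2; mid <- (a + b) / 2
    # quadrature points: intervals x gauss nodes
    rq <- outer(h2, g$x) + mid
    Rq <- sqrt(k * (rq^2 - r_i_ref^2) + R_i^2)
    ltq <- k * rq / Rq
    dq <- .stress_diff_raw(1 / ltq, ltq, lay[[j]])
    incr <- (matrix(dq / rq, nrow = length(a)) %*% g$w) * h2
    # fibre-engagement kink: redo the interval containing it with a
    # split rule so the derivative jump sits on a panel boundary
    layer <- lay[[j]]
    f_int <- function(rr) {
      RR <- sqrt(k * (rr^2 - r_i_ref^2) + R_i^2)
      lt <- k * rr / RR
      .stress_diff_raw(1 / lt, lt, layer) / rr
    }
    for (rc in .engagement_radius(k, R_i, r_i_ref, layer)) {
      hit <- which(a < rc & rc < b)
      for (i in hit)
        incr[i] <- .integrate_split(f_int, a[i], b[i], rc, 2L,
                                    n_gauss_int)
    }
    s_rr_fine <- s_start + c(0, cumsum(incr))
    s_rr <- s_rr_fine[1L + (seq_len(m) - 1L) * n_sub]
    Rn <- sqrt(k * (r^2 - r_i_ref^2) + R_i^2)
    lam_t <- k * r / Rn
    pt <- deformation_point(1 / lam_t, lam_t, 1)
    st <- cauchy_stress(pt, lay[[j]], s_rr)
    out[[j]] <- data.frame(
      r_mm = r, layer = names(lay)[j],
      lambda_r = pt$lam_r, lambda_t = pt$lam_t,
      sigma_rr_kPa = st$s_rr, sigma_tt_kPa = st$s_tt,
      sigma_zz_kPa = st$s_zz, p_lag_kPa = st$p_lag,
      stringsAsFactors = FALSE)
    s_start <- s_rr[length(s_rr)]
  }
  df <- rbind(out[[1L]], out[[2L]])
  rownames(df) <- NULL
  class(df) <- c("wall_state", "data.frame")
  df
}

#' @export
print.wall_state <- function(x, ...) {
  cat(sprintf(
    paste0("Wall state: %d nodes, r in [%.4f, %.4f] mm\n",
           "  sigma_rr range [%.4g, %.4g] kPa, ",
           "sigma_tt range [%.4g, %.4g] kPa\n"),
    nrow(x), min(x$r_mm), max(x$r_mm),
    min(x$sigma_rr_kPa), max(x$sigma_rr_kPa),
    min(x$sigma_tt_kPa), max(x$sigma_tt_kPa)))
  invisible(x)
}

#' Close an open sector into the unloaded residually-stressed annulus
#'
#' Forward opening-angle problem: given the stress-free open sector and
#' its materials, find the closed inner radius for which the annulus is
#' in equilibrium with traction-free surfaces, then recover the full
#' transmural stress state.  The root is found by safeguarded
#' bracketing on [wall_residual()] over `[0.01 R_i, R_o]`.
#'
#' @param sector an [open_sector()].
#' @param materials a [wall_materials()].
#' @param n_nodes output grid size (unique radii; the interface row is
#'   duplicated per layer).
#' @param panels,order composite quadrature for the root solve; a
#'   doubled-panel refinement check is reported in `info`.
#' @return List with elements `annulus` (a [closed_annulus()]), `state`
#'   (a `wall_state` profile) and `info` (iterations, residual, bracket
#'   and quadrature-refinement diagnostics).
#' @export
solve_unloaded <- function(sector, materials, n_nodes = 401,
                           panels = 10, order = 10) {
  stopifnot(inherits(sector, "open_sector"),
            inherits(materials, "wall_materials"))
  bracket <- c(0.01 * sector$R_i, sector$R_o)
  sol <- .safe_root(
    function(ri) .forward_residual(sector, ri, materials, panels,
                                   order),
    bracket[1], bracket[2], tol_x = 1e-13,
    what = "solve_unloaded")
  r_i <- sol$root
  refine <- .forward_residual(sector, r_i, materials, 2L * panels,
                              order)
  annulus <- closed_annulus(
    r_i = r_i,
    r_m = close_map(sector$R_m, sector, r_i),
    r_o = close_map(sector$R_o, sector, r_i))
  state <- residual_stress_profile(sector, annulus, materials, n_nodes)
  list(annulus = annulus, state = state,
       info = list(iterations = sol$iter, residual = sol$f_root,
                   residual_refined = refine, bracket = bracket))
}

#' Recover the stress-free open sector from the unloaded annulus
#'
#' Inverse opening-angle problem: given the closed, unloaded,
#' residually-stressed annulus and an opening angle, find the
#' stress-free sector that closes into it.  Solves the same integral
#' condition written in the deformed radius, bracketing the stress-free
#' inner radius over `[r_i, 10 r_i]`.
#'
#' @param annulus a [closed_annulus()] with `p_lumen = 0`.
#' @param alpha opening angle, degrees.
#' @param materials a [wall_materials()].
#' @inheritParams solve_unloaded
#' @return List with elements `sector`, `state`, `info` as in
#'   [solve_unloaded()].
#' @export
solve_stress_free <- function(annulus, alpha, materials,
                              n_nodes = 401, panels = 10,
                              order = 10) {
  stopifnot(inherits(annulus, "closed_annulus"),
            inherits(materials, "wall_materials"))
  if (annulus$p_lumen != 0)
    stop("the unloaded annulus must have zero lumen pressure")
  if (alpha == 0) {
    sector <- open_sector(annulus$r_i, annulus$r_m, annulus$r_o, 0)
    state <- residual_stress_profile(sector, annulus, materials, n_nodes)
    return(list(sector = sector, state = state,
                info = list(iterations = 0L, residual = 0,
                            residual_refined = 0,
                            bracket = c(annulus$r_i, annulus$r_i))))
  }
  bracket <- c(annulus$r_i, 10 * annulus$r_i)
  sol <- .safe_root(
    function(Ri) .inverse_residual(annulus, Ri, alpha, materials,
                                   panels, order),
    bracket[1], bracket[2], tol_x = 1e-13,
    what = "solve_stress_free")
  R_i <- sol$root
  refine <- .inverse_residual(annulus, R_i, alpha, materials,
                              2L * panels, order)
  sector <- open_sector(
    R_i = R_i,
    R_m = open_map(annulus$r_m, annulus, R_i, alpha),
    R_o = open_map(annulus$r_o, annulus, R_i, alpha),
    alpha = alpha)
  state <- residual_stress_profile(sector, annulus, materials, n_nodes)
  list(sector = sector, state = state,
       info = list(iterations = sol$iter, residual = sol$f_root,
                   residual_refined = refine, bracket = bracket))
}

#' Transmural residual-stress profile of a solved configuration pair
#'
#' Given a consistent (sector, annulus) equilibrium pair, integrates
#' the radial equilibrium equation cumulatively from the traction-free
#' inner surface and recovers all Cauchy stress components and the
#' incompressibility multiplier on a radial grid.  The interface node
#' is duplicated with layer tags: the radial stress is continuous
#' across it while the hoop stress jumps.
#'
#' @param sector an [open_sector()].
#' @param annulus the matching [closed_annulus()] (from
#'   [solve_unloaded()] or [solve_stress_free()]).
#' @param materials a [wall_materials()].
#' @param n_nodes grid size (unique radii).
#' @param check_tol consistency tolerance on the outer-surface radial
#'   stress, as a fraction of the media stiffness.
#' @return A `wall_state` data frame with columns `r_mm`, `layer`,
#'   `lambda_r`, `lambda_t`, `sigma_rr_kPa`, `sigma_tt_kPa`,
#'   `sigma_zz_kPa`, `p_lag_kPa`.
#' @export
residual_stress_profile <- function(sector, annulus, materials,
                                    n_nodes = 401, check_tol = 1e-6) {
  stopifnot(inherits(sector, "open_sector"),
            inherits(annulus, "closed_annulus"),
            inherits(materials, "wall_materials"))
  k <- k_factor(sector$alpha)
  grid <- .profile_grid(annulus$r_i, annulus$r_m, annulus$r_o, n_nodes)
  state <- .compute_profile(k, sector$R_i, annulus$r_i, grid,
                            materials, s_rr_inner = 0)
  s_outer <- state$sigma_rr_kPa[nrow(state)]
  scale <- max(materials$media$c, max(abs(state$sigma_tt_kPa)))
  if (abs(s_outer) > check_tol * scale)
    stop(sprintf(
      paste0("inconsistent configuration pair: outer-surface radial ",
             "stress %.3g kPa is not traction-free"), s_outer))
  state
}

#' Relative L2 error between two stress profiles
#'
#' The maximum over the radial and circumferential components of
#' \eqn{\|\sigma - \sigma^{ref}\|_2 / \|\sigma^{ref}\|_2}, evaluated on
#' a shared radial grid.
#'
#' @param test,reference `wall_state` objects on identical grids.
#' @return Dimensionless error fraction.
#' @export
relative_error_profiles <- function(test, reference) {
  stopifnot(inherits(test, "wall_state"), inherits(reference, "wall_state"))
  if (nrow(test) != nrow(reference) ||
      max(abs(test$r_mm - reference$r_mm)) > 1e-9 * max(reference$r_mm))
    stop("profiles must share the same radial grid")
  n_rr <- sqrt(sum(reference$sigma_rr_kPa^2))
  n_tt <- sqrt(sum(reference$sigma_tt_kPa^2))
  if (n_rr == 0 || n_tt == 0)
    stop("relative error undefined: reference profile has zero norm")
  max(sqrt(sum((test$sigma_rr_kPa - reference$sigma_rr_kPa)^2)) / n_rr,
      sqrt(sum((test$sigma_tt_kPa - reference$sigma_tt_kPa)^2)) / n_tt)
}

#' Recover the opening angle from a residual-stress profile
#'
#' Parameter-recovery harness: given a (possibly noisy) transmural
#' residual-stress profile and the unloaded annulus it belongs to, find
#' the opening angle whose regenerated profile best matches it in the
#' relative L2 sense of [relative_error_profiles()].  A coarse scan
#' guards against (and flags) a non-unimodal objective before bounded
#' scalar minimisation.
#'
#' @param profile a `wall_state` generated at some true opening angle.
#' @param annulus the matching unloaded [closed_annulus()].
#' @param materials a [wall_materials()].
#' @param interval search interval for the angle, degrees.
#' @param coarse_step grid step of the unimodality scan, degrees.
#' @return List with `alpha` (degrees), `objective` (relative error at
#'   the optimum) and `multimodal` (logical warning flag).
#' @export
recover_opening_angle <- function(profile, annulus, materials,
                                  interval = c(0, 250),
                                  coarse_step = 10) {
  stopifnot(inherits(profile, "wall_state"),
            inherits(annulus, "closed_annulus"))
  n_nodes <- nrow(profile) - 1L
  if (sqrt(sum(profile$sigma_tt_kPa^2)) == 0)
    return(list(alpha = 0, objective = 0, multimodal = FALSE))
  objective <- function(alpha) {
    fit <- solve_stress_free(annulus, alpha, materials,
                             n_nodes = n_nodes)
    relative_error_profiles(fit$state, profile)
  }
  obj0 <- function(alpha) {
    # alpha = 0 regenerates a zero profile: error is exactly 1
    if (alpha == 0) 1 else objective(alpha)
  }
  grid <- seq(interval[1], interval[2], by = coarse_step)
  vals <- vapply(grid, obj0, numeric(1))
  idx <- which(diff(sign(diff(vals))) > 0) + 1L  # interior local minima
  multimodal <- length(idx) > 1L
  i_best <- which.min(vals)
  lo <- grid[max(1L, i_best - 1L)]
  hi <- grid[min(length(grid), i_best + 1L)]
  opt <- optimize(obj0, c(lo, hi), tol = 1e-4)
  list(alpha = opt$minimum, objective = opt$objective,
       multimodal = multimodal)
}
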