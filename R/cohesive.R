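#' Linear cohesive traction-separation law
#'
#' The triangular (initially rigid, linearly softening) law relating
#' the traction bridging a tear to the displacement jump across it.
#' It is fully specified by any two of: peak traction `T_c` (kPa),
#' separation energy `G_c` (N/mm), and displacement jump at full
#' separation `du_c` (mm); the triangle area fixes the third through
#' \eqn{G_c = T_c \Delta u_c / 2}.  Supplying all three is allowed if
#' they are mutually consistent.
#'
#' Units: with tractions in kPa and jumps in mm the triangle area comes
#' out in kPa mm = N/m = 1e-3 N/mm, so the stored `G_c` (N/mm) is
#' `T_c * du_c / 2000`.
#'
#' @param T_c peak traction, kPa.
#' @param G_c separation energy, N/mm.
#' @param du_c displacement jump at full separation, mm.
#' @param rel_tol consistency tolerance when all three are given.
#' @return Object of class `cohesive_law` with all three fields filled.
#' @export
cohesive_law <- function(T_c = NULL, G_c = NULL, du_c = NULL,
                         rel_tol = 1e-3) {
  given <- !vapply(list(T_c, G_c, du_c), is.null, logical(1))
  if (sum(given) < 2L)
    stop("supply at least two of T_c, G_c, du_c")
  kpamm <- 1e-3  # kPa mm in N/mm
  if (all(given)) {
    if (abs(G_c - T_c * du_c / 2 * kpamm) > rel_tol * abs(G_c))
      stop(sprintf(
        "inconsistent cohesive triple: G_c = %g N/mm but T_c*du_c/2 = %g N/mm",
        G_c, T_c * du_c / 2 * kpamm))
  } else if (is.null(G_c)) {
    G_c <- T_c * du_c / 2 * kpamm
  } else if (is.null(du_c)) {
    du_c <- 2 * G_c / kpamm / T_c
  } else {
    T_c <- 2 * G_c / kpamm / du_c
  }
  if (T_c <= 0 || G_c <= 0 || du_c <= 0)
    stop("cohesive parameters must be positive")
  structure(list(T_c = T_c, G_c = G_c, du_c = du_c),
            class = "cohesive_law")
}

#' @export
print.cohesive_law <- function(x, ...) {
  cat(sprintf(
    "Linear cohesive law: T_c = %g kPa, G_c = %g N/mm, du_c = %g mm\n",
    x$T_c, x$G_c, x$du_c))
  invisible(x)
}

#' Damage bookkeeping for the cohesive law
#'
#' Records the largest displacement jump a cohesive point has
#' experienced.  The scalar damage `min(du_max_seen / du_c, 1)` is
#' non-decreasing over any loading history (irreversibility).
#'
#' @param du_max_seen largest jump experienced so far, mm.
#' @return Object of class `damage_state`.
#' @export
damage_state <- function(du_max_seen = 0) {
  stopifnot(du_max_seen >= 0)
  structure(list(du_max_seen = du_max_seen), class = "damage_state")
}

#' Damage scalar of a state under a given law
#'
#' @param state a [damage_state()].
#' @param law a [cohesive_law()].
#' @return Damage in \[0, 1\].
#' @export
cohesive_damage <- function(state, law) {
  min(state$du_max_seen / law$du_c, 1)
}

#' Cohesive traction at a displacement jump
#'
#' On the virgin softening envelope the traction is
#' \eqn{T = T_c (1 - \Delta u / \Delta u_c)} (zero beyond full
#' separation).  After partial damage, unloading and reloading follow
#' the linear secant through the origin and the envelope point at the
#' largest jump seen — the standard irreversible cohesive-zone
#' treatment; the law itself only prescribes the envelope.  The state
#' is updated and returned alongside the traction.
#'
#' @param du current displacement jump, mm (non-negative; face
#'   interpenetration is the caller's concern).
#' @param law a [cohesive_law()].
#' @param state a [damage_state()]; defaults to virgin.
#' @return List with `traction` (kPa) and the updated `state`.
#' @export
cohesive_traction <- function(du, law, state = damage_state()) {
  stopifnot(inherits(law, "cohesive_law"),
            inherits(state, "damage_state"))
  if (du < 0) stop("displacement jump must be non-negative")
  envelope <- function(u) law$T_c * max(0, 1 - u / law$du_c)
  if (du >= state$du_max_seen) {
    state <- damage_state(du)
    traction <- envelope(du)
  } else {
    u_max <- state$du_max_seen
    slope <- if (u_max >= law$du_c) 0 else envelope(u_max) / u_max
    traction <- slope * du
  }
  list(traction = traction, state = state)
}

#' Energy dissipated along a loading history
#'
#' Path integral \eqn{\int T \, d(\Delta u)} along the piecewise-linear
#' jump history starting from the virgin state at zero jump.  The
#' traction path is piecewise linear between its kinks (the previous
#' maximum jump and full separation), so each leg is integrated
#' exactly by the trapezoid rule after splitting at those kinks.
#' Monotone loading to full separation dissipates exactly `G_c`; no
#' admissible history dissipates more.  The kPa mm integral is reported
#' in N/mm to match `G_c`.
#'
#' @param history numeric vector of successive displacement jumps, mm
#'   (non-negative; may be empty).
#' @param law a [cohesive_law()].
#' @return Dissipated energy, N/mm.
#' @export
dissipated_energy <- function(history, law) {
  stopifnot(inherits(law, "cohesive_law"))
  if (length(history) == 0) return(0)
  if (any(history < 0)) stop("displacement jumps must be non-negative")
  state <- damage_state()
  prev <- 0
  energy <- 0
  for (target in history) {
    kinks <- c(state$du_max_seen, law$du_c)
    pts <- sort(unique(c(prev, target,
                         kinks[kinks > min(prev, target) &
                               kinks < max(prev, target)])))
    if (target < prev) pts <- rev(pts)
    for (i in seq_len(length(pts) - 1L)) {
      a <- pts[i]; b <- pts[i + 1L]
      ta <- cohesive_traction(a, law, state)
      state <- ta$state
      tb <- cohesive_traction(b, law, state)
      state <- tb$state
      energy <- energy + (ta$traction + tb$traction) / 2 * (b - a)
    }
    prev <- target
  }
  energy * 1e-3  # kPa mm -> N/mm
}

#' Tear-initiation criterion
#'
#' A tear initiates where the maximum principal Cauchy stress reaches
#' the cohesive strength: \eqn{\sigma_{mp} \ge T_c} (boundary
#' inclusive).  In the shear-free axisymmetric states of this package
#' \eqn{\sigma_{mp}} is simply the largest diagonal component.
#'
#' @param stress a `stress_components` object (from [cauchy_stress()])
#'   or a numeric vector of principal stresses, kPa.
#' @param law a [cohesive_law()], or a single number taken as `T_c`.
#' @return List with `initiated` (logical) and `margin`
#'   (\eqn{\sigma_{mp} - T_c}, kPa).
#' @export
initiation_check <- function(stress, law) {
  s <- if (inherits(stress, "stress_components"))
    c(stress$s_rr, stress$s_tt, stress$s_zz) else as.numeric(stress)
  T_c <- if (inherits(law, "cohesive_law")) law$T_c else as.numeric(law)
  margin <- max(s) - T_c
  list(initiated = margin >= 0, margin = margin)
}

#' Propagation direction from the local stress state
#'
#' A tear propagates perpendicular to the maximum tensile principal
#' stress.  Restricted to the \eqn{(r, \theta)} plane of the
#' cross-section: a dominant tensile hoop stress drives radial
#' propagation (the typical outcome in a pressurised wall); a dominant
#' tensile radial stress drives circumferential propagation.
#'
#' @param stress a `stress_components` object or numeric vector
#'   `c(s_rr, s_tt, ...)`, kPa.
#' @return `"radial"`, `"circumferential"`, or `"none"` when no
#'   in-plane component is tensile.
#' @export
propagation_direction <- function(stress) {
  s <- if (inherits(stress, "stress_components"))
    c(stress$s_rr, stress$s_tt) else as.numeric(stress)[1:2]
  if (max(s) <= 0) return("none")
  if (s[2] >= s[1]) "radial" else "circumferential"
}
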