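#' Stress-free open-sector configuration
#'
#' The zero-stress reference state of the arterial ring: a circular
#' sector of inner radius `R_i`, media-adventitia interface `R_m`,
#' outer radius `R_o`, spanning the angle \eqn{2\pi - \alpha}.  The
#' opening angle `alpha` quantifies the residual stress locked into the
#' closed, unloaded artery.  A single opening angle applies to both
#' layers: the two-layer ring opens and closes as one continuous
#' sector.
#'
#' @param R_i,R_m,R_o inner, interface and outer radii, mm
#'   (`0 < R_i < R_m < R_o`).
#' @param alpha opening angle, degrees, in \[0, 360).
#' @return Immutable object of class `open_sector`.
#' @export
open_sector <- function(R_i, R_m, R_o, alpha) {
  stopifnot(is.numeric(R_i), is.numeric(R_m), is.numeric(R_o),
            is.numeric(alpha),
            length(R_i) == 1L, length(R_m) == 1L, length(R_o) == 1L,
            length(alpha) == 1L)
  if (!(R_i > 0 && R_i < R_m && R_m < R_o))
    stop("radii must satisfy 0 < R_i < R_m < R_o")
  if (alpha < 0 || alpha >= 360)
    stop("opening angle must lie in [0, 360) degrees")
  structure(list(R_i = R_i, R_m = R_m, R_o = R_o, alpha = alpha),
            class = "open_sector")
}

#' @export
print.open_sector <- function(x, ...) {
  cat(sprintf(
    paste0("Open sector (stress-free): R_i = %.4f, R_m = %.4f, ",
           "R_o = %.4f mm; T_m = %.4f, T_a = %.4f mm; alpha = %g deg\n"),
    x$R_i, x$R_m, x$R_o, x$R_m - x$R_i, x$R_o - x$R_m, x$alpha))
  invisible(x)
}

#' Closed annulus configuration
#'
#' The intact closed cross-section: either the unloaded,
#' residually-stressed state (lumen pressure 0) or a loaded state under
#' lumen pressure `p_lumen`.
#'
#' @param r_i,r_m,r_o inner, interface and outer radii, mm
#'   (`0 < r_i < r_m < r_o`).
#' @param p_lumen lumen pressure, kPa (non-negative; 0 for the unloaded
#'   state).
#' @return Immutable object of class `closed_annulus`.
#' @export
closed_annulus <- function(r_i, r_m, r_o, p_lumen = 0) {
  stopifnot(is.numeric(r_i), is.numeric(r_m), is.numeric(r_o),
            is.numeric(p_lumen),
            length(r_i) == 1L, length(r_m) == 1L, length(r_o) == 1L,
            length(p_lumen) == 1L)
  if (!(r_i > 0 && r_i < r_m && r_m < r_o))
    stop("radii must satisfy 0 < r_i < r_m < r_o")
  if (p_lumen < 0) stop("lumen pressure must be non-negative")
  structure(list(r_i = r_i, r_m = r_m, r_o = r_o, p_lumen = p_lumen),
            class = "closed_annulus")
}

#' @export
print.closed_annulus <- function(x, ...) {
  cat(sprintf(
    paste0("Closed annulus: r_i = %.4f, r_m = %.4f, r_o = %.4f mm; ",
           "t_m = %.4f, t_a = %.4f mm; p_lumen = %g kPa\n"),
    x$r_i, x$r_m, x$r_o, x$r_m - x$r_i, x$r_o - x$r_m, x$p_lumen))
  invisible(x)
}

#' Tear descriptor (metadata only)
#'
#' Records the circumferential tear used in dissection studies: an arc
#' of constant radius `r_t` subtending `eta` degrees in the closed
#' configuration.  The package evaluates initiation criteria on the
#' intact wall; tear propagation itself is not simulated, so this type
#' only documents a tear geometry.
#'
#' @param r_t tear-surface radius in the closed configuration, mm.
#' @param eta tear arc angle, degrees, in (0, 360).
#' @param annulus optional `closed_annulus` against which `r_t` is
#'   validated to lie strictly inside the wall.
#' @return Object of class `tear_spec`.
#' @export
tear_spec <- function(r_t, eta, annulus = NULL) {
  stopifnot(is.numeric(r_t), length(r_t) == 1L,
            is.numeric(eta), length(eta) == 1L)
  if (eta <= 0 || eta >= 360) stop("tear arc must lie in (0, 360) degrees")
  if (!is.null(annulus)) {
    stopifnot(inherits(annulus, "closed_annulus"))
    if (r_t <= annulus$r_i || r_t >= annulus$r_o)
      stop("tear radius must lie strictly inside the wall")
  } else if (r_t <= 0) stop("tear radius must be positive")
  structure(list(r_t = r_t, eta = eta), class = "tear_spec")
}

#' Circumferential closing factor
#'
#' \eqn{k = 2\pi / (2\pi - \alpha)}: the factor by which azimuthal
#' angles are stretched when the open sector closes into a full
#' annulus.  `k = 1` for no opening, and grows without bound as the
#' opening angle approaches a full turn.
#'
#' @param alpha opening angle, degrees, in \[0, 360).
#' @return Dimensionless factor `>= 1`.
#' @export
k_factor <- function(alpha) {
  if (any(alpha < 0) || any(alpha >= 360))
    stop("opening angle must lie in [0, 360) degrees")
  2 * pi / (2 * pi - alpha * pi / 180)
}

#' Incompressible radial map from the open sector to the closed annulus
#'
#' For a candidate closed inner radius `r_i`, plane-strain
#' incompressibility fixes the image of every reference radius:
#' \deqn{r(R) = \sqrt{(R^2 - R_i^2)/k + r_i^2}.}
#' The map is strictly increasing in `R` and sends `R_i` to `r_i`.
#'
#' @param R reference radii, mm (vectorised), within
#'   `[sector$R_i, sector$R_o]`.
#' @param sector an [open_sector()].
#' @param r_i candidate closed inner radius, mm (positive).
#' @return Deformed radii, mm.
#' @export
close_map <- function(R, sector, r_i) {
  stopifnot(inherits(sector, "open_sector"), r_i > 0)
  tol <- 1e-12 * sector$R_o
  if (any(R < sector$R_i - tol) || any(R > sector$R_o + tol))
    stop("reference radius outside the open sector")
  k <- k_factor(sector$alpha)
  sqrt((R^2 - sector$R_i^2) / k + r_i^2)
}

#' Inverse radial map from the closed annulus to the open sector
#'
#' Exact algebraic inverse of [close_map()]:
#' \deqn{R(r) = \sqrt{k (r^2 - r_i^2) + R_i^2}.}
#'
#' @param r deformed radii, mm (vectorised), within
#'   `[annulus$r_i, annulus$r_o]`.
#' @param annulus a [closed_annulus()].
#' @param R_i candidate stress-free inner radius, mm.
#' @param alpha opening angle, degrees.
#' @return Reference radii, mm.
#' @export
open_map <- function(r, annulus, R_i, alpha) {
  stopifnot(inherits(annulus, "closed_annulus"), R_i > 0)
  tol <- 1e-12 * annulus$r_o
  if (any(r < annulus$r_i - tol) || any(r > annulus$r_o + tol))
    stop("radius outside the closed annulus")
  k <- k_factor(alpha)
  sqrt(k * (r^2 - annulus$r_i^2) + R_i^2)
}

#' Principal stretches of the closing deformation
#'
#' Differentiating the incompressible map gives
#' \eqn{\lambda_r = R/(rk)} and \eqn{\lambda_\theta = kr/R}, with
#' \eqn{\lambda_z = 1} (plane strain); the product is identically 1.
#'
#' @inheritParams close_map
#' @return A [deformation_point()] whose fields are vectors matching
#'   `R`.
#' @export
stretches <- function(R, sector, r_i) {
  r <- close_map(R, sector, r_i)
  k <- k_factor(sector$alpha)
  lam_t <- k * r / R
  deformation_point(lam_r = 1 / lam_t, lam_t = lam_t, lam_z = 1)
}
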