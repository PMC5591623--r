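#' Holzapfel-Gasser-Ogden layer parameters
#'
#' Bundles the material constants of one arterial layer (media or
#' adventitia) under the incompressible HGO strain-energy function
#' \deqn{W = c(I_1 - 3) + \sum_{n=4,6} \frac{k_1}{2k_2}
#'   \{\exp[k_2 (I_n - 1)^2] - 1\},}
#' where the fibre terms act only in extension (\eqn{I_n > 1}), together
#' with the linear cohesive traction-separation parameters used by the
#' dissection-initiation criterion.
#'
#' The two symmetric collagen-fibre families lie at \eqn{\pm\beta} from
#' the circumferential direction.  Under the plane-strain idealisation
#' used throughout this package the axial component of the fibre
#' direction is ignored, so the fibre invariant reduces to
#' \eqn{I_4 = \lambda_\theta^2 \cos^2\beta} and the fibre stress acts
#' purely circumferentially.  A consequence worth knowing: fibres at
#' angle \eqn{\beta} engage only once \eqn{\lambda_\theta > 1/\cos\beta},
#' so steep fibre angles behave exactly like the fibre-free matrix over
#' moderate hoop stretches.
#'
#' Of the three cohesive parameters only two are independent: the law is
#' triangular, so \eqn{G_c = T_c \Delta u_c / 2}.  Supply any two (or a
#' consistent triple) or none.
#'
#' @param c matrix (neo-Hookean) stiffness, kPa; must be positive.
#' @param k1 fibre stiffness, kPa; non-negative (0 switches fibres off).
#' @param k2 dimensionless fibre exponent; must be positive.
#' @param beta fibre angle from the circumferential direction, degrees,
#'   in \[0, 90\].
#' @param T_c peak cohesive traction, kPa (optional).
#' @param G_c cohesive separation energy, N/mm (optional).
#' @param du_c displacement jump at full separation, mm (optional).
#' @return An object of class `hgo_layer`.
#' @examples
#' media <- hgo_layer(c = 1.5, k1 = 2.3632, k2 = 0.8393, beta = 29,
#'                    T_c = 3, du_c = 0.667)
#' media$G_c  # completed from the triangle area
#' @export
hgo_layer <- function(c, k1, k2, beta, T_c = NULL, G_c = NULL,
                      du_c = NULL) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c),
            is.numeric(k1), length(k1) == 1L, is.finite(k1),
            is.numeric(k2), length(k2) == 1L, is.finite(k2),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (c <= 0) stop("matrix stiffness 'c' must be positive")
  if (k1 < 0) stop("fibre stiffness 'k1' must be non-negative")
  if (k2 <= 0) stop("fibre exponent 'k2' must be positive")
  if (beta < 0 || beta > 90)
    stop("fibre angle 'beta' must lie in [0, 90] degrees")
  coh <- NULL
  n_given <- sum(!vapply(list(T_c, G_c, du_c), is.null, logical(1)))
  if (n_given > 0) {
    coh <- cohesive_law(T_c = T_c, G_c = G_c, du_c = du_c)
  }
  structure(
    list(c = c, k1 = k1, k2 = k2, beta = beta,
         T_c = coh$T_c, G_c = coh$G_c, du_c = coh$du_c),
    class = "hgo_layer")
}

#' @export
print.hgo_layer <- function(x, ...) {
  cat(sprintf(
    "HGO layer: c = %g kPa, k1 = %g kPa, k2 = %g, beta = %g deg\n",
    x$c, x$k1, x$k2, x$beta))
  if (!is.null(x$T_c))
    cat(sprintf("  cohesive: T_c = %g kPa, G_c = %g N/mm, du_c = %g mm\n",
                x$T_c, x$G_c, x$du_c))
  invisible(x)
}

#' Pair of layer materials for a two-layer wall
#'
#' @param media,adventitia `hgo_layer` objects for the inner and outer
#'   layer.
#' @return A named list of class `wall_materials`.
#' @export
wall_materials <- function(media, adventitia) {
  stopifnot(inherits(media, "hgo_layer"), inherits(adventitia, "hgo_layer"))
  structure(list(media = media, adventitia = adventitia),
            class = "wall_materials")
}

#' Incompressible principal deformation state
#'
#' Principal stretches aligned with the cylindrical axes \eqn{(r,
#' \theta, z)}.  Incompressibility (\eqn{\lambda_r \lambda_\theta
#' \lambda_z = 1}) is enforced at construction.  Vector arguments give a
#' deformation state per radial grid node.
#'
#' @param lam_r,lam_t,lam_z radial, circumferential and axial principal
#'   stretches (dimensionless, positive).  `lam_z` defaults to 1
#'   (plane strain).
#' @param tol relative tolerance on the incompressibility product.
#' @return Object of class `deformation_point` with fields `lam_r`,
#'   `lam_t`, `lam_z`.
#' @export
deformation_point <- function(lam_r, lam_t, lam_z = 1, tol = 1e-8) {
  if (length(lam_z) == 1L) lam_z <- rep(lam_z, length(lam_r))
  stopifnot(length(lam_t) == length(lam_r),
            length(lam_z) == length(lam_r))
  if (any(!is.finite(lam_r)) || any(lam_r <= 0) ||
      any(!is.finite(lam_t)) || any(lam_t <= 0) ||
      any(!is.finite(lam_z)) || any(lam_z <= 0))
    stop("invalid deformation: stretches must be positive and finite")
  J <- lam_r * lam_t * lam_z
  if (any(abs(J - 1) > tol))
    stop("invalid deformation: lam_r * lam_t * lam_z must equal 1")
  structure(list(lam_r = lam_r, lam_t = lam_t, lam_z = lam_z),
            class = "deformation_point")
}

#' Deformation invariants for the HGO law
#'
#' Computes \eqn{I_1 = \mathrm{tr}\,C} and the fibre invariants
#' \eqn{I_4, I_6 = C : M_n} for the two mirror-symmetric fibre families
#' at \eqn{\pm\beta} from the circumferential direction.  With the axial
#' fibre component ignored (plane strain) both families share
#' \eqn{I_4 = I_6 = \lambda_\theta^2 \cos^2\beta}.
#'
#' @param point a [deformation_point()].
#' @param beta fibre angle from the circumferential direction, degrees.
#' @return List with fields `I1`, `I4`, `I6` (vectors matching `point`).
#' @export
hgo_invariants <- function(point, beta) {
  stopifnot(inherits(point, "deformation_point"))
  b <- beta * pi / 180
  I1 <- point$lam_r^2 + point$lam_t^2 + point$lam_z^2
  I4 <- point$lam_t^2 * cos(b)^2
  list(I1 = I1, I4 = I4, I6 = I4)
}

#' Fibre strain-energy density
#'
#' The tension-only exponential fibre potential of one family,
#' \eqn{w(I_n) = \frac{k_1}{2k_2}\{\exp[k_2(I_n-1)^2]-1\}} for
#' \eqn{I_n > 1} and exactly zero otherwise.  The switch is a hard
#' branch at \eqn{I_n = 1}; the function is continuously differentiable
#' there.
#'
#' @param I_n fibre invariant (vectorised, positive).
#' @param layer an [hgo_layer()].
#' @return Energy density in kPa.
#' @export
fibre_energy <- function(I_n, layer) {
  stopifnot(inherits(layer, "hgo_layer"))
  if (any(!is.finite(I_n)) || any(I_n <= 0))
    stop("fibre invariant must be positive and finite")
  w <- numeric(length(I_n))
  on <- I_n > 1
  if (layer$k1 > 0 && any(on)) {
    e <- I_n[on] - 1
    w[on] <- layer$k1 / (2 * layer$k2) * expm1(layer$k2 * e^2)
  }
  w
}

#' Derivative of the fibre energy with respect to its invariant
#'
#' \eqn{w'(I_n) = k_1 (I_n - 1) \exp[k_2 (I_n - 1)^2]} for
#' \eqn{I_n > 1}, zero otherwise.  This is the scalar that multiplies
#' the push-forward structure tensor in the Cauchy stress.
#'
#' @inheritParams fibre_energy
#' @return \eqn{w'} in kPa.
#' @export
fibre_stress_derivative <- function(I_n, layer) {
  stopifnot(inherits(layer, "hgo_layer"))
  if (any(!is.finite(I_n)) || any(I_n <= 0))
    stop("fibre invariant must be positive and finite")
  wp <- numeric(length(I_n))
  on <- I_n > 1
  if (layer$k1 > 0 && any(on)) {
    e <- I_n[on] - 1
    wp[on] <- layer$k1 * e * exp(layer$k2 * e^2)
  }
  wp
}

# sigma_tt - sigma_rr from raw stretches; hot path of every integrand,
# so it bypasses the deformation_point validation.
.stress_diff_raw <- function(lam_r, lam_t, layer) {
  cb2 <- cos(layer$beta * pi / 180)^2
  I4 <- lam_t^2 * cb2
  2 * layer$c * (lam_t^2 - lam_r^2) +
    4 * fibre_stress_derivative(I4, layer) * lam_t^2 * cb2
}

#' Circumferential-radial Cauchy stress difference
#'
#' Returns \eqn{\sigma_{\theta\theta} - \sigma_{rr} =
#' 2c(\lambda_\theta^2 - \lambda_r^2) + 4 w'(I_4) \lambda_\theta^2
#' \cos^2\beta}, the Lagrange-multiplier-free combination driving the
#' radial equilibrium equation.  Both fibre families contribute equally;
#' the fibres have no radial component, so \eqn{\sigma_{rr}} carries no
#' fibre term.
#'
#' @param point a [deformation_point()] (fields may be vectors).
#' @param layer an [hgo_layer()].
#' @return Stress difference in kPa.
#' @export
stress_difference <- function(point, layer) {
  stopifnot(inherits(point, "deformation_point"),
            inherits(layer, "hgo_layer"))
  .stress_diff_raw(point$lam_r, point$lam_t, layer)
}

#' Full Cauchy stress components at a known radial stress
#'
#' Once the radial stress at a material point is known (from the
#' equilibrium integral), the incompressibility multiplier follows as
#' \eqn{\mathfrak{p} = -\sigma_{rr} + 2c\lambda_r^2} and the remaining
#' diagonal components are recovered from the constitutive law.  Under
#' the plane-strain fibre convention the axial stress carries no fibre
#' term: \eqn{\sigma_{zz} = -\mathfrak{p} + 2c\lambda_z^2}.
#'
#' @param point a [deformation_point()] (fields may be vectors).
#' @param layer an [hgo_layer()].
#' @param s_rr_known radial Cauchy stress, kPa (vectorised).
#' @return List of class `stress_components` with fields `s_rr`, `s_tt`,
#'   `s_zz`, `p_lag` (kPa).
#' @export
cauchy_stress <- function(point, layer, s_rr_known) {
  stopifnot(inherits(point, "deformation_point"),
            inherits(layer, "hgo_layer"))
  cb2 <- cos(layer$beta * pi / 180)^2
  I4 <- point$lam_t^2 * cb2
  p_lag <- -s_rr_known + 2 * layer$c * point$lam_r^2
  s_tt <- -p_lag + 2 * layer$c * point$lam_t^2 +
    4 * fibre_stress_derivative(I4, layer) * point$lam_t^2 * cb2
  s_zz <- -p_lag + 2 * layer$c * point$lam_z^2
  structure(list(s_rr = s_rr_known, s_tt = s_tt, s_zz = s_zz,
                 p_lag = p_lag),
            class = "stress_components")
}
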