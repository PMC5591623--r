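#' Draw a seeded random admissible parameter set
#'
#' Generates a physiologically-plausible two-layer geometry, opening
#' angle, and HGO/cohesive material pair for property testing and
#' parameter-recovery studies.  Stiffness-like parameters are drawn
#' log-uniformly; angles and radius ratios uniformly.  The generator is
#' pinned to the Mersenne-Twister / Inversion RNG so a seed identifies
#' one draw across platforms and R versions; the caller's RNG state is
#' left untouched.
#'
#' Ranges: inner radius 0.5-3 mm, media thickness 15-35% of the inner
#' radius, adventitia 30-80% of the media thickness, opening angle
#' 0-220 degrees, matrix stiffness 0.1-50 kPa, fibre stiffness
#' 0.05-120 kPa, fibre exponent 0.1-30, fibre angle 0-90 degrees.
#' Cohesive strength is tied to the layer matrix stiffness
#' (`T_c = 2c`) with a 0.3-1 mm separation jump.
#'
#' @param seed integer seed.
#' @return Object of class `parameter_draw`: list with `seed`,
#'   `sector` (an [open_sector()]), `materials` (a
#'   [wall_materials()]) and `alpha` (degrees, equal to
#'   `sector$alpha`).
#' @export
draw_parameter_set <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  R_i <- runif(1, 0.5, 3)
  T_m <- R_i * runif(1, 0.15, 0.35)
  T_a <- T_m * runif(1, 0.3, 0.8)
  alpha <- runif(1, 0, 220)
  draw_layer <- function() {
    c0 <- exp(runif(1, log(0.1), log(50)))
    hgo_layer(c = c0,
              k1 = exp(runif(1, log(0.05), log(120))),
              k2 = exp(runif(1, log(0.1), log(30))),
              beta = runif(1, 0, 90),
              T_c = 2 * c0,
              du_c = runif(1, 0.3, 1))
  }
  structure(
    list(seed = seed,
         sector = open_sector(R_i, R_i + T_m, R_i + T_m + T_a, alpha),
         materials = wall_materials(draw_layer(), draw_layer()),
         alpha = alpha),
    class = "parameter_draw")
}

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "artwall")
  if (p == "") stop("packaged fixture file not found: ", file)
  p
}

.materials_from_table <- function(tab) {
  mk <- function(x) hgo_layer(c = x$c, k1 = x$k1, k2 = x$k2,
                              beta = x$beta, T_c = x$T_c, G_c = x$G_c,
                              du_c = x$du_c)
  wall_materials(mk(tab$media), mk(tab$adventitia))
}

#' Packaged reference parameter sets
#'
#' Returns the published two-layer rabbit carotid configurations and
#' materials, and the (partially parsed) aged human thoracic aorta
#' set.
#'
#' Available names:
#' \describe{
#'   \item{`rabbit_omega0`}{stress-free open sector of the rabbit
#'     carotid (opening angle 160 degrees) with materials.}
#'   \item{`rabbit_omega_r`}{the corresponding unloaded closed annulus
#'     with materials.}
#'   \item{`rabbit_open_geometry`}{the published stress-free geometry
#'     for a given opening angle (`alpha` one of 0, 40, 80, 120, 160,
#'     200), all closing into the same unloaded annulus.}
#'   \item{`human_aorta`}{aged human thoracic aorta; provisional: only
#'     fields whose published formatting is unambiguous are stored,
#'     the rest are flagged `unparsed`.}
#' }
#'
#' @param name fixture name (see above).
#' @param alpha opening angle selecting a row of
#'   `rabbit_open_geometry`, degrees.
#' @return A list; for the rabbit fixtures it contains `sector` or
#'   `annulus`, `materials` and `alpha`.  The human set carries a
#'   `provisional` flag and an `unparsed` field list.
#' @export
fixture <- function(name, alpha = NULL) {
  rabbit <- yaml::read_yaml(.fixture_path("rabbit_carotid.yaml"))
  switch(
    name,
    rabbit_omega0 = {
      g <- rabbit$geometry$stress_free
      list(sector = open_sector(g$R_i, g$R_i + g$T_m,
                                g$R_i + g$T_m + g$T_a, g$alpha),
           materials = .materials_from_table(rabbit$materials),
           alpha = g$alpha)
    },
    rabbit_omega_r = {
      g <- rabbit$geometry$unloaded
      list(annulus = closed_annulus(g$r_i, g$r_i + g$t_m,
                                    g$r_i + g$t_m + g$t_a),
           materials = .materials_from_table(rabbit$materials),
           alpha = 0)
    },
    rabbit_open_geometry = {
      if (is.null(alpha))
        stop("rabbit_open_geometry needs an 'alpha' argument")
      rows <- yaml::read_yaml(.fixture_path("rabbit_open_geometries.yaml"))
      hit <- Filter(function(r) r$alpha == alpha, rows$geometries)
      if (length(hit) != 1L)
        stop("no published open geometry for alpha = ", alpha)
      g <- hit[[1L]]
      list(sector = open_sector(g$R_i, g$R_i + g$T_m,
                                g$R_i + g$T_m + g$T_a, g$alpha),
           materials = .materials_from_table(rabbit$materials),
           alpha = g$alpha)
    },
    human_aorta = {
      h <- yaml::read_yaml(.fixture_path("human_aorta_provisional.yaml"))
      h
    },
    stop("unknown fixture: ", name)
  )
}

#' Perturb a stress profile with multiplicative noise
#'
#' Applies seeded multiplicative Gaussian noise to the stress columns
#' of a wall state, leaving the first and last grid nodes exact (the
#' boundary tractions are presumed known).  Used to exercise
#' [recover_opening_angle()] under measurement-like noise.
#'
#' @param profile a `wall_state`.
#' @param noise_sd_rel relative standard deviation of the noise
#'   (non-negative; 0 returns the profile unchanged).
#' @param seed integer seed.
#' @return A `wall_state` with perturbed stresses.
#' @export
noisy_profile <- function(profile, noise_sd_rel, seed) {
  stopifnot(inherits(profile, "wall_state"), noise_sd_rel >= 0)
  if (noise_sd_rel == 0) return(profile)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  n <- nrow(profile)
  interior <- seq_len(n) > 1L & seq_len(n) < n
  for (col in c("sigma_rr_kPa", "sigma_tt_kPa", "sigma_zz_kPa")) {
    fac <- 1 + noise_sd_rel * rnorm(n)
    profile[[col]][interior] <- profile[[col]][interior] * fac[interior]
  }
  profile
}
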