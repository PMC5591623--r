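#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing an analysis run: a geometry
#' (either a packaged fixture name or literal radii/thicknesses), a
#' material table, and optional opening-angle and pressure sweeps.
#' Unknown keys are rejected; defaults are filled for everything
#' optional.
#'
#' Recognised keys: `geometry` (fixture name, or a mapping with either
#' `R_i/T_m/T_a/alpha` for a stress-free sector or `r_i/t_m/t_a` for an
#' unloaded annulus), `materials` (fixture name or a
#' `media`/`adventitia` parameter table), `alpha` (numeric vector,
#' degrees), `pressure` (non-negative numeric vector, kPa), `out_dir`,
#' `n_nodes` (>= 11, default 401), `seed` (default 1), `tol` (positive,
#' default 1e-10).
#'
#' @param path path to a YAML file.
#' @return Object of class `run_config` with resolved `geometry` and
#'   `materials` objects.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("geometry", "materials", "alpha", "pressure", "out_dir",
             "n_nodes", "seed", "tol")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (is.null(raw$geometry)) stop("config must name a geometry")
  defaults <- list(alpha = numeric(0), pressure = numeric(0),
                   out_dir = ".", n_nodes = 401L, seed = 1L,
                   tol = 1e-10)
  cfg <- modifyList(defaults, raw)
  if (cfg$n_nodes < 11) stop("n_nodes must be at least 11")
  if (cfg$tol <= 0) stop("tol must be positive")
  if (any(cfg$pressure < 0)) stop("pressures must be non-negative")
  if (any(cfg$alpha < 0 | cfg$alpha >= 360))
    stop("opening angles must lie in [0, 360) degrees")
  geometry <-
    if (is.character(cfg$geometry)) {
      fx <- fixture(cfg$geometry)
      if (!is.null(fx$sector)) fx$sector else fx$annulus
    } else if (!is.null(cfg$geometry$R_i)) {
      g <- cfg$geometry
      open_sector(g$R_i, g$R_i + g$T_m, g$R_i + g$T_m + g$T_a, g$alpha)
    } else {
      g <- cfg$geometry
      closed_annulus(g$r_i, g$r_i + g$t_m, g$r_i + g$t_m + g$t_a)
    }
  materials <-
    if (is.null(cfg$materials)) {
      if (is.character(raw$geometry)) fixture(raw$geometry)$materials
      else stop("literal geometry needs an explicit materials table")
    } else if (is.character(cfg$materials)) {
      fixture(cfg$materials)$materials
    } else {
      .materials_from_table(cfg$materials)
    }
  structure(
    list(geometry = geometry, materials = materials,
         alpha = as.numeric(cfg$alpha),
         pressure = as.numeric(cfg$pressure),
         out_dir = cfg$out_dir, n_nodes = as.integer(cfg$n_nodes),
         seed = as.integer(cfg$seed), tol = cfg$tol),
    class = "run_config")
}

#' Write a wall-state profile to CSV
#'
#' Deterministic output: fixed column order, one comment header line
#' stating the units, numbers at 12 significant digits.  An identical
#' state always yields a byte-identical file.
#'
#' @param state a `wall_state`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(state, path) {
  stopifnot(inherits(state, "wall_state"))
  cols <- c("r_mm", "layer", "lambda_r", "lambda_t", "sigma_rr_kPa",
            "sigma_tt_kPa", "sigma_zz_kPa", "p_lag_kPa")
  num <- function(x) formatC(x, digits = 12, format = "g")
  body <- do.call(paste, c(lapply(cols, function(cn) {
    v <- state[[cn]]
    if (is.numeric(v)) num(v) else v
  }), sep = ","))
  lines <- c(
    "# wall-state profile; units: radii mm, stresses kPa, angles degrees",
    paste(cols, collapse = ","),
    body)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a wall-state profile written by [write_profile_csv()]
#'
#' @param path CSV file path.
#' @return A `wall_state` data frame.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  class(df) <- c("wall_state", "data.frame")
  df
}
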