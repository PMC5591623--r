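#!/usr/bin/env Rscript
# Transmural residual-stress profiles versus opening angle.
#
# For each opening angle the closed, unloaded ring carries a
# self-equilibrated stress field: the media's inner surface ends up in
# circumferential compression, the outer media and the adventitia in
# tension, with a hoop-stress jump at the interface.  Both |sigma_rr|
# and |sigma_tt| grow monotonically with the opening angle; the
# adventitia (ten times softer in its matrix) carries much less
# residual stress.

suppressPackageStartupMessages(library(artwall))
dir.create("results", showWarnings = FALSE)

fx <- fixture("rabbit_omega_r")
alphas <- c(0, 40, 80, 120, 160, 200)

profiles <- list()
summary_rows <- list()
for (a in alphas) {
  inv <- solve_stress_free(fx$annulus, a, fx$materials, n_nodes = 101)
  st <- inv$state
  st$alpha_deg <- a
  profiles[[as.character(a)]] <- st
  summary_rows[[as.character(a)]] <- data.frame(
    alpha_deg = a,
    sigma_tt_media_inner_kPa = st$sigma_tt_kPa[1],
    sigma_tt_adventitia_outer_kPa = st$sigma_tt_kPa[nrow(st)],
    max_abs_sigma_tt_kPa = max(abs(st$sigma_tt_kPa)),
    max_abs_sigma_rr_kPa = max(abs(st$sigma_rr_kPa)),
    r_at_max_abs_sigma_rr_mm =
      st$r_mm[which.max(abs(st$sigma_rr_kPa))])
}

all_profiles <- do.call(rbind, profiles)
write.csv(all_profiles, "results/residual_stress_profiles.csv",
          row.names = FALSE)
summary_tab <- do.call(rbind, summary_rows)
write.csv(summary_tab, "results/residual_stress_summary.csv",
          row.names = FALSE)

cat("Residual-stress landmarks by opening angle:\n\n")
print(summary_tab, digits = 4, row.names = FALSE)
cat("\nThe peak |sigma_rr| sits near the media mid-radius;",
    "\nhoop compression at the media inner surface and tension at the",
    "\nadventitia outer surface both deepen as alpha grows.\n")
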