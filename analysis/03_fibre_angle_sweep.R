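#!/usr/bin/env Rscript
# Effect of fibre orientation on the stress-free geometry family.
#
# Repeating the inverse solves with both layers assigned the same
# fibre angle beta shows how much of the opening-angle geometry is
# carried by the collagen fibres.  Because the fibre families only
# measure their circumferential projection (plane strain), a family at
# angle beta engages only where lam_t > 1/cos(beta).  The hoop stretch
# of the closing map never exceeds ~1.14 here, so for beta >= 30 deg
# the fibres stay slack and the geometry collapses onto the fibre-free
# curve; small beta (0-20 deg) stiffens the outer wall and bends the
# media-thickness trend the other way.

suppressPackageStartupMessages(library(artwall))
dir.create("results", showWarnings = FALSE)

fx <- fixture("rabbit_omega_r")
t_m0 <- fx$annulus$r_m - fx$annulus$r_i
t_a0 <- fx$annulus$r_o - fx$annulus$r_m
alphas <- seq(0, 200, by = 40)
betas <- c(0, 10, 15, 20, 30, 60, 90)

mats_at <- function(beta) wall_materials(
  hgo_layer(1.5, 2.3632, 0.8393, beta),
  hgo_layer(0.15, 0.5620, 0.7112, beta))
mats_free <- wall_materials(hgo_layer(1.5, 0, 1, 0),
                            hgo_layer(0.15, 0, 1, 0))

sweep <- function(mats, label) {
  do.call(rbind, lapply(alphas, function(a) {
    s <- solve_stress_free(fx$annulus, a, mats, n_nodes = 51)$sector
    data.frame(fibres = label, alpha_deg = a,
               T_m_norm = (s$R_m - s$R_i) / t_m0,
               T_a_norm = (s$R_o - s$R_m) / t_a0)
  }))
}

tab <- rbind(
  do.call(rbind, lapply(betas, function(b)
    sweep(mats_at(b), sprintf("beta_%g", b)))),
  sweep(mats_free, "fibre_free"),
  sweep(fx$materials, "true_29_62"))

write.csv(tab, "results/thickness_vs_alpha_by_beta.csv",
          row.names = FALSE)

# how far does each fibre case sit from the fibre-free curve?
free_Tm <- tab$T_m_norm[tab$fibres == "fibre_free"]
dev <- vapply(split(tab, tab$fibres), function(d)
  max(abs(d$T_m_norm - free_Tm)), numeric(1))
cat("Max |T_m' - fibre-free| by fibre case:\n")
print(round(dev, 8))
cat("\nCases beta >= 30, beta = 90 and the physiological (29/62) pair",
    "\ncoincide with the fibre-free curve: their fibres never reach",
    "\nlam_t cos(beta) > 1 during closing.  The adventitia thickness",
    "\nT_a' increases with alpha in every case.\n")
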