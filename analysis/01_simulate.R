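#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study set.
#
# Builds C-alpha dimer models emulating the photosensory-module comparison
# set -- a CBD-like dimer (interface offset 32 deg), the PCM reference
# (46 deg, PHY centroids 30 A apart, opening angle 54 deg), a mutant-like
# dimer (26 A / 44 deg, 2 deg PHY rotation), and Pr-like / Pfr-like dimers
# (35 A / 66 deg with 8 deg rotation; 46 A / 85 deg with 33 deg rotation) --
# plus dark/illuminated two-band absorption spectra. Fixtures and their
# ground-truth sidecars go to scratch/fixtures/ for stages 2 and 3.

suppressMessages(library(bphpgeom))

seed <- 20260925L
fix_dir <- "scratch/fixtures"
dir.create(fix_dir, showWarnings = FALSE, recursive = TRUE)

message("Generating synthetic dimers (516 residues/subunit, noise 0.05 A)...")
specs <- list(
  cbd_like   = dimer_spec(phi = 32, seed = seed, noise_sigma = 0.05,
                          noise_seed = seed + 1L),
  reference  = dimer_spec(seed = seed, noise_sigma = 0.05,
                          noise_seed = seed + 2L),
  t289h_like = dimer_spec(d_centroids = 26, omega = 44, phy_rotation = 2,
                          seed = seed, noise_sigma = 0.05,
                          noise_seed = seed + 3L),
  pr_like    = dimer_spec(d_centroids = 35, omega = 66, phy_rotation = 8,
                          seed = seed, noise_sigma = 0.05,
                          noise_seed = seed + 4L),
  pfr_like   = dimer_spec(d_centroids = 46, omega = 85, phy_rotation = 33,
                          seed = seed, noise_sigma = 0.05,
                          noise_seed = seed + 5L))

for (nm in names(specs)) {
  g <- make_synthetic_dimer(specs[[nm]])
  g$structure$identifier <- nm
  write_structure_pdb(g$structure, file.path(fix_dir, paste0(nm, ".pdb")))
  write_ground_truth(g$truth, file.path(fix_dir, paste0(nm, "_truth.yaml")))
  message(sprintf("  %-10s phi=%5.1f  d=%5.1f A  omega=%5.1f deg  rot=%4.1f deg",
                  nm, g$truth$phi, g$truth$d_centroids, g$truth$omega,
                  g$truth$phy_rotation))
}

message("Generating dark/illuminated spectra (240-800 nm, 0.5 nm grid)...")
mixture <- function(f, s) make_synthetic_spectrum(band_spec(
  bands = data.frame(center = c(700, 750), width = 15,
                     amplitude = c(1 - f, f)),
  noise_sigma = 0.002, seed = s))
write_spectrum(mixture(0.05, seed + 10L), file.path(fix_dir, "pcm_dark.csv"))
write_spectrum(mixture(0.70, seed + 11L),
               file.path(fix_dir, "pcm_illuminated.csv"))
# single-band spectra at the four measured absorption maxima
maxima <- c(cbd_wt = 698, cbd_t289h = 702, pcm_wt = 701.5, pcm_t289h = 706)
for (nm in names(maxima)) {
  s <- make_synthetic_spectrum(band_spec(
    bands = data.frame(center = maxima[[nm]], width = 20, amplitude = 1)))
  write_spectrum(s, file.path(fix_dir, paste0("band_", nm, ".csv")))
}

message("Done: fixtures in ", fix_dir)
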