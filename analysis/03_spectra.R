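#!/usr/bin/env Rscript

# Stage 3: spectral analysis of the simulated photoconversion.
#
# Reads the stage-1 spectra, normalizes to the red/far-red band, forms the
# illuminated-minus-dark difference spectrum of the Pr-to-Pfr mixture job,
# and extracts absorption maxima for the four single-band spectra generated
# at the measured maxima (698 / 702 / 701.5 / 706 nm). Writes
# results/spectra/ (normalized + difference CSVs, summary TSV) and
# results/lambda_max.tsv.

suppressMessages(library(bphpgeom))

fix_dir <- "scratch/fixtures"
if (!file.exists(file.path(fix_dir, "pcm_dark.csv")))
  stop("fixtures not found; run analysis/01_simulate.R first")
dir.create("results/spectra", showWarnings = FALSE, recursive = TRUE)

cfg <- run_config(
  spectra_jobs = list(
    pcm = list(dark = file.path(fix_dir, "pcm_dark.csv"),
               illuminated = file.path(fix_dir, "pcm_illuminated.csv"))),
  out_dir = "results/spectra")
summary <- run_spectra(cfg)
message("Photoconversion difference spectrum (results/spectra/):")
message(sprintf(
  "  bleach (Pr) at %.1f nm, gain (Pfr) at %.1f nm, amplitudes %.2f / %+.2f",
  summary$diff_neg_nm, summary$diff_pos_nm,
  summary$diff_neg_au, summary$diff_pos_au))

files <- Sys.glob(file.path(fix_dir, "band_*.csv"))
rows <- do.call(rbind, lapply(files, function(f) {
  s <- read_spectrum(f, label = sub("^band_(.*)\\.csv$", "\\1", basename(f)))
  data.frame(sample = s$label, lambda_max_nm = lambda_max(s)$lambda_max)
}))
utils::write.table(rows, "results/lambda_max.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
message("\nAbsorption maxima (results/lambda_max.tsv):")
for (i in seq_len(nrow(rows)))
  message(sprintf("  %-10s %6.1f nm", rows$sample[i], rows$lambda_max_nm[i]))
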