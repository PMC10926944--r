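#!/usr/bin/env Rscript

# Stage 2 — fit the Ising potential energy landscape of every estimation
# region in both samples by maximum likelihood, and write the per-region
# parameter tables plus per-sample MML/NME browser tracks.

suppressPackageStartupMessages(library(methpel))
source(file.path("analysis", "helpers.R"))

sim <- load_sim()
out <- res_dir("fits")

for (sample_name in c("normal", "tumor")) {
  reads <- sim[[sample_name]]
  t0 <- Sys.time()
  fit <- fit_sample(reads, sim$map, sim$partition)
  message(sprintf("%s: fit %d/%d regions (median n_reads %.0f) in %.0f s",
                  sample_name, sum(!is.na(fit$a)), nrow(fit),
                  median(fit$n_reads),
                  as.numeric(Sys.time() - t0, units = "secs")))
  write_parameter_table(fit, file.path(out,
                                       paste0(sample_name, ".params.tsv")))
  track <- landscape_track(fit, sim$map, sim$partition)
  message(sprintf("  scored %d/%d subregions; median MML %.3f, NME %.3f",
                  sum(is.finite(track$mml)), nrow(track),
                  median(track$mml, na.rm = TRUE),
                  median(track$nme, na.rm = TRUE)))
  write_track(sim$partition, track$mml,
              file.path(out, paste0(sample_name, ".mml.bedGraph")),
              paste(sample_name, "MML"))
  write_track(sim$partition, track$nme,
              file.path(out, paste0(sample_name, ".nme.bedGraph")),
              paste(sample_name, "NME"))
}
message("wrote ", out)
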