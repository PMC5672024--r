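#!/usr/bin/env Rscript
# Simulate the raw inputs of the whole characterization study: a panel of
# two-channel immunofluorescence images (one per treatment, three
# replicate images each) with known per-cell N/C ground truth.
# Active GR ligands drive nuclear accumulation (high true N/C); the
# inactive analogs and solvent stay cytoplasmic (N/C near 1).

suppressPackageStartupMessages(library(segraquant))

seed0 <- 20260922L
out_dir <- file.path("results", "01_sim")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# true N/C ratio per treatment: strong translocation for Dex, Dex-Mes,
# GSK866 and the covalent analogs 1217/1218; none for 1158/1159
panel <- data.frame(
  treatment = c("solvent", "Dex", "Dex-Mes", "GSK866",
                "UAMC-1158", "UAMC-1159", "UAMC-1217", "UAMC-1218"),
  nc_true = c(1.0, 3.0, 2.5, 3.0, 1.0, 1.0, 2.8, 2.6)
)
n_replicate_images <- 3

truth_all <- list()
for (i in seq_len(nrow(panel))) {
  for (rep in seq_len(n_replicate_images)) {
    cfg <- sim_config(seed = seed0 + 100 * i + rep, n_cells = 20,
                      nc_ratio_true = panel$nc_true[i], noise_cv = 0.05,
                      touching_frac = 0.2)
    sim <- gen_translocation_image(cfg)
    stem <- sprintf("%s_rep%d", gsub("[^A-Za-z0-9]", "", panel$treatment[i]),
                    rep)
    write_translocation_tiff(sim$nuclear, sim$gr,
                             file.path(out_dir, paste0(stem, ".tif")))
    write_truth_csv(sim$truth, cfg$image_shape,
                    file.path(out_dir, paste0(stem, "_truth.csv")))
    ts <- sim$truth_summary
    ts$treatment <- panel$treatment[i]
    ts$image <- stem
    truth_all[[length(truth_all) + 1L]] <- ts
  }
}
truth_all <- do.call(rbind, truth_all)
write.csv(truth_all, file.path(out_dir, "truth_summary.csv"),
          row.names = FALSE)

cat(sprintf("simulated %d images (%d treatments x %d replicates), %d cells total\n",
            nrow(panel) * n_replicate_images, nrow(panel),
            n_replicate_images, nrow(truth_all)))
cat("outputs in", out_dir, "\n")
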