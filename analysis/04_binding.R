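#!/usr/bin/env Rscript
# Competition-binding analysis: percent displacement from raw counts,
# four-parameter-logistic IC50 fits of simulated displacement curves at
# the ligand panel's potencies, and Cheng-Prusoff conversion to Ki
# (1.5 nM radioligand, Kd assumed 1.5 nM).

suppressPackageStartupMessages(library(segraquant))

seed0 <- 20260924L
out_dir <- file.path("results", "04_binding")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## --- percent displacement from counts ---------------------------------
# counts at 1 uM competitor; nonspecific 200, total 10200
total <- 10200; nonspec <- 200
counts <- c(Dex = 200, `Dex-Mes` = 300, GSK866 = 200,
            `UAMC-1158` = 10400, `UAMC-1159` = 11400,
            `UAMC-1217` = 1000, `UAMC-1218` = 600)
disp <- data.frame(
  ligand = names(counts),
  pct_inhibition = round(percent_displacement(counts, total, nonspec))
)
write.csv(disp, file.path(out_dir, "percent_displacement.csv"),
          row.names = FALSE)
cat("percent inhibition of radioligand binding (negative = none):\n")
print(disp)

## --- IC50 fits and Ki for the competing ligands ------------------------
true_ic50 <- c(`Dex-Mes` = 7.3, GSK866 = 4.6, `UAMC-1217` = 22,
               `UAMC-1218` = 34) # nM
conc <- 10^seq(log10(0.1), log10(1000), length.out = 9) # nM
rows <- lapply(names(true_ic50), function(lig) {
  cur <- gen_binding_curve(true_ic50[[lig]], hill = 1, top = 100,
                           bottom = 0, concentrations = conc,
                           noise_cv = 0.03,
                           seed = seed0 + match(lig, names(true_ic50)))
  f <- fit_4pl(cur$concentration, cur$response)
  data.frame(ligand = lig, true_ic50_nM = true_ic50[[lig]],
             fitted_ic50_nM = f$ic50, hill = f$hill,
             ki_nM = cheng_prusoff_ki(f$ic50),
             ki_2sf = signif_half_up(cheng_prusoff_ki(f$ic50), 2),
             converged = f$converged)
})
fits <- do.call(rbind, rows)
write.csv(fits, file.path(out_dir, "ic50_ki.csv"), row.names = FALSE)
print(fits, digits = 3)

# the Ki implied by the printed IC50s themselves
ref <- data.frame(ligand = names(true_ic50),
                  ic50_nM = unname(true_ic50),
                  ki_2sf = signif_half_up(cheng_prusoff_ki(unname(true_ic50)), 2))
write.csv(ref, file.path(out_dir, "ki_from_tabulated_ic50.csv"),
          row.names = FALSE)
cat("Ki = IC50/2 under the 1.5 nM / 1.5 nM assay constants:\n")
print(ref)
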