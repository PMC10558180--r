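#!/usr/bin/env Rscript
# PET-uptake correlate analysis on the synthetic cohort: contralaterally
# normalized tumor-level and voxel-level tables, log-standardized
# multivariate OLS (with and without lectin), partial-regression points per
# regressor, and a coefficient-recovery simulation over repeated
# study-sized cohorts.

library(tumorburden)

seed <- 42L
dir.create("results", showWarnings = FALSE)
cohort <- generate_cohort(4, 5, 4, master_seed = seed)

cat("Building tumor-level correlate table (13 cases) ...\n")
tumor_tab <- build_tumor_table(cohort)
write_tsv_table(tumor_tab, file.path("results", "correlates_tumor_level.tsv"))
print(tumor_tab, digits = 3, row.names = FALSE)

# voxel-level table on the PET lattice, first PET-visible case
vis <- which(tumor_tab$pet_uptake > 1.05)
vox <- build_voxel_table(cohort[[vis[1]]])
write_tsv_table(vox, file.path("results", "correlates_voxel_level.tsv"))
cat(
  "\nVoxel-level table for ", cohort[[vis[1]]]$case_id, ": ", nrow(vox),
  " tumor voxels on the 0.5 x 0.5 x 1 mm PET grid; PET-tdTomato correlation ",
  round(cor(vox$pet_uptake, vox$tdtomato), 3), "\n",
  sep = ""
)

# regression restricted to PET-visible cases (uptake above background)
z <- log_standardize(tumor_tab[vis, ])
fit <- fit_multivariate(z)
cat("\nTumor-level multivariate fit (PET-visible cases):\n")
print(fit)
sink(file.path("results", "correlates_fit.txt"))
print(fit)
sink()
write_tsv_table(fit$coefficients, file.path("results", "correlates_coefficients.tsv"))
cat(
  "\nNote: phantom fluorescence channels are all driven by the same cell-",
  "density field,\nso the tumor-level design is highly collinear and ",
  "individual coefficients are\nunstable at n = ", fit$n, "; the recovery ",
  "simulation below is the calibrated check.\n",
  sep = ""
)

partials <- do.call(rbind, lapply(fit$regressors, function(reg) {
  pr <- partial_regression(z, reg)
  data.frame(
    regressor = reg, x_residual = pr$x_residuals, y_residual = pr$y_residuals,
    slope = pr$slope
  )
}))
write_tsv_table(partials, file.path("results", "partial_regression_points.tsv"))
cat("\nPartial-regression slopes equal the multivariate coefficients",
    "(Frisch-Waugh-Lovell):\n")
print(unique(partials[c("regressor", "slope")]), digits = 3, row.names = FALSE)

# coefficient recovery at the study size
effects <- c(tdtomato = 1.0, asct2 = 0.3, lectin = 0.2,
             tumor_volume = 0.25, gd_status = 0.35)
n_rep <- 200
ests <- matrix(NA_real_, n_rep, length(effects), dimnames = list(NULL, names(effects)))
for (r in seq_len(n_rep)) {
  sim <- generate_correlate_cohort(n = 13, effects = effects, seed = seed * 1000L + r)
  f <- fit_multivariate(log_standardize(sim, standardize_response = FALSE))
  ests[r, ] <- f$coefficients$estimate[match(names(effects), f$coefficients$term)]
}
recovery <- data.frame(
  regressor = names(effects), true_effect = unname(effects),
  mean_estimate = colMeans(ests), sd_estimate = apply(ests, 2, sd)
)
write_tsv_table(recovery, file.path("results", "correlates_recovery.tsv"))
cat("\nCoefficient recovery over", n_rep, "simulated 13-tumor cohorts:\n")
print(recovery, digits = 3, row.names = FALSE)
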