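#!/usr/bin/env Rscript
# Landmark-based slice registration check: slice the first case's tdTomato
# channel into 1-mm sections, deform every section with a known random 2D
# affine, then register the stack back through per-slice landmark fits and
# measure how well the tumor mask is recovered.

library(tumorburden)

seed <- 42L
cohort <- generate_cohort(4, 5, 4, master_seed = seed)

rows <- lapply(cohort[1:3], function(case) {
  problem <- make_slice_registration_problem(case$volumes$tdtomato, seed = seed)
  recovered <- register_slice_stack(
    problem$slices, problem$landmarks, problem$target,
    interpolation = "nearest"
  )
  thr <- case$thresholds[["tdtomato"]]
  ref_mask <- threshold_segment(problem$reference, thr)
  rec_mask <- threshold_segment(recovered, thr)
  fre <- vapply(
    problem$landmarks,
    function(lm) attr(fit_affine_landmarks(lm), "fre_mm"), numeric(1)
  )
  data.frame(
    case_id = case$case_id,
    n_slices = problem$target$shape[3],
    mean_fre_mm = mean(fre),
    recovery_dice = dice(rec_mask, ref_mask),
    recovery_msd_mm = max_surface_distance(rec_mask, ref_mask)
  )
})
report <- do.call(rbind, rows)

dir.create("results", showWarnings = FALSE)
write_tsv_table(report, file.path("results", "registration_recovery.tsv"))
cat("Slice-stack registration recovery (exact landmarks, nearest resampling):\n")
print(report, digits = 4)
cat("\nAll recovered tumor masks overlap the originals with Dice >",
  round(min(report$recovery_dice), 3), "\n")
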