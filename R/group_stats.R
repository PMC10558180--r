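#' Median and range of a sample
#'
#' Sample median (midpoint of the two central order statistics for even n)
#' with minimum and maximum.
#'
#' @param values non-empty numeric vector; `NA` entries (e.g. "nd" surface
#'   distances) are dropped when `na.rm = TRUE`.
#' @param na.rm drop `NA` values first.
#' @return named list `median`, `min`, `max`, `n`.
#' @export
median_range <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  if (length(values) == 0) stop("median_range requires a non-empty sample")
  if (any(is.na(values))) stop("median_range: NA values present (use na.rm = TRUE)")
  list(
    median = stats::median(values), min = min(values), max = max(values),
    n = length(values)
  )
}

#' Percent change of one median relative to a reference
#'
#' `100 * (new - ref) / ref`, e.g. a combined-modality median sensitivity of
#' 0.86 against an MRI-alone 0.61 is a 41% increase.
#'
#' @param new_median,ref_median numeric; `ref_median` must be > 0.
#' @param digits rounding for the reported percentage (default integer).
#' @return percent change (positive = increase).
#' @export
percent_increase <- function(new_median, ref_median, digits = 0) {
  if (!is.finite(ref_median) || ref_median <= 0) {
    stop("percent_increase requires a positive reference median")
  }
  round(100 * (new_median - ref_median) / ref_median, digits)
}

# Exact null distribution helpers ------------------------------------------
#
# Both tests enumerate their exact permutation null over midranks. Ties make
# midranks half-integers, so ranks are doubled to integers and distributions
# are built by dynamic-programming convolution (equivalent to enumerating all
# 2^m sign assignments / all C(n1+n2, n1) group assignments).

# counts[s+1] = number of subsets of `weights` (integer >= 0) summing to s
subset_sum_counts <- function(weights) {
  total <- sum(weights)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (w in weights) {
    if (w == 0) {
      counts <- counts * 2
    } else {
      shifted <- c(numeric(w), counts[seq_len(total + 1 - w)])
      counts <- counts + shifted
    }
  }
  counts
}

# counts[s+1] = number of k-subsets of `weights` summing to s
k_subset_sum_counts <- function(weights, k) {
  total <- sum(weights)
  counts <- matrix(0, nrow = k + 1, ncol = total + 1)
  counts[1, 1] <- 1
  for (w in weights) {
    for (kk in k:1) {
      row <- counts[kk, ]
      if (w == 0) {
        counts[kk + 1, ] <- counts[kk + 1, ] + row
      } else {
        counts[kk + 1, ] <- counts[kk + 1, ] +
          c(numeric(w), row[seq_len(total + 1 - w)])
      }
    }
  }
  counts[k + 1, ]
}

two_sided_from_tail <- function(counts, observed) {
  # counts over statistic values 0..length-1 (doubled-rank scale)
  total <- sum(counts)
  vals <- seq_along(counts) - 1
  p_le <- sum(counts[vals <= observed]) / total
  p_ge <- sum(counts[vals >= observed]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Exact Wilcoxon signed-rank test (paired, zeros discarded)
#'
#' Paired two-sided test by full enumeration. Zero differences are discarded
#' (the classical Wilcoxon convention); the absolute nonzero differences are
#' ranked with midranks for ties, and the exact two-sided p-value is computed
#' from the distribution of the positive-rank sum over all `2^m` sign
#' assignments of the m nonzero pairs (two-sided p = twice the smaller tail,
#' capped at 1).
#'
#' @param paired_a,paired_b equal-length numeric vectors (n <= 25).
#' @return list with `p_value`, `statistic` (positive-rank sum),
#'   `n_nonzero`, and `degenerate` (`TRUE` when all differences are zero, in
#'   which case `p_value = 1`).
#' @export
wilcoxon_signed_rank_exact <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) stop("paired samples must have equal length")
  if (length(paired_a) > 25) stop("exact enumeration limited to n <= 25")
  d <- paired_a - paired_b
  if (any(is.na(d))) stop("paired samples must not contain NA")
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(list(p_value = 1, statistic = 0, n_nonzero = 0L, degenerate = TRUE))
  }
  r2 <- as.integer(round(2 * rank(abs(d)))) # doubled midranks: integers
  w_plus2 <- sum(r2[d > 0])
  counts <- subset_sum_counts(r2)
  p <- two_sided_from_tail(counts, w_plus2)
  list(
    p_value = p, statistic = w_plus2 / 2, n_nonzero = m, degenerate = FALSE
  )
}

#' Exact Wilcoxon rank-sum test (unpaired)
#'
#' Two-sided two-sample test by full enumeration: the pooled values are
#' midranked, and the exact distribution of the first group's rank sum over
#' all `choose(n1 + n2, n1)` group assignments gives the p-value (twice the
#' smaller tail, capped at 1).
#'
#' @param group_a,group_b non-empty numeric vectors, combined n <= 25.
#' @return list with `p_value`, `statistic` (group-a rank sum), `n_a`, `n_b`.
#' @export
wilcoxon_rank_sum_exact <- function(group_a, group_b) {
  n1 <- length(group_a)
  n2 <- length(group_b)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  if (n1 + n2 > 25) stop("exact enumeration limited to combined n <= 25")
  pooled <- c(group_a, group_b)
  if (any(is.na(pooled))) stop("groups must not contain NA")
  r2 <- as.integer(round(2 * rank(pooled)))
  w_a2 <- sum(r2[seq_len(n1)])
  counts <- k_subset_sum_counts(r2, n1)
  p <- two_sided_from_tail(counts, w_a2)
  list(p_value = p, statistic = w_a2 / 2, n_a = n1, n_b = n2)
}

# grouping predicates over a per-tumor score table (long format)
cohort_groups <- function(scores) {
  ids <- unique(scores$case_id)
  gd <- vapply(ids, function(i) scores$gd_status[scores$case_id == i][1], logical(1))
  petvis <- vapply(ids, function(i) {
    pet <- scores[scores$case_id == i & scores$modality == "PET", , drop = FALSE]
    nrow(pet) > 0 && isTRUE(pet$volume_mm3[1] > 0)
  }, logical(1))
  list(
    "overall" = ids,
    "Gd+" = ids[gd],
    "Gd-" = ids[!gd],
    "Gd- PET-visible" = ids[!gd & petvis],
    "Gd- PET-invisible" = ids[!gd & !petvis],
    "PET-visible" = ids[petvis]
  )
}

#' Cohort summary tables and exact comparisons
#'
#' From a long per-tumor score table (the output of [evaluate_case()] rows
#' bound together, or the packaged printed-table fixture), computes:
#'
#' * `summary`: median/min/max/n per grouping (overall, Gd+, Gd-,
#'   Gd- PET-visible, Gd- PET-invisible, PET-visible) x modality x metric.
#'   `NA` ("nd") surface distances are excluded from distance medians; a
#'   grouping with zero members is omitted with a warning.
#' * `comparisons`: paired exact signed-rank tests between modalities
#'   (sensitivity and specificity for MRI+PET vs each component, PET vs MRI;
#'   volumes vs the optical ground truth), unpaired exact rank-sum tests of
#'   Gd+ vs Gd- combined-MRI scores, and percent changes of the medians.
#'
#' @param scores data.frame with columns `case_id`, `modality`,
#'   `volume_mm3`, `sensitivity`, `specificity`, `dice`,
#'   `max_surface_distance_mm`, `gd_status`.
#' @return list with data.frames `summary` and `comparisons`.
#' @export
summarize_cohort <- function(scores) {
  metrics <- c("volume_mm3", "sensitivity", "specificity", "dice", "max_surface_distance_mm")
  groups <- cohort_groups(scores)
  empty <- vapply(groups, function(g) length(g) == 0, logical(1))
  if (any(empty)) {
    warning("omitting empty grouping(s): ", paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  rows <- list()
  for (gname in names(groups)) {
    sub <- scores[scores$case_id %in% groups[[gname]], , drop = FALSE]
    for (mod in unique(sub$modality)) {
      msub <- sub[sub$modality == mod, , drop = FALSE]
      for (metric in metrics) {
        vals <- msub[[metric]]
        vals <- vals[!is.na(vals)]
        if (length(vals) == 0) next
        mr <- median_range(vals)
        rows[[length(rows) + 1]] <- data.frame(
          group = gname, modality = mod, metric = metric,
          median = mr$median, min = mr$min, max = mr$max, n = mr$n,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  summary_tab <- do.call(rbind, rows)

  # paired comparisons on common cases, aligned by case_id
  wide <- function(metric, modality, ids) {
    vapply(ids, function(i) {
      v <- scores[scores$case_id == i & scores$modality == modality, metric]
      if (length(v) == 0) NA_real_ else v[1]
    }, numeric(1))
  }
  ids_all <- unique(scores$case_id)
  cmp_rows <- list()
  add_paired <- function(label, metric, mod_a, mod_b, ids = ids_all) {
    a <- wide(metric, mod_a, ids)
    b <- wide(metric, mod_b, ids)
    keep <- !is.na(a) & !is.na(b)
    if (sum(keep) < 1) return(invisible(NULL))
    test <- wilcoxon_signed_rank_exact(a[keep], b[keep])
    med_a <- stats::median(a[keep])
    med_b <- stats::median(b[keep])
    pct <- if (med_b > 0) percent_increase(med_a, med_b) else NA_real_
    cmp_rows[[length(cmp_rows) + 1]] <<- data.frame(
      comparison = label, metric = metric, test = "signed-rank (exact, zeros discarded)",
      n = sum(keep), median_a = med_a, median_b = med_b,
      percent_change = pct, p_value = test$p_value,
      degenerate = test$degenerate, stringsAsFactors = FALSE
    )
  }
  add_unpaired <- function(label, metric, modality, ids_a, ids_b) {
    a <- wide(metric, modality, ids_a)
    b <- wide(metric, modality, ids_b)
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) return(invisible(NULL))
    test <- wilcoxon_rank_sum_exact(a, b)
    cmp_rows[[length(cmp_rows) + 1]] <<- data.frame(
      comparison = label, metric = metric, test = "rank-sum (exact)",
      n = length(a) + length(b), median_a = stats::median(a), median_b = stats::median(b),
      percent_change = NA_real_, p_value = test$p_value,
      degenerate = FALSE, stringsAsFactors = FALSE
    )
  }
  for (metric in c("sensitivity", "specificity")) {
    add_paired("MRI+PET vs T1+T2", metric, "MRI+PET", "T1+T2")
    add_paired("MRI+PET vs PET", metric, "MRI+PET", "PET")
    add_paired("PET vs T1+T2", metric, "PET", "T1+T2")
  }
  add_paired("T1+T2 vs Optical", "volume_mm3", "T1+T2", "Optical")
  pv <- groups[["PET-visible"]]
  if (!is.null(pv) && length(pv) > 0) {
    add_paired("PET vs Optical (PET-visible)", "volume_mm3", "PET", "Optical", pv)
    add_paired("PET vs T1+T2 (PET-visible)", "volume_mm3", "PET", "T1+T2", pv)
  }
  gdp <- groups[["Gd+"]]
  gdn <- groups[["Gd-"]]
  if (!is.null(gdp) && !is.null(gdn) && length(gdp) > 0 && length(gdn) > 0) {
    add_unpaired("Gd+ vs Gd- (T1+T2)", "sensitivity", "T1+T2", gdp, gdn)
    add_unpaired("Gd+ vs Gd- (T1+T2)", "specificity", "T1+T2", gdp, gdn)
  }
  comparisons <- do.call(rbind, cmp_rows)
  list(summary = summary_tab, comparisons = comparisons)
}

#' Reporting rounding rules
#'
#' Round half-up to a fixed number of decimals (volumes to whole mm^3,
#' scores to 2 decimals) — only at the reporting layer; raw precision is kept
#' internally. P-values are formatted to 1 significant figure at or below
#' 0.01 and to 2 decimals above.
#'
#' @param x numeric.
#' @param digits decimals to keep.
#' @return `round_half_up`: numeric; `format_p_value`: character.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' @rdname round_half_up
#' @param p a p-value in `[0, 1]`.
#' @export
format_p_value <- function(p) {
  ifelse(p <= 0.01, formatC(signif(p, 1), format = "fg"), formatC(round_half_up(p, 2), format = "fg"))
}
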