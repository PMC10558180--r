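#' Contralateral normalization
#'
#' Divides a tumor-side summary statistic by the mean signal in mirrored
#' normal brain, removing global scale differences between animals and
#' acquisitions. Invariant to rescaling the whole image by any positive
#' constant.
#'
#' @param tumor_stat numeric tumor summary (max PET uptake, mean
#'   fluorescence, ...).
#' @param contralateral_mean positive mean over the contralateral normal
#'   region.
#' @return dimensionless ratio.
#' @export
normalize_to_contralateral <- function(tumor_stat, contralateral_mean) {
  if (!is.finite(contralateral_mean) || contralateral_mean <= 0) {
    stop("contralateral mean must be > 0")
  }
  tumor_stat / contralateral_mean
}

#' Tumor-level correlate table
#'
#' One record per tumor: PET summarized by its maximum over the ground-truth
#' tumor mask, each fluorescence channel (tdTomato, ASCT2, optionally
#' lectin) by its mean over the mask — each normalized to the mean of the
#' same image over the contralateral normal-brain mask — plus the tumor
#' volume (mm^3) and gadolinium status. A case without a lectin channel
#' yields `NA` lectin (absent, not zero).
#'
#' @param cases list of tumor cases; each a list with `case_id`,
#'   `gd_status`, masks `truth` and `contralateral`, and a `volumes` list
#'   with entries `pet`, `tdtomato`, `asct2` and optionally `lectin`. `pet`
#'   may live on its own (coarser) grid: the truth/contralateral masks are
#'   then brought to the PET grid by nearest-neighbour resampling of the
#'   masks themselves... see Details.
#' @details PET summaries are taken on the PET grid, using the truth and
#'   contralateral masks downsampled to it by nearest-neighbour; fluorescence
#'   summaries are taken on the fine grid.
#' @return data.frame with columns `case_id`, `pet_uptake`, `tdtomato`,
#'   `asct2`, `lectin`, `tumor_volume`, `gd_status`.
#' @export
build_tumor_table <- function(cases) {
  rows <- lapply(cases, function(case) {
    truth <- case$masks$truth
    contra <- case$masks$contralateral
    if (!any(contra$values)) stop("empty contralateral mask for case ", case$case_id)
    summarize_channel <- function(vol, statistic) {
      t_mask <- truth
      c_mask <- contra
      if (!geom_equal(vol$geometry, truth$geometry)) {
        t_mask <- mask_on_grid(truth, vol$geometry)
        c_mask <- mask_on_grid(contra, vol$geometry)
        if (!any(t_mask$values)) stop("no tumor voxels on the channel grid for ", case$case_id)
        if (!any(c_mask$values)) stop("no contralateral voxels on the channel grid for ", case$case_id)
      }
      normalize_to_contralateral(
        statistic(vol$values[t_mask$values]),
        mean(vol$values[c_mask$values])
      )
    }
    data.frame(
      case_id = case$case_id,
      pet_uptake = summarize_channel(case$volumes$pet, max),
      tdtomato = summarize_channel(case$volumes$tdtomato, mean),
      asct2 = summarize_channel(case$volumes$asct2, mean),
      lectin = if (is.null(case$volumes$lectin)) NA_real_ else summarize_channel(case$volumes$lectin, mean),
      tumor_volume = mask_volume_mm3(truth),
      gd_status = as.numeric(case$gd_status),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Nearest-neighbour representation of a fine-grid mask on a coarser grid:
# each coarse voxel takes the fine voxel value whose center is nearest.
mask_on_grid <- function(mask, target) {
  g <- mask$geometry
  idx <- lapply(seq_len(geom_ndim(g)), function(ax) {
    centers <- axis_coords(target, ax)
    i <- floor((centers - g$origin[ax]) / g$spacing[ax] + 0.5)
    pmin(pmax(i, 0), g$shape[ax] - 1) + 1L
  })
  vals <- do.call(`[`, c(list(mask$values), idx, list(drop = FALSE)))
  dim(vals) <- target$shape
  binary_mask(vals, target)
}

#' Voxel-level correlate table for one case
#'
#' Fluorescence channels are brought to the PET grid by block averaging
#' (through the common-refinement resampler, honouring the stated
#' 0.5 x 0.5 x 1 mm PET voxel), the tumor mask is restricted to that grid,
#' and one record per tumor voxel is emitted with the PET value and each
#' downsampled fluorescence value, normalized to the contralateral means on
#' the same grid.
#'
#' @param case a tumor case as in [build_tumor_table()].
#' @param pet_spacing target grid spacing, mm (default `c(0.5, 0.5, 1)`).
#' @return data.frame with one row per tumor voxel on the PET grid.
#' @export
build_voxel_table <- function(case, pet_spacing = c(0.5, 0.5, 1)) {
  pet <- case$volumes$pet
  if (any(abs(pet$geometry$spacing - pet_spacing) > 1e-6)) {
    pet <- resample_to_spacing(pet, pet_spacing)
  }
  truth_pet <- mask_on_grid(case$masks$truth, pet$geometry)
  contra_pet <- mask_on_grid(case$masks$contralateral, pet$geometry)
  if (!any(truth_pet$values)) stop("no tumor voxels on the PET grid for ", case$case_id)
  if (!any(contra_pet$values)) stop("no contralateral voxels on the PET grid for ", case$case_id)
  norm_col <- function(vol) {
    v <- if (geom_equal(vol$geometry, pet$geometry)) vol else resample_to_spacing(vol, pet_spacing)
    normalize_to_contralateral(v$values[truth_pet$values], mean(v$values[contra_pet$values]))
  }
  out <- data.frame(
    case_id = case$case_id,
    pet_uptake = norm_col(case$volumes$pet),
    tdtomato = norm_col(case$volumes$tdtomato),
    asct2 = norm_col(case$volumes$asct2),
    stringsAsFactors = FALSE
  )
  out$lectin <- if (is.null(case$volumes$lectin)) NA_real_ else norm_col(case$volumes$lectin)
  out$gd_status <- as.numeric(case$gd_status)
  out
}

#' Log-transform and z-score a correlate table
#'
#' Continuous columns (uptake, fluorescence ratios, volume) are natural-log
#' transformed then standardized to mean 0, sd 1 (denominator n - 1). The
#' binary gadolinium status is standardized but *not* logged (log 0 is
#' undefined). The response is standardized too by default; set
#' `standardize_response = FALSE` to keep it on the log scale only.
#'
#' @param table data.frame from [build_tumor_table()] / [build_voxel_table()].
#' @param response name of the response column (default `"pet_uptake"`).
#' @param standardize_response logical.
#' @return data.frame with the same columns, transformed.
#' @export
log_standardize <- function(table, response = "pet_uptake", standardize_response = TRUE) {
  continuous <- intersect(
    c("pet_uptake", "tdtomato", "asct2", "lectin", "tumor_volume"),
    names(table)
  )
  out <- table
  zscore <- function(x, label) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("cannot standardize constant column ", label)
    (x - mean(x)) / s
  }
  for (col in continuous) {
    x <- out[[col]]
    if (all(is.na(x))) next
    if (any(is.na(x))) stop("column ", col, " has missing values; drop or use the reduced model")
    if (any(x <= 0)) {
      bad <- which(x <= 0)[1]
      stop(
        "log transform requires positive values; column ", col,
        " is <= 0 at record ", bad
      )
    }
    x <- log(x)
    if (col != response || standardize_response) x <- zscore(x, col)
    out[[col]] <- x
  }
  if ("gd_status" %in% names(out)) {
    out$gd_status <- zscore(out$gd_status, "gd_status")
  }
  out
}

#' Multivariate OLS of PET uptake on biologic correlates
#'
#' Ordinary least squares of the (log-standardized) response on all other
#' continuous columns plus gadolinium status. Records with a missing lectin
#' value are dropped when lectin is among the regressors; fit the
#' lectin-free model (`use_lectin = FALSE`) to use every case.
#'
#' @param table a log-standardized table (see [log_standardize()]).
#' @param response response column name.
#' @param use_lectin include the lectin regressor (complete cases only).
#' @return list of class `correlate_fit`: `coefficients` (data.frame with
#'   estimate, std. error, t, p per regressor), `r_squared`, `residuals`,
#'   `n`, `model` (the underlying `lm`).
#' @export
fit_multivariate <- function(table, response = "pet_uptake", use_lectin = TRUE) {
  regressors <- setdiff(
    intersect(c("tdtomato", "asct2", "lectin", "tumor_volume", "gd_status"), names(table)),
    response
  )
  if (!use_lectin) regressors <- setdiff(regressors, "lectin")
  dat <- table[, c(response, regressors), drop = FALSE]
  if ("lectin" %in% regressors) dat <- dat[!is.na(dat$lectin), , drop = FALSE]
  n <- nrow(dat)
  if (n <= length(regressors) + 1) {
    stop("need n > number of regressors + 1 (have n = ", n, ")")
  }
  qr_design <- qr(as.matrix(cbind(1, dat[regressors])))
  if (qr_design$rank < length(regressors) + 1) {
    cols <- c("(intercept)", regressors)
    bad <- cols[qr_design$pivot[(qr_design$rank + 1):length(cols)]]
    stop("rank-deficient design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  fml <- stats::as.formula(paste(response, "~", paste(regressors, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "std_error", "t_value", "p_value")
  coefs$term <- rownames(coefs)
  rownames(coefs) <- NULL
  structure(
    list(
      coefficients = coefs[, c("term", "estimate", "std_error", "t_value", "p_value")],
      r_squared = sm$r.squared,
      residuals = stats::residuals(fit),
      n = n,
      regressors = regressors,
      response = response,
      model = fit
    ),
    class = "correlate_fit"
  )
}

#' @export
print.correlate_fit <- function(x, ...) {
  cat(
    "correlate_fit: ", x$response, " ~ ", paste(x$regressors, collapse = " + "),
    "  (n = ", x$n, ", R^2 = ", format(round(x$r_squared, 3)), ")\n",
    sep = ""
  )
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Partial-regression (added-variable) construction
#'
#' Residualizes both the response and the regressor of interest against all
#' the other regressors; the slope of the y-residuals on the x-residuals
#' equals the multivariate coefficient of that regressor
#' (Frisch-Waugh-Lovell), and the fitted line passes through the origin.
#'
#' @param table a log-standardized table.
#' @param regressor regressor of interest (column name).
#' @param response response column name.
#' @param use_lectin include lectin among the adjusting regressors.
#' @return list with `x_residuals`, `y_residuals`, `slope`.
#' @export
partial_regression <- function(table, regressor, response = "pet_uptake",
                               use_lectin = TRUE) {
  regressors <- setdiff(
    intersect(c("tdtomato", "asct2", "lectin", "tumor_volume", "gd_status"), names(table)),
    response
  )
  if (!use_lectin) regressors <- setdiff(regressors, "lectin")
  if (!regressor %in% regressors) {
    stop("regressor ", regressor, " not among the model regressors")
  }
  others <- setdiff(regressors, regressor)
  dat <- table[, c(response, regressors), drop = FALSE]
  if ("lectin" %in% regressors) dat <- dat[!is.na(dat$lectin), , drop = FALSE]
  resid_on <- function(target) {
    if (length(others) == 0) {
      return(dat[[target]] - mean(dat[[target]]))
    }
    fml <- stats::as.formula(paste(target, "~", paste(others, collapse = " + ")))
    stats::residuals(stats::lm(fml, data = dat))
  }
  y_res <- resid_on(response)
  x_res <- resid_on(regressor)
  slope <- sum(x_res * y_res) / sum(x_res^2)
  list(x_residuals = unname(x_res), y_residuals = unname(y_res), slope = slope)
}
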