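#' Specification of one synthetic multimodal tumor case
#'
#' Generative parameters for a co-registered multimodal phantom emulating the
#' study geometry: a fine "optical/MRI-class" grid (0.2 x 0.2 x 0.5 mm), a
#' coarse PET grid (0.5 x 0.5 x 1 mm), an ellipsoidal brain, a spherical
#' enhancing tumor core with an irregular infiltrative margin, T2 detecting
#' only part of the truth, T1 enhancing only in Gd+ cases, PET as the truth
#' density blurred by a Gaussian point-spread function over a uniform brain
#' background (partial-volume overshoot of boundaries), and fluorescence
#' channels that are linear functions of the tumor cell density plus noise.
#'
#' @param shape,spacing,origin fine-grid geometry (defaults 70 x 60 x 24
#'   voxels at 0.2 x 0.2 x 0.5 mm).
#' @param pet_spacing PET grid spacing, mm.
#' @param brain_semiaxes_mm ellipsoid semi-axes of the brain, mm.
#' @param core_center_mm tumor core center offset from the brain center, mm
#'   (positive x = implanted hemisphere).
#' @param core_radius_mm enhancing-core radius, mm.
#' @param infiltration_width_mm width of the infiltrative margin beyond the
#'   core, mm (0 = sharply demarcated tumor).
#' @param density_cutoff cell-density level defining the tdTomato-positive
#'   ground truth (and the generative segmentation cutoffs).
#' @param gd_status logical: gadolinium-enhancing (T1-visible core, higher
#'   PET contrast).
#' @param t2_detect_fraction fraction (0, 1] of the truth, by descending cell
#'   density, visible on T2.
#' @param pet_psf_fwhm_mm PET point-spread FWHM, mm (sigma = FWHM / 2.355
#'   per axis).
#' @param pet_tumor_to_background peak tumor-to-background PET activity
#'   ratio; 1 means PET-invisible.
#' @param noise_sd named noise standard deviations per channel (`t1`, `t2`,
#'   `pet`, `tdtomato`, `asct2`, `lectin`), in units of a contrast of 1.
#' @param has_lectin include the lectin channel.
#' @param seed integer RNG seed; every random draw in the phantom flows from
#'   it.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(70L, 60L, 24L),
                         spacing = c(0.2, 0.2, 0.5),
                         origin = c(0, 0, 0),
                         pet_spacing = c(0.5, 0.5, 1),
                         brain_semiaxes_mm = c(6.6, 5.4, 5.4),
                         core_center_mm = c(2.2, 0, 0),
                         core_radius_mm = 2.0,
                         infiltration_width_mm = 1.0,
                         density_cutoff = 0.2,
                         gd_status = TRUE,
                         t2_detect_fraction = 0.8,
                         pet_psf_fwhm_mm = 1.5,
                         pet_tumor_to_background = 3,
                         noise_sd = c(
                           t1 = 0.02, t2 = 0.02, pet = 0.02,
                           tdtomato = 0.02, asct2 = 0.05, lectin = 0.05
                         ),
                         has_lectin = TRUE,
                         seed = 1L) {
  spec <- list(
    shape = as.integer(shape), spacing = spacing, origin = origin,
    pet_spacing = pet_spacing,
    brain_semiaxes_mm = brain_semiaxes_mm,
    core_center_mm = core_center_mm,
    core_radius_mm = core_radius_mm,
    infiltration_width_mm = infiltration_width_mm,
    density_cutoff = density_cutoff,
    gd_status = isTRUE(gd_status),
    t2_detect_fraction = t2_detect_fraction,
    pet_psf_fwhm_mm = pet_psf_fwhm_mm,
    pet_tumor_to_background = pet_tumor_to_background,
    noise_sd = noise_sd,
    has_lectin = isTRUE(has_lectin),
    seed = as.integer(seed)
  )
  if (any(brain_semiaxes_mm <= 0) || core_radius_mm <= 0 || infiltration_width_mm < 0) {
    stop("geometric phantom parameters must be positive (width >= 0)")
  }
  if (t2_detect_fraction <= 0 || t2_detect_fraction > 1) {
    stop("t2_detect_fraction must lie in (0, 1]")
  }
  if (pet_psf_fwhm_mm < 0 || pet_tumor_to_background < 1) {
    stop("pet_psf_fwhm_mm >= 0 and pet_tumor_to_background >= 1 required")
  }
  tumor_extent <- sqrt(sum(core_center_mm^2)) + core_radius_mm + infiltration_width_mm
  if (tumor_extent >= min(brain_semiaxes_mm)) {
    stop(
      "tumor (offset + core + infiltration = ", format(tumor_extent),
      " mm) exceeds the brain ellipsoid (min semi-axis ",
      format(min(brain_semiaxes_mm)), " mm)"
    )
  }
  structure(spec, class = "phantom_spec")
}

# separable Gaussian blur of a 3D array, sigma in mm per axis; kernel
# truncated at 4 sigma, renormalized (zero-padded boundaries)
gaussian_blur_mm <- function(values, sigma_mm, spacing) {
  for (ax in seq_along(dim(values))) {
    s <- sigma_mm[ax]
    if (s <= 0) next
    step <- spacing[ax]
    half <- max(1L, ceiling(4 * s / step))
    x <- (-half:half) * step
    kern <- exp(-x^2 / (2 * s^2))
    kern <- kern / sum(kern)
    n <- dim(values)[ax]
    # banded convolution matrix acting on the axis (zero padding outside)
    conv <- matrix(0, n, n)
    for (j in seq_along(kern)) {
      off <- j - half - 1L
      idx <- seq_len(n)
      src <- idx + off
      ok <- src >= 1 & src <= n
      conv[cbind(idx[ok], src[ok])] <- conv[cbind(idx[ok], src[ok])] + kern[j]
    }
    d <- length(dim(values))
    perm <- seq_len(d)
    perm[c(1L, ax)] <- perm[c(ax, 1L)]
    values <- aperm(values, perm)
    dims <- dim(values)
    values <- conv %*% matrix(values, nrow = dims[1])
    dim(values) <- dims
    values <- aperm(values, perm)
  }
  values
}

#' Generate one synthetic multimodal tumor case
#'
#' Deterministic given `spec$seed`. Returns co-registered channels on the
#' fine grid (T1, T2, tdTomato, ASCT2, lectin), PET on the PET grid (blurred
#' on the fine grid, then brought to the PET lattice by block averaging over
#' the common refinement), the ground-truth tumor mask (noiseless tdTomato
#' thresholded at its generative cutoff), brain and contralateral
#' normal-brain masks, and the per-modality segmentation thresholds a reader
#' of each image would use.
#'
#' @param spec a [phantom_spec()].
#' @param case_id label for the case.
#' @return list of class `tumor_case` with elements `case_id`, `gd_status`,
#'   `spec`, `geometry`, `volumes` (scalar volumes per channel), `masks`
#'   (`truth`, `brain`, `contralateral`), `thresholds` (named numeric) and
#'   `stratum`.
#' @export
generate_phantom <- function(spec, case_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    g <- grid_geometry(spec$shape, spec$spacing, spec$origin)
    centers <- voxel_centers(g)
    brain_center <- g$origin + (g$shape - 1) * g$spacing / 2
    rel <- sweep(centers, 2, brain_center, "-")
    brain_v <- rowSums(sweep(rel, 2, spec$brain_semiaxes_mm, "/")^2) <= 1
    core_center <- brain_center + spec$core_center_mm
    dist_core <- sqrt(rowSums(sweep(centers, 2, core_center, "-")^2))

    # cell density: 1 in the core, ramping to 0 across the infiltrative
    # margin, modulated by a smooth random field so the margin is irregular
    density <- numeric(nrow(centers))
    density[dist_core <= spec$core_radius_mm] <- 1
    if (spec$infiltration_width_mm > 0) {
      shell <- dist_core > spec$core_radius_mm &
        dist_core <= spec$core_radius_mm + spec$infiltration_width_mm
      ramp <- 1 - (dist_core[shell] - spec$core_radius_mm) / spec$infiltration_width_mm
      field <- array(stats::runif(prod(g$shape)), g$shape)
      field <- gaussian_blur_mm(field, rep(0.6, 3), g$spacing)
      f <- field[shell]
      f <- (f - min(f)) / max(1e-12, diff(range(f))) # to [0, 1]
      density[shell] <- ramp * (0.4 + 0.6 * f) # stays within [0, 1]
    }
    density[!brain_v] <- 0
    dim(density) <- g$shape
    brain_arr <- array(brain_v, g$shape)

    # ground truth := noiseless tdTomato channel at its generative cutoff
    bg_f <- 0.1
    amp_f <- 1
    tdt_clean <- bg_f * brain_arr + amp_f * density
    tdt_threshold <- bg_f + amp_f * spec$density_cutoff
    truth_arr <- tdt_clean >= tdt_threshold

    noise <- function(sd) {
      if (sd <= 0) array(0, g$shape) else array(stats::rnorm(prod(g$shape), 0, sd), g$shape)
    }
    sd_of <- function(ch) {
      if (ch %in% names(spec$noise_sd)) as.numeric(spec$noise_sd[[ch]]) else 0
    }

    tdtomato <- scalar_volume(tdt_clean + noise(sd_of("tdtomato")), g)

    # T2: detects tumor down to a cellularity limit; t2_detect_fraction = 1
    # sees the whole truth, smaller fractions raise the visibility cutoff so
    # sparse infiltrative margins go undetected
    t2_cutoff <- spec$density_cutoff +
      (1 - spec$t2_detect_fraction) * (1 - spec$density_cutoff)
    t2_region <- truth_arr & density >= t2_cutoff
    bg_mr <- 0.2
    t2 <- scalar_volume(bg_mr * brain_arr + 1 * t2_region + noise(sd_of("t2")), g)

    # T1: enhancing core only in Gd+ cases
    core_arr <- array(dist_core <= spec$core_radius_mm, g$shape)
    t1_signal <- if (spec$gd_status) 1 * core_arr else 0 * core_arr
    t1 <- scalar_volume(bg_mr * brain_arr + t1_signal + noise(sd_of("t1")), g)
    mr_threshold <- bg_mr + 0.5

    # PET: background activity in brain plus contrast x density, blurred by
    # the PSF (partial-volume overshoot), noise added, then block-averaged
    # onto the PET lattice
    bg_pet <- 1
    contrast <- bg_pet * (spec$pet_tumor_to_background - 1)
    activity <- bg_pet * brain_arr + contrast * density
    sigma <- rep(spec$pet_psf_fwhm_mm / 2.355, 3)
    blurred <- gaussian_blur_mm(activity, sigma, g$spacing)
    pet_fine <- scalar_volume(blurred + noise(sd_of("pet")), g)
    pet <- resample_to_spacing(pet_fine, spec$pet_spacing)
    pet_threshold <- if (contrast > 0) {
      bg_pet + spec$density_cutoff * contrast
    } else {
      # invisible tumor: the operator segments nothing
      bg_pet * (1 + spec$density_cutoff)
    }

    # fluorescence correlates: linear in cell density + noise
    asct2 <- scalar_volume(0.3 * brain_arr + 0.8 * density + noise(sd_of("asct2")), g)
    lectin <- if (spec$has_lectin) {
      scalar_volume(0.5 * brain_arr + 0.5 * density + noise(sd_of("lectin")), g)
    } else {
      NULL
    }

    # contralateral normal brain: mirrored hemisphere, clear of the tumor and
    # eroded 1.2 mm from the brain surface so coarse-grid (PET) samples of
    # the region are not diluted by partial-volume averaging with background
    opposite <- centers[, 1] < brain_center[1] - spec$core_radius_mm / 2
    depth2 <- edt_squared_mm2(!brain_v, g$shape, g$spacing) # dist to non-brain
    interior <- depth2 > 1.2^2
    contra_arr <- array(brain_v & opposite & interior, g$shape) & !truth_arr
    truth <- binary_mask(truth_arr, g)
    brain <- binary_mask(brain_arr, g)
    pet_visible <- contrast > 0
    structure(
      list(
        case_id = case_id,
        gd_status = spec$gd_status,
        stratum = if (spec$gd_status) {
          "Gd+"
        } else if (pet_visible) "Gd- PET-visible" else "Gd- PET-invisible",
        spec = spec,
        geometry = g,
        volumes = list(
          t1 = t1, t2 = t2, pet = pet, tdtomato = tdtomato,
          asct2 = asct2, lectin = lectin
        ),
        masks = list(truth = truth, brain = brain,
                     contralateral = binary_mask(contra_arr, g)),
        thresholds = c(
          t1 = mr_threshold, t2 = mr_threshold,
          pet = pet_threshold, tdtomato = tdt_threshold
        )
      ),
      class = "tumor_case"
    )
  })
}

#' Segment the standard modalities of a case
#'
#' Applies [threshold_segment()] with the case's per-modality thresholds:
#' T1 and T2 on the fine grid, PET on the PET grid.
#'
#' @param case a `tumor_case`.
#' @return named list of [binary_mask()]: `t1`, `t2`, `pet`.
#' @export
segment_case <- function(case) {
  list(
    t1 = threshold_segment(case$volumes$t1, case$thresholds[["t1"]]),
    t2 = threshold_segment(case$volumes$t2, case$thresholds[["t2"]]),
    pet = threshold_segment(case$volumes$pet, case$thresholds[["pet"]])
  )
}

#' Generate a stratified synthetic cohort
#'
#' Mirrors the study composition: `n_gd_pos` gadolinium-enhancing cases
#' (T1-visible core, full PET contrast), `n_gd_neg_pet_pos` non-enhancing
#' but PET-visible cases (no T1 enhancement, reduced PET contrast) and
#' `n_gd_neg_pet_neg` non-enhancing PET-invisible cases (PET contrast 1:1).
#' Per-case geometry (core radius, infiltration width, T2 detected fraction)
#' is jittered around the base spec; per-case seeds derive reproducibly from
#' `master_seed`.
#'
#' @param n_gd_pos,n_gd_neg_pet_pos,n_gd_neg_pet_neg stratum sizes (the
#'   study's composition is 4 / 5 / 4).
#' @param base_spec template [phantom_spec()].
#' @param master_seed integer seed for the whole cohort.
#' @return list of `tumor_case` objects.
#' @export
generate_cohort <- function(n_gd_pos = 4, n_gd_neg_pet_pos = 5, n_gd_neg_pet_neg = 4,
                            base_spec = phantom_spec(), master_seed = 1L) {
  strata <- c(
    rep("Gd+", n_gd_pos),
    rep("Gd- PET-visible", n_gd_neg_pet_pos),
    rep("Gd- PET-invisible", n_gd_neg_pet_neg)
  )
  n <- length(strata)
  if (n == 0) {
    return(list())
  }
  params <- with_seed(master_seed, {
    list(
      seeds = sample.int(2^31 - 2, n),
      radius_scale = stats::runif(n, 0.75, 1.25),
      infil_scale = stats::runif(n, 0.7, 1.3),
      t2_fraction = stats::runif(n, 0.6, 0.95),
      pet_ratio_pos = stats::runif(n, 2.5, 3.5),
      pet_ratio_mid = stats::runif(n, 1.8, 2.4)
    )
  })
  lapply(seq_len(n), function(i) {
    stratum <- strata[i]
    spec <- base_spec
    spec$seed <- as.integer(params$seeds[i])
    spec$core_radius_mm <- base_spec$core_radius_mm * params$radius_scale[i]
    spec$infiltration_width_mm <- base_spec$infiltration_width_mm * params$infil_scale[i]
    spec$t2_detect_fraction <- params$t2_fraction[i]
    spec$gd_status <- stratum == "Gd+"
    spec$pet_tumor_to_background <- switch(stratum,
      "Gd+" = params$pet_ratio_pos[i],
      "Gd- PET-visible" = params$pet_ratio_mid[i],
      "Gd- PET-invisible" = 1
    )
    class(spec) <- "phantom_spec"
    generate_phantom(spec, case_id = sprintf("SYN%02d", i))
  })
}

#' Score a cohort of synthetic cases
#'
#' Segments every case at its per-modality thresholds and evaluates all
#' modalities against the tdTomato truth ([evaluate_case()]), binding the
#' per-tumor rows into one long score table.
#'
#' @param cases list of `tumor_case` objects.
#' @param expand_radius_mm expansion radius for the expanded-MRI row.
#' @return data.frame of per-tumor, per-modality detection scores.
#' @export
score_cohort <- function(cases, expand_radius_mm = 2) {
  rows <- lapply(cases, function(case) {
    evaluate_case(
      segment_case(case),
      truth = case$masks$truth, brain = case$masks$brain,
      case_id = case$case_id, gd_status = case$gd_status,
      expand_radius_mm = expand_radius_mm
    )
  })
  do.call(rbind, rows)
}

#' Write a cohort to disk as NIfTI volumes plus a manifest
#'
#' One directory per case containing the channel volumes and masks; a
#' top-level `manifest.tsv` records ids, strata, thresholds and file paths.
#'
#' @param cases list of `tumor_case` objects.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cases, function(case) {
    cdir <- file.path(dir, case$case_id)
    dir.create(cdir, showWarnings = FALSE)
    for (ch in names(case$volumes)) {
      if (!is.null(case$volumes[[ch]])) {
        write_volume(case$volumes[[ch]], file.path(cdir, paste0(ch, ".nii.gz")))
      }
    }
    for (mk in names(case$masks)) {
      write_mask(case$masks[[mk]], file.path(cdir, paste0(mk, "_mask.nii.gz")))
    }
    data.frame(
      case_id = case$case_id, stratum = case$stratum,
      gd_status = case$gd_status,
      threshold_t1 = case$thresholds[["t1"]],
      threshold_t2 = case$thresholds[["t2"]],
      threshold_pet = case$thresholds[["pet"]],
      path = cdir, stringsAsFactors = FALSE
    )
  })
  manifest <- do.call(rbind, rows)
  write_tsv_table(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Synthetic table-level correlate cohorts
#'
#' Draws tumor-level correlate tables directly from the generative
#' log-linear model used to reason about the regression: standardized
#' log-regressors (tdTomato, ASCT2, lectin, volume) and a binary gadolinium
#' status, with the log PET uptake a linear combination plus Gaussian noise.
#' Used for coefficient-recovery simulations where full 3D phantoms would
#' be wasteful.
#'
#' @param n tumors per cohort (study size 13).
#' @param effects named standardized effect sizes on log PET uptake;
#'   tdTomato dominant by default, matching the biology the pipeline is
#'   meant to detect.
#' @param noise_sd residual sd of the log response.
#' @param seed integer seed.
#' @return data.frame shaped like [build_tumor_table()] output (positive
#'   ratios, ready for [log_standardize()]).
#' @export
generate_correlate_cohort <- function(n = 13,
                                      effects = c(
                                        tdtomato = 1.0, asct2 = 0.3,
                                        lectin = 0.2, tumor_volume = 0.25,
                                        gd_status = 0.35
                                      ),
                                      noise_sd = 0.5,
                                      seed = 1L) {
  with_seed(seed, {
    z <- function() stats::rnorm(n)
    log_tdt <- z()
    log_asct2 <- 0.5 * log_tdt + sqrt(1 - 0.25) * z() # transporters track density
    log_lectin <- z()
    log_vol <- z()
    n_pos <- max(1L, round(n * 4 / 13)) # the study's Gd+ share
    gd <- sample(c(rep(1, n_pos), rep(0, n - n_pos)))
    # effects act on the z-scored regressors — the scale the model reports
    zs <- function(x) (x - mean(x)) / stats::sd(x)
    log_pet <- effects[["tdtomato"]] * zs(log_tdt) +
      effects[["asct2"]] * zs(log_asct2) +
      effects[["lectin"]] * zs(log_lectin) +
      effects[["tumor_volume"]] * zs(log_vol) +
      effects[["gd_status"]] * zs(gd) +
      stats::rnorm(n, 0, noise_sd)
    data.frame(
      case_id = sprintf("SIM%02d", seq_len(n)),
      pet_uptake = exp(log_pet),
      tdtomato = exp(log_tdt),
      asct2 = exp(log_asct2),
      lectin = exp(log_lectin),
      tumor_volume = 60 * exp(log_vol),
      gd_status = gd,
      stringsAsFactors = FALSE
    )
  })
}
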