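test_that("contralateral normalization is a plain positive ratio", {
  expect_equal(normalize_to_contralateral(2, 1), 2)
  expect_equal(normalize_to_contralateral(1.7, 1.7), 1)
  expect_error(normalize_to_contralateral(1, 0), "> 0")
  expect_error(normalize_to_contralateral(1, -2), "> 0")
})

test_that("a noiseless high-contrast phantom yields its generative uptake ratio", {
  spec <- phantom_spec(
    noise_sd = c(t1 = 0, t2 = 0, pet = 0, tdtomato = 0, asct2 = 0, lectin = 0),
    pet_psf_fwhm_mm = 0, pet_tumor_to_background = 3, seed = 8L
  )
  case <- generate_phantom(spec, "ratio")
  tab <- build_tumor_table(list(case))
  expect_equal(tab$pet_uptake, 3, tolerance = 1e-9)
  expect_equal(tab$tumor_volume, mask_volume_mm3(case$masks$truth))
  expect_equal(tab$gd_status, 1)
})

test_that("tumor table marks missing lectin as absent and max-PET dominates mean-PET", {
  spec <- phantom_spec(has_lectin = FALSE, seed = 12L)
  case <- generate_phantom(spec, "nolectin")
  tab <- build_tumor_table(list(case))
  expect_true(is.na(tab$lectin))

  cases <- test_cohort()[1:3]
  tab3 <- build_tumor_table(cases)
  for (i in seq_along(cases)) {
    pet <- cases[[i]]$volumes$pet
    t_mask <- tumorburden:::mask_on_grid(cases[[i]]$masks$truth, pet$geometry)
    c_mask <- tumorburden:::mask_on_grid(cases[[i]]$masks$contralateral, pet$geometry)
    mean_ratio <- mean(pet$values[t_mask$values]) / mean(pet$values[c_mask$values])
    expect_gte(tab3$pet_uptake[i], mean_ratio)
  }
})

test_that("voxel table has one record per tumor voxel on the PET grid", {
  case <- test_cohort()[[1]]
  vox <- build_voxel_table(case)
  truth_pet <- tumorburden:::mask_on_grid(
    case$masks$truth, case$volumes$pet$geometry
  )
  expect_equal(nrow(vox), sum(truth_pet$values))
  expect_true(all(c("pet_uptake", "tdtomato", "asct2", "lectin", "gd_status") %in% names(vox)))
})

test_that("voxel-level PET tracks tdTomato in a noiseless sharp phantom", {
  spec <- phantom_spec(
    noise_sd = c(t1 = 0, t2 = 0, pet = 0, tdtomato = 0, asct2 = 0, lectin = 0),
    pet_psf_fwhm_mm = 0, seed = 14L
  )
  case <- generate_phantom(spec, "corr")
  vox <- build_voxel_table(case)
  # both channels are affine in cell density, so the correlation is ~1
  expect_gte(stats::cor(vox$pet_uptake, vox$tdtomato), 0.99)
})

test_that("log-standardization gives exact z-scores and rejects bad columns", {
  tab <- data.frame(
    pet_uptake = c(exp(1), exp(3)), tdtomato = c(2, 4), asct2 = c(1, 2),
    lectin = c(1, 3), tumor_volume = c(10, 20), gd_status = c(0, 1)
  )
  z <- log_standardize(tab)
  expect_equal(z$pet_uptake, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  for (col in c("pet_uptake", "tdtomato", "asct2", "lectin", "tumor_volume", "gd_status")) {
    expect_lt(abs(mean(z[[col]])), 1e-12)
    expect_equal(stats::sd(z[[col]]), 1, tolerance = 1e-12)
  }
  expect_error(
    log_standardize(transform(tab, tdtomato = c(3, 3))),
    "constant column"
  )
  expect_error(
    log_standardize(transform(tab, asct2 = c(-1, 2))),
    "positive"
  )
})

test_that("an exact linear response is recovered with R^2 = 1", {
  set.seed(101)
  n <- 30
  tab <- data.frame(
    tdtomato = exp(rnorm(n)), asct2 = exp(rnorm(n)), lectin = exp(rnorm(n)),
    tumor_volume = exp(rnorm(n, 3)), gd_status = rbinom(n, 1, 0.4)
  )
  lt <- log(tab$tdtomato)
  tab$pet_uptake <- exp(1.2 * scale(lt)[, 1] - 0.4 * scale(log(tab$asct2))[, 1])
  z <- log_standardize(tab, standardize_response = FALSE)
  # lm warns that a zero-residual fit makes its own summary unreliable;
  # the exactness is the point here
  suppressWarnings(fit <- fit_multivariate(z))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "tdtomato"], 1.2, tolerance = 1e-9)
  expect_equal(est$estimate[est$term == "asct2"], -0.4, tolerance = 1e-9)
  expect_equal(est$estimate[est$term == "lectin"], 0, tolerance = 1e-9)
  expect_lt(abs(sum(fit$residuals)), 1e-9)
})

test_that("a pure-noise response yields near-null coefficients and the chi-square R^2 level", {
  set.seed(102)
  n <- 200
  tab <- data.frame(
    pet_uptake = exp(rnorm(n)), tdtomato = exp(rnorm(n)), asct2 = exp(rnorm(n)),
    lectin = exp(rnorm(n)), tumor_volume = exp(rnorm(n)), gd_status = rbinom(n, 1, 0.3)
  )
  fit <- fit_multivariate(log_standardize(tab))
  k <- length(fit$regressors)
  expect_lt(fit$r_squared, 3 * k / (n - 1)) # null expectation ~ k / (n - 1)
  ests <- fit$coefficients$estimate[fit$coefficients$term != "(Intercept)"]
  expect_true(all(abs(ests) < 0.25))
})

test_that("collinear designs are rejected naming the offending column", {
  set.seed(103)
  n <- 15
  tab <- data.frame(
    pet_uptake = exp(rnorm(n)), tdtomato = exp(rnorm(n)),
    asct2 = exp(rnorm(n)), tumor_volume = exp(rnorm(n)), gd_status = rbinom(n, 1, 0.4)
  )
  tab$lectin <- tab$tdtomato^2 # log-collinear with tdtomato
  z <- log_standardize(tab)
  expect_error(fit_multivariate(z), "collinear")
})

test_that("missing lectin selects complete cases or the lectin-free model on all cases", {
  tab <- generate_correlate_cohort(n = 13, seed = 21L)
  tab$lectin[c(2, 7)] <- NA
  z_free <- log_standardize(tab[setdiff(names(tab), "lectin")])
  full <- fit_multivariate(log_standardize(tab[!is.na(tab$lectin), ]))
  reduced <- fit_multivariate(z_free, use_lectin = FALSE)
  expect_equal(full$n, 11)
  expect_equal(reduced$n, 13)
  expect_false("lectin" %in% reduced$coefficients$term)
})

test_that("partial-regression slopes equal the multivariate coefficients (FWL)", {
  for (seed in c(111, 112, 113)) {
    tab <- log_standardize(generate_correlate_cohort(n = 20, seed = seed))
    fit <- fit_multivariate(tab)
    for (reg in fit$regressors) {
      pr <- partial_regression(tab, reg)
      expect_equal(
        pr$slope,
        fit$coefficients$estimate[fit$coefficients$term == reg],
        tolerance = 1e-10
      )
      # added-variable line passes through the origin
      expect_lt(abs(mean(pr$y_residuals)), 1e-10)
      expect_lt(abs(mean(pr$x_residuals)), 1e-10)
    }
  }
})

test_that("a single-regressor partial regression degenerates to simple regression", {
  set.seed(104)
  tab <- data.frame(pet_uptake = exp(rnorm(12)), tdtomato = exp(rnorm(12)))
  z <- log_standardize(tab)
  pr <- partial_regression(z, "tdtomato")
  simple <- stats::lm(pet_uptake ~ tdtomato, data = z)
  expect_equal(pr$slope, unname(stats::coef(simple)["tdtomato"]), tolerance = 1e-12)
})

test_that("standardized coefficients are recovered without bias over repeated cohorts", {
  effects <- c(
    tdtomato = 1.0, asct2 = 0.3, lectin = 0.2,
    tumor_volume = 0.25, gd_status = 0.35
  )
  n_rep <- 200
  ests <- matrix(NA_real_, n_rep, length(effects),
    dimnames = list(NULL, names(effects))
  )
  dominant <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    tab <- generate_correlate_cohort(n = 13, effects = effects, seed = 3000 + r)
    fit <- fit_multivariate(log_standardize(tab, standardize_response = FALSE))
    co <- fit$coefficients
    slopes <- co$estimate[match(names(effects), co$term)]
    ests[r, ] <- slopes
    dominant[r] <- names(effects)[which.max(abs(slopes))] == "tdtomato"
  }
  bias <- colMeans(ests) - effects
  mc_se <- apply(ests, 2, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(bias) < 4 * mc_se + 1e-3))
  expect_gt(mean(dominant), 0.9)
})
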