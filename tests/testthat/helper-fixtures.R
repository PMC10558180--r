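# Shared generated fixtures, memoized across test files.

.tb_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .tb_cache)) assign(key, force(expr), envir = .tb_cache)
  get(key, envir = .tb_cache)
}

test_cohort <- function() {
  memo("cohort", generate_cohort(4, 5, 4, master_seed = 42L))
}

test_scores <- function() {
  memo("scores", score_cohort(test_cohort()))
}

# small but structured random mask: thresholded smoothed noise
random_blob_mask <- function(geometry, fill = 0.35) {
  v <- array(stats::runif(prod(geometry$shape)), geometry$shape)
  k <- c(0.25, 0.5, 0.25)
  smooth1 <- function(a, ax) {
    lo <- tumorburden:::shift_axis(a, ax, 1L)
    hi <- tumorburden:::shift_axis(a, ax, -1L)
    k[1] * lo + k[2] * a + k[3] * hi
  }
  for (ax in seq_along(geometry$shape)) v <- smooth1(v, ax)
  binary_mask(v >= stats::quantile(v, 1 - fill), geometry)
}

random_geometry <- function(max_side = 20L) {
  shape <- sample(4:max_side, 3, replace = TRUE)
  spacing <- sample(c(0.2, 0.25, 0.5, 1), 3, replace = TRUE)
  grid_geometry(shape, spacing)
}
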