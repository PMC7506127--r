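# Shared fixtures and independent brute-force oracles.

# brute-force anisotropic distance from every voxel to the nearest
# feature voxel (exhaustive nearest-neighbour search)
bf_distance_to <- function(feature, grid) {
  idx <- which(feature, arr.ind = TRUE)
  pts <- t(t(idx - 1) * grid$spacing_mm)
  out <- array(NA_real_, grid$shape)
  for (i in seq_len(grid$shape[1]))
    for (j in seq_len(grid$shape[2]))
      for (k in seq_len(grid$shape[3])) {
        p <- (c(i, j, k) - 1) * grid$spacing_mm
        out[i, j, k] <- sqrt(min(colSums((t(pts) - p)^2)))
      }
  out
}

# random small dose/mask pair on an anisotropic grid
random_dose_mask <- function(max_dim = 12, max_dose = 80) {
  shape <- sample(3:max_dim, 3, replace = TRUE)
  spacing <- sample(c(0.5, 1, 2, 3), 3, replace = TRUE)
  g <- voxel_grid(shape, spacing_mm = spacing)
  vox <- array(stats::runif(prod(shape)) < 0.4, dim = shape)
  if (!any(vox)) vox[1, 1, 1] <- TRUE
  list(grid = g,
       dose = dose_grid(array(stats::runif(prod(shape), 0, max_dose),
                              dim = shape), g),
       mask = structure_mask("m", vox, g))
}

# cached default phantom (geometry + derived regions + one noisy base
# dose); built once per test run
fixture_env <- new.env(parent = emptyenv())

fixture_phantom <- function() {
  if (is.null(fixture_env$phantom)) {
    st <- derive_regions(build_phantom(phantom_spec()))
    fixture_env$phantom <- list(
      structs = st,
      dose = simulate_base_dose(st, seed = 7))
  }
  fixture_env$phantom
}

# cached 10-patient synthetic cohort with metrics and PQM scores (the
# cohort-scale study conditions)
fixture_cohort <- function() {
  if (is.null(fixture_env$cohort)) {
    cohort <- generate_cohort(10, master_seed = 42)
    metrics <- cohort_metrics(cohort)
    scores <- cohort_scores(metrics)
    fixture_env$cohort <- list(cohort = cohort, metrics = metrics,
                               scores = scores)
  }
  fixture_env$cohort
}

# exact two-sided p-value of the signed-rank statistic by enumerating
# all 2^n sign assignments (tie-free data)
exact_signed_rank_p <- function(a, b) {
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
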