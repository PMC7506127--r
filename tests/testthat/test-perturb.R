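test_that("a zero-amplitude perturbation is the identity map", {
  fx <- fixture_phantom()
  for (cond in c("B15_RECAL", "B15_REOPT")) {
    out <- apply_field_perturbation(fx$dose, fx$structs,
                                    perturbation_params(), cond, seed = 3)
    expect_identical(out$values, fx$dose$values)
  }
  b0 <- apply_field_perturbation(
    fx$dose, fx$structs, default_perturbation_params("B15_RECAL"), "B0")
  expect_identical(b0$values, fx$dose$values)  # B0 ignores amplitudes
  expect_error(apply_field_perturbation(fx$dose, fx$structs,
                                        perturbation_params(), "B3"),
               "arg")
})

test_that("a full-ring skin boost adds exactly its depth-decayed mean", {
  # small spherical body: expected increase computed by brute-force
  # nearest-neighbour distances, independent of the package's EDT
  g <- voxel_grid(c(40, 40, 40), spacing_mm = c(1, 1, 1))
  ctr <- c(19.5, 19.5, 19.5)
  x <- (seq_len(40) - 1)
  bd <- outer(x, x, function(a, b) (a - ctr[1])^2 + (b - ctr[2])^2)
  body_vox <- array(outer(as.vector(bd), (x - ctr[3])^2, "+") <= 15^2,
                    dim = g$shape)
  body <- structure_mask("body", body_vox, g)
  st <- structure_set(g, list(body))
  dose <- dose_grid(array(10 * body_vox, g$shape), g)

  pars <- perturbation_params(skin_boost_amplitude_Gy = 2,
                              skin_decay_length_mm = 5,
                              skin_sector_width_deg = 40)
  out <- apply_field_perturbation(dose, st, pars, "B15_REOPT",
                                  cavities = character(0))
  shell <- skin_shell(body, 1)$voxels
  d_bf <- bf_distance_to(!body_vox, g)
  expected <- 2 * mean(exp(-d_bf[shell] / 5))
  got <- mean(out$values[shell]) - mean(dose$values[shell])
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("the exit-sector mask covers the configured circumference", {
  fx <- fixture_phantom()
  st <- fx$structs
  shell <- get_structure(st, "skin")$voxels
  base <- fx$dose
  half <- apply_field_perturbation(
    base, st, perturbation_params(skin_boost_amplitude_Gy = 2,
                                  skin_sector_width_deg = 20),
    "B15_RECAL", cavities = character(0))
  boosted <- sum(half$values[shell] > base$values[shell])
  expect_equal(boosted / sum(shell), 0.5, tolerance = 0.05)
})

test_that("the antisymmetric cavity shift nearly cancels over the shell", {
  fx <- fixture_phantom()
  st <- fx$structs
  B <- 2
  pars <- perturbation_params(cavity_shift_amplitude_Gy = B)
  out <- apply_field_perturbation(fx$dose, st, pars, "B15_REOPT")
  for (nm in c("interface_larynx_trachea", "interface_pharynx")) {
    shell <- get_structure(st, nm)$voxels
    delta <- out$values[shell] - fx$dose$values[shell]
    # both-sided mean cancels; single sides shift by about +-B
    expect_lt(abs(mean(delta)), 0.05 * B)
    expect_true(all(round(delta, 9) %in% c(-B, 0, B)))
    expect_equal(mean(delta[delta > 0]), B)
    expect_equal(mean(delta[delta < 0]), -B)
  }
})

test_that("coverage degradation scales target dose down", {
  fx <- fixture_phantom()
  st <- fx$structs
  pars <- perturbation_params(coverage_degradation = 0.03)
  out <- apply_field_perturbation(fx$dose, st, pars, "B15_RECAL")
  ptv <- get_structure(st, "ptv")$voxels
  ratio <- out$values[ptv] / fx$dose$values[ptv]
  expect_true(all(abs(ratio - 0.97) < 1e-9))
  # far from the PTV the dose is untouched
  nt <- get_structure(st, "nt")$voxels
  far <- nt & distance_to_mask(get_structure(st, "ptv")) > 30
  expect_true(all(abs(out$values[far] / pmax(fx$dose$values[far], 1e-12)
                      - 1) < 0.001))
})
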