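test_that("homogeneity index arithmetic and scale invariance", {
  expect_equal(homogeneity_index(10, 10, 10), 0)
  expect_equal(homogeneity_index(72, 66, 70), 6 / 70)
  for (c_scale in c(0.5, 2, 17.3)) {
    expect_equal(homogeneity_index(72 * c_scale, 66 * c_scale, 70 * c_scale),
                 6 / 70, tolerance = 1e-12)
  }
  expect_error(homogeneity_index(72, 66, 0), "d50")
  expect_error(homogeneity_index(60, 66, 70), "d2")
})

test_that("conformity index reproduces voxel-counted worked cases", {
  # toy grid engineered to V_PTV = 100, TV = 150, TV_PTV = 90
  g <- voxel_grid(c(20, 20, 1), spacing_mm = c(1, 1, 1))
  body <- structure_mask("body", array(TRUE, g$shape), g)
  tv_vox <- array(FALSE, g$shape)
  tv_vox[1:10, 1:10, 1] <- TRUE                 # target: 100 voxels
  target <- structure_mask("t", tv_vox, g)
  dosev <- array(0, g$shape)
  dosev[1:9, 1:10, 1] <- 50                     # 90 hot target voxels
  dosev[11:16, 1:10, 1] <- 50                   # 60 hot outside voxels
  dose <- dose_grid(dosev, g)
  expect_equal(as.numeric(conformity_index(target, dose, 50, body)),
               90^2 / (100 * 150))

  # perfect conformity and complete miss
  perfect <- dose_grid(array(0, g$shape) + 50 * tv_vox, g)
  expect_equal(as.numeric(conformity_index(target, perfect, 50, body)), 1)
  miss <- dose_grid(array(0, g$shape) + 50 * (!tv_vox), g)
  expect_equal(as.numeric(conformity_index(target, miss, 50, body)), 0)
  cold <- dose_grid(array(1, g$shape), g)
  ci0 <- conformity_index(target, cold, 50, body)
  expect_equal(as.numeric(ci0), 0)
  expect_true(isTRUE(attr(ci0, "degenerate")))
})

test_that("conformity index stays in [0, 1] under random fuzzing", {
  set.seed(404)
  for (case in 1:50) {
    f <- random_dose_mask()
    body <- structure_mask("body", array(TRUE, f$grid$shape), f$grid)
    ci <- as.numeric(conformity_index(f$mask, f$dose,
                                      stats::runif(1, 1, 90), body))
    expect_gte(ci, 0)
    expect_lte(ci, 1)
  }
})

test_that("plan metric extraction is pure and complete", {
  fx <- fixture_phantom()
  m1 <- extract_plan_metrics(fx$dose, fx$structs)
  m2 <- extract_plan_metrics(fx$dose, fx$structs)
  expect_identical(m1, m2)
  expect_length(unclass(m1), 21)
  vals <- unlist(m1)
  expect_true(all(is.finite(vals)))
  # percentages, index ranges, max >= mean
  for (nm in grep("v_presc$", names(m1), value = TRUE)) {
    expect_gte(m1[[nm]], 0); expect_lte(m1[[nm]], 100)
  }
  for (nm in grep("_ci$", names(m1), value = TRUE)) {
    expect_gte(m1[[nm]], 0); expect_lte(m1[[nm]], 1)
  }
  for (nm in grep("_hi$", names(m1), value = TRUE)) expect_gte(m1[[nm]], 0)
  expect_gte(m1$skin_dmax, m1$skin_dmean)
  expect_gte(m1$interface_larynx_trachea_dmax,
             m1$interface_larynx_trachea_dmean)

  incomplete <- structure_set(fx$structs$grid,
                              fx$structs$masks[c("body", "ptv")])
  expect_error(extract_plan_metrics(fx$dose, incomplete), "lacks")
})

test_that("uniform prescription dose gives full coverage and HI ~ 0", {
  fx <- fixture_phantom()
  uni <- dose_grid(array(60.06, fx$structs$grid$shape), fx$structs$grid)
  m <- extract_plan_metrics(uni, fx$structs)
  expect_equal(m$ptv_v_presc, 100)
  expect_lt(m$ptv_hi, 2e-3)   # bin-resolution residual only
  expect_equal(m$pgtvtb_v_presc, 0)  # 60.06 < 69.96 everywhere
})
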