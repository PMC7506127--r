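make_sphere <- function(g, center_mm, r_mm) {
  x <- (seq_len(g$shape[1]) - 1) * g$spacing_mm[1]
  y <- (seq_len(g$shape[2]) - 1) * g$spacing_mm[2]
  z <- (seq_len(g$shape[3]) - 1) * g$spacing_mm[3]
  m <- outer((x - center_mm[1])^2, (y - center_mm[2])^2, "+")
  array(outer(as.vector(m), (z - center_mm[3])^2, "+") <= r_mm^2,
        dim = g$shape)
}

test_that("skin shell is the digital boundary layer of a sphere", {
  g <- voxel_grid(c(46, 46, 46), spacing_mm = c(1, 1, 1))
  body <- structure_mask("body", make_sphere(g, c(22, 22, 22), 20), g)
  shell <- skin_shell(body, 1)
  expect_true(all(shell$voxels[!body$voxels] == FALSE))  # subset of body
  # on an isotropic 1-mm grid the 1-mm shell is exactly the layer of
  # voxels with a face neighbour outside; for a digitised ball that
  # layer counts about 0.80 x the smooth surface area x thickness (the
  # staircase surface exposes fewer face-boundary voxel centres than
  # the smooth area suggests) -- value frozen from the exhaustive
  # nearest-neighbour oracle
  expect_equal(sum(shell$voxels), 4026)
  analytic <- 4 * pi * 20^2 * 1
  expect_gt(sum(shell$voxels) / analytic, 0.75)
  expect_lt(sum(shell$voxels) / analytic, 0.95)
  # saturation: a huge thickness returns the whole body
  expect_equal(skin_shell(body, 1e6)$voxels, body$voxels)
  expect_error(skin_shell(body, 0), "> 0")
})

test_that("cavity interface shell matches the analytic cylinder side wall", {
  g <- voxel_grid(c(40, 40, 12), spacing_mm = c(1, 1, 3))
  body <- structure_mask("body", array(TRUE, g$shape), g)
  x <- (seq_len(40) - 1)
  circ <- outer((x - 19.5)^2, (x - 19.5)^2, "+") <= 8^2
  cav_vox <- array(circ, dim = g$shape)
  cav <- structure_mask("cav", cav_vox, g)
  shell <- cavity_interface_shell(cav, body, 1)
  expect_false(any(shell$voxels & cav$voxels))  # disjoint from cavity
  L <- 12 * 3
  analytic <- 2 * pi * 8 * L * 1 / 3   # side wall, 3-mm slices
  expect_lt(abs(sum(shell$voxels) - analytic) / analytic, 0.15)

  # empty cavity gives an empty shell; escape from the body is an error
  empty <- structure_mask("e", array(FALSE, g$shape), g)
  expect_equal(sum(cavity_interface_shell(empty, body, 1)$voxels), 0)
  small_body <- structure_mask("body", make_sphere(g, c(20, 20, 15), 5), g)
  expect_error(cavity_interface_shell(cav, small_body, 1), "contained")
})

test_that("union of touching cavities never double-counts shell voxels", {
  g <- voxel_grid(c(24, 24, 6), spacing_mm = c(1, 1, 1))
  body <- structure_mask("body", array(TRUE, g$shape), g)
  a <- array(FALSE, g$shape); a[8:11, 10:13, 2:5] <- TRUE
  b <- array(FALSE, g$shape); b[12:15, 10:13, 2:5] <- TRUE
  both <- structure_mask("ab", a | b, g)
  shell <- cavity_interface_shell(both, body, 1)
  expect_true(all(shell$voxels %in% c(TRUE, FALSE)))
  expect_false(any(shell$voxels & both$voxels))
  # the union shell is exactly the set-union semantics of the two shells
  # minus the opposite cavity interiors
  sa <- cavity_interface_shell(structure_mask("a", a, g), body, 1)$voxels
  sb <- cavity_interface_shell(structure_mask("b", b, g), body, 1)$voxels
  expect_equal(shell$voxels, (sa | sb) & !(a | b))
})

test_that("margin expansion reproduces the anisotropic ball", {
  g <- voxel_grid(c(11, 11, 7), spacing_mm = c(1, 1, 3))
  all_g <- structure_mask("clip", array(TRUE, g$shape), g)
  pt <- array(FALSE, g$shape); pt[6, 6, 4] <- TRUE
  ptm <- structure_mask("pt", pt, g)
  exp3 <- expand_margin(ptm, 3, all_g)
  # exhaustive enumeration: voxels within 3 mm of the centre voxel
  d <- bf_distance_to(pt, g)
  expect_equal(exp3$voxels, d <= 3)
  expect_equal(sum(exp3$voxels), sum(d <= 3))
  # margin 0 is the identity within the clip
  expect_equal(expand_margin(ptm, 0, all_g)$voxels, pt)
})

test_that("margins and shells are monotone in their parameter", {
  set.seed(77)
  f <- random_dose_mask()
  clip <- structure_mask("clip", array(TRUE, f$grid$shape), f$grid)
  for (pair in list(c(1, 2), c(2, 5), c(0, 3))) {
    small <- expand_margin(f$mask, pair[1], clip)$voxels
    big <- expand_margin(f$mask, pair[2], clip)$voxels
    expect_true(all(big[small]))
  }
  body <- structure_mask("body", array(TRUE, f$grid$shape), f$grid)
  s1 <- skin_shell(body, 1)$voxels
  s2 <- skin_shell(body, 3)$voxels
  expect_true(all(s2[s1]))
})

test_that("normal tissue partitions the body with the 10-mm PTV expansion", {
  g <- voxel_grid(c(40, 40, 14), spacing_mm = c(1, 1, 3))
  body <- structure_mask("body", make_sphere(g, c(19.5, 19.5, 19.5), 18), g)
  ptv <- structure_mask("ptv", make_sphere(g, c(19.5, 19.5, 19.5), 6), g)
  nt <- normal_tissue(body, ptv, 10)
  expanded <- expand_margin(ptv, 10, body)
  expect_false(any(nt$voxels & expanded$voxels))       # disjoint (<= vs >)
  expect_equal(nt$voxels | expanded$voxels, body$voxels)  # exact partition

  # limits: ptv = body empties NT; margin 0 gives body \ ptv
  expect_equal(sum(normal_tissue(body, body, 10)$voxels), 0)
  expect_equal(normal_tissue(body, ptv, 0)$voxels,
               body$voxels & !ptv$voxels)
  expect_error(normal_tissue(body, structure_mask(
    "p", array(FALSE, g$shape), g)), "empty")
})

test_that("derived phantom regions respect containment", {
  fx <- fixture_phantom()
  st <- fx$structs
  body <- get_structure(st, "body")$voxels
  skin <- get_structure(st, "skin")$voxels
  air <- get_structure(st, "air_larynx_trachea")$voxels |
    get_structure(st, "air_pharynx")$voxels
  expect_false(any(skin & air))
  expect_true(all(body[skin]))
  nt <- get_structure(st, "nt")$voxels
  exp10 <- expand_margin(get_structure(st, "ptv"), 10,
                         get_structure(st, "body"))$voxels
  expect_equal(nt | exp10, body)
  expect_false(any(nt & exp10))
})
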