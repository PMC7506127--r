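# run expr with a fixed seed, then restore the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Parameters of the phenomenological dose model
#'
#' The simulated plan dose is not a particle-transport calculation: it
#' is a sum of equiangular in-plane beams with build-up and exponential
#' depth attenuation, multiplied into a conformal target component and
#' an out-of-target background, then calibrated to the prescription
#' medians. Its fidelity target is the downstream metric structure
#' (DVHs, shells, scores), not physics.
#'
#' @param mu_mm effective linear attenuation (1/mm) of the depth-dose
#'   kernel.
#' @param buildup_mm build-up length (mm) of the kernel's entrance rise.
#' @param tau_ptv_mm exponential falloff length (mm) of the conformal
#'   dose outside the PTV.
#' @param boost_taper_mm width (mm) of the cosine taper carrying the
#'   high-dose boost from its PGTVtb/GTVnd plateau down to zero; the
#'   boost has compact support so the low-dose PTV plateau stays flat.
#' @param bg_fraction background (scatter-like) dose level as a fraction
#'   of the conformal component; suppressed smoothly inside the PTV.
#' @param mod_fraction amplitude of residual beam modulation inside the
#'   target.
#' @param ptv_headroom,boost_headroom calibration targets for the PTV
#'   and PGTVtb/GTVnd median doses, as multiples of the prescriptions
#'   (slightly above 1 so that coverage at the prescription stays high
#'   despite the stochastic dose noise).
#' @param noise_sigma_fraction relative sigma of the multiplicative
#'   Gaussian noise emulating the 1% Monte Carlo statistical
#'   uncertainty.
#' @return Named list of model parameters.
#' @export
dose_model_params <- function(mu_mm = 0.045,
                              buildup_mm = 3,
                              tau_ptv_mm = 6,
                              boost_taper_mm = 2.5,
                              bg_fraction = 0.18,
                              mod_fraction = 0.005,
                              ptv_headroom = 1.018,
                              boost_headroom = 1.016,
                              noise_sigma_fraction = 0.01) {
  as.list(environment())
}

#' Depth-dose kernel of one beam
#'
#' Build-up rise times exponential attenuation:
#' `k(t) = (1 - exp(-(t + 0.5) / buildup_mm)) * exp(-mu_mm * t)`.
#' Beyond the build-up peak the kernel is monotone non-increasing.
#'
#' @param t_mm depth below the entrance surface in mm (`>= 0`).
#' @param params a [dose_model_params()] list.
#' @return Kernel values (arbitrary units).
#' @export
depth_dose_kernel <- function(t_mm, params = dose_model_params()) {
  (1 - exp(-(t_mm + 0.5) / params$buildup_mm)) * exp(-params$mu_mm * t_mm)
}

# in-plane centre and effective radius of the (cylindrical) body mask,
# estimated from the mask itself
body_cylinder_fit <- function(body) {
  grid <- body$grid
  idx <- which(body$voxels, arr.ind = TRUE)
  x <- axis_coords(grid, 1)[idx[, 1]]
  y <- axis_coords(grid, 2)[idx[, 2]]
  ctr <- c(mean(x), mean(y))
  nz <- length(unique(idx[, 3]))
  area_mm2 <- nrow(idx) / nz * grid$spacing_mm[1] * grid$spacing_mm[2]
  list(center_mm = ctr, radius_mm = sqrt(area_mm2 / pi))
}

#' Summed attenuation field of equiangular in-plane beams
#'
#' For each body voxel, the sum over `n_beams` equally spaced gantry
#' angles of the depth-dose kernel evaluated at the voxel's depth below
#' the entrance surface along that beam (depth computed analytically
#' against the fitted body cylinder). Zero outside the body.
#'
#' @param body body [structure_mask()] (a cylinder-like region).
#' @param n_beams number of equiangular beams (default 9).
#' @param params a [dose_model_params()] list.
#' @return Numeric 3-D array.
#' @export
beam_fluence_field <- function(body, n_beams = 9,
                               params = dose_model_params()) {
  grid <- body$grid
  fit <- body_cylinder_fit(body)
  inb <- which(body$voxels)
  idx <- arrayInd(inb, grid$shape)
  px <- axis_coords(grid, 1)[idx[, 1]] - fit$center_mm[1]
  py <- axis_coords(grid, 2)[idx[, 2]] - fit$center_mm[2]
  r2 <- px^2 + py^2
  R2 <- fit$radius_mm^2
  f <- numeric(length(inb))
  angles <- (seq_len(n_beams) - 1) * 2 * pi / n_beams
  for (phi in angles) {
    # beam travels along u = -(cos phi, sin phi): entry at angle phi
    ux <- -cos(phi)
    uy <- -sin(phi)
    a <- px * ux + py * uy
    t <- a + sqrt(pmax(a^2 - r2 + R2, 0))
    f <- f + depth_dose_kernel(t, params)
  }
  out <- array(0, dim = grid$shape)
  out[inb] <- f
  out
}

#' Simulate the magnetic-field-free base plan dose
#'
#' Composes the 9-beam attenuation field with a conformal component
#' (uniform over the PTV, exponential falloff outside) and a high-dose
#' boost around PGTVtb/GTVnd, calibrates the two amplitudes so that the
#' PTV median dose sits at `ptv_headroom` times 60.06 Gy and the
#' PGTVtb/GTVnd median at `boost_headroom` times 69.96 Gy, and applies
#' multiplicative Gaussian noise emulating the Monte Carlo statistical
#' uncertainty. Dose is zero outside the body and non-negative
#' everywhere; with `noise_sigma_fraction = 0` the result is a
#' deterministic function of the structures.
#'
#' @param structs a [build_phantom()] structure set (needs `body`,
#'   `ptv`, `pgtvtb`, `gtvnd`).
#' @param prescriptions named list of [prescription()]s.
#' @param seed integer seed for the noise stream.
#' @param params a [dose_model_params()] list.
#' @param n_beams number of equiangular beams.
#' @return A [dose_grid()].
#' @export
simulate_base_dose <- function(structs,
                               prescriptions = default_prescriptions(),
                               seed = 1L,
                               params = dose_model_params(),
                               n_beams = 9) {
  for (p in c("pgtvtb", "gtvnd", "ptv"))
    if (is.null(prescriptions[[p]]))
      stop("missing prescription for target '", p, "'")
  body <- get_structure(structs, "body")
  ptv <- get_structure(structs, "ptv")
  high <- structure_mask("high",
                         get_structure(structs, "pgtvtb")$voxels |
                           get_structure(structs, "gtvnd")$voxels,
                         structs$grid)

  f <- beam_fluence_field(body, n_beams, params)
  inb <- body$voxels
  F <- f / mean(f[inb])

  s60 <- exp(-distance_to_mask(ptv) / params$tau_ptv_mm)
  dH <- distance_to_mask(high)
  # compact-support cosine taper: 1 on PGTVtb/GTVnd, 0 beyond the taper
  sH <- ifelse(dH < params$boost_taper_mm,
               0.5 * (1 + cos(pi * dH / params$boost_taper_mm)), 0)
  m <- 1 + params$mod_fraction * (F / mean(F[ptv$voxels]) - 1)

  u1 <- s60 * m + params$bg_fraction * F * (1 - s60)
  u2 <- sH * m

  # calibrate the two amplitudes against the actual dose medians: the
  # PTV median at ptv_headroom x 60.06 Gy, the PGTVtb/GTVnd median at
  # boost_headroom x 69.96 Gy
  t_ptv <- params$ptv_headroom * prescriptions$ptv$total_dose_Gy
  t_high <- params$boost_headroom * prescriptions$pgtvtb$total_dose_Gy
  u1_ptv <- u1[ptv$voxels]
  u2_ptv <- u2[ptv$voxels]
  u1_h <- u1[high$voxels]
  u2_h <- u2[high$voxels]
  a <- t_ptv
  b <- t_high - t_ptv
  for (it in 1:8) {
    a <- a + (t_ptv - stats::median(a * u1_ptv + b * u2_ptv)) /
      stats::median(u1_ptv)
    b <- b + (t_high - stats::median(a * u1_h + b * u2_h)) /
      stats::median(u2_h)
  }

  dose <- a * u1 + b * u2
  dose[!inb] <- 0
  if (params$noise_sigma_fraction > 0) {
    nb <- sum(inb)
    dose[inb] <- dose[inb] * with_seed(
      seed, 1 + params$noise_sigma_fraction * stats::rnorm(nb))
    # the noise smears the PTV plateau against the one-sided boost tail
    # and drifts the median upward; pin it back exactly
    dose <- dose * (t_ptv / stats::median(dose[ptv$voxels]))
  }
  dose[dose < 0] <- 0
  dose_grid(dose, structs$grid)
}
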