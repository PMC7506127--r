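#' Dose prescription
#'
#' Total dose, fraction count and dose per fraction; the per-fraction
#' dose is derived (rounded to 0.01 Gy) when not given, and the three
#' fields must agree within that rounding.
#'
#' @param total_dose_Gy total prescribed dose in Gy, `> 0`.
#' @param n_fractions number of fractions, positive integer.
#' @param dose_per_fraction_Gy optional; defaults to
#'   `round(total / n, 2)`.
#' @return An object of class `prescription`.
#' @export
#' @examples
#' prescription(69.96, 33)  # 2.12 Gy per fraction
prescription <- function(total_dose_Gy, n_fractions,
                         dose_per_fraction_Gy = NULL) {
  if (!is.numeric(total_dose_Gy) || total_dose_Gy <= 0)
    stop("'total_dose_Gy' must be > 0")
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop("'n_fractions' must be a positive integer")
  dpf <- total_dose_Gy / n_fractions
  if (is.null(dose_per_fraction_Gy)) {
    dose_per_fraction_Gy <- round(dpf, 2)
  } else if (abs(dose_per_fraction_Gy - dpf) > 0.005) {
    stop(sprintf(
      "dose per fraction %.4f inconsistent with %.2f Gy / %d fractions",
      dose_per_fraction_Gy, total_dose_Gy, n_fractions))
  }
  structure(list(total_dose_Gy = total_dose_Gy,
                 n_fractions = n_fractions,
                 dose_per_fraction_Gy = dose_per_fraction_Gy),
            class = "prescription")
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf("prescription: %.2f Gy / %.2f Gy / %d fractions\n",
              x$total_dose_Gy, x$dose_per_fraction_Gy, x$n_fractions))
  invisible(x)
}

#' Default head-and-neck prescriptions
#'
#' The standard simultaneous-integrated-boost scheme for hypopharyngeal
#' carcinoma: 69.96 Gy in 33 fractions (2.12 Gy/f) to the tumour-bed
#' planning gross tumour volume (PGTVtb) and involved nodes (GTVnd),
#' 60.06 Gy in 33 fractions (1.82 Gy/f) to the PTV.
#'
#' @return Named list of [prescription()] objects
#'   (`pgtvtb`, `gtvnd`, `ptv`).
#' @export
default_prescriptions <- function() {
  list(pgtvtb = prescription(69.96, 33),
       gtvnd = prescription(69.96, 33),
       ptv = prescription(60.06, 33))
}

#' The three plan conditions
#'
#' `B0` is the plan optimised without a magnetic field; `B15_RECAL` the
#' same segments and monitor units recalculated at 1.5 T; `B15_REOPT`
#' the plan reoptimised at 1.5 T with the original cost function.
#'
#' @return Character vector of the three condition labels.
#' @export
plan_conditions <- function() c("B0", "B15_RECAL", "B15_REOPT")

# ---- geometry descriptors -------------------------------------------------

# shape: "cylinder" (in-plane circle over a z range) or "spheres" (one or
# more balls). Offsets are mm relative to the body axis; z in absolute mm.
geom_cylinder <- function(name, radius_mm, offset_mm, z_range_mm) {
  list(name = name, shape = "cylinder", radius_mm = radius_mm,
       offset_mm = offset_mm, z_range_mm = z_range_mm)
}

geom_spheres <- function(name, radius_mm, centers) {
  list(name = name, shape = "spheres", radius_mm = radius_mm,
       centers = centers)
}

#' Synthetic neck phantom specification
#'
#' Parametric geometry of a neck-like phantom on a 1 x 1 x 3 mm grid: a
#' cylindrical body with an anterior larynx/trachea air tube and a
#' superior naso/oropharyngeal air pocket, a central tumour-bed target
#' (PGTVtb) with a lateral nodal target (GTVnd), a PTV grown from both,
#' and posterior/lateral organs at risk (brain stem, spinal cord,
#' parotids, thyroid). All coordinates are mm; in-plane offsets are
#' relative to the body axis (+y anterior).
#'
#' @param grid_shape integer triple; default `c(104, 104, 44)`.
#' @param spacing_mm voxel spacing; default `c(1, 1, 3)` mm.
#' @param body_radius_mm body cylinder radius (default 45 mm).
#' @param body_z_range_mm inferior/superior extent of the body in mm.
#' @param larynx_radius_mm,pharynx_radius_mm air-cavity radii.
#' @param pgtvtb_radius_mm,gtvnd_radius_mm target radii.
#' @param gtvnd_offset_mm in-plane offset of the nodal target.
#' @param ptv_margin_mm margin growing PGTVtb + GTVnd into the PTV.
#' @param target_z_mm axial centre of the targets.
#' @param prescriptions named list of [prescription()]s
#'   (`pgtvtb`, `gtvnd`, `ptv`).
#' @param seed integer carried along for downstream dose simulation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(104, 104, 44),
                         spacing_mm = c(1, 1, 3),
                         body_radius_mm = 45,
                         body_z_range_mm = c(6, 123),
                         larynx_radius_mm = 6,
                         pharynx_radius_mm = 8,
                         pgtvtb_radius_mm = 14,
                         gtvnd_radius_mm = 8,
                         gtvnd_offset_mm = c(-24, 4),
                         ptv_margin_mm = 8,
                         target_z_mm = 45,
                         prescriptions = default_prescriptions(),
                         seed = 1L) {
  grid <- voxel_grid(grid_shape, spacing_mm)
  if (body_radius_mm <= 0) stop("'body_radius_mm' must be > 0")
  spec <- list(
    grid = grid,
    body_radius_mm = body_radius_mm,
    body_z_range_mm = body_z_range_mm,
    cavity_specs = list(
      geom_cylinder("air_larynx_trachea", larynx_radius_mm,
                    c(0, 18), c(body_z_range_mm[1], 90)),
      geom_spheres("air_pharynx", pharynx_radius_mm,
                   list(c(0, 12, 102)))),
    target_specs = list(
      pgtvtb = list(geom = geom_spheres("pgtvtb", pgtvtb_radius_mm,
                                        list(c(0, 10, target_z_mm))),
                    prescription = prescriptions$pgtvtb),
      gtvnd = list(geom = geom_spheres(
        "gtvnd", gtvnd_radius_mm,
        list(c(gtvnd_offset_mm, target_z_mm))),
        prescription = prescriptions$gtvnd),
      ptv = list(margin_mm = ptv_margin_mm,
                 prescription = prescriptions$ptv)),
    oar_specs = list(
      geom_cylinder("brainstem", 5.5, c(0, -14), c(108, 123)),
      geom_cylinder("cord", 4.5, c(0, -26), c(body_z_range_mm[1], 108)),
      geom_spheres("parotid_l", 11, list(c(-30, 8, 111))),
      geom_spheres("parotid_r", 11, list(c(30, 8, 111))),
      geom_spheres("thyroid", 6, list(c(-10, 24, 21), c(10, 24, 21)))),
    prescriptions = prescriptions,
    seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec on %s, body radius %.1f mm, seed %d\n",
              format(x$grid), x$body_radius_mm, x$seed))
  invisible(x)
}

# centre of the body axis in physical mm (in-plane grid centre)
body_axis_mm <- function(grid) {
  c(grid$origin_mm[1] + (grid$shape[1] - 1) / 2 * grid$spacing_mm[1],
    grid$origin_mm[2] + (grid$shape[2] - 1) / 2 * grid$spacing_mm[2])
}

# rasterise one geometry descriptor into a logical array
rasterize_geom <- function(geom, grid, axis_mm) {
  x <- axis_coords(grid, 1)
  y <- axis_coords(grid, 2)
  z <- axis_coords(grid, 3)
  out <- array(FALSE, dim = grid$shape)
  if (geom$shape == "cylinder") {
    cx <- axis_mm[1] + geom$offset_mm[1]
    cy <- axis_mm[2] + geom$offset_mm[2]
    inplane <- outer((x - cx)^2, (y - cy)^2, "+") <= geom$radius_mm^2
    zin <- z >= geom$z_range_mm[1] & z <= geom$z_range_mm[2]
    out <- array(as.vector(inplane), dim = grid$shape) &
      array(rep(zin, each = grid$shape[1] * grid$shape[2]),
            dim = grid$shape)
  } else if (geom$shape == "spheres") {
    for (ctr in geom$centers) {
      cx <- axis_mm[1] + ctr[1]
      cy <- axis_mm[2] + ctr[2]
      cz <- ctr[3]
      inplane <- outer((x - cx)^2, (y - cy)^2, "+")
      ball <- outer(as.vector(inplane), (z - cz)^2, "+") <=
        geom$radius_mm^2
      out <- out | array(ball, dim = grid$shape)
    }
  } else stop("unknown geometry shape '", geom$shape, "'")
  out
}

touches_grid_face <- function(vox) {
  d <- dim(vox)
  any(vox[1, , ]) || any(vox[d[1], , ]) ||
    any(vox[, 1, ]) || any(vox[, d[2], ]) ||
    any(vox[, , 1]) || any(vox[, , d[3]])
}

#' Build the phantom structure set
#'
#' Rasterises a [phantom_spec()] into binary masks: body, the two air
#' cavities, PGTVtb, GTVnd and PTV (targets exclude air voxels; the PTV
#' is the `ptv_margin_mm` expansion of PGTVtb + GTVnd clipped to the
#' body), and the organs at risk. Purely deterministic: the geometry
#' never consumes the random stream.
#'
#' @param spec a [phantom_spec()].
#' @return A [structure_set()] with masks `body`, `air_larynx_trachea`,
#'   `air_pharynx`, `pgtvtb`, `gtvnd`, `ptv`, `brainstem`, `cord`,
#'   `parotid_l`, `parotid_r`, `thyroid`.
#' @export
build_phantom <- function(spec) {
  grid <- spec$grid
  ctr <- body_axis_mm(grid)
  body_geom <- geom_cylinder("body", spec$body_radius_mm, c(0, 0),
                             spec$body_z_range_mm)
  body_vox <- rasterize_geom(body_geom, grid, ctr)
  if (!any(body_vox)) stop("invalid phantom spec: empty body")
  if (touches_grid_face(body_vox))
    stop("invalid phantom spec: body touches the grid boundary; ",
         "enlarge the grid or shrink the body")

  masks <- list(structure_mask("body", body_vox, grid))
  air_vox <- array(FALSE, dim = grid$shape)
  for (cav in spec$cavity_specs) {
    v <- rasterize_geom(cav, grid, ctr)
    if (any(v & !body_vox))
      stop("invalid phantom spec: cavity '", cav$name,
           "' extends outside the body")
    air_vox <- air_vox | v
    masks <- c(masks, list(structure_mask(cav$name, v, grid)))
  }

  tvox <- list()
  for (tn in c("pgtvtb", "gtvnd")) {
    v <- rasterize_geom(spec$target_specs[[tn]]$geom, grid, ctr) &
      body_vox & !air_vox
    if (!any(v))
      stop("invalid phantom spec: target '", tn,
           "' has no tissue voxels (entirely in air or outside the body)")
    tvox[[tn]] <- v
    masks <- c(masks, list(structure_mask(tn, v, grid)))
  }
  seed_mask <- structure_mask("ptv_seed", tvox$pgtvtb | tvox$gtvnd, grid)
  ptv_vox <- expand_margin(seed_mask,
                           spec$target_specs$ptv$margin_mm,
                           structure_mask("body", body_vox, grid),
                           name = "ptv")$voxels & !air_vox
  masks <- c(masks, list(structure_mask("ptv", ptv_vox, grid)))

  for (oar in spec$oar_specs) {
    v <- rasterize_geom(oar, grid, ctr) & body_vox
    if (!any(v))
      stop("invalid phantom spec: OAR '", oar$name, "' is empty")
    masks <- c(masks, list(structure_mask(oar$name, v, grid)))
  }
  structure_set(grid, masks)
}
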