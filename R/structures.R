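#' Skin shell: first millimetre under the body outline
#'
#' Voxels inside the body whose distance to the body exterior is at most
#' `thickness_mm`. With the default 1-mm thickness on a 1 x 1 x 3 mm grid
#' this selects a single in-plane voxel layer and no purely axial
#' (superior/inferior) face layer, because axial neighbours are 3 mm
#' away -- matching slice-wise skin contouring practice.
#'
#' @param body nonempty body [structure_mask()].
#' @param thickness_mm shell thickness in mm (closed threshold, `<=`).
#' @return A [structure_mask()] named `"skin"`, a subset of `body`.
#' @export
skin_shell <- function(body, thickness_mm = 1.0) {
  if (!is.numeric(thickness_mm) || thickness_mm <= 0)
    stop("'thickness_mm' must be > 0")
  d <- distance_to_complement(body)
  structure_mask("skin", body$voxels & d <= thickness_mm, body$grid)
}

#' Air-cavity interface shell: first millimetre outside a cavity
#'
#' Tissue voxels (inside the body, outside the cavity) within
#' `thickness_mm` of the cavity. This is the region where the electron
#' return effect concentrates dose perturbations at tissue-air
#' interfaces.
#'
#' @param cavity nonempty air-cavity [structure_mask()], must lie inside
#'   `body`.
#' @param body body [structure_mask()] on the same grid.
#' @param thickness_mm shell thickness in mm (closed threshold).
#' @param name name for the returned mask; default
#'   `"interface_<cavity name>"`.
#' @return A [structure_mask()], disjoint from the cavity.
#' @export
cavity_interface_shell <- function(cavity, body, thickness_mm = 1.0,
                                   name = paste0("interface_", cavity$name)) {
  stop_if_grid_mismatch(cavity$grid, body$grid)
  if (!is.numeric(thickness_mm) || thickness_mm <= 0)
    stop("'thickness_mm' must be > 0")
  if (!any(cavity$voxels))
    return(structure_mask(name, array(FALSE, dim = body$grid$shape),
                          body$grid))
  if (any(cavity$voxels & !body$voxels))
    stop("cavity '", cavity$name, "' is not contained in the body")
  d <- distance_to_mask(cavity)
  vox <- body$voxels & !cavity$voxels & d <= thickness_mm
  structure_mask(name, vox, body$grid)
}

#' Isotropic margin expansion (PRV construction)
#'
#' All voxels within `margin_mm` (anisotropic Euclidean, voxel-centre
#' distance) of the mask, intersected with a clip region -- the planning
#' organ-at-risk volume construction (3-mm brain stem, 5-mm spinal cord
#' margins).
#'
#' @param mask nonempty [structure_mask()] to expand.
#' @param margin_mm margin in mm, `>= 0` (closed threshold; 0 returns
#'   `mask` clipped).
#' @param clip [structure_mask()] limiting the expansion (normally the
#'   body).
#' @param name name for the returned mask; default `"<mask name>_prv"`.
#' @return A [structure_mask()] containing `mask` intersected with `clip`.
#' @export
expand_margin <- function(mask, margin_mm, clip,
                          name = paste0(mask$name, "_prv")) {
  stop_if_grid_mismatch(mask$grid, clip$grid)
  if (!is.numeric(margin_mm) || margin_mm < 0)
    stop("'margin_mm' must be >= 0")
  d <- distance_to_mask(mask)
  structure_mask(name, (d <= margin_mm) & clip$voxels, mask$grid)
}

#' Normal tissue: body farther than a margin from the PTV
#'
#' Body voxels at Euclidean distance strictly greater than `margin_mm`
#' from the planning target volume. With the default 10 mm this is the
#' normal-tissue region whose mean dose enters the plan-quality metric;
#' it partitions the body together with the 10-mm PTV expansion.
#'
#' @param body body [structure_mask()].
#' @param ptv nonempty PTV [structure_mask()] contained in `body`.
#' @param margin_mm exclusion margin in mm (strict threshold, `>`).
#' @return A [structure_mask()] named `"nt"`.
#' @export
normal_tissue <- function(body, ptv, margin_mm = 10.0) {
  stop_if_grid_mismatch(body$grid, ptv$grid)
  if (!any(ptv$voxels)) stop("PTV mask is empty")
  if (any(ptv$voxels & !body$voxels))
    stop("PTV is not contained in the body")
  d <- distance_to_mask(ptv)
  structure_mask("nt", body$voxels & d > margin_mm, body$grid)
}

#' Derive all bespoke evaluation regions of a phantom structure set
#'
#' Adds to a structure set every derived region the plan metrics need:
#' the 1-mm skin shell, a 1-mm interface shell per air cavity, the brain
#' stem and spinal cord PRVs (3- and 5-mm margins) and the normal-tissue
#' region (> 10 mm from the PTV).
#'
#' @param structs a [structure_set()] containing at least `body`, `ptv`,
#'   `brainstem`, `cord`, and the air cavities named in `cavities`.
#' @param cavities names of the air-cavity masks.
#' @param skin_thickness_mm,interface_thickness_mm shell thicknesses (mm).
#' @param brainstem_margin_mm,cord_margin_mm PRV margins (mm).
#' @param nt_margin_mm normal-tissue exclusion margin (mm).
#' @return The enriched [structure_set()].
#' @export
derive_regions <- function(structs,
                           cavities = c("air_larynx_trachea", "air_pharynx"),
                           skin_thickness_mm = 1.0,
                           interface_thickness_mm = 1.0,
                           brainstem_margin_mm = 3.0,
                           cord_margin_mm = 5.0,
                           nt_margin_mm = 10.0) {
  body <- get_structure(structs, "body")
  structs <- set_structure(structs, skin_shell(body, skin_thickness_mm))
  for (cav in cavities) {
    shell <- cavity_interface_shell(get_structure(structs, cav), body,
                                    interface_thickness_mm,
                                    name = sub("^interface_air_",
                                               "interface_",
                                               paste0("interface_", cav)))
    structs <- set_structure(structs, shell)
  }
  structs <- set_structure(
    structs, expand_margin(get_structure(structs, "brainstem"),
                           brainstem_margin_mm, body))
  structs <- set_structure(
    structs, expand_margin(get_structure(structs, "cord"),
                           cord_margin_mm, body))
  set_structure(structs, normal_tissue(body, get_structure(structs, "ptv"),
                                       nt_margin_mm))
}
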