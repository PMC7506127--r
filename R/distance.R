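#' @useDynLib mrplanqa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# squared anisotropic EDT to the nearest TRUE voxel of `feature`
edt_squared <- function(feature, grid) {
  if (!any(feature)) {
    out <- array(Inf, dim = grid$shape)
    return(out)
  }
  d <- .edt_squared_cpp(as.logical(feature), grid$shape,
                        as.numeric(grid$spacing_mm))
  array(d, dim = grid$shape)
}

# perpendicular distance from each voxel centre to the nearest voxel
# centre just beyond a grid face (the world outside the grid counts as
# background for distance_to_complement)
boundary_distance <- function(grid) {
  dx <- pmin(seq_len(grid$shape[1]), rev(seq_len(grid$shape[1]))) *
    grid$spacing_mm[1]
  dy <- pmin(seq_len(grid$shape[2]), rev(seq_len(grid$shape[2]))) *
    grid$spacing_mm[2]
  dz <- pmin(seq_len(grid$shape[3]), rev(seq_len(grid$shape[3]))) *
    grid$spacing_mm[3]
  a <- array(dx, dim = grid$shape)
  a <- pmin(a, array(rep(dy, each = grid$shape[1]), dim = grid$shape))
  pmin(a, array(rep(dz, each = grid$shape[1] * grid$shape[2]),
                dim = grid$shape))
}

#' Distance from inside a mask to its complement
#'
#' For every voxel inside the mask, the anisotropic Euclidean distance
#' (mm, voxel centre to voxel centre) to the nearest voxel outside the
#' mask; 0 outside the mask. Space beyond the grid faces counts as
#' outside, so a mask touching the grid edge still has a finite distance
#' there. This is the primitive underlying the skin shell, the cavity
#' interface shells and the normal-tissue region.
#'
#' @param mask a nonempty [structure_mask()].
#' @return Numeric 3-D array of distances in mm.
#' @export
#' @examples
#' g <- voxel_grid(c(9, 9, 9), spacing_mm = c(1, 1, 1))
#' m <- structure_mask("cube", array(TRUE, dim = c(9, 9, 9)), g)
#' d <- distance_to_complement(m)
#' d[5, 5, 5]  # 5 mm to the nearest outside-grid voxel centre
distance_to_complement <- function(mask) {
  if (!any(mask$voxels)) stop("mask '", mask$name, "' is empty")
  d <- sqrt(edt_squared(!mask$voxels, mask$grid))
  d <- pmin(d, boundary_distance(mask$grid))
  d[!mask$voxels] <- 0
  d
}

#' Distance from outside a mask to the mask
#'
#' For every voxel, the anisotropic Euclidean distance in mm to the
#' nearest voxel inside the mask (0 inside). Basis of margin expansion
#' and of the normal-tissue definition.
#'
#' @param mask a nonempty [structure_mask()].
#' @return Numeric 3-D array of distances in mm.
#' @export
distance_to_mask <- function(mask) {
  if (!any(mask$voxels)) stop("mask '", mask$name, "' is empty")
  sqrt(edt_squared(mask$voxels, mask$grid))
}
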