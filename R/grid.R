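#' Voxel grid geometry
#'
#' A `voxel_grid` describes the common geometry shared by every dose grid
#' and structure mask of one patient: array shape, anisotropic voxel
#' spacing in mm, and the physical position (mm) of the centre of voxel
#' `(1, 1, 1)`. The default spacing, 1 x 1 x 3 mm, follows head-and-neck
#' CT convention (1-mm planar voxels, 3-mm slices).
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing_mm positive numeric vector of length 3, mm per voxel.
#' @param origin_mm numeric vector of length 3, centre of the first voxel.
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' voxel_grid(c(64, 64, 30))
voxel_grid <- function(shape, spacing_mm = c(1, 1, 3),
                       origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three positive integers")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be three strictly positive numbers")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be three finite numbers")
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  invisible(x)
}

#' @export
format.voxel_grid <- function(x, ...) {
  sprintf("%dx%dx%d @ %gx%gx%g mm", x$shape[1], x$shape[2], x$shape[3],
          x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3])
}

grids_equal <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm)) &&
    isTRUE(all.equal(a$origin_mm, b$origin_mm))
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grids_equal(a, b))
    stop("objects are defined on different voxel grids (",
         format(a), " vs ", format(b), ")")
  invisible(TRUE)
}

#' Voxel volume in cubic centimetres
#' @param grid a [voxel_grid()].
#' @return Scalar volume of one voxel in cc.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing_mm) / 1000

# physical coordinates (mm) of voxel centres along one axis
axis_coords <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing_mm[axis]
}

#' Dose grid
#'
#' Per-voxel absorbed dose in Gy on a [voxel_grid()].
#'
#' @param values numeric 3-D array of doses (Gy), non-negative.
#' @param grid the [voxel_grid()] the array lives on.
#' @return An object of class `dose_grid`: list with `values` and `grid`.
#' @export
dose_grid <- function(values, grid) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("dose array shape does not match the grid")
  if (anyNA(values) || any(values < 0))
    stop("doses must be non-negative and non-missing")
  structure(list(values = values, grid = grid), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid on %s: range %.2f-%.2f Gy\n", format(x$grid),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary structure mask
#'
#' @param name structure identifier (e.g. `"ptv"`, `"cord"`).
#' @param voxels logical 3-D array; `TRUE` marks voxels inside the structure.
#' @param grid the [voxel_grid()] the mask lives on.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, voxels, grid) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array")
  if (!is.logical(voxels)) storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask contains missing values")
  if (!identical(as.integer(dim(voxels)), grid$shape))
    stop("mask shape does not match the grid")
  structure(list(name = name, voxels = voxels, grid = grid),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask '%s' on %s: %d voxels (%.1f cc)\n",
              x$name, format(x$grid), sum(x$voxels),
              sum(x$voxels) * voxel_volume_cc(x$grid)))
  invisible(x)
}

mask_count <- function(mask) sum(mask$voxels)

#' Named collection of structure masks on one grid
#'
#' @param grid shared [voxel_grid()].
#' @param masks named list of [structure_mask()] objects; names must match
#'   each mask's own `name` and all masks must share `grid`.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(grid, masks = list()) {
  if (length(masks)) {
    nm <- vapply(masks, function(m) m$name, character(1))
    if (is.null(names(masks))) names(masks) <- nm
    if (!identical(unname(names(masks)), unname(nm)))
      stop("list names must equal the masks' own names")
    if (anyDuplicated(nm)) stop("duplicate structure names")
    for (m in masks) stop_if_grid_mismatch(grid, m$grid)
  }
  structure(list(grid = grid, masks = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("structure_set on %s with %d structures:\n", format(x$grid),
              length(x$masks)))
  for (m in x$masks)
    cat(sprintf("  %-24s %8d voxels\n", m$name, sum(m$voxels)))
  invisible(x)
}

#' Retrieve one mask from a structure set
#' @param structs a [structure_set()].
#' @param name structure name.
#' @return The [structure_mask()].
#' @export
get_structure <- function(structs, name) {
  m <- structs$masks[[name]]
  if (is.null(m))
    stop("structure '", name, "' not present (have: ",
         paste(names(structs$masks), collapse = ", "), ")")
  m
}

#' Add or replace a mask in a structure set
#' @param structs a [structure_set()].
#' @param mask a [structure_mask()] on the same grid.
#' @return The updated `structure_set`.
#' @export
set_structure <- function(structs, mask) {
  stop_if_grid_mismatch(structs$grid, mask$grid)
  structs$masks[[mask$name]] <- mask
  structs
}

#' @export
names.structure_set <- function(x) names(x$masks)
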