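# Dose comparisons use a 1e-9 Gy guard so that doses exactly equal to a
# bin edge or prescription level count as "receiving" that dose despite
# binary floating point (0.01-Gy edges are not exactly representable).
DOSE_EPS <- 1e-9

#' Cumulative dose-volume histogram
#'
#' Builds the cumulative DVH of one structure from the multiset of
#' in-mask voxel doses: for every bin edge `e`, the fraction of the
#' structure volume receiving at least `e` Gy.
#'
#' @param dose a [dose_grid()].
#' @param mask a nonempty [structure_mask()] on the same grid.
#' @param bin_width_Gy histogram resolution in Gy (default 0.01).
#' @return An object of class `dvh`: list with `structure`,
#'   `bin_edges_Gy` (increasing, starting at 0),
#'   `cumulative_volume_fraction` (non-increasing, 1 at 0 Gy) and
#'   `total_volume_cc`.
#' @export
compute_dvh <- function(dose, mask, bin_width_Gy = 0.01) {
  stop_if_grid_mismatch(dose$grid, mask$grid)
  if (!any(mask$voxels)) stop("mask '", mask$name, "' is empty")
  if (!is.numeric(bin_width_Gy) || bin_width_Gy <= 0)
    stop("'bin_width_Gy' must be > 0")
  dv <- dose$values[mask$voxels]
  n <- length(dv)
  nbin <- ceiling(max(dv) / bin_width_Gy) + 1L
  edges <- bin_width_Gy * (0:nbin)
  # left-closed binning with the epsilon guard: dose d falls in bin j iff
  # edges[j] - eps <= d < edges[j+1] - eps
  idx <- findInterval(dv + DOSE_EPS, edges)  # in 1..nbin+1
  counts <- tabulate(idx, nbins = nbin + 1L)
  at_least <- n - c(0, cumsum(counts))[seq_len(nbin + 1L)]
  structure(list(structure = mask$name,
                 bin_edges_Gy = edges,
                 cumulative_volume_fraction = at_least / n,
                 total_volume_cc = n * voxel_volume_cc(mask$grid)),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("dvh '%s': %.1f cc, D50 ~ %.2f Gy, Dmax bin %.2f Gy\n",
              x$structure, x$total_volume_cc, dose_at_volume(x, 50),
              max(x$bin_edges_Gy)))
  invisible(x)
}

#' Dose received by the hottest q% of a structure (Dq%)
#'
#' The dose `d` such that q% of the structure volume receives at least
#' `d`, read from the cumulative DVH with linear interpolation; where the
#' curve is flat at exactly q% the higher dose is returned (conservative
#' "hottest q%" convention). `D100%` is the in-mask minimum dose bin.
#'
#' @param dvh a [compute_dvh()] result.
#' @param q_percent volume percentage in (0, 100].
#' @return Dose in Gy; non-increasing in `q_percent`.
#' @export
dose_at_volume <- function(dvh, q_percent) {
  if (!is.numeric(q_percent) || length(q_percent) != 1L ||
      q_percent <= 0 || q_percent > 100)
    stop("'q_percent' must be in (0, 100]")
  qf <- q_percent / 100
  v <- dvh$cumulative_volume_fraction
  e <- dvh$bin_edges_Gy
  j <- max(which(v >= qf - 1e-12))   # exists: v[1] = 1 >= qf
  if (j == length(v) || v[j] <= qf + 1e-12) return(e[j])
  # v[j] > qf > v[j+1]: interpolate within the bin
  e[j] + (v[j] - qf) / (v[j] - v[j + 1]) * (e[j + 1] - e[j])
}

#' Volume receiving at least a dose (Vd)
#'
#' Percentage of the structure volume receiving at least `d_Gy`, read
#' from the cumulative DVH (step resolution one bin width).
#'
#' @param dvh a [compute_dvh()] result.
#' @param d_Gy dose threshold in Gy, `>= 0`.
#' @return Volume percentage in \[0, 100\]; non-increasing in `d_Gy`.
#' @export
volume_at_dose <- function(dvh, d_Gy) {
  if (!is.numeric(d_Gy) || length(d_Gy) != 1L || d_Gy < 0)
    stop("'d_Gy' must be >= 0")
  e <- dvh$bin_edges_Gy
  j <- findInterval(d_Gy - DOSE_EPS, e - DOSE_EPS, left.open = TRUE) + 1L
  # j = smallest index with e[j] >= d (up to eps)
  if (j > length(e)) return(0)
  100 * dvh$cumulative_volume_fraction[j]
}
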