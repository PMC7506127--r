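#' Homogeneity index
#'
#' `HI = (D2% - D98%) / D50%`, reported as a fraction (0 = perfectly
#' homogeneous). The fraction form is the one the plan-quality metric
#' consumes (scoring intervals 0-0.2 / 0-0.3); HI is invariant under
#' global dose scaling.
#'
#' @param d2,d98,d50 minimum doses (Gy) delivered to the hottest 2, 98
#'   and 50% of the structure; `d2 >= d98`, `d50 > 0`.
#' @return HI as a dimensionless fraction `>= 0`.
#' @export
#' @examples
#' homogeneity_index(72, 66, 70)  # ~0.0857
homogeneity_index <- function(d2, d98, d50) {
  if (!all(is.finite(c(d2, d98, d50)))) stop("doses must be finite")
  if (d50 <= 0) stop("'d50' must be > 0")
  if (d2 < d98 - DOSE_EPS) stop("'d2' must be >= 'd98'")
  max(d2 - d98, 0) / d50
}

#' Conformity index
#'
#' `CI = TV_PTV^2 / (V_PTV x TV)` where `TV` is the in-body volume
#' receiving at least the prescription dose, `TV_PTV` its intersection
#' with the target, and `V_PTV` the target volume. CI lies in \[0, 1\]
#' and equals 1 exactly when the prescription isodose region coincides
#' with the target. The treated volume is clipped to the body because
#' Monte Carlo dose grids deposit dose in the air outside the patient.
#' A degenerate plan in which no voxel reaches the prescription gives
#' CI = 0 with attribute `degenerate = TRUE`.
#'
#' @param target nonempty target [structure_mask()], inside `body`.
#' @param dose a [dose_grid()] on the same grid.
#' @param prescription_Gy prescription dose in Gy, `> 0`.
#' @param body body [structure_mask()].
#' @return CI in \[0, 1\].
#' @export
conformity_index <- function(target, dose, prescription_Gy, body) {
  stop_if_grid_mismatch(target$grid, dose$grid)
  stop_if_grid_mismatch(target$grid, body$grid)
  if (!is.numeric(prescription_Gy) || prescription_Gy <= 0)
    stop("'prescription_Gy' must be > 0")
  if (!any(target$voxels)) stop("target mask is empty")
  if (any(target$voxels & !body$voxels))
    stop("target is not contained in the body")
  hot <- dose$values >= prescription_Gy - DOSE_EPS
  tv <- sum(hot & body$voxels)
  if (tv == 0) return(structure(0, degenerate = TRUE))
  tv_ptv <- sum(hot & target$voxels)
  v_ptv <- sum(target$voxels)
  as.numeric(tv_ptv)^2 / (as.numeric(v_ptv) * as.numeric(tv))
}

#' Maximum and mean in-mask dose
#'
#' `Dmax` is the single hottest voxel (point maximum, as a Monte Carlo
#' planning system reports it); `Dmean` the arithmetic in-mask mean.
#'
#' @param dose a [dose_grid()].
#' @param mask a nonempty [structure_mask()] on the same grid.
#' @return Named numeric vector `c(dmax = , dmean = )` in Gy.
#' @export
dose_max_mean <- function(dose, mask) {
  stop_if_grid_mismatch(dose$grid, mask$grid)
  if (!any(mask$voxels)) stop("mask '", mask$name, "' is empty")
  dv <- dose$values[mask$voxels]
  c(dmax = max(dv), dmean = mean(dv))
}

target_metrics <- function(dose, structs, target_name, presc_Gy, body,
                           bin_width_Gy) {
  m <- get_structure(structs, target_name)
  dvh <- compute_dvh(dose, m, bin_width_Gy)
  d2 <- dose_at_volume(dvh, 2)
  d98 <- dose_at_volume(dvh, 98)
  d50 <- dose_at_volume(dvh, 50)
  list(v_presc = volume_at_dose(dvh, presc_Gy),
       hi = homogeneity_index(d2, d98, d50),
       ci = as.numeric(conformity_index(m, dose, presc_Gy, body)))
}

#' Extract the full per-plan metric set
#'
#' Computes every scalar dosimetric parameter used in plan evaluation:
#' for PGTVtb and GTVnd the coverage at 69.96 Gy, HI and CI; for the PTV
#' the coverage at 60.06 Gy, HI and CI; Dmax of brain stem, brain stem
#' PRV, spinal cord and cord PRV; Dmean of the parotids (union of both
#' lobes) and of normal tissue; and Dmean/Dmax of the skin shell and of
#' each air-cavity interface shell. Coverage and Dq% values are read from
#' the cumulative DVH; Dmax/Dmean are computed directly on the voxel
#' multiset.
#'
#' @param dose a [dose_grid()].
#' @param structs a [structure_set()] holding the primary and derived
#'   structures (see [derive_regions()]).
#' @param prescriptions named list of [prescription()] objects with
#'   entries `pgtvtb`, `gtvnd`, `ptv`.
#' @param bin_width_Gy DVH resolution (default 0.01 Gy).
#' @return An object of class `metric_set`: named list of scalars.
#' @export
extract_plan_metrics <- function(dose, structs,
                                 prescriptions = default_prescriptions(),
                                 bin_width_Gy = 0.01) {
  required <- c("body", "pgtvtb", "gtvnd", "ptv", "brainstem",
                "brainstem_prv", "cord", "cord_prv", "parotid_l",
                "parotid_r", "nt", "skin", "interface_larynx_trachea",
                "interface_pharynx")
  missing <- setdiff(required, names(structs$masks))
  if (length(missing))
    stop("structure set lacks required structures: ",
         paste(missing, collapse = ", "))
  for (p in c("pgtvtb", "gtvnd", "ptv"))
    if (is.null(prescriptions[[p]]))
      stop("missing prescription for target '", p, "'")
  body <- get_structure(structs, "body")

  tm <- lapply(c(pgtvtb = "pgtvtb", gtvnd = "gtvnd", ptv = "ptv"),
               function(s) target_metrics(
                 dose, structs, s, prescriptions[[s]]$total_dose_Gy,
                 body, bin_width_Gy))

  mm <- function(name) dose_max_mean(dose, get_structure(structs, name))
  parotids <- structure_mask(
    "parotids",
    get_structure(structs, "parotid_l")$voxels |
      get_structure(structs, "parotid_r")$voxels,
    structs$grid)

  out <- list(
    pgtvtb_v_presc = tm$pgtvtb$v_presc,
    pgtvtb_ci = tm$pgtvtb$ci,
    pgtvtb_hi = tm$pgtvtb$hi,
    gtvnd_v_presc = tm$gtvnd$v_presc,
    gtvnd_ci = tm$gtvnd$ci,
    gtvnd_hi = tm$gtvnd$hi,
    ptv_v_presc = tm$ptv$v_presc,
    ptv_ci = tm$ptv$ci,
    ptv_hi = tm$ptv$hi,
    brainstem_dmax = mm("brainstem")[["dmax"]],
    brainstem_prv_dmax = mm("brainstem_prv")[["dmax"]],
    cord_dmax = mm("cord")[["dmax"]],
    cord_prv_dmax = mm("cord_prv")[["dmax"]],
    parotids_dmean = dose_max_mean(dose, parotids)[["dmean"]],
    nt_dmean = mm("nt")[["dmean"]],
    skin_dmean = mm("skin")[["dmean"]],
    skin_dmax = mm("skin")[["dmax"]],
    interface_larynx_trachea_dmean = mm("interface_larynx_trachea")[["dmean"]],
    interface_larynx_trachea_dmax = mm("interface_larynx_trachea")[["dmax"]],
    interface_pharynx_dmean = mm("interface_pharynx")[["dmean"]],
    interface_pharynx_dmax = mm("interface_pharynx")[["dmax"]])
  structure(out, class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat("metric_set:\n")
  for (nm in names(x)) cat(sprintf("  %-32s %8.3f\n", nm, x[[nm]]))
  invisible(x)
}

#' Convert a metric set (or list of them) to a one-row-per-plan data frame
#' @param x a `metric_set` or a named list of them.
#' @param ... unused.
#' @return A data frame with one column per metric.
#' @export
as.data.frame.metric_set <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}
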