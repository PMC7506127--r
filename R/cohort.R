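LARGE_PRIME <- 7919

# deterministic per-patient seed derived from the master seed
patient_seed <- function(master_seed, patient) {
  (as.numeric(master_seed) + LARGE_PRIME * patient) %% 2147483647
}

# jitter the default phantom geometry for one patient; consumes the
# patient's own seeded stream only
jitter_phantom_spec <- function(seed, base = phantom_spec()) {
  with_seed(seed, {
    r_body <- stats::runif(1, -4, 4)
    r_pgtv <- stats::runif(1, 0.88, 1.12)
    r_gtvnd <- stats::runif(1, 0.88, 1.12)
    r_cav <- stats::runif(1, -1, 1)
    ang <- stats::runif(1, -pi / 8, pi / 8)
    off <- base$target_specs$gtvnd$geom$centers[[1]][1:2]
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    off <- as.numeric(rot %*% off)
    phantom_spec(
      grid_shape = base$grid$shape,
      spacing_mm = base$grid$spacing_mm,
      body_radius_mm = base$body_radius_mm + r_body,
      body_z_range_mm = base$body_z_range_mm,
      larynx_radius_mm = base$cavity_specs[[1]]$radius_mm + r_cav,
      pharynx_radius_mm = base$cavity_specs[[2]]$radius_mm,
      pgtvtb_radius_mm =
        base$target_specs$pgtvtb$geom$radius_mm * r_pgtv,
      gtvnd_radius_mm = base$target_specs$gtvnd$geom$radius_mm * r_gtvnd,
      gtvnd_offset_mm = off,
      ptv_margin_mm = base$target_specs$ptv$margin_mm,
      prescriptions = base$prescriptions,
      seed = as.integer(seed %% 2147483647))
  })
}

#' Generate a synthetic patient cohort with three plan conditions
#'
#' For each patient: a geometry-jittered neck phantom (body and target
#' radii, cavity radius and nodal-target position vary patient to
#' patient), the derived evaluation regions, a base plan dose, and the
#' three condition doses -- `B0` (the base plan), `B15_RECAL` and
#' `B15_REOPT` (field perturbations per
#' [default_perturbation_params()]). Fully reproducible from
#' `master_seed`; per-patient seeds are derived by a fixed offset.
#'
#' @param n_patients number of patients, `>= 1`.
#' @param master_seed integer master seed.
#' @param base_spec the unjittered [phantom_spec()].
#' @param perturbations named list of [perturbation_params()] per
#'   non-`B0` condition; defaults per condition.
#' @param dose_params a [dose_model_params()] list.
#' @return List of class `phantom_cohort`; each element has `patient`,
#'   `seed`, `spec`, `structs` (with derived regions) and `doses`
#'   (named list of [dose_grid()]s per condition).
#' @export
generate_cohort <- function(n_patients, master_seed = 1L,
                            base_spec = phantom_spec(),
                            perturbations = list(
                              B15_RECAL =
                                default_perturbation_params("B15_RECAL"),
                              B15_REOPT =
                                default_perturbation_params("B15_REOPT")),
                            dose_params = dose_model_params()) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L)
    stop("'n_patients' must be >= 1")
  cohort <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    sd_i <- patient_seed(master_seed, i)
    spec <- jitter_phantom_spec(sd_i, base_spec)
    structs <- derive_regions(build_phantom(spec))
    base <- simulate_base_dose(structs, spec$prescriptions,
                               seed = sd_i + 1, params = dose_params)
    doses <- list(B0 = base)
    k <- 1
    for (cond in setdiff(plan_conditions(), "B0")) {
      k <- k + 1
      doses[[cond]] <- apply_field_perturbation(
        base, structs, perturbations[[cond]], cond, seed = sd_i + k)
    }
    cohort[[i]] <- list(patient = i, seed = sd_i, spec = spec,
                        structs = structs, doses = doses)
  }
  structure(cohort, class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d patients x %d conditions on %s\n",
              length(x), length(x[[1]]$doses), format(x[[1]]$structs$grid)))
  invisible(x)
}

#' Extract per-patient, per-condition metrics from a cohort
#'
#' Runs [extract_plan_metrics()] for every patient and condition.
#'
#' @param cohort a [generate_cohort()] result.
#' @param bin_width_Gy DVH resolution.
#' @return Data frame with `patient`, `condition` and one column per
#'   metric.
#' @export
cohort_metrics <- function(cohort, bin_width_Gy = 0.01) {
  rows <- list()
  for (pat in cohort) {
    presc <- pat$spec$prescriptions
    for (cond in names(pat$doses)) {
      ms <- extract_plan_metrics(pat$doses[[cond]], pat$structs, presc,
                                 bin_width_Gy)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(patient = pat$patient, condition = cond,
                   stringsAsFactors = FALSE),
        as.data.frame(ms))
    }
  }
  do.call(rbind, rows)
}

#' Score a cohort metrics table with the PQM
#'
#' @param metrics_df a [cohort_metrics()] data frame.
#' @param table a [pqm_table()].
#' @return Data frame with `patient`, `condition`, one column per
#'   submetric score, and `total`.
#' @export
cohort_scores <- function(metrics_df, table = default_pqm_table()) {
  rows <- lapply(seq_len(nrow(metrics_df)), function(i) {
    res <- pqm_score(as.list(metrics_df[i, , drop = FALSE]), table)
    cbind(data.frame(patient = metrics_df$patient[i],
                     condition = metrics_df$condition[i],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(res$per_metric)),
          data.frame(total = res$total))
  })
  do.call(rbind, rows)
}
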