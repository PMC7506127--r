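#' Define one PQM submetric
#'
#' A submetric maps one dosimetric parameter onto a 0-10 point scale via
#' a clamped linear value function over an evaluation interval
#' `[lower, upper]`. Coverage (Vp) and conformity (CI) score higher for
#' larger values (`direction = "increasing"`); every other parameter
#' (HI, Dmax, Dmean) scores higher for smaller values.
#'
#' @param metric_id identifier matching a [extract_plan_metrics()] name.
#' @param lower,upper evaluation interval limits, `lower < upper`.
#' @param direction `"increasing"` or `"decreasing"`.
#' @param s_min,s_max point range (default 0 to 10), `s_min < s_max`.
#' @return An object of class `pqm_metric_def`.
#' @export
pqm_metric_def <- function(metric_id, lower, upper,
                           direction = c("decreasing", "increasing"),
                           s_min = 0, s_max = 10) {
  direction <- match.arg(direction)
  if (!is.character(metric_id) || length(metric_id) != 1L)
    stop("'metric_id' must be a string")
  if (!is.numeric(lower) || !is.numeric(upper) || !(lower < upper))
    stop("metric '", metric_id, "': lower limit must be < upper limit")
  if (!(s_min < s_max))
    stop("metric '", metric_id, "': s_min must be < s_max")
  structure(list(metric_id = metric_id, lower = lower, upper = upper,
                 direction = direction, s_min = s_min, s_max = s_max),
            class = "pqm_metric_def")
}

#' The default 15-submetric PQM table
#'
#' Evaluation intervals for the 15 submetrics of a hypopharyngeal
#' carcinoma plan: coverage, CI and HI for PGTVtb, GTVnd and PTV, Dmax
#' for brain stem, brain stem PRV, spinal cord and cord PRV, and Dmean
#' for the parotids and normal tissue. Every value function spans 0-10
#' points; the total score therefore spans 0-150.
#'
#' @return An object of class `pqm_table` (list with `defs`, `k = 15`).
#' @export
default_pqm_table <- function() {
  inc <- "increasing"
  dec <- "decreasing"
  defs <- list(
    pqm_metric_def("pgtvtb_v_presc", 80, 95, inc),
    pqm_metric_def("pgtvtb_ci", 0, 1, inc),
    pqm_metric_def("pgtvtb_hi", 0, 0.2, dec),
    pqm_metric_def("gtvnd_v_presc", 80, 95, inc),
    pqm_metric_def("gtvnd_ci", 0, 1, inc),
    pqm_metric_def("gtvnd_hi", 0, 0.2, dec),
    pqm_metric_def("ptv_v_presc", 90, 95, inc),
    pqm_metric_def("ptv_ci", 0.6, 1, inc),
    pqm_metric_def("ptv_hi", 0, 0.3, dec),
    pqm_metric_def("brainstem_dmax", 25, 40, dec),
    pqm_metric_def("brainstem_prv_dmax", 30, 45, dec),
    pqm_metric_def("cord_dmax", 30, 40, dec),
    pqm_metric_def("cord_prv_dmax", 35, 45, dec),
    pqm_metric_def("parotids_dmean", 40, 55, dec),
    pqm_metric_def("nt_dmean", 10, 30, dec))
  pqm_table(defs)
}

#' Assemble a PQM table from metric definitions
#' @param defs list of [pqm_metric_def()] objects with unique ids.
#' @return An object of class `pqm_table`.
#' @export
pqm_table <- function(defs) {
  ids <- vapply(defs, function(d) d$metric_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate metric ids in PQM table")
  structure(list(defs = stats::setNames(defs, ids), k = length(defs)),
            class = "pqm_table")
}

#' @export
print.pqm_table <- function(x, ...) {
  cat(sprintf("pqm_table with %d submetrics:\n", x$k))
  for (d in x$defs)
    cat(sprintf("  %-22s [%g, %g] %s, %g-%g points\n", d$metric_id,
                d$lower, d$upper, d$direction, d$s_min, d$s_max))
  invisible(x)
}

#' Score one submetric
#'
#' Clamped linear value function: for an increasing metric,
#' `S = clamp((M - lower) / (upper - lower), 0, 1) * (s_max - s_min) + s_min`;
#' for a decreasing metric the ramp is mirrored. Values beyond the
#' evaluation interval saturate at the 0- or 10-point plateau.
#'
#' @param value the measured metric value (finite).
#' @param def a [pqm_metric_def()].
#' @return Score in `[def$s_min, def$s_max]`.
#' @export
#' @examples
#' submetric_score(95, pqm_metric_def("v", 80, 95, "increasing"))  # 10
submetric_score <- function(value, def) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("metric '", def$metric_id, "': value must be a finite number")
  frac <- (value - def$lower) / (def$upper - def$lower)
  if (def$direction == "decreasing") frac <- 1 - frac
  def$s_min + min(max(frac, 0), 1) * (def$s_max - def$s_min)
}

#' Total PQM score of a plan
#'
#' Sums the 15 submetric scores; the total ranges from 0 (every metric
#' at or beyond its worst limit) to 150 (every metric at or beyond its
#' best limit). All submetrics are weighted equally.
#'
#' @param metrics a [extract_plan_metrics()] result (or any named list
#'   containing a value for every metric id in `table`).
#' @param table a [pqm_table()]; default [default_pqm_table()].
#' @return An object of class `pqm_result`: list with `per_metric`
#'   (named scores) and `total`.
#' @export
pqm_score <- function(metrics, table = default_pqm_table()) {
  ids <- names(table$defs)
  absent <- ids[!vapply(ids, function(id)
    !is.null(metrics[[id]]), logical(1))]
  if (length(absent))
    stop("metric set lacks values for: ", paste(absent, collapse = ", "))
  s <- vapply(ids, function(id)
    submetric_score(metrics[[id]], table$defs[[id]]), numeric(1))
  structure(list(per_metric = s, total = sum(s)), class = "pqm_result")
}

#' @export
print.pqm_result <- function(x, ...) {
  cat(sprintf("pqm_result: total %.1f / %g\n", x$total,
              sum(vapply(seq_along(x$per_metric), function(i) 10,
                         numeric(1)))))
  for (nm in names(x$per_metric))
    cat(sprintf("  %-22s %5.2f\n", nm, x$per_metric[[nm]]))
  invisible(x)
}

#' Read / write a PQM table as JSON or YAML
#'
#' The on-disk form is a list of records with fields `metric_id`,
#' `lower`, `upper`, `direction`, `s_min`, `s_max`; format chosen by
#' file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path file path.
#' @param table a [pqm_table()] (for writing).
#' @return `read_pqm_table` returns a `pqm_table`; `write_pqm_table`
#'   returns `path` invisibly.
#' @export
read_pqm_table <- function(path) {
  recs <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  defs <- lapply(recs, function(r)
    pqm_metric_def(r$metric_id, r$lower, r$upper, r$direction,
                   if (is.null(r$s_min)) 0 else r$s_min,
                   if (is.null(r$s_max)) 10 else r$s_max))
  pqm_table(defs)
}

#' @rdname read_pqm_table
#' @export
write_pqm_table <- function(table, path) {
  recs <- lapply(unname(table$defs), function(d)
    list(metric_id = d$metric_id, lower = d$lower, upper = d$upper,
         direction = d$direction, s_min = d$s_min, s_max = d$s_max))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(recs, path)
  else
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}
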