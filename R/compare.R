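#' Cohort summary statistics
#'
#' Mean, standard deviation and median of a set of per-patient values.
#' The standard deviation is the population form (divide by `n`), the
#' convention used when reporting cohort plan-quality scores; the sample
#' form (divide by `n - 1`) is available via `sd_type = "sample"`. The
#' median of an even-sized cohort is the midpoint of the two central
#' order statistics. Nothing is rounded here; rounding belongs to the
#' presentation layer.
#'
#' @param values numeric vector, length `>= 1`.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Named list with `mean`, `sd`, `median`, `n`.
#' @export
#' @examples
#' summarize_values(c(88.4, 73.0, 89.7, 82.0, 79.7,
#'                    79.2, 88.8, 72.8, 93.0, 75.8))
summarize_values <- function(values, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!is.numeric(values) || length(values) < 1L || anyNA(values))
    stop("'values' must be a nonempty numeric vector without NAs")
  n <- length(values)
  m <- mean(values)
  ss <- sum((values - m)^2)
  s <- if (n == 1L) 0
  else if (sd_type == "population") sqrt(ss / n)
  else sqrt(ss / (n - 1))
  list(mean = m, sd = s, median = stats::median(values), n = n)
}

#' Paired Wilcoxon signed-rank test, asymptotic (SPSS convention)
#'
#' Tests paired samples via the signed-rank statistic with the normal
#' approximation: differences `d = b - a`, zeros dropped, `|d|` ranked
#' with mid-ranks for ties, and
#' `z = (W+ - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - tie correction)`
#' with no continuity correction, `W+` the positive-rank sum. The
#' two-sided p-value is the normal tail probability -- exactly the
#' asymptotic output SPSS prints. The reported `W` statistic is
#' `min(W+, W-)`.
#'
#' @param a,b equal-length numeric vectors of paired observations.
#' @return An object of class `paired_comparison`: list with
#'   `mean_diff`, `sd_diff` (population), `median_a`, `median_b`,
#'   `W_statistic`, `z`, `p_two_sided`, `n_effective`, and
#'   `approx_unreliable` (`TRUE` when fewer than 5 nonzero differences
#'   remain). With no nonzero differences `z` and `p` are `NA`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (anyNA(a) || anyNA(b)) stop("missing values in paired data")
  d <- b - a
  dnz <- d[d != 0]
  n <- length(dnz)
  res <- list(mean_diff = mean(d),
              sd_diff = summarize_values(d)$sd,
              median_a = stats::median(a),
              median_b = stats::median(b),
              n_effective = n,
              approx_unreliable = n < 5L)
  if (n == 0L) {
    res$W_statistic <- 0
    res$z <- NA_real_
    res$p_two_sided <- NA_real_
    return(structure(res, class = "paired_comparison"))
  }
  r <- rank(abs(dnz))              # mid-ranks for ties
  w_pos <- sum(r[dnz > 0])
  w_neg <- sum(r[dnz < 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(abs(dnz))
  tie_corr <- sum(tie_tab^3 - tie_tab) / 48
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_corr
  if (sigma2 <= 0) {
    res$W_statistic <- min(w_pos, w_neg)
    res$z <- NA_real_
    res$p_two_sided <- NA_real_
    return(structure(res, class = "paired_comparison"))
  }
  z <- (w_pos - mu) / sqrt(sigma2)
  res$W_statistic <- min(w_pos, w_neg)
  res$z <- z
  res$p_two_sided <- 2 * stats::pnorm(-abs(z))
  structure(res, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "paired_comparison: mean diff %.3f, W = %g, z = %.3f, p = %.3f (n = %d)\n",
    x$mean_diff, x$W_statistic,
    ifelse(is.na(x$z), NaN, x$z), ifelse(is.na(x$p_two_sided), NaN,
                                         x$p_two_sided), x$n_effective))
  if (x$approx_unreliable)
    cat("  note: < 5 nonzero differences; normal approximation unreliable\n")
  invisible(x)
}

#' Paired metric differences across plan conditions
#'
#' For every metric column and every contrast between two plan
#' conditions, the per-patient paired differences with mean, population
#' sd, median, and the asymptotic Wilcoxon signed-rank p-value. The sign
#' convention is `second - first` per contrast, so with contrasts like
#' `B15_RECAL - B0` a positive difference marks an increase in the
#' magnetic-field plan.
#'
#' @param metrics_df data frame with columns `patient`, `condition`, and
#'   one numeric column per metric.
#' @param contrasts list of 2-element character vectors
#'   `c(first, second)`; default the three contrasts among
#'   `B0`, `B15_RECAL`, `B15_REOPT`.
#' @return Data frame with columns `metric`, `contrast`, `mean_diff`,
#'   `sd_diff`, `median_diff`, `p_value`, `n`.
#' @export
paired_difference_table <- function(
    metrics_df,
    contrasts = list(c("B0", "B15_RECAL"),
                     c("B0", "B15_REOPT"),
                     c("B15_RECAL", "B15_REOPT"))) {
  if (!all(c("patient", "condition") %in% names(metrics_df)))
    stop("'metrics_df' needs 'patient' and 'condition' columns")
  metric_cols <- setdiff(names(metrics_df), c("patient", "condition"))
  out <- list()
  for (ct in contrasts) {
    a_df <- metrics_df[metrics_df$condition == ct[1], , drop = FALSE]
    b_df <- metrics_df[metrics_df$condition == ct[2], , drop = FALSE]
    pats <- sort(unique(metrics_df$patient))
    if (!setequal(a_df$patient, pats) || !setequal(b_df$patient, pats))
      stop("incomplete paired data for contrast ",
           ct[2], " - ", ct[1])
    a_df <- a_df[match(pats, a_df$patient), , drop = FALSE]
    b_df <- b_df[match(pats, b_df$patient), , drop = FALSE]
    for (mc in metric_cols) {
      cmp <- wilcoxon_signed_rank(a_df[[mc]], b_df[[mc]])
      d <- b_df[[mc]] - a_df[[mc]]
      out[[length(out) + 1L]] <- data.frame(
        metric = mc,
        contrast = paste(ct[2], "-", ct[1]),
        mean_diff = cmp$mean_diff,
        sd_diff = cmp$sd_diff,
        median_diff = stats::median(d),
        p_value = cmp$p_two_sided,
        n = length(d),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Voxel-wise dose-difference map
#'
#' `(b - a)` per voxel in centigray, with a symmetric clip (default
#' +/- 700 cGy) applied for rendering; the unclipped map is returned
#' alongside.
#'
#' @param dose_a,dose_b [dose_grid()] objects on the same grid.
#' @param clip_cGy rendering clip in cGy, `> 0`.
#' @return List with `cgy` (clipped 3-D array), `cgy_raw` (unclipped),
#'   `clip_cGy` and `grid`.
#' @export
dose_difference_map <- function(dose_a, dose_b, clip_cGy = 700) {
  stop_if_grid_mismatch(dose_a$grid, dose_b$grid)
  if (!is.numeric(clip_cGy) || clip_cGy <= 0)
    stop("'clip_cGy' must be > 0")
  raw <- (dose_b$values - dose_a$values) * 100
  list(cgy = pmin(pmax(raw, -clip_cGy), clip_cGy),
       cgy_raw = raw, clip_cGy = clip_cGy, grid = dose_a$grid)
}

#' Presentation rounding: half away from zero
#'
#' Clinical reports round 0.05 up to 0.1 (and -0.05 down to -0.1),
#' unlike R's banker's rounding. Use for presentation only; all
#' statistics are computed at full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
#' @examples
#' round_half_away(80.85, 1)  # 80.9, where round() gives 80.8
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Published plan-quality scores of a 10-patient hypopharyngeal cohort
#'
#' Per-patient total PQM scores (0-150 scale) of three plan conditions
#' for a reference cohort of 10 hypopharyngeal-carcinoma patients: the
#' plan optimised without a magnetic field (`B0`), the same segments and
#' monitor units recalculated at 1.5 T (`B15_RECAL`), and the plan
#' reoptimised at 1.5 T with the original cost function (`B15_REOPT`).
#' Useful as a worked example for [summarize_values()],
#' [wilcoxon_signed_rank()] and [paired_difference_table()].
#'
#' @return Data frame with columns `patient`, `B0`, `B15_RECAL`,
#'   `B15_REOPT`.
#' @export
reference_cohort_scores <- function() {
  data.frame(
    patient = 1:10,
    B0 = c(88.4, 73.0, 89.7, 82.0, 79.7, 79.2, 88.8, 72.8, 93.0, 75.8),
    B15_RECAL = c(72.8, 58.1, 81.6, 65.6, 75.9, 62.1, 64.9, 52.2, 81.7,
                  65.7),
    B15_REOPT = c(81.6, 67.8, 90.0, 81.3, 79.8, 76.4, 82.2, 74.1, 92.6,
                  74.7))
}
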