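test_that("the default table encodes the 15 clinical submetrics", {
  tab <- default_pqm_table()
  expect_equal(tab$k, 15)
  expect_length(tab$defs, 15)
  nt <- tab$defs$nt_dmean
  expect_equal(nt$lower, 10)
  expect_equal(nt$upper, 30)
  expect_equal(tab$defs$cord_dmax$lower, 30)
  expect_equal(tab$defs$cord_dmax$upper, 40)
  expect_equal(tab$defs$ptv_v_presc$lower, 90)
  dirs <- vapply(tab$defs, function(d) d$direction, character(1))
  inc <- grepl("v_presc$|_ci$", names(dirs))
  expect_true(all(dirs[inc] == "increasing"))
  expect_true(all(dirs[!inc] == "decreasing"))
  expect_true(all(vapply(tab$defs, function(d) d$s_min == 0 &&
                           d$s_max == 10, logical(1))))
})

test_that("submetric value functions hit the documented anchor points", {
  v <- pqm_metric_def("pgtvtb_v_presc", 80, 95, "increasing")
  expect_equal(submetric_score(95, v), 10)
  expect_equal(submetric_score(80, v), 0)
  cord <- pqm_metric_def("cord_dmax", 30, 40, "decreasing")
  expect_equal(submetric_score(40, cord), 0)
  expect_equal(submetric_score(30, cord), 10)
  ci <- pqm_metric_def("ptv_ci", 0.6, 1, "increasing")
  expect_equal(submetric_score(0.8, ci), 5)
  par <- pqm_metric_def("parotids_dmean", 40, 55, "decreasing")
  expect_equal(submetric_score(60, par), 0)   # clamped beyond the limit
  expect_error(submetric_score(NaN, par), "finite")
})

test_that("total score spans 0-150 with linear midpoints", {
  tab <- default_pqm_table()
  best <- lapply(tab$defs, function(d)
    if (d$direction == "increasing") d$upper else d$lower)
  worst <- lapply(tab$defs, function(d)
    if (d$direction == "increasing") d$lower else d$upper)
  mid <- lapply(tab$defs, function(d) (d$lower + d$upper) / 2)
  expect_equal(pqm_score(best, tab)$total, 150)
  expect_equal(pqm_score(worst, tab)$total, 0)
  expect_equal(pqm_score(mid, tab)$total, 75)
  expect_error(pqm_score(best[-1], tab), "lacks")
})

test_that("scores are bounded, monotone, affine inside the interval", {
  set.seed(505)
  tab <- default_pqm_table()
  for (rep in 1:10000) {
    d <- tab$defs[[sample.int(15, 1)]]
    span <- d$upper - d$lower
    x <- stats::runif(1, d$lower - 2 * span, d$upper + 2 * span)
    s <- submetric_score(x, d)
    expect_gte(s, 0)
    expect_lte(s, 10)
    # monotone in the clinically better direction
    eps <- span * 1e-3
    s2 <- submetric_score(x + eps, d)
    if (d$direction == "increasing") expect_gte(s2, s - 1e-12)
    else expect_lte(s2, s + 1e-12)
  }
  # affine on the inside: S(alpha) linear in alpha
  for (d in tab$defs) {
    al <- c(0.2, 0.5, 0.8)
    s <- vapply(al, function(a)
      submetric_score(a * d$lower + (1 - a) * d$upper, d), numeric(1))
    expect_equal(s[2] - s[1], s[3] - s[2], tolerance = 1e-9)
  }
})

test_that("the total is invariant under submetric reordering", {
  tab <- default_pqm_table()
  set.seed(9)
  shuffled <- pqm_table(sample(unname(tab$defs)))
  vals <- lapply(tab$defs, function(d) stats::runif(1, d$lower, d$upper))
  expect_equal(pqm_score(vals, tab)$total,
               pqm_score(vals, shuffled)$total)
})

test_that("PQM tables round-trip through JSON and YAML", {
  tab <- default_pqm_table()
  for (ext in c("json", "yaml")) {
    p <- tempfile(fileext = paste0(".", ext))
    write_pqm_table(tab, p)
    expect_equal(read_pqm_table(p), tab)
    unlink(p)
  }
  # the shipped default table file matches the in-code default
  shipped <- system.file("extdata", "pqm_table_default.json",
                         package = "mrplanqa")
  expect_true(nzchar(shipped))
  expect_equal(read_pqm_table(shipped), tab)
})

test_that("invalid metric intervals are rejected by name", {
  expect_error(pqm_metric_def("cord_dmax", 40, 30), "cord_dmax")
  expect_error(pqm_table(list(pqm_metric_def("a", 0, 1, "increasing"),
                              pqm_metric_def("a", 0, 2, "increasing"))),
               "duplicate")
})
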