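test_that("summary statistics use the population sd and midpoint median", {
  s <- summarize_values(c(1, 1, 3, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)           # population form
  expect_equal(s$median, 2)
  expect_equal(summarize_values(c(1, 1, 3, 3), sd_type = "sample")$sd,
               sqrt(4 / 3))
  one <- summarize_values(5)
  expect_equal(one$sd, 0)
  expect_equal(one$median, 5)
  expect_error(summarize_values(numeric(0)), "nonempty")

  # permutation invariance and population <= sample sd
  set.seed(66)
  x <- stats::rnorm(11)
  sp <- summarize_values(sample(x))
  expect_equal(sp$mean, mean(x))
  expect_equal(sp$sd, summarize_values(x)$sd)
  expect_lte(sp$sd, summarize_values(x, "sample")$sd)
})

test_that("signed-rank test follows the SPSS asymptotic convention", {
  sc <- reference_cohort_scores()
  cmp <- wilcoxon_signed_rank(sc$B0, sc$B15_RECAL)
  expect_equal(cmp$W_statistic, 0)       # all ten differences one-signed
  expect_equal(cmp$z, -2.803, tolerance = 1e-3)
  expect_equal(cmp$n_effective, 10)

  cmp2 <- wilcoxon_signed_rank(sc$B0, sc$B15_REOPT)
  expect_equal(cmp2$W_statistic, 9)
  expect_equal(cmp2$z, -1.886, tolerance = 1e-3)

  # cross-check the asymptotic p against the base-R implementation of
  # the same approximation (no continuity correction, no exact mode)
  set.seed(77)
  for (rep in 1:10) {
    a <- stats::rnorm(12)
    b <- a + stats::rnorm(12, 0.3)
    ours <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(b, a, paired = TRUE, exact = FALSE,
                              correct = FALSE)
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-10)
  }
})

test_that("asymptotic p tracks the exact permutation distribution", {
  # complete check over every achievable signed-rank statistic for
  # tie-free data: at n >= 10 the tie-free normal approximation stays
  # within 0.05 of the exact 2^n sign-enumeration p everywhere (the
  # worst case over W at n = 10 is 0.0499; smaller n can deviate by up
  # to ~0.10, which is why the implementation flags small samples)
  for (n in c(10, 12)) {
    for (w_target in 0:(n * (n + 1) / 2)) {
      # realise W+ = w_target with ranks 1..n: greedy subset sum
      remaining <- w_target
      pos <- logical(n)
      for (r in n:1) {
        if (remaining >= r) {
          pos[r] <- TRUE
          remaining <- remaining - r
        }
      }
      d <- ifelse(pos, 1, -1) * (1:n)
      ours <- wilcoxon_signed_rank(rep(0, n), d)
      expect_equal(sum((1:n)[pos]), w_target)
      expect_lt(abs(ours$p_two_sided -
                      exact_signed_rank_p(rep(0, n), d)), 0.05)
    }
  }
})

test_that("signed-rank symmetries hold", {
  set.seed(99)
  a <- stats::rnorm(10, 50, 5)
  b <- a + stats::rnorm(10, 1)
  ab <- wilcoxon_signed_rank(a, b)
  ba <- wilcoxon_signed_rank(b, a)
  expect_equal(ab$W_statistic, ba$W_statistic)
  expect_equal(ab$p_two_sided, ba$p_two_sided)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$mean_diff, -ba$mean_diff)
  shifted <- wilcoxon_signed_rank(a + 100, b + 100)
  expect_equal(shifted$p_two_sided, ab$p_two_sided)
  expect_equal(shifted$W_statistic, ab$W_statistic)

  same <- wilcoxon_signed_rank(a, a)
  expect_equal(same$n_effective, 0)
  expect_true(is.na(same$p_two_sided))
  expect_true(same$approx_unreliable)
})

test_that("presentation rounding goes half away from zero", {
  expect_equal(round_half_away(80.85, 1), 80.9)
  expect_equal(round_half_away(-0.05, 1), -0.1)
  expect_equal(round_half_away(0.0055, 3), 0.006)
  expect_equal(round_half_away(2.4), 2)
})

test_that("paired difference tables carry the increase-at-1.5T sign", {
  sc <- reference_cohort_scores()
  long <- do.call(rbind, lapply(c("B0", "B15_RECAL", "B15_REOPT"),
                                function(cc) data.frame(
                                  patient = sc$patient, condition = cc,
                                  score = sc[[cc]])))
  tab <- paired_difference_table(long)
  expect_equal(nrow(tab), 3)  # one metric x three contrasts
  rc <- tab[tab$contrast == "B15_RECAL - B0", ]
  expect_lt(rc$mean_diff, 0)  # recalculated plans score lower
  expect_equal(rc$mean_diff,
               mean(sc$B15_RECAL) - mean(sc$B0), tolerance = 1e-12)

  # identical conditions: zero differences, degenerate p
  long0 <- long
  long0$score[long0$condition != "B0"] <- rep(sc$B0, 2)
  tab0 <- paired_difference_table(long0)
  expect_true(all(tab0$mean_diff == 0))
  expect_true(all(is.na(tab0$p_value)))

  expect_error(paired_difference_table(long[-1, ]), "incomplete")
})

test_that("dose difference maps are antisymmetric and clip correctly", {
  g <- voxel_grid(c(4, 4, 2))
  a <- dose_grid(array(stats::runif(32, 0, 60), g$shape), g)
  b <- dose_grid(a$values + 1, g)
  m <- dose_difference_map(a, b)
  expect_true(all(abs(m$cgy_raw - 100) < 1e-9))  # +1 Gy = +100 cGy
  m_ab <- dose_difference_map(a, b)
  m_ba <- dose_difference_map(b, a)
  expect_equal(m_ab$cgy_raw, -m_ba$cgy_raw)

  big <- dose_grid(a$values + 10, g)
  mb <- dose_difference_map(a, big)
  expect_true(all(mb$cgy == 700))      # saturates at the render clip
  expect_true(all(abs(mb$cgy_raw - 1000) < 1e-9))
  same <- dose_difference_map(a, a)
  expect_true(all(same$cgy_raw == 0))
})
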