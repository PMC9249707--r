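# Observer-study statistics: Welch t, chi-square, Wilson intervals,
# truncation rounding, Fleiss kappa, rater table.

test_that("Welch t-test matches hand-computed values and conventions", {
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 4, p = 1))
  # hand Welch formulas: t = -2 / sqrt(5/3 / 4 * 2), Satterthwaite df = 6
  ht <- welch_t_test(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(ht$t, -2 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(ht$t, -2.19089, tolerance = 1e-5)
  expect_equal(ht$df, 6)
  expect_equal(ht$p, 2 * pt(-2 / sqrt(5 / 6), 6), tolerance = 1e-12)
  expect_equal(ht$p, 0.071, tolerance = 1e-3)
  expect_equal(welch_t_test(c(5, 5, 5), c(5, 5))$p, 1)
  expect_error(welch_t_test(c(5, 5, 5), c(4, 4)), "constant")
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
})

test_that("chi-square on 2x2 tables matches the Pearson formula", {
  flat <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  ht <- chi_square_2x2(matrix(c(20, 10, 10, 20), 2))
  expect_equal(ht$statistic, 20 / 3, tolerance = 1e-4)
  expect_equal(ht$p, 0.00982, tolerance = 1e-3)

  pooled <- chi_square_2x2(matrix(c(26, 189, 163, 42), 2))
  expect_lt(pooled$p, 0.001)

  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "marginals")
})

test_that("chi-square is invariant under transpose and row/column swaps", {
  set.seed(90)
  for (i in 1:25) {
    tab <- matrix(sample(1:50, 4, replace = TRUE), 2)
    s <- chi_square_2x2(tab)$statistic
    expect_equal(chi_square_2x2(t(tab))$statistic, s, tolerance = 1e-12)
    expect_equal(chi_square_2x2(tab[2:1, 2:1])$statistic, s,
                 tolerance = 1e-12)
  }
})

test_that("Wilson intervals match the closed form and an independent route", {
  ci <- wilson_ci(8, 10)
  expect_equal(unname(ci), c(0.4901, 0.9433), tolerance = 1e-4)

  # independent route: prop.test without continuity correction
  for (k in c(0, 1, 5, 8, 10)) {
    pt <- stats::prop.test(k, 10, correct = FALSE)
    expect_equal(unname(wilson_ci(k, 10)), as.numeric(pt$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("Wilson intervals contain the estimate, stay in [0,1] and shrink in n", {
  for (p in c(0.1, 0.5, 0.818, 1)) {
    widths <- vapply(c(10, 40, 160, 640), function(n) {
      k <- round(p * n)
      ci <- wilson_ci(k, n)
      expect_gte(ci[["lower"]], 0)
      expect_lte(ci[["upper"]], 1)
      expect_lte(ci[["lower"]], k / n)
      expect_gte(ci[["upper"]], k / n)
      ci[["upper"]] - ci[["lower"]]
    }, numeric(1))
    expect_true(all(diff(widths) < 0))
  }
})

test_that("percentages are truncated toward zero to one decimal", {
  expect_equal(percent_trunc(13 / 27), 48.1)
  expect_equal(percent_trunc(26 / 33), 78.7)
  expect_equal(percent_trunc(0.4545), 45.4)
  expect_equal(percent_trunc(0.5185), 51.8)
  expect_equal(percent_trunc(0), 0)
  expect_equal(percent_trunc(1), 100)
  expect_error(percent_trunc(1.2), "\\[0, 1\\]")
})

test_that("diagnostic metrics reproduce the pooled observer row", {
  dm <- diagnostic_metrics(tp = 189, fn = 42, fp = 26, tn = 163)
  expect_equal(dm$sensitivity, 189 / 231)
  expect_equal(dm$specificity, 163 / 189)
  expect_equal(unname(dm$display),
               c(81.8, 76.3, 86.2, 86.2, 80.6, 90.4))

  perfect <- diagnostic_metrics(tp = 33, fn = 0, fp = 0, tn = 27)
  expect_equal(perfect$display[["sensitivity"]], 100)
  expect_equal(perfect$display[["specificity"]], 100)

  expect_error(diagnostic_metrics(0, 0, 5, 5), "tp \\+ fn")
})

test_that("swapping the positive and negative labels swaps sens and spec", {
  set.seed(61)
  for (i in 1:20) {
    cnt <- sample(1:100, 4, replace = TRUE)
    a <- diagnostic_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    b <- diagnostic_metrics(tp = cnt[4], fn = cnt[3], fp = cnt[2],
                            tn = cnt[1])
    expect_equal(b$sensitivity, a$specificity)
    expect_equal(b$specificity, a$sensitivity)
    expect_equal(unname(b$sens_ci), unname(a$spec_ci))
  }
})

test_that("Fleiss kappa matches hand calculations and conventions", {
  # 3 raters, 4 items, unanimous, both categories present
  calls <- rbind(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0), c(0, 0, 0))
  expect_equal(fleiss_kappa(calls)$kappa, 1)

  # observed agreement 0.5 equals chance agreement 0.5
  calls <- rbind(c(1, 1), c(0, 0), c(1, 0), c(0, 1))
  expect_equal(fleiss_kappa(calls)$kappa, 0)

  # single-category degenerate case: perfect agreement -> kappa 1
  expect_equal(fleiss_kappa(matrix(1L, 4, 3))$kappa, 1)

  expect_error(fleiss_kappa(matrix(c(1, NA, 0, 1), 2)), "complete")
  expect_error(fleiss_kappa(matrix(1L, 1, 3)), ">= 2 items")
})

test_that("Fleiss kappa equals the pooled-marginal hand oracle for 2 raters", {
  # independent oracle: observed agreement vs chance from pooled marginals
  two_rater_kappa <- function(calls) {
    po <- mean(calls[, 1] == calls[, 2])
    p1 <- mean(calls)
    pe <- p1^2 + (1 - p1)^2
    (po - pe) / (1 - pe)
  }
  set.seed(333)
  tried <- 0
  while (tried < 50) {
    calls <- matrix(rbinom(2 * sample(4:12, 1), 1, runif(1, 0.2, 0.8)),
                    ncol = 2)
    p1 <- mean(calls)
    if (p1 %in% c(0, 1)) next
    tried <- tried + 1
    k <- suppressWarnings(fleiss_kappa(calls)$kappa)
    expect_equal(k, two_rater_kappa(calls), tolerance = 1e-12)
  }
})

test_that("kappa bands follow the Landis-Koch cut points", {
  expect_identical(interpret_kappa(0.53), "moderate")
  expect_identical(interpret_kappa(0.20), "low")
  expect_identical(interpret_kappa(0.21), "fair")
  expect_identical(interpret_kappa(0.61), "substantial")
  expect_identical(interpret_kappa(1.0), "almost perfect")
  expect_warning(band <- interpret_kappa(-0.2), "negative")
  expect_identical(band, "low")
  expect_error(interpret_kappa(1.5), "\\[-1, 1\\]")
})

test_that("simulated observer panels put kappa = 0.53 inside the central band", {
  # the item-level rating matrix behind the published kappa is unavailable;
  # check that panels drawn from the per-rater operating points cover it
  set.seed(108)
  labels <- rep(c("benign", "scc"), times = c(27, 33))
  profiles <- observer_rater_profiles()
  kappas <- replicate(400, {
    fleiss_kappa(simulate_raters(labels, profiles))$kappa
  })
  qs <- quantile(kappas, c(0.025, 0.975))
  expect_lt(qs[[1]], 0.53)
  expect_gt(qs[[2]], 0.53)
  expect_identical(interpret_kappa(median(kappas)), "moderate")
})

test_that("the rater table recomputes the observer study from counts", {
  tab <- rater_table(cle_observer_counts())
  expect_equal(nrow(tab), 8)
  all_row <- tab[tab$rater == "All", ]
  expect_equal(all_row$scc_inhom, 189)
  expect_equal(all_row$benign_inhom, 26)
  expect_equal(all_row$sensitivity_pct, 81.8)
  expect_equal(all_row$specificity_pct, 86.2)
  # per-rater sensitivities recomputed from counts (printed-typo rows
  # intentionally differ from some published display values)
  expect_equal(tab$sensitivity_pct[tab$rater == "rater1"], 45.4)
  expect_equal(tab$sensitivity_pct[tab$rater == "rater7"], 90.9)
  expect_true(all(tab$chisq_p < 0.001, na.rm = TRUE))

  # single perfect rater
  rm <- rating_matrix(matrix(c(0L, 0L, 1L, 1L), 4, 1),
                      c("benign", "benign", "scc", "scc"))
  one <- rater_table(rm)
  expect_equal(one$sensitivity_pct, c(100, 100))
  expect_equal(one$specificity_pct, c(100, 100))
})

test_that("pooled counts equal the sum of per-rater counts", {
  set.seed(272)
  for (i in 1:10) {
    labels <- sample(c("benign", "scc"), 30, replace = TRUE,
                     prob = c(0.45, 0.55))
    if (length(unique(labels)) < 2) next
    rm <- simulate_raters(labels, observer_rater_profiles()[1:3])
    tab <- rater_table(rm)
    per <- tab[tab$rater != "All", ]
    all_row <- tab[tab$rater == "All", ]
    expect_equal(all_row$benign_inhom, sum(per$benign_inhom))
    expect_equal(all_row$scc_inhom, sum(per$scc_inhom))
    expect_equal(all_row$n_benign, sum(per$n_benign))
    expect_equal(all_row$n_scc, sum(per$n_scc))
  }
})
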