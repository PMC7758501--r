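test_that("Kruskal-Wallis reproduces hand-computed H and degenerate cases", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2, tolerance = 1e-10)
  expect_equal(kw$df, 2)
  expect_equal(kw$p, stats::pchisq(7.2, 2, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5)))$H, 0)
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5)))$p, 1)

  # H depends only on the pooled ranks, not within-group ordering
  a <- c(3.2, 1.5, 9.9, 4.4); b <- c(2.2, 8.8, 0.1)
  expect_equal(kruskal_wallis(list(a, b))$H,
               kruskal_wallis(list(sample(a), rev(b)))$H)
})

test_that("exact Mann-Whitney agrees with complete enumeration", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$mode_used, "exact")

  same <- suppressMessages(mann_whitney_u(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(same$p, 1.0)

  set.seed(13)
  for (i in 1:30) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    x <- stats::rnorm(na); y <- stats::rnorm(nb, mean = stats::runif(1, -1, 1))
    mw <- mann_whitney_u(x, y)
    orc <- mw_exact_oracle(x, y)
    expect_equal(mw$U, orc$U)
    expect_equal(mw$p, orc$p, tolerance = 1e-12)
  }
})

test_that("tied data fall back from exact to the normal approximation with a notice", {
  expect_message(mw <- mann_whitney_u(c(1, 2, 2), c(2, 3, 4), mode = "exact"),
                 "tied")
  expect_equal(mw$mode_used, "normal")
  expect_true(mw$ties)
  auto <- suppressMessages(mann_whitney_u(c(1, 2, 2), c(2, 3, 4)))
  expect_equal(auto$mode_used, "normal")
})

test_that("Bonferroni adjustment multiplies, caps, and respects the strict threshold", {
  expect_equal(bonferroni_adjust(0.004, 10), 0.04)
  expect_equal(bonferroni_adjust(0.2, 10), 1.0)
  # raw p exactly at the 0.005 boundary is NOT significant at alpha 0.05
  expect_false(bonferroni_adjust(0.005, 10) < 0.05)
  expect_true(bonferroni_adjust(0.00499, 10) < 0.05)

  p <- c(0.001, 0.01, 0.04)
  expect_true(all(diff(bonferroni_adjust(p, 10)) >= 0))
  expect_true(all(bonferroni_adjust(p, 20) >= bonferroni_adjust(p, 10)))
  expect_error(bonferroni_adjust(p, 2), "smaller")
  expect_error(bonferroni_adjust(0.1, 0), ">= 1")
})

test_that("two-group Kruskal-Wallis ranks datasets like the exact Mann-Whitney", {
  set.seed(5)
  kw_p <- mw_p <- numeric(12)
  for (i in 1:12) {
    x <- stats::rnorm(6); y <- stats::rnorm(6, mean = stats::runif(1, 0, 2))
    kw_p[i] <- kruskal_wallis(list(x, y))$p
    mw_p[i] <- mann_whitney_u(x, y)$p
  }
  expect_equal(order(kw_p), order(mw_p))
})

test_that("the cascade flags programmed effects, skips missing groups, and audits", {
  design <- cohort_design(ages = c(3, 19), n_per_cell = 4)
  tab <- simulate_metrics_table(design, seed = 31)
  cmp <- run_cascade(tab)
  expect_true(all(cmp$p_adj == pmin(1, cmp$p_raw * cmp$m)))
  expect_true(all(cmp$significant == (cmp$p_adj < 0.05)))
  expect_true(all(c("H", "p_omnibus", "U", "n_a", "n_b", "mode", "ties")
                  %in% names(cmp)))
  # the programmed dorsolateral striosome effect at the earliest age is found
  dl3 <- cmp[cmp$metric == "strio_intensity" & cmp$age_months == 3 &
               cmp$sector == "dorsolateral" & cmp$level == "rostral", ]
  expect_true(dl3$significant)
  # matrix is null at the earliest age
  mx3 <- cmp[cmp$metric == "matrix_intensity" & cmp$age_months == 3 &
               cmp$level == "rostral", ]
  expect_true(all(!mx3$significant | mx3$p_raw > 0.0001))

  solo <- tab[tab$genotype == "WT", ]
  w <- capture_warnings(cmp2 <- run_cascade(solo))
  expect_true(all(grepl("fewer than 2 groups", w)) && length(w) > 0)
  expect_equal(nrow(cmp2), 0)
})

test_that("flagged-comparison count grows monotonically with effect size", {
  pc <- power_curve(multipliers = c(0.25, 1, 2), n_rep = 20, seed = 17,
                    design = cohort_design(ages = c(3, 19), n_per_cell = 4,
                                           levels = "rostral"))
  expect_true(all(diff(pc$n_flagged) >= 0))
  expect_gt(pc$n_flagged[3], pc$n_flagged[1])
})
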