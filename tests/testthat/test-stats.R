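test_that("paired tests behave at analytic cases", {
  pre <- c(1, 2, 3, 4)
  post <- pre + c(1, -1, 2, -2) # mean difference zero
  r <- paired_tests(pre, post, "t")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # identical samples: all differences zero -> degenerate
  w <- paired_tests(pre, pre, "wilcoxon")
  expect_true(w$degenerate)
  expect_true(is.na(w$p_value))
  expect_error(paired_tests(1, 1), "at least 2")
  expect_error(paired_tests(1:4, 1:5), "paired")
})

test_that("the simulated ischemic thickening decrease is overwhelmingly
           significant", {
  # effect ~2 mm at SD 0.5 over 100 ischemic pairs: power ~ 1
  params <- segment_sim_params(n_subjects = 20, seed = 5L)
  d <- sample_segment_dataset(params)
  isch <- d[d$class == "ischemic", ]
  pre <- isch$wall_thickening_mm[isch$phase == "pre"]
  post <- isch$wall_thickening_mm[isch$phase == "post"]
  expect_equal(length(pre), 100)
  expect_lt(paired_tests(pre, post, "t")$p_value, 0.001)
  expect_lt(pre_post_w <- paired_tests(pre, post, "wilcoxon")$p_value, 0.001)
})

test_that("roc_scan separates separable classes and respects direction", {
  r <- roc_scan(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
    direction = "below"
  )
  expect_gt(r$optimal_threshold, 2)
  expect_lt(r$optimal_threshold, 3)
  expect_equal(r$optimal_sensitivity, 1)
  expect_equal(r$optimal_specificity, 1)
  r2 <- roc_scan(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE),
    direction = "above"
  )
  expect_gt(r2$optimal_threshold, 2)
  expect_lt(r2$optimal_threshold, 3)
  expect_equal(r2$optimal_sensitivity, 1)
  expect_error(roc_scan(1:4, rep(TRUE, 4)), "class error")
})

test_that("roc curve stays in the unit square with the right endpoints", {
  set.seed(6)
  v <- rnorm(200)
  lab <- v + rnorm(200) < 0
  r <- roc_scan(v, lab, direction = "below")
  expect_true(all(r$sensitivity >= 0 & r$sensitivity <= 1))
  expect_true(all(r$specificity >= 0 & r$specificity <= 1))
  # threshold at the minimum: nothing called positive
  expect_equal(r$sensitivity[1], 0)
  expect_equal(r$specificity[1], 1)
  # near the maximum almost everything is called positive
  expect_gt(r$sensitivity[1000], 0.95)
  # monotone sensitivity in the threshold for below-positive calls
  expect_true(all(diff(r$sensitivity) >= 0))
})

test_that("the 1000-step scan agrees with the exhaustive-threshold oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    # values on a lattice coarser than the scan grid
    v <- sample(seq(0, 10, by = 0.05), n, replace = TRUE)
    lab <- rep(FALSE, n)
    lab[sample(n, sample(seq_len(n - 1), 1))] <- TRUE
    dir <- sample(c("below", "above"), 1)
    r <- roc_scan(v, lab, n_steps = 1000, direction = dir)
    o <- roc_oracle(v, lab, direction = dir)
    expect_equal(r$optimal_sensitivity + r$optimal_specificity - 1, o$youden)
    expect_equal(r$optimal_sensitivity, o$sensitivity)
    expect_equal(r$optimal_specificity, o$specificity)
  }
})

test_that("labels independent of the values give a near-zero Youden optimum", {
  set.seed(8)
  v <- rnorm(2000)
  lab <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  r <- roc_scan(v, lab, direction = "below")
  expect_lt(r$optimal_sensitivity + r$optimal_specificity - 1, 0.15)
})

test_that("roc_scan optimum is confirmed by an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(9)
  v <- c(rnorm(60, 1), rnorm(80, 2.5))
  lab <- rep(c(TRUE, FALSE), c(60, 80))
  r <- roc_scan(v, lab, direction = "below")
  pr <- pROC::roc(response = lab, predictor = v, direction = ">",
    levels = c(FALSE, TRUE), quiet = TRUE
  )
  best <- pROC::coords(pr, "best", best.method = "youden",
    ret = c("sensitivity", "specificity"), transpose = FALSE
  )
  expect_equal(
    r$optimal_sensitivity + r$optimal_specificity,
    max(best$sensitivity + best$specificity),
    tolerance = 1e-6
  )
})

test_that("adjacent band sensitivity/specificity follow the definition", {
  v <- c(1.0, 1.8, 1.9, 2.5, 3.0)
  adj <- c(FALSE, TRUE, TRUE, FALSE, FALSE)
  b <- adjacent_band(1.4, 2.1, v, adj)
  expect_equal(b$sensitivity, 1)
  expect_equal(b$specificity, 1)
  expect_error(adjacent_band(2.1, 1.4, v, adj), "band error")
})

test_that("threshold table orders cutoffs and penalizes the middle class", {
  set.seed(10)
  params <- segment_sim_params(n_subjects = 30, seed = 10L)
  d <- sample_segment_dataset(params)
  rt <- roc_table(d[d$phase == "post", ])
  tab <- rt$table
  expect_equal(nrow(tab), 9) # 3 metrics x (ischemic, adjacent band, remote)
  # band ordering: ischemic cutoff below the remote cutoff for thickening
  wt <- tab[tab$metric == "wall_thickening_mm", ]
  expect_lt(
    wt$threshold[wt$comparison == "ischemic"],
    wt$threshold[wt$comparison == "remote"]
  )
  # middle-class band detection is worse than either binary comparison
  expect_lt(
    wt$sensitivity_pct[wt$comparison == "adjacent"],
    min(wt$sensitivity_pct[wt$comparison != "adjacent"])
  )
})
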