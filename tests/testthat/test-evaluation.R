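# Metrics, confusion matrices, folds, and the A/B protocols.

test_that("perfect prediction zeroes every error metric", {
  y <- c(0.2, 0.5, 0.9, 0.4)
  m <- regression_metrics(y, y)
  expect_equal(unname(unlist(m[c("mse", "rmse", "mae", "rse")])), rep(0, 4))
  expect_equal(m$r2_pct, 100)
  expect_equal(m$r2_conventional_pct, 100)
})

test_that("the 3-point hand-computed example matches to 1e-9", {
  m <- regression_metrics(c(0, 1, 2), c(0, 1, 3))
  expect_equal(m$mse, 1 / 3, tolerance = 1e-9)
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-9)
  expect_equal(m$mae, 1 / 3, tolerance = 1e-9)
  expect_equal(m$rse, sqrt(1 / 2), tolerance = 1e-9)
  expect_equal(m$r2_pct, (1 - sqrt(1 / 2)) * 100, tolerance = 1e-9)
})

test_that("metric identities hold on random data", {
  withr::with_seed(1, {
    for (i in 1:5) {
      y <- rnorm(50); yh <- y + rnorm(50, sd = 0.3)
      m <- regression_metrics(y, yh)
      expect_equal(m$rmse, sqrt(m$mse))
      expect_lte(m$mae, m$rmse + 1e-12)
    }
  })
})

test_that("the printed RSE convention scales with sqrt(k), not k", {
  y <- c(0.1, 0.7, 0.3, 0.9); yh <- c(0.2, 0.6, 0.4, 0.7)
  k <- 4
  m1 <- regression_metrics(y, yh)
  mk <- regression_metrics(k * y, k * yh)
  expect_equal(mk$mae, k * m1$mae)
  expect_equal(mk$rmse, k * m1$rmse)
  expect_equal(mk$rse, sqrt(k) * m1$rse)
  expect_equal(mk$r2_conventional_pct, m1$r2_conventional_pct)
})

test_that("constant observations are a degenerate input", {
  expect_error(regression_metrics(rep(1, 5), rnorm(5)), "constant")
})

test_that("confusion matrices count exactly", {
  y <- c(0, 0, 0, 1, 1, 1, 1, 0, 1, 0)
  expect_equal(confusion(y, y)$accuracy, 100)
  expect_equal(confusion(y, 1 - y)$accuracy, 0)
  yh <- y; yh[c(2, 5, 9)] <- 1 - yh[c(2, 5, 9)]
  cm <- confusion(y, yh)
  expect_equal(cm$accuracy, 70)
  expect_identical(sum(cm$table), 10L)
  expect_error(confusion(y, yh[-1]), "mismatch")
})

test_that("cross-validation folds partition reproducibly and stratified", {
  f1 <- cv_folds(1000, 10, seed = 3)
  f2 <- cv_folds(1000, 10, seed = 3)
  expect_identical(f1, f2)
  expect_identical(as.vector(table(f1)), rep(100L, 10))
  strata <- rep(c(0, 1), c(300, 700))
  fs <- cv_folds(1000, 10, seed = 4, strata = strata)
  expect_identical(as.vector(table(fs[strata == 0])), rep(30L, 10))
  expect_identical(as.vector(table(fs[strata == 1])), rep(70L, 10))
})

test_that("approach B reports train, cv and test phases for classification", {
  cohort <- generate_cohort(1, seed = 81)
  res <- quiet_protocol(cohort, model = "rf", mode = "B", seed = 1, folds = 5)
  expect_setequal(unique(res$phase), c("train", "cv", "test"))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
  expect_identical(nrow(res), 6L)  # (train, cv, test) x (S1, mean)
})

test_that("mode B split counts and cohort means are exact", {
  cohort <- generate_cohort(2, seed = 82)
  res <- quiet_protocol(cohort, model = "svr", mode = "B", seed = 2, folds = 0)
  # 2 trials x 299 windows pooled; 70/30 split
  expect_equal(res$n[res$subject == "S1" & res$phase == "train"], 418)
  expect_equal(res$n[res$subject == "S1" & res$phase == "test"], 180)
  # cohort mean rows are the arithmetic mean of the per-subject rows
  for (ph in c("train", "test")) {
    sub <- res[res$subject != "mean" & res$phase == ph, ]
    mrow <- res[res$subject == "mean" & res$phase == ph, ]
    expect_equal(mrow$r2_pct, mean(sub$r2_pct))
    expect_equal(mrow$rmse, mean(sub$rmse))
  }
})

test_that("approach A requires two trials and stays close to train metrics", {
  cohort <- generate_cohort(1, seed = 83)
  expect_error(quiet_protocol(cohort[1], model = "svr", mode = "A"),
               "second trial")
  gaps <- vapply(1:3, function(s) {
    r <- quiet_protocol(generate_cohort(1, seed = 83 + s), model = "svr",
                        mode = "A", seed = s)
    r$r2_pct[r$phase == "train" & r$subject != "mean"] -
      r$r2_pct[r$phase == "test" & r$subject != "mean"]
  }, numeric(1))
  # identical-protocol trials: no distribution shift beyond noise
  expect_lt(mean(gaps), 5)
})

test_that("pooled-split estimation is at least as good as trial holdout", {
  deltas <- vapply(1:3, function(s) {
    cohort <- generate_cohort(1, seed = 90 + s)
    rA <- quiet_protocol(cohort, model = "svr", mode = "A", seed = s)
    rB <- quiet_protocol(cohort, model = "svr", mode = "B", seed = s, folds = 0)
    rB$r2_pct[rB$phase == "test" & rB$subject != "mean"] -
      rA$r2_pct[rA$phase == "test" & rA$subject != "mean"]
  }, numeric(1))
  expect_gte(mean(deltas), -2)  # trend, with tolerance
})
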