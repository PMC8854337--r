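# SVM and random-forest classifiers, majority voting, OOB estimation.

test_that("SVM separates linear clusters and learns XOR with an RBF kernel", {
  withr::with_seed(1, {
    x <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
               matrix(rnorm(40, 3, 0.3), ncol = 2))
  })
  y <- rep(c(0L, 1L), each = 20)
  m <- fit_svm(x, y, svm_spec(C = 10, kernel_width = 1))
  expect_equal(predict(m, x), y)

  xor_x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  xor_y <- c(0L, 1L, 1L, 0L)
  m2 <- fit_svm(xor_x, xor_y, svm_spec(C = 10, kernel_width = 0.5), scale = FALSE)
  expect_equal(predict(m2, xor_x), xor_y)
})

test_that("SVM rejects degenerate inputs and is order-invariant", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_svm(x, rep(0L, 10)), "single class")
  withr::with_seed(2, {
    x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 2.5), ncol = 2))
  })
  y <- rep(c(0L, 1L), each = 30)
  perm <- withr::with_seed(3, sample(60))
  m1 <- fit_svm(x, y, svm_spec())
  m2 <- fit_svm(x[perm, ], y[perm], svm_spec())
  grid <- matrix(runif(40, -1, 3.5), ncol = 2)
  expect_equal(predict(m1, grid), predict(m2, grid))
})

test_that("the Gaussian kernel is 1 at zero distance", {
  v <- withr::with_seed(4, rnorm(5))
  expect_identical(rbf_kernel(v, v, sigma_sq = 0.125), 1)
})

test_that("a single full-sample tree reduces to a decision tree", {
  withr::with_seed(5, x <- matrix(c(rnorm(30, 0), rnorm(30, 4)), ncol = 1))
  y <- rep(c(0L, 1L), each = 30)
  m <- fit_rf(x, y, rf_spec(trees = 1, max_depth = 20, replace = FALSE,
                            sample_fraction = 1), seed = 1)
  expect_equal(predict_vote(m, x), y)       # consistent data memorised
  expect_true(all(m$inbag > 0))             # nothing out of bag ...
  expect_error(oob_error(m), "out of bag")  # ... so OOB error is undefined
})

test_that("forests are reproducible for a fixed seed", {
  withr::with_seed(6, x <- matrix(rnorm(200), ncol = 2))
  y <- as.integer(x[, 1] + 0.3 * rnorm(100) > 0)
  m1 <- fit_rf(x, y, rf_spec(trees = 25), seed = 42)
  m2 <- fit_rf(x, y, rf_spec(trees = 25), seed = 42)
  expect_identical(m1$inbag, m2$inbag)
  expect_identical(predict_vote(m1, x), predict_vote(m2, x))
})

test_that("stumps solve threshold-separable data with low OOB error", {
  withr::with_seed(7, x <- matrix(c(runif(400, 0, 1), runif(400, 2, 3)), ncol = 1))
  y <- rep(c(0L, 1L), each = 400)
  m <- fit_rf(x, y, rf_spec(trees = 25, max_depth = 1), seed = 3)
  expect_lte(oob_error(m)$error, 0.05)
})

test_that("majority voting tallies votes with the documented tie-break", {
  m <- manual_forest(votes = matrix(c(1, 1, 0), nrow = 1), y = 1L)
  expect_identical(predict_vote(m), 1L)
  tie <- manual_forest(votes = matrix(c(0, 1), nrow = 1), y = 0L)
  expect_identical(predict_vote(tie), 0L)  # tie -> lowest class index
  # 5-tree ensemble vs brute-force tally on 20 random vote rows
  votes <- withr::with_seed(8, matrix(sample(0:1, 100, replace = TRUE), ncol = 5))
  got <- predict_vote(manual_forest(votes))
  want <- apply(votes, 1, function(v) if (sum(v == 1) > sum(v == 0)) 1L else 0L)
  expect_identical(got, want)
})

test_that("OOB estimation matches exhaustive hand enumeration", {
  # 3 trees x 4 samples with fixed memberships (0 = out of bag)
  inbag <- rbind(c(1, 0, 0),
                 c(0, 1, 0),
                 c(1, 1, 1),
                 c(0, 0, 1))
  votes <- rbind(c(1, 1, 0),
                 c(0, 0, 1),
                 c(1, 0, 1),
                 c(0, 1, 0))
  y <- c(1L, 0L, 1L, 1L)
  m <- manual_forest(votes, inbag, y)
  res <- oob_error(m)
  # sample 1: OOB trees 2,3 vote (1,0) -> tie -> 0 (wrong)
  # sample 2: OOB trees 1,3 vote (0,1) -> tie -> 0 (right)
  # sample 3: no OOB tree -> excluded
  # sample 4: OOB trees 1,2 vote (0,1) -> tie -> 0 (wrong)
  expect_identical(res$predictions, c(0L, 0L, NA, 0L))
  expect_identical(res$n_oob, 3L)
  expect_equal(res$error, 2 / 3)
})

test_that("a perfect forest has zero OOB error", {
  votes <- matrix(rep(c(0L, 1L), each = 3), nrow = 2, byrow = TRUE)
  inbag <- matrix(c(0, 1, 0, 1, 0, 0), nrow = 2)
  m <- manual_forest(votes, inbag, y = c(0L, 1L))
  expect_equal(oob_error(m)$error, 0)
})

test_that("OOB membership complements the bootstrap and hits the e^-1 rate", {
  withr::with_seed(9, x <- matrix(rnorm(2000), ncol = 2))
  y <- as.integer(rowSums(x) > 0)
  m <- fit_rf(x, y, rf_spec(trees = 30), seed = 11)
  expect_identical(dim(m$inbag), c(1000L, 30L))
  # every bootstrap draws n with replacement: counts sum to n per tree
  expect_true(all(colSums(m$inbag) == 1000L))
  expect_lt(abs(oob_fraction(m) - exp(-1)), 0.03)
})

test_that("growing the forest does not degrade OOB error", {
  fm <- cohort_feature_table(1, seed = 55)
  x <- as.matrix(fm[feature_columns(fm)])
  deltas <- vapply(1:10, function(s) {
    e5 <- oob_error(fit_rf(x, fm$label, rf_spec(trees = 5), seed = s))$error
    e50 <- oob_error(fit_rf(x, fm$label, rf_spec(trees = 50), seed = s))$error
    e50 - e5
  }, numeric(1))
  expect_lte(mean(deltas), 0.02)
})
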