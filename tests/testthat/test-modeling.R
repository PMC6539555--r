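test_that("random-forest ranking recovers a copied feature and permutes consistently", {
  set.seed(8)
  x <- matrix(rnorm(300 * 20), nrow = 300)
  y <- x[, 1]
  rk <- rf_rank(x, y, seed = 101)
  expect_equal(rk$order[1], 1)
  # permuting the feature columns permutes the ranking accordingly
  perm <- c(5, 1, 4, 2, 3, 6:20)
  rk2 <- rf_rank(x[, perm], y, seed = 101)
  expect_equal(perm[rk2$order[1]], 1)
  # the copied feature dominates in both runs by a wide margin
  expect_gt(rk$importance[1], 5 * max(rk$importance[-1]))
  expect_gt(rk2$importance[2], 5 * max(rk2$importance[-2]))
})

test_that("identical columns tie and break deterministically by index", {
  set.seed(9)
  col <- rnorm(50)
  x <- cbind(col, col, col)
  colnames(x) <- NULL
  y <- col + rnorm(50, 0, 0.1)
  rk <- rf_rank(x, y, seed = 5)
  rk2 <- rf_rank(x, y, seed = 5)
  expect_identical(rk$order, rk2$order)
  expect_lt(diff(range(rk$importance)), 0.2 * max(abs(rk$importance)))
  expect_error(rf_rank(x[1:10, ], y[1:10]), "at least")
})

test_that("feedforward selection honors its contract", {
  set.seed(12)
  x <- matrix(rnorm(100 * 6), nrow = 100)
  y <- 0.5 + 0.3 * x[, 1] + rnorm(100, 0, 0.1)
  # single candidate dimension
  sel1 <- feedforward_select(x, y, reducer = "none", ordered_dims = 1,
                             seed = 3)
  expect_equal(sel1$chosen_k, 1)
  sel <- feedforward_select(x, y, reducer = "none", ordered_dims = 1:6,
                            seed = 3)
  expect_length(sel$mean_cv_rmse, length(sel$k_values))
  expect_length(sel$mean_cv_pve, length(sel$k_values))
  expect_equal(sel$mean_cv_rmse[match(sel$chosen_k, sel$k_values)],
               min(sel$mean_cv_rmse))
  # tie-free: chosen_k is the smallest minimizer by construction
  expect_equal(sel$chosen_k,
               sel$k_values[which.min(sel$mean_cv_rmse)])
})

test_that("feedforward selection finds a compact signal-bearing prefix", {
  set.seed(14)
  n <- 400
  x <- matrix(rnorm(n * 12), nrow = n)
  y <- 0.4 * x[, 1] + 0.3 * x[, 2] + 0.25 * x[, 3] + rnorm(n, 0, 0.05)
  sel <- feedforward_select(x, y, reducer = "none", ordered_dims = 1:12,
                            seed = 5)
  expect_gte(sel$chosen_k, 2)
  expect_lte(sel$chosen_k, 6)
})

test_that("a fold with a constant response errors", {
  x <- matrix(rnorm(40), nrow = 20)
  y <- rep(c(0.2, 0.2, 0.2, 0.2, 0.7), 4)
  expect_error(feedforward_select(x, rep(0.5, 20), reducer = "none",
                                  ordered_dims = 1:2),
               "distinct")
})

test_that("the dimension schedule is unit-stride then strided, ending at k_max", {
  expect_equal(k_schedule(5), 1:5)
  expect_equal(k_schedule(30), 1:30)
  ks <- k_schedule(47)
  expect_equal(ks[1:30], 1:30)
  expect_equal(diff(ks[30:length(ks)])[1], 5)
  expect_equal(ks[length(ks)], 47)
  expect_equal(k_schedule(100, step1_until = 10, step = 10),
               c(1:10, seq(20, 100, 10)))
})

test_that("final SVM fits are deterministic and reject degenerate input", {
  set.seed(15)
  x <- matrix(rnorm(200 * 3), nrow = 200)
  y <- 0.5 + 0.2 * x[, 1] - 0.1 * x[, 2] + rnorm(200, 0, 0.05)
  m1 <- fit_final(x, y)
  m2 <- fit_final(x, y)
  expect_identical(predict(m1, x), predict(m2, x))
  expect_error(fit_final(x, rep(0.5, 200)), "constant")
  # training error stays near the noise floor on a linear signal
  rmse <- sqrt(mean((predict(m1, x) - y)^2))
  expect_lt(rmse, 0.05 * 1.5)
  expect_error(predict(m1, x[, 1:2]), "dims")
})

test_that("evaluation matches a by-hand PVE and RMSE calculation", {
  y <- c(0, 0.25, 0.5, 1)
  pred <- c(0.1, 0.25, 0.4, 0.9)
  s <- metricqsar:::score_predictions(pred, y)
  # by hand: SS_res = 0.03, SS_tot = 0.546875, rmse = sqrt(0.03/4)
  expect_equal(s$rmse, 0.0866025403784439, tolerance = 1e-12)
  expect_equal(s$pve, 1 - 0.03 / 0.546875, tolerance = 1e-12)
  perfect <- metricqsar:::score_predictions(y, y)
  expect_equal(perfect$pve, 1)
  expect_equal(perfect$rmse, 0)
  atmean <- metricqsar:::score_predictions(rep(mean(y), 4), y)
  expect_equal(atmean$pve, 0)
  # constant evaluation response: PVE undefined, RMSE still real
  s2 <- metricqsar:::score_predictions(c(0.4, 0.6), c(0.5, 0.5))
  expect_true(is.na(s2$pve))
  expect_equal(s2$rmse, 0.1)
})

test_that("fold-wise metric reduction keeps noise at chance level", {
  set.seed(16)
  bits <- random_bits(120, 64)
  S <- similarity_matrix(feature_matrix(bits, "bits"))$values
  y <- runif(120)
  sel <- feedforward_select(S, y, reducer = "metric", k_max = 8, seed = 2)
  expect_true(all(sel$mean_cv_pve <= 0.1))
})
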