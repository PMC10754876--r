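test_that("the rank-sum AUC handles perfect, inverted and tied scores", {
  expect_equal(auc_mw(c(0, 1), c(0.2, 0.8)), 1)
  expect_equal(auc_mw(c(1, 0), c(0.2, 0.8)), 0)
  expect_equal(auc_mw(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(auc_mw(c(1, 1), c(0.1, 0.2)), "both classes")
  expect_error(auc_mw(c(0, 1), c(0.1, 0.2, 0.3)), "equal length")
})

test_that("AUC respects score symmetry and monotone invariance", {
  rng <- local_rng(51)
  for (i in 1:20) {
    y <- c(rep(0, 12), rep(1, 13))[rng$sample(25)]
    s <- rng$rnorm(25)
    a <- auc_mw(y, s)
    expect_equal(a + auc_mw(y, -s), 1, tolerance = 1e-12)
    expect_equal(auc_mw(y, exp(2 * s + 1)), a, tolerance = 1e-12)
  }
})

test_that("accuracy counts threshold agreements", {
  expect_equal(accuracy_at(c(0, 0, 1, 1), c(0.1, 0.2, 0.9, 0.8)), 1)
  expect_equal(accuracy_at(c(0, 0, 1, 1), c(0.6, 0.4, 0.6, 0.4)), 0.5)
  # threshold 0 predicts everything positive: accuracy = prevalence
  y <- c(0, 1, 1, 0, 1)
  expect_equal(accuracy_at(y, stats::runif(5), threshold = 0), mean(y))
  expect_error(accuracy_at(numeric(0), numeric(0)), "non-empty")
})

test_that("ROC curves are monotone, anchored and integrate to the AUC", {
  rng <- local_rng(52)
  for (i in 1:200) {
    n <- 10 + rng$sample(40, size = 1)
    y <- c(0, 1, as.integer(rng$runif(n - 2) < 0.4))
    s <- round(rng$rnorm(n), 1)  # coarse scores force ties
    roc <- roc_points(y, s)
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(gaitcast:::trapezoid_area(roc$fpr, roc$tpr), auc_mw(y, s),
                 tolerance = 1e-12)
  }
  # perfect separation passes through (0, 1)
  roc_p <- roc_points(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_true(any(roc_p$fpr == 0 & roc_p$tpr == 1))
  # reversing scores reflects the curve through the diagonal
  y <- c(0, 1, 1, 0, 1, 0, 0, 1)
  s <- c(0.1, 0.9, 0.7, 0.3, 0.6, 0.2, 0.4, 0.8)
  r1 <- roc_points(y, s)
  r2 <- roc_points(y, -s)
  # the reflected curve's points are the original's with both axes flipped
  expect_equal(r2$fpr, rev(1 - r1$fpr), tolerance = 1e-12)
  expect_equal(r2$tpr, rev(1 - r1$tpr), tolerance = 1e-12)
  expect_equal(gaitcast:::trapezoid_area(r2$fpr, r2$tpr),
               1 - gaitcast:::trapezoid_area(r1$fpr, r1$tpr),
               tolerance = 1e-12)
})

test_that("AUC and ROC agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  rng <- local_rng(53)
  for (i in 1:5) {
    y <- c(0, 1, as.integer(rng$runif(60) < 0.5))
    s <- rng$rnorm(62)
    expect_equal(auc_mw(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("a separable problem is learned to near-perfect validation AUC", {
  rng <- local_rng(54)
  n <- 160
  y <- rep(c(0, 1), n / 2)
  x <- array(rng$rnorm(n * 101 * 9, 0, 0.5), c(n, 101, 9))
  bump <- sin(2 * pi * (0:100) / 100)
  for (i in seq_len(n)) x[i, , ] <- x[i, , ] + (1 + 2 * y[i]) * bump
  spec <- architecture_spec("mlp_4_200", list(num_layers = 2L, units = 32L))
  cfg <- training_config(max_epochs = 25L, early_stopping_patience = 8L,
                         seed = 55, batch_size = 32L)
  fit <- train_model(build_signal_model(spec, seed = 56),
                     x[1:120, , , drop = FALSE], y[1:120],
                     x[121:160, , , drop = FALSE], y[121:160], cfg,
                     transform_fn = gaitcast:::flatten_batch)
  expect_gte(fit$val_auc, 0.99)
  expect_gte(fit$epoch_of_convergence, 1L)
  expect_true(all(c("epoch", "train_loss", "val_auc") %in%
                    names(fit$history)))
})

test_that("randomly permuted labels keep validation AUC near chance", {
  rng <- local_rng(57)
  n <- 2000
  y <- as.integer(rng$runif(n) < 0.5)
  x <- array(rng$rnorm(n * 101 * 9), c(n, 101, 9))
  spec <- architecture_spec("mlp_4_200", list(num_layers = 2L, units = 16L))
  cfg <- training_config(max_epochs = 4L, early_stopping_patience = 0L,
                         seed = 58, batch_size = 128L)
  fit <- train_model(build_signal_model(spec, seed = 59),
                     x[1:1000, , , drop = FALSE], y[1:1000],
                     x[1001:2000, , , drop = FALSE], y[1001:2000], cfg,
                     transform_fn = gaitcast:::flatten_batch)
  expect_gte(fit$val_auc, 0.4)
  expect_lte(fit$val_auc, 0.6)
})

test_that("training rejects single-class sets", {
  x <- array(0, c(4, 101, 9))
  cfg <- training_config(max_epochs = 1L, seed = 1)
  m <- build_signal_model("fcn")
  expect_error(train_model(m, x, c(1, 1, 1, 1), x, c(0, 1, 0, 1), cfg),
               "both classes")
})

test_that("identical score vectors degenerate DeLong's test to p = 1", {
  y <- c(0, 1, 0, 1, 1, 0)
  s <- c(0.2, 0.7, 0.4, 0.9, 0.6, 0.1)
  res <- delong_test(y, s, s)
  expect_equal(res$z_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$variance_of_difference, 0)
})

test_that("swapping the two models negates z and preserves p", {
  rng <- local_rng(60)
  y <- c(0, 1, as.integer(rng$runif(80) < 0.5))
  a <- rng$rnorm(82) + y
  b <- rng$rnorm(82) + 0.5 * y
  r1 <- delong_test(y, a, b)
  r2 <- delong_test(y, b, a)
  expect_equal(r1$z_statistic, -r2$z_statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_error(delong_test(y, a, b[-1]), "mismatch")
})

test_that("DeLong agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  rng <- local_rng(61)
  y <- c(0, 1, as.integer(rng$runif(120) < 0.45))
  a <- rng$rnorm(122) + 0.8 * y
  b <- rng$rnorm(122) + 0.3 * y
  ours <- delong_test(y, a, b)
  ra <- pROC::roc(y, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(abs(ours$z_statistic), abs(unname(ref$statistic)),
               tolerance = 1e-9)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(ours$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
})

test_that("evaluate_model reports AUC, accuracy and a valid ROC", {
  rng <- local_rng(62)
  m <- build_signal_model(architecture_spec("mlp_4_200",
                                            list(num_layers = 1L,
                                                 units = 8L)), seed = 63)
  x <- array(rng$rnorm(40 * 101 * 9), c(40, 101, 9))
  y <- rep(c(0, 1), 20)
  ev <- evaluate_model(m, x, y, transform_fn = gaitcast:::flatten_batch)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_equal(ev$roc$fpr[1], 0)
  expect_length(ev$scores, 40L)
})
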