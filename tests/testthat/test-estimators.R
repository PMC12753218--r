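test_that("standardizer matches hand arithmetic and transforms to z-scores", {
  X <- rbind(c(1, 10, 100, -5), c(3, 20, 200, -3), c(5, 30, 300, -1))
  colnames(X) <- c("t_min", "g_max", "d2_max", "d2_min")
  std <- fit_standardizer(X)
  # hand-computed: means 3,20,200,-3; sds 2,10,100,2
  expect_equal(unname(std$means), c(3, 20, 200, -3))
  expect_equal(unname(std$sds), c(2, 10, 100, 2))
  Z <- apply_standardizer(std, X)
  expect_equal(unname(colMeans(Z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 4), tolerance = 1e-12)
  Xd <- X; Xd[, 2] <- 7
  expect_error(fit_standardizer(Xd), "g_max")
})

test_that("linear model recovers exact and constant targets", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, c("t_min", "g_max", "d2_max", "d2_min")))
  beta <- c(2, -1, 0.5, 3)
  y <- 1.5 + as.numeric(X %*% beta)
  m <- fit_linear_model(X, y)
  expect_equal(m$intercept, 1.5, tolerance = 1e-9)
  expect_equal(unname(m$coefficients), beta, tolerance = 1e-9)
  expect_equal(predict_linear(m, X), y, tolerance = 1e-9)
  mc <- fit_linear_model(X, rep(4.2, 10))
  expect_equal(mc$intercept, 4.2, tolerance = 1e-9)
  expect_equal(unname(mc$coefficients), rep(0, 4), tolerance = 1e-9)
  expect_error(fit_linear_model(X[1:5, ], y[1:5]), "at least 6")
  Xr <- X; Xr[, 4] <- Xr[, 1]
  expect_error(fit_linear_model(Xr, y), "rank-deficient")
})

test_that("noisy OLS agrees with stats::lm as an independent route", {
  set.seed(2)
  X <- matrix(rnorm(800), 200, 4,
              dimnames = list(NULL, c("t_min", "g_max", "d2_max", "d2_min")))
  beta <- c(0.8, -0.4, 1.2, 0.1)
  y <- 2 + as.numeric(X %*% beta) + rnorm(200, 0, 0.1)
  m <- fit_linear_model(X, y)
  ref <- lm(y ~ ., data = as.data.frame(X))
  expect_equal(m$intercept, unname(coef(ref)[1]), tolerance = 1e-8)
  expect_equal(unname(m$coefficients), unname(coef(ref)[-1]), tolerance = 1e-8)
  # and estimates sit within 3 standard errors of the truth
  se <- summary(ref)$coefficients[-1, "Std. Error"]
  expect_true(all(abs(m$coefficients - beta) < 3 * se))
})

test_that("network forward pass is hand-checkable and bounded", {
  zero <- structure(list(W1 = matrix(0, 3, 4), b1 = rep(0, 3),
                         W2 = matrix(0, 1, 3), b2 = 2.5,
                         standardizer = NULL), class = "nn_model")
  x <- c(t_min = 1000, g_max = 50, d2_max = 20, d2_min = -30)
  expect_equal(nn_forward(zero, rbind(x)), 2.5)
  # single active path: y = 0.5 * tanh(2 * x1) + 1
  m <- zero
  m$W1[1, 1] <- 2; m$W2[1, 1] <- 0.5; m$b2 <- 1
  xs <- rbind(c(t_min = 0.3, g_max = 0, d2_max = 0, d2_min = 0))
  expect_equal(nn_forward(m, xs), 0.5 * tanh(0.6) + 1, tolerance = 1e-12)
  # saturation bound: |y| <= |b2| + sum |W2|
  big <- structure(list(W1 = matrix(1e6, 3, 4), b1 = rep(0, 3),
                        W2 = matrix(c(1, -2, 3), 1, 3), b2 = -0.5,
                        standardizer = NULL), class = "nn_model")
  set.seed(4)
  preds <- nn_forward(big, matrix(rnorm(40, 0, 100), 10, 4,
                                  dimnames = list(NULL, c("t_min", "g_max",
                                                          "d2_max", "d2_min"))))
  expect_true(all(abs(preds) <= 0.5 + 6))
})

test_that("Adam training is deterministic and reduces the loss", {
  set.seed(6)
  X <- matrix(rnorm(48), 12, 4,
              dimnames = list(NULL, c("t_min", "g_max", "d2_max", "d2_min")))
  cfg <- train_config(epochs = 4000, seed = 3)
  # constant target: the bias-only solution is reachable
  mc <- fit_nn(X, rep(2.5, 12), cfg)
  expect_lt(unname(mc$loss["final"]), 1e-3)
  # linear-in-one-standardized-feature toy trains well past 10x reduction
  Z <- apply_standardizer(fit_standardizer(X), X)
  y <- 2 * Z[, 1]
  mt <- fit_nn(X, y, cfg)
  expect_lt(unname(mt$loss["final"]), unname(mt$loss["initial"]) / 10)
  # bit-identical under the same seed
  m1 <- fit_nn(X, y, cfg)
  m2 <- fit_nn(X, y, cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$b2, m2$b2)
  # different seeds explore different weights
  m3 <- fit_nn(X, y, train_config(epochs = 4000, seed = 4))
  expect_false(identical(m1$W1, m3$W1))
  expect_error(train_config(learning_rate = 0), "> 0")
  expect_error(fit_nn(X[1:5, ], y[1:5], cfg), "at least 8")
})

test_that("the 6 g/L gate picks the network above and the regression below", {
  lr <- structure(list(intercept = 4.2, coefficients = setNames(rep(0, 4),
                       c("t_min", "g_max", "d2_max", "d2_min"))),
                  class = "linear_model")
  nn_at <- function(v) structure(list(W1 = matrix(0, 3, 4), b1 = rep(0, 3),
                                      W2 = matrix(0, 1, 3), b2 = v,
                                      standardizer = NULL), class = "nn_model")
  x <- rbind(c(t_min = 1, g_max = 1, d2_max = 1, d2_min = 1))
  expect_equal(predict_combined(lr, nn_at(5.0), x), 4.2)   # below gate: regression
  lr65 <- lr; lr65$intercept <- 6.5
  expect_equal(predict_combined(lr65, nn_at(7.0), x), 7.0) # above gate: network
  lr58 <- lr; lr58$intercept <- 5.8
  expect_equal(predict_combined(lr58, nn_at(6.0), x), 6.0) # boundary: network
  # the output is always one of the two inputs
  set.seed(8)
  for (i in 1:10) {
    a <- runif(1, 0, 12); b <- runif(1, 0, 12)
    lrx <- lr; lrx$intercept <- a
    out <- predict_combined(lrx, nn_at(b), x)
    expect_true(out %in% c(a, b))
  }
})

test_that("leave-one-out with exactly-linear targets is perfect", {
  fx <- fixture_feature_records(n = 12, beta = c(-0.002, 0.05, 0.1, 0.08),
                                intercept = 9)
  ps <- loo_evaluate(fx$records, "PT", train_config(seed = 1),
                     methods = "linear")
  expect_false(any(ps$excluded))
  expect_equal(ps$pred_linear, ps$truth_g_L, tolerance = 1e-6)
  pe <- pearson_eval(ps, "linear")
  expect_equal(pe$r, 1.0, tolerance = 1e-9)
  expect_lt(pe$p, 1e-10)
})

test_that("leave-one-out linear equals a brute-force per-fold refit oracle", {
  fx <- fixture_feature_records(n = 10, beta = c(-0.001, 0.03, 0.05, 0.04),
                                intercept = 5, seed = 77)
  # add target noise so folds genuinely differ
  recs <- fx$records
  withr::with_seed(12, {
    for (i in seq_along(recs)) {
      recs[[i]]$fibrinogen_ref <- recs[[i]]$fibrinogen_ref + abs(rnorm(1, 0, 0.4))
    }
  })
  ps <- loo_evaluate(recs, "PT", train_config(seed = 1), methods = "linear")
  feats <- do.call(rbind, lapply(recs, function(r) {
    as.numeric(extract_features(r$waveforms$pt))
  }))
  truth <- vapply(recs, function(r) r$fibrinogen_ref, numeric(1))
  for (i in seq_along(recs)) {
    df <- as.data.frame(feats[-i, , drop = FALSE])
    names(df) <- paste0("f", 1:4)
    fit <- lm(y ~ ., data = cbind(df, y = truth[-i]))
    oracle <- sum(coef(fit) * c(1, feats[i, ]))
    expect_equal(ps$pred_linear[i], oracle, tolerance = 1e-8)
  }
})

test_that("records without required inputs are excluded with a reason", {
  fx <- fixture_feature_records(n = 10, beta = c(-0.001, 0.03, 0.05, 0.04),
                                intercept = 5)
  recs <- fx$records
  recs[[3]]$waveforms$pt <- NULL
  recs[[7]]$fibrinogen_ref <- NA_real_
  ps <- loo_evaluate(recs, "PT", train_config(seed = 1), methods = "linear")
  expect_equal(sum(ps$excluded), 2)
  expect_equal(sum(!is.na(ps$pred_linear)), 8)
  expect_match(ps$reason[3], "missing PT waveform")
  expect_match(ps$reason[7], "reference fibrinogen")
  expect_true(all(is.na(ps$pred_linear[ps$excluded])))
  recs2 <- fx$records[1:8]
  recs2[[1]]$waveforms$pt <- NULL
  expect_error(loo_evaluate(recs2, "PT", methods = "linear"), "at least 8")
})

test_that("Pearson evaluation matches the textbook formula", {
  mk <- function(pred, truth) {
    structure(data.frame(sample_id = as.character(seq_along(pred)),
                         truth_g_L = truth, pred_linear = pred,
                         pred_nn = NA_real_, pred_combined = NA_real_,
                         inr_stratum = "regular", antixa_pos = FALSE,
                         excluded = FALSE, reason = ""),
              class = c("prediction_set", "data.frame"))
  }
  t5 <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_eval(mk(t5, t5), "linear")$r, 1.0)
  expect_equal(pearson_eval(mk(-t5, t5), "linear")$r, -1.0)
  p5 <- c(2, 2.9, 4.2, 3.9, 5.1)
  pe <- pearson_eval(mk(p5, t5), "linear")
  # textbook sums, written out
  n <- 5
  num <- n * sum(p5 * t5) - sum(p5) * sum(t5)
  den <- sqrt(n * sum(p5^2) - sum(p5)^2) * sqrt(n * sum(t5^2) - sum(t5)^2)
  r_hand <- num / den
  t_stat <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_stat), n - 2)
  expect_equal(pe$r, r_hand, tolerance = 1e-12)
  expect_equal(pe$p, p_hand, tolerance = 1e-12)
  expect_equal(pe$n, 5)
  expect_error(pearson_eval(mk(t5, t5)[1:2, ], "linear"), "fewer than 3")
})

test_that("regular-strata filtering drops anticoagulated samples", {
  df <- data.frame(sample_id = as.character(1:10),
                   truth_g_L = 1:10,
                   pred_linear = (1:10) + 0.1,
                   pred_nn = NA_real_, pred_combined = NA_real_,
                   inr_stratum = c(rep("regular", 6), "high", "intermediate",
                                   "regular", "regular"),
                   antixa_pos = c(rep(FALSE, 8), TRUE, FALSE),
                   excluded = FALSE, reason = "",
                   stringsAsFactors = FALSE)
  class(df) <- c("prediction_set", "data.frame")
  expect_equal(pearson_eval(df, "linear", "all")$n, 10)
  expect_equal(pearson_eval(df, "linear", "regular")$n, 7)
})
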