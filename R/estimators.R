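#' Feature standardizer (zero mean, unit SD)
#'
#' Per-feature sample mean and standard deviation (denominator n-1) fitted on
#' a training set; the same constants are reused at inference so the held-out
#' sample never influences the scaling.
#'
#' @param X Numeric matrix, one row per sample, columns `t_min`, `g_max`,
#'   `d2_max`, `d2_min`.
#' @return An object of class `standardizer` with `means` and `sds`.
#' @export
fit_standardizer <- function(X) {
  X <- feature_matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples to fit a standardizer", call. = FALSE)
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds <= 0)) {
    stop(sprintf("zero-variance feature(s): %s",
                 paste(colnames(X)[sds <= 0], collapse = ", ")), call. = FALSE)
  }
  structure(list(means = means, sds = sds), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std A fitted `standardizer`.
#' @export
apply_standardizer <- function(std, X) {
  stopifnot(inherits(std, "standardizer"))
  X <- feature_matrix(X)
  sweep(sweep(X, 2, std$means, "-"), 2, std$sds, "/")
}

# coerce feature input (feature_vector, list of them, matrix, data.frame)
# to an n x 4 matrix with canonical column order
feature_matrix <- function(X) {
  if (inherits(X, "feature_vector")) X <- matrix(unclass(X), nrow = 1,
                                                 dimnames = list(NULL, names(X)))
  if (is.list(X) && !is.data.frame(X)) {
    X <- do.call(rbind, lapply(X, function(f) unclass(f)[feature_names]))
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- feature_names
  X <- X[, feature_names, drop = FALSE]
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("features must all be finite", call. = FALSE)
  X
}

#' Multivariate linear fibrinogen model
#'
#' Ordinary least squares with intercept on the four raw (unstandardized)
#' waveform features.
#'
#' @param X Feature matrix (n x 4) or list of feature vectors.
#' @param y Reference fibrinogen, g/L.
#' @return An object of class `linear_model` with `intercept` and
#'   `coefficients`.
#' @export
fit_linear_model <- function(X, y) {
  X <- feature_matrix(X)
  if (nrow(X) != length(y)) stop("X rows and y length differ", call. = FALSE)
  if (nrow(X) < 6L) stop("need at least 6 samples (more than parameters)", call. = FALSE)
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("rank-deficient feature design", call. = FALSE)
  beta <- qr.coef(qrD, y)
  structure(list(intercept = unname(beta[1]),
                 coefficients = beta[-1]),
            class = "linear_model")
}

#' @rdname fit_linear_model
#' @param model A fitted `linear_model`.
#' @param newX Feature matrix or feature vector(s) to predict.
#' @export
predict_linear <- function(model, newX) {
  stopifnot(inherits(model, "linear_model"))
  X <- feature_matrix(newX)
  as.numeric(model$intercept + X %*% model$coefficients)
}

#' Adam training configuration
#'
#' Keras-style defaults for full-batch Adam on mean squared error.
#'
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param epochs Number of full-batch epochs.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, epochs = 10000L, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1) {
    stop("beta1 and beta2 must lie in (0, 1)", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Forward pass of the 4-3-1 network
#'
#' `y = W2 tanh(W1 standardize(f) + b1) + b2`: four inputs, one dense hidden
#' layer of three tanh units, a linear scalar output. Because tanh is bounded,
#' the output is always within `|b2| + sum(|W2|)` of zero.
#'
#' @param model An `nn_model` (see [fit_nn()]).
#' @param newX Feature matrix or feature vector(s).
#' @return Predicted fibrinogen, g/L (numeric vector).
#' @export
nn_forward <- function(model, newX) {
  stopifnot(inherits(model, "nn_model"))
  Xs <- if (is.null(model$standardizer)) feature_matrix(newX)
        else apply_standardizer(model$standardizer, newX)
  H <- tanh(Xs %*% t(model$W1) + matrix(model$b1, nrow(Xs), 3, byrow = TRUE))
  as.numeric(H %*% t(model$W2) + model$b2)
}

# Glorot-uniform initial weights, deterministic given seed; leaves the
# caller's RNG stream untouched
nn_init <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  lim1 <- sqrt(6 / (4 + 3)); lim2 <- sqrt(6 / (3 + 1))
  list(W1 = matrix(stats::runif(12, -lim1, lim1), 3, 4),
       b1 = numeric(3),
       W2 = matrix(stats::runif(3, -lim2, lim2), 1, 3),
       b2 = 0)
}

#' Fit the 4-3-1 network with full-batch Adam
#'
#' Features are standardized to zero mean and unit SD (constants stored in
#' the model and reused at inference); weights are Glorot-uniform initialized
#' from `cfg$seed`; training minimizes the mean squared error between network
#' output and reference fibrinogen with full-batch Adam for `cfg$epochs`
#' epochs. Deterministic given the seed. Adam may oscillate locally, but the
#' final loss is checked against the initial loss.
#'
#' @param X Feature matrix (n x 4) or list of feature vectors.
#' @param y Reference fibrinogen, g/L.
#' @param cfg A [train_config].
#' @return An object of class `nn_model`: `W1` (3x4), `b1` (3), `W2` (1x3),
#'   `b2`, `standardizer`, `seed`, and the training `loss` trace (initial and
#'   final MSE).
#' @export
fit_nn <- function(X, y, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  X <- feature_matrix(X)
  n <- nrow(X)
  if (n != length(y)) stop("X rows and y length differ", call. = FALSE)
  if (n < 8L) stop("need at least 8 samples to train the network", call. = FALSE)
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  w <- nn_init(cfg$seed)
  W1 <- w$W1; b1 <- w$b1; W2 <- w$W2; b2 <- w$b2
  # Adam state, one slot per tensor
  mW1 <- vW1 <- matrix(0, 3, 4); mb1 <- vb1 <- numeric(3)
  mW2 <- vW2 <- matrix(0, 1, 3); mb2 <- vb2 <- 0
  lr <- cfg$learning_rate; b1c <- cfg$beta1; b2c <- cfg$beta2; eps <- cfg$epsilon
  tXs <- t(Xs)
  loss0 <- NA_real_; loss <- NA_real_
  for (epoch in seq_len(cfg$epochs)) {
    Z1 <- W1 %*% tXs + b1            # 3 x n
    H <- tanh(Z1)
    yhat <- as.numeric(W2 %*% H + b2)
    r <- yhat - y
    loss <- mean(r * r)
    if (!is.finite(loss)) stop(sprintf("non-finite loss at epoch %d", epoch), call. = FALSE)
    if (epoch == 1L) loss0 <- loss
    d <- matrix(2 * r / n, 1, n)     # dL/dyhat
    gW2 <- d %*% t(H); gb2 <- sum(d)
    dH <- t(W2) %*% d                # 3 x n
    dZ1 <- dH * (1 - H * H)
    gW1 <- dZ1 %*% Xs; gb1 <- rowSums(dZ1)
    corr1 <- 1 - b1c^epoch; corr2 <- 1 - b2c^epoch
    step <- function(theta, g, m, v) {
      m <- b1c * m + (1 - b1c) * g
      v <- b2c * v + (1 - b2c) * g * g
      theta <- theta - lr * (m / corr1) / (sqrt(v / corr2) + eps)
      list(theta, m, v)
    }
    s <- step(W1, gW1, mW1, vW1); W1 <- s[[1]]; mW1 <- s[[2]]; vW1 <- s[[3]]
    s <- step(b1, gb1, mb1, vb1); b1 <- s[[1]]; mb1 <- s[[2]]; vb1 <- s[[3]]
    s <- step(W2, gW2, mW2, vW2); W2 <- s[[1]]; mW2 <- s[[2]]; vW2 <- s[[3]]
    s <- step(b2, gb2, mb2, vb2); b2 <- s[[1]]; mb2 <- s[[2]]; vb2 <- s[[3]]
  }
  structure(list(W1 = W1, b1 = as.numeric(b1), W2 = W2, b2 = as.numeric(b2),
                 standardizer = std, seed = cfg$seed,
                 loss = c(initial = loss0, final = loss)),
            class = "nn_model")
}

#' Combined fibrinogen prediction (6 g/L gating rule)
#'
#' The network is the better estimator at high fibrinogen and the linear
#' model below; the gate is the network's own prediction: when the network
#' predicts at least 6 g/L its prediction is returned, otherwise the linear
#' model's. The 6 g/L boundary itself goes to the network branch.
#'
#' @param lr_model A fitted [fit_linear_model()] model.
#' @param nn_model A fitted [fit_nn()] model (same training fold).
#' @param newX Feature matrix or feature vector(s).
#' @param threshold Gate, g/L (default 6).
#' @return Predicted fibrinogen, g/L (numeric vector).
#' @export
predict_combined <- function(lr_model, nn_model, newX, threshold = 6) {
  p_nn <- nn_forward(nn_model, newX)
  p_lr <- predict_linear(lr_model, newX)
  ifelse(p_nn >= threshold, p_nn, p_lr)
}

#' Leave-one-out evaluation of the waveform estimators
#'
#' For each usable sample the standardizer, the linear model and the network
#' are fitted on all remaining samples and the held-out sample is predicted
#' by each method (`linear`, `nn`, and their 6 g/L `combined`). Samples
#' lacking the assay waveform or the reference fibrinogen are excluded with
#' an explicit reason and carry no predictions. Fold f trains with seed
#' `cfg$seed + f` so the evaluation is reproducible without correlating fold
#' initializations.
#'
#' @param records List of [sample_record]s.
#' @param assay `"PT"` or `"RT"`: which transparency waveform to use
#'   (record keys `pt` / `rt`).
#' @param cfg A [train_config]; `cfg$seed` seeds the folds.
#' @param methods Character subset of `c("linear", "nn", "combined")`.
#' @param window,polyorder Passed to [extract_features()].
#' @return A `prediction_set`: data.frame with columns `sample_id`,
#'   `truth_g_L`, `pred_linear`, `pred_nn`, `pred_combined`, `inr_stratum`,
#'   `antixa_pos`, `excluded`, `reason`.
#' @export
loo_evaluate <- function(records, assay = c("PT", "RT"), cfg = train_config(),
                         methods = c("linear", "nn", "combined"),
                         window = 5L, polyorder = 2L) {
  assay <- match.arg(assay)
  methods <- match.arg(methods, several.ok = TRUE)
  key <- tolower(assay)
  n <- length(records)
  if (n == 0L) stop("no records supplied", call. = FALSE)
  ids <- vapply(records, function(r) r$sample_id, character(1))
  truth <- vapply(records, function(r) r$fibrinogen_ref, numeric(1))
  strata <- lapply(records, classify_sample)

  reason <- character(n)
  for (i in seq_len(n)) {
    if (is.null(records[[i]]$waveforms[[key]])) {
      reason[i] <- sprintf("missing %s waveform", assay)
    } else if (is.na(truth[i])) {
      reason[i] <- "missing reference fibrinogen"
    }
  }
  usable <- which(reason == "")
  if (length(usable) < 8L) {
    stop(sprintf("only %d usable records; need at least 8", length(usable)),
         call. = FALSE)
  }
  feats <- matrix(NA_real_, n, 4, dimnames = list(NULL, feature_names))
  for (i in usable) {
    feats[i, ] <- extract_features(records[[i]]$waveforms[[key]],
                                   window = window, polyorder = polyorder)
  }

  pred_lr <- pred_nn <- pred_cmb <- rep(NA_real_, n)
  for (pos in seq_along(usable)) {
    i <- usable[pos]
    train <- setdiff(usable, i)
    Xtr <- feats[train, , drop = FALSE]
    ytr <- truth[train]
    if ("linear" %in% methods || "combined" %in% methods) {
      lrm <- fit_linear_model(Xtr, ytr)
      pred_lr[i] <- predict_linear(lrm, feats[i, , drop = FALSE])
    }
    if ("nn" %in% methods || "combined" %in% methods) {
      fold_cfg <- cfg; fold_cfg$seed <- cfg$seed + pos
      nnm <- fit_nn(Xtr, ytr, fold_cfg)
      pred_nn[i] <- nn_forward(nnm, feats[i, , drop = FALSE])
    }
    if ("combined" %in% methods) {
      pred_cmb[i] <- if (pred_nn[i] >= 6) pred_nn[i] else pred_lr[i]
    }
  }
  out <- data.frame(
    sample_id = ids, truth_g_L = truth,
    pred_linear = pred_lr, pred_nn = pred_nn, pred_combined = pred_cmb,
    inr_stratum = vapply(strata, `[[`, character(1), "inr_stratum"),
    antixa_pos = vapply(strata, `[[`, logical(1), "anti_xa_positive"),
    excluded = reason != "", reason = reason,
    stringsAsFactors = FALSE)
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Pearson correlation of predictions against reference fibrinogen
#'
#' Sample Pearson r between a method's predictions and the reference values,
#' with a two-sided p-value from the t distribution on n - 2 degrees of
#' freedom. `strata = "regular"` restricts to samples that are neither
#' INR-elevated (stratum above regular) nor anti-Xa positive, mirroring the
#' exclusion analyses run on anticoagulated samples.
#'
#' @param preds A [loo_evaluate()] prediction set.
#' @param method One of `"linear"`, `"nn"`, `"combined"`.
#' @param strata `"all"` or `"regular"`.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_eval <- function(preds, method = c("combined", "linear", "nn"),
                         strata = c("all", "regular")) {
  stopifnot(inherits(preds, "prediction_set"))
  method <- match.arg(method)
  strata <- match.arg(strata)
  col <- paste0("pred_", method)
  keep <- !preds$excluded & !is.na(preds[[col]])
  if (strata == "regular") {
    keep <- keep & !(preds$inr_stratum %in% c("intermediate", "high")) &
      !preds$antixa_pos
  }
  x <- preds[[col]][keep]; y <- preds$truth_g_L[keep]
  if (length(x) < 3L) stop("fewer than 3 paired values after filtering", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
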