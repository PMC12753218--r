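test_that("waveform constructor enforces its invariants", {
  expect_s3_class(waveform(0:3, c(4, 3, 2, 1), kind = "transparency"), "waveform")
  expect_error(waveform(0:2, 1:2), "equal length")
  expect_error(waveform(c(0, 2, 1), 1:3), "strictly increasing")
  expect_error(waveform(c(-1, 0), 1:2), "t >= 0")
  expect_error(waveform(0:1, c(1, NA)), "finite")
  expect_error(waveform(0:1, c(-5, 1), kind = "transparency"), ">= 0")
  # thrombin curves may legitimately be recorded before correction as >= 0 only
  expect_s3_class(waveform(0:1, c(0, 10), kind = "thrombin"), "waveform")
})

test_that("resampling is the identity on an already-uniform grid", {
  v <- cumsum(runif(61))
  wf <- waveform(0:60, v, kind = "transparency")
  out <- resample_uniform(wf, dt = 1, t_end = 60)
  expect_identical(out$values, v)
  expect_identical(out$times, as.numeric(0:60))
})

test_that("resampling interpolates linearly and holds ends one step at most", {
  wf <- waveform(c(0, 2), c(100, 300), kind = "transparency")
  out <- resample_uniform(wf, dt = 1, t_end = 2)
  expect_equal(out$values, c(100, 200, 300))
  # one-step tail hold is allowed ...
  out2 <- resample_uniform(wf, dt = 1, t_end = 3)
  expect_equal(out2$values, c(100, 200, 300, 300))
  # ... more than one step is not
  expect_error(resample_uniform(wf, dt = 1, t_end = 5), "one step")
  expect_error(resample_uniform(waveform(0, 1, kind = "transparency"), dt = 1),
               "fewer than 2")
})

test_that("resampling matches a brute-force piecewise-linear oracle", {
  set.seed(7)
  times <- cumsum(rep(0.37, 170)) - 0.37
  vals <- 4000 - cumsum(abs(rnorm(170, 5, 10)))
  wf <- waveform(times, pmax(vals, 0), kind = "transparency")
  out <- resample_uniform(wf, dt = 1, t_end = 60)
  # independent oracle: explicit segment search + linear blend
  oracle <- vapply(0:60, function(t) {
    if (t <= times[1]) return(wf$values[1])
    i <- max(which(times <= t))
    if (i == length(times)) return(wf$values[i])
    w <- (t - times[i]) / (times[i + 1] - times[i])
    (1 - w) * wf$values[i] + w * wf$values[i + 1]
  }, numeric(1))
  expect_equal(out$values, oracle, tolerance = 1e-12)
})

test_that("Savitzky-Golay derivatives are exact on low-order polynomials", {
  t <- 0:10
  d1 <- waveform_derivative(waveform(t, 3 * t + 1, kind = "transparency"), 1)
  expect_equal(d1$values, rep(3, 11), tolerance = 1e-9)
  d2 <- waveform_derivative(waveform(t, t^2, kind = "transparency"), 2)
  expect_equal(d2$values, rep(2, 11), tolerance = 1e-9)
  # scaling by the sampling interval is honoured
  th <- seq(0, 5, by = 0.5)
  d2h <- waveform_derivative(waveform(th, th^2, kind = "transparency"), 2)
  expect_equal(d2h$values, rep(2, length(th)), tolerance = 1e-9)
})

test_that("first derivative of a logistic matches a dense finite-difference oracle", {
  t <- 0:60
  f <- function(t) 4000 - 2000 / (1 + exp(-(t - 30) / 6))
  wf <- waveform(t, f(t), kind = "transparency")
  d1 <- waveform_derivative(wf, 1)
  h <- 1e-3
  oracle <- (f(t + h) - f(t - h)) / (2 * h)
  interior <- 5:57
  rel <- abs(d1$values[interior] - oracle[interior]) / max(abs(oracle))
  expect_lt(max(rel), 0.01)
})

test_that("derivative rejects non-uniform grids and bad windows", {
  wf <- waveform(c(0, 1, 3, 4, 5), 1:5, kind = "transparency")
  expect_error(waveform_derivative(wf, 1), "resample")
  u <- waveform(0:4, 1:5, kind = "transparency")
  expect_error(waveform_derivative(u, 1, window = 4), "odd")
  expect_error(waveform_derivative(u, 1, window = 5, polyorder = 5), "polyorder")
  expect_error(waveform_derivative(waveform(0:2, 1:3, kind = "transparency"), 1),
               "shorter")
})

test_that("feature extraction handles flat and monotone curves", {
  flat <- waveform(0:20, rep(1500, 21), kind = "transparency")
  fv <- extract_features(flat)
  expect_equal(as.numeric(fv), c(1500, 0, 0, 0))
  sig <- fixture_sigmoid_pt(depth = 2000, t_mid = 25)
  fv2 <- extract_features(sig)
  expect_equal(fv2[["t_min"]], min(sig$values))
  expect_gt(fv2[["g_max"]], 0)
  expect_gte(fv2[["d2_max"]], fv2[["d2_min"]])
  expect_error(extract_features(waveform(0:20, rep(1, 21), kind = "attenuance")),
               "transparency")
})

test_that("feature extraction equals an exhaustive index scan", {
  set.seed(11)
  for (rep in 1:5) {
    wf <- fixture_sigmoid_pt(depth = runif(1, 500, 3500),
                             t_mid = runif(1, 10, 45), steep = runif(1, 2, 9))
    wf$values <- pmax(wf$values + rnorm(61, 0, 10), 0)
    fv <- extract_features(wf)
    d1 <- waveform_derivative(wf, 1)$values
    d2 <- waveform_derivative(wf, 2)$values
    # brute-force scan over every index
    t_min <- Inf; g_max <- -Inf; d2_max <- -Inf; d2_min <- Inf
    for (i in seq_along(wf$values)) {
      if (wf$values[i] < t_min) t_min <- wf$values[i]
      if (abs(d1[i]) > g_max) g_max <- abs(d1[i])
      if (d2[i] > d2_max) d2_max <- d2[i]
      if (d2[i] < d2_min) d2_min <- d2[i]
    }
    expect_identical(as.numeric(fv), c(t_min, g_max, d2_max, d2_min))
  }
})

test_that("transparency/attenuance conversion is exact and invertible", {
  t <- 0:30
  Tm <- 4000 * 10^(-seq(0, 0.5, length.out = 31))
  wf <- waveform(t, Tm, kind = "transparency")
  A <- attenuance_from_transparency(wf)
  expect_equal(A$values[1], 0)
  expect_equal(A$kind, "attenuance")
  # one decade drop is exactly attenuance 1
  wf10 <- waveform(0:1, c(4000, 400), kind = "transparency")
  expect_equal(attenuance_from_transparency(wf10)$values[2], 1.0)
  # flat signal has zero attenuance
  expect_equal(attenuance_from_transparency(
    waveform(0:5, rep(1234, 6), kind = "transparency"))$values, rep(0, 6))
  # round trip
  back <- transparency_from_attenuance(A, t_ref = 4000)
  expect_equal(back$values, Tm, tolerance = 1e-12)
  expect_error(attenuance_from_transparency(
    waveform(0:1, c(0, 4), kind = "thrombin")), "transparency")
})

test_that("max attenuance increase is a supremum over the trace", {
  expect_equal(max_attenuance_increase(
    waveform(0:10, rep(0, 11), kind = "attenuance")), 0)
  A <- waveform(0:10, c(seq(0, 0.35, length.out = 8), 0.35, 0.34, 0.35),
                kind = "attenuance")
  expect_equal(max_attenuance_increase(A), 0.35)
  set.seed(3)
  vals <- cumsum(rnorm(50, 0.01, 0.02))
  An <- waveform(0:49, vals, kind = "attenuance")
  expect_equal(max_attenuance_increase(An), max(vals - vals[1]))
})

test_that("strata classification follows the printed INR/anti-Xa/D-dimer rules", {
  rec <- function(...) sample_record("x", ...)
  expect_equal(classify_sample(rec(inr = 1.0))$inr_stratum, "regular")
  expect_false(classify_sample(rec(inr = 1.0))$challenging)
  # band edges are inclusive as printed
  expect_equal(classify_sample(rec(inr = 1.1))$inr_stratum, "regular")
  expect_equal(classify_sample(rec(inr = 1.2))$inr_stratum, "intermediate")
  expect_equal(classify_sample(rec(inr = 1.5))$inr_stratum, "intermediate")
  expect_equal(classify_sample(rec(inr = 1.51))$inr_stratum, "high")
  # the open gap (1.1, 1.2) resolves by rounding to one decimal
  expect_equal(classify_sample(rec(inr = 1.14))$inr_stratum, "regular")
  expect_equal(classify_sample(rec(inr = 1.16))$inr_stratum, "intermediate")
  # anti-Xa positivity is strict
  expect_false(classify_sample(rec(anti_xa = 0.10))$anti_xa_positive)
  expect_true(classify_sample(rec(anti_xa = 0.11))$anti_xa_positive)
  expect_true(classify_sample(rec(anti_xa = 0.11))$challenging)
  expect_false(classify_sample(rec(d_dimer = 0.5))$d_dimer_elevated)
  expect_true(classify_sample(rec(d_dimer = 0.51))$d_dimer_elevated)
  # missing fields: unknown stratum, not challenging
  u <- classify_sample(rec())
  expect_equal(u$inr_stratum, "unknown")
  expect_false(u$challenging)
  expect_error(sample_record("x", inr = -1), ">= 0")
})
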