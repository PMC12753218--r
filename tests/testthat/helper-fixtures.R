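# shared fixtures, all generated in code

# canonical synthetic thrombin curve used by polymer/TG tests
fixture_thrombin <- function(peak = 200) {
  synth_thrombin_curve(tg_curve_params(lag = 60, peak = peak, t_peak = 180,
                                       decay = 0.01),
                       sample_id = "FIX")
}

# smooth sigmoid transparency drop on the PT grid (t = 0..60 s)
fixture_sigmoid_pt <- function(depth = 2000, t_mid = 25, steep = 4,
                               t0 = 4000, sample_id = "SIG") {
  t <- 0:60
  waveform(t, t0 - depth / (1 + exp(-(t - t_mid) / steep)),
           kind = "transparency", assay = "PT", sample_id = sample_id)
}

# records whose PT waveforms vary smoothly; used to build feature matrices
# and, where needed, targets exactly linear in those features
fixture_feature_records <- function(n = 12, beta = NULL, intercept = 1,
                                    seed = 42) {
  withr::with_seed(seed, {
    recs <- lapply(seq_len(n), function(i) {
      wf <- fixture_sigmoid_pt(depth = runif(1, 500, 3500),
                               t_mid = runif(1, 15, 40),
                               steep = runif(1, 2, 8),
                               sample_id = sprintf("F%02d", i))
      sample_record(sprintf("F%02d", i), fibrinogen_ref = 1, waveforms = list(pt = wf))
    })
    feats <- do.call(rbind, lapply(recs, function(r) {
      as.numeric(extract_features(r$waveforms$pt))
    }))
    colnames(feats) <- c("t_min", "g_max", "d2_max", "d2_min")
    if (!is.null(beta)) {
      y <- intercept + as.numeric(feats %*% beta)
      for (i in seq_len(n)) recs[[i]]$fibrinogen_ref <- y[i]
    }
    list(records = recs, features = feats)
  })
}

# render a curve (values in mA on t = 0..60) into a grayscale raster with a
# given stroke width; returns the image plus its calibration
fixture_render_curve <- function(values, px_per_s = 5, px_per_mA = 0.05,
                                 stroke = 3, margin = 10) {
  stopifnot(length(values) == 61)
  width <- margin * 2 + 60 * px_per_s
  height <- margin * 2 + round(4000 * px_per_mA)
  img <- matrix(1, nrow = height, ncol = width)
  cal <- axis_calibration(left = margin, top = margin,
                          right = margin + 60 * px_per_s,
                          bottom = margin + round(4000 * px_per_mA))
  # dense parameterization so the stroke is continuous
  tt <- seq(0, 60, by = 1 / (2 * px_per_s))
  vv <- approx(0:60, values, xout = tt)$y
  for (i in seq_along(tt)) {
    px <- round(cal$left + tt[i] / 60 * (cal$right - cal$left))
    fy <- 1 - vv[i] / 4000
    py <- round(cal$top + fy * (cal$bottom - cal$top))
    rows <- pmax(1, pmin(nrow(img), (py - stroke %/% 2):(py + stroke %/% 2)))
    img[rows, px] <- 0
  }
  list(img = img, cal = cal,
       quantum = 4000 / (cal$bottom - cal$top))
}
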