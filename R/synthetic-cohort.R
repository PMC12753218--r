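#' Synthetic cohort configuration
#'
#' Defaults emulate the study mix: 44 samples spanning fibrinogen
#' 1.1-16.6 g/L, 24/44 with a prolonged PT (vitamin-K-antagonist-like INR
#' 2-3), 14/44 anti-Xa positive (0.1-1.37 U/mL) and 4/44 with elevated
#' D-dimer; instrument-like additive Gaussian noise at 1% of the
#' transparency amplitude on a 4000 mA baseline.
#'
#' @param n Number of samples.
#' @param fib_range Fibrinogen range, g/L (log-uniform sampling).
#' @param frac_prolonged_pt,frac_antixa,frac_ddimer Challenge fractions.
#' @param noise_sd_frac Noise SD as a fraction of each waveform's
#'   transparency amplitude.
#' @param t0_light Baseline transmitted light, mA.
#' @param seed Integer seed; the cohort is a pure function of this config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 44L, fib_range = c(1.1, 16.6),
                          frac_prolonged_pt = 24 / 44, frac_antixa = 14 / 44,
                          frac_ddimer = 4 / 44, noise_sd_frac = 0.01,
                          t0_light = 4000, seed = 1L) {
  n <- as.integer(n)
  if (n < 8L) stop("cohort size must be at least 8", call. = FALSE)
  if (length(fib_range) != 2L || any(fib_range <= 0) || diff(fib_range) <= 0) {
    stop("fib_range must be positive and increasing", call. = FALSE)
  }
  for (f in c(frac_prolonged_pt, frac_antixa, frac_ddimer)) {
    if (f < 0 || f > 1) stop("challenge fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n = n, fib_range = fib_range,
                 frac_prolonged_pt = frac_prolonged_pt,
                 frac_antixa = frac_antixa, frac_ddimer = frac_ddimer,
                 noise_sd_frac = noise_sd_frac, t0_light = t0_light,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Parametric thrombin-generation curve
#'
#' Smooth unimodal stand-in for a measured thrombin curve: zero during the
#' lag phase, then a gamma-shaped rise peaking at `t_peak` followed by
#' exponential decay at rate `decay` (the alpha-2-macroglobulin/antithrombin
#' tail). Sampled like the assay: every 30 s for 1 h.
#'
#' @param lag Lag time, s.
#' @param peak Peak thrombin, nM.
#' @param t_peak Time of the peak, s (`> lag`).
#' @param decay Decay rate, 1/s.
#' @return An object of class `tg_curve_params`.
#' @export
tg_curve_params <- function(lag = 60, peak = 200, t_peak = 180, decay = 0.01) {
  if (any(c(lag, peak, t_peak, decay) < 0)) stop("parameters must be >= 0", call. = FALSE)
  if (t_peak <= lag) stop("t_peak must be greater than lag", call. = FALSE)
  structure(list(lag = lag, peak = peak, t_peak = t_peak, decay = decay),
            class = "tg_curve_params")
}

#' @rdname tg_curve_params
#' @param p A `tg_curve_params` object.
#' @param t_grid Sampling times, s (default 0 to 3600 by 30).
#' @param sample_id Label for the returned waveform.
#' @return `synth_thrombin_curve()`: a thrombin [waveform] in nM.
#' @export
synth_thrombin_curve <- function(p = tg_curve_params(),
                                 t_grid = seq(0, 3600, by = 30),
                                 sample_id = "") {
  stopifnot(inherits(p, "tg_curve_params"))
  s <- t_grid - p$lag
  sp <- p$t_peak - p$lag
  k <- max(p$decay * sp, 1e-6)
  v <- ifelse(s <= 0, 0, p$peak * (s / sp)^k * exp(k * (1 - s / sp)))
  waveform(t_grid, pmax(v, 0), kind = "thrombin", assay = "TG",
           sample_id = sample_id)
}

# anti-Xa (U/mL) -> thrombin amplitude scale, interpolating 1 -> 0.02
# geometrically as anti-Xa goes 0 -> 1.4 U/mL (heparin suppression of
# thrombin generation is closer to log-linear than linear in dose)
antixa_thrombin_scale <- function(anti_xa) {
  x <- pmin(pmax(anti_xa, 0), 1.4) / 1.4
  0.02^x
}

#' Generate one synthetic sample
#'
#' Draws per-sample thrombin-curve parameters, runs the forward
#' polymerization model for the requested assays and converts the attenuance
#' outputs to noisy transmitted-light waveforms
#' (`T = t0_light * 10^(-A)` plus Gaussian noise of SD `noise_sd_frac`
#' times the waveform's amplitude, clipped to `[0, t0_light]`).
#' Challenge effects: anti-Xa scales the thrombin amplitude down
#' (interpolating 1 to 0.02 as anti-Xa goes 0 to 1.4 U/mL); a prolonged-PT
#' flag assigns a VKA-like INR in 2-3 and stretches the PT burst rise time
#' by that INR; D-dimer affects metadata only. PT and RT waveforms are on
#' the t = 0..60 s unit grid, TG waveforms on the 0..3600 s 30-s grid.
#'
#' @param fib True fibrinogen, g/L.
#' @param sample_id Label.
#' @param prolonged_pt,antixa_pos,ddimer_elev Challenge flags.
#' @param cfg A [cohort_config] (noise and baseline settings).
#' @param params [kinetic_parameters] for the forward model.
#' @param assays Subset of `c("TG", "PT", "RT")` to generate.
#' @param seed Integer seed; the record is a pure function of its arguments.
#' @param pt_amplitude,pt_rise,rt_level Enzyme-input baselines: PT burst
#'   plateau (uM) and rise time (s), RT batroxobin-like level (uM).
#' @return A [sample_record] with metadata and the requested waveforms.
#' @export
synth_sample <- function(fib, sample_id = "S1", prolonged_pt = FALSE,
                         antixa_pos = FALSE, ddimer_elev = FALSE,
                         cfg = cohort_config(), params = kinetic_parameters(),
                         assays = c("TG", "PT", "RT"), seed = 1L,
                         pt_amplitude = 0.1, pt_rise = 3, rt_level = 0.1) {
  if (fib <= 0) stop("fibrinogen must be > 0 g/L", call. = FALSE)
  if (!all(assays %in% c("TG", "PT", "RT"))) stop("unknown assay flag", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  inr <- if (prolonged_pt) stats::runif(1, 2, 3) else stats::runif(1, 0.9, 1.1)
  anti_xa <- if (antixa_pos) stats::runif(1, 0.1, 1.37) else 0
  d_dimer <- if (ddimer_elev) stats::runif(1, 0.6, 4) else stats::runif(1, 0.05, 0.4)

  noisy_transparency <- function(sim, assay) {
    Tm <- cfg$t0_light * 10^(-sim$attenuance$values)
    amp <- max(Tm) - min(Tm)
    Tn <- Tm + stats::rnorm(length(Tm), 0, cfg$noise_sd_frac * amp)
    waveform(sim$times, pmin(pmax(Tn, 0), cfg$t0_light),
             kind = "transparency", assay = assay, sample_id = sample_id)
  }

  wfs <- list()
  if ("TG" %in% assays) {
    tgp <- tg_curve_params(
      lag = stats::runif(1, 30, 90),
      peak = stats::rlnorm(1, log(200), 0.25) * antixa_thrombin_scale(anti_xa),
      t_peak = stats::runif(1, 150, 260),
      decay = stats::runif(1, 0.006, 0.015))
    tgp$t_peak <- max(tgp$t_peak, tgp$lag + 30)
    thr <- synth_thrombin_curve(tgp, sample_id = sample_id)
    sim <- simulate_polymerization(
      fib, enzyme_input("TG_driven", curve = thr), params,
      t_grid = seq(0, 3600, by = 30))
    wfs$tg_thrombin <- thr
    wfs$tg_turbidity <- noisy_transparency(sim, "TG")
  }
  if ("PT" %in% assays) {
    rise <- pt_rise * if (prolonged_pt) inr else 1
    sim <- simulate_polymerization(
      fib, enzyme_input("PT_burst", amplitude = pt_amplitude, rise_s = rise),
      params, t_grid = seq(0, 60, by = 1))
    wfs$pt <- noisy_transparency(sim, "PT")
  }
  if ("RT" %in% assays) {
    sim <- simulate_polymerization(
      fib, enzyme_input("RT_constant", level = rt_level),
      params, t_grid = seq(0, 60, by = 1))
    wfs$rt <- noisy_transparency(sim, "RT")
  }
  sample_record(sample_id, fibrinogen_ref = fib, inr = inr,
                anti_xa = anti_xa, d_dimer = d_dimer, waveforms = wfs)
}

#' Generate a synthetic cohort
#'
#' Draws `cfg$n` fibrinogen values log-uniformly over `cfg$fib_range`,
#' assigns challenge flags to match the configured fractions exactly
#' (rounded counts, independently drawn index sets), and generates each
#' sample with [synth_sample()] using per-sample seeds derived from
#' `cfg$seed`. Bit-reproducible: the same config always yields the same
#' cohort, and the caller's RNG stream is left untouched.
#'
#' @param cfg A [cohort_config].
#' @param params [kinetic_parameters] for the forward model.
#' @param assays Subset of `c("TG", "PT", "RT")` to generate per sample.
#' @return List of [sample_record]s.
#' @export
synth_cohort <- function(cfg = cohort_config(), params = kinetic_parameters(),
                         assays = c("TG", "PT", "RT")) {
  stopifnot(inherits(cfg, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(cfg$seed)
  n <- cfg$n
  fib <- exp(stats::runif(n, log(cfg$fib_range[1]), log(cfg$fib_range[2])))
  pick <- function(frac) {
    k <- round(frac * n)
    flags <- logical(n)
    if (k > 0) flags[sample.int(n, k)] <- TRUE
    flags
  }
  prolonged <- pick(cfg$frac_prolonged_pt)
  antixa <- pick(cfg$frac_antixa)
  ddimer <- pick(cfg$frac_ddimer)
  seeds <- sample.int(2^30, n)
  lapply(seq_len(n), function(i) {
    synth_sample(fib[i], sample_id = sprintf("SYN%03d", i),
                 prolonged_pt = prolonged[i], antixa_pos = antixa[i],
                 ddimer_elev = ddimer[i], cfg = cfg, params = params,
                 assays = assays, seed = seeds[i])
  })
}

#' Cohort manifest
#'
#' One row of metadata per sample: truth fibrinogen, INR, anti-Xa, D-dimer,
#' strata labels and which waveforms are present.
#'
#' @param records List of [sample_record]s.
#' @return data.frame.
#' @export
cohort_manifest <- function(records) {
  rows <- lapply(records, function(r) {
    s <- classify_sample(r)
    data.frame(sample_id = r$sample_id, fibrinogen_ref = r$fibrinogen_ref,
               inr = r$inr, anti_xa = r$anti_xa, d_dimer = r$d_dimer,
               inr_stratum = s$inr_stratum, antixa_pos = s$anti_xa_positive,
               ddimer_elev = s$d_dimer_elevated, challenging = s$challenging,
               waveforms = paste(names(r$waveforms), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
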