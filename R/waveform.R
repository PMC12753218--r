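#' Clot waveform time series
#'
#' A `waveform` holds a single sampled optical or enzymatic time series from a
#' clotting assay: transmitted light ("transparency", mA), dimensionless
#' attenuance (decadic, relative to the well's own baseline), a thrombin
#' concentration curve (nM), or a raw fluorescence trace. Times are seconds
#' from assay start and must be strictly increasing.
#'
#' @param times Numeric vector of sampling times in seconds, strictly
#'   increasing, `times[1] >= 0`.
#' @param values Numeric vector of the same length as `times`; units depend on
#'   `kind` (mA for transparency, nM for thrombin, dimensionless attenuance).
#' @param kind Signal kind, one of `"transparency"`, `"attenuance"`,
#'   `"thrombin"`, `"fluorescence"`.
#' @param assay Assay tag, one of `"none"`, `"TG"`, `"PT"`, `"RT"`.
#' @param sample_id Opaque sample label.
#' @return An object of class `waveform`.
#' @examples
#' wf <- waveform(0:60, 4000 - 10 * (0:60), kind = "transparency", assay = "PT")
#' wf
#' @export
waveform <- function(times, values,
                     kind = c("transparency", "attenuance", "thrombin", "fluorescence"),
                     assay = c("none", "TG", "PT", "RT"),
                     sample_id = "") {
  kind <- match.arg(kind)
  assay <- match.arg(assay)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (length(times) == 0L) stop("waveform must contain at least one point", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(values))) {
    stop("waveform times and values must all be finite", call. = FALSE)
  }
  if (times[1] < 0) stop("waveform times must start at t >= 0", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("waveform times must be strictly increasing", call. = FALSE)
  }
  if (kind == "transparency" && any(values < 0)) {
    stop("transparency values must be >= 0", call. = FALSE)
  }
  structure(
    list(times = times, values = values, kind = kind, assay = assay,
         sample_id = as.character(sample_id)),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> kind=%s assay=%s n=%d t=[%g, %g] s%s\n",
              x$kind, x$assay, length(x$times), x$times[1],
              x$times[length(x$times)],
              if (nzchar(x$sample_id)) paste0(" sample=", x$sample_id) else ""))
  invisible(x)
}

#' @export
as.data.frame.waveform <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values)
}

#' @export
length.waveform <- function(x) length(x$times)

# sampling interval of a uniform waveform, or error pointing at resampling
uniform_dt <- function(wf, tol = 1e-8) {
  if (length(wf$times) < 2L) stop("waveform has fewer than 2 points", call. = FALSE)
  dts <- diff(wf$times)
  dt <- dts[1]
  if (any(abs(dts - dt) > tol * max(dt, 1))) {
    stop("waveform is not uniformly sampled; call resample_uniform() first",
         call. = FALSE)
  }
  dt
}

#' Resample a waveform onto a uniform grid
#'
#' Linear interpolation onto `t = 0, dt, ..., t_end`. The grid may extend at
#' most one step beyond the last sample (hold-last-value); before the first
#' sample the first value is held. Longer extrapolation is an error.
#'
#' @param wf A [waveform].
#' @param dt Grid step in seconds.
#' @param t_end Last grid time in seconds; must satisfy
#'   `t_end <= max(wf$times) + dt`.
#' @return A [waveform] on the uniform grid, same kind/assay/sample_id.
#' @export
resample_uniform <- function(wf, dt = 1, t_end = NULL) {
  stopifnot(inherits(wf, "waveform"))
  if (length(wf$times) < 2L) {
    stop("cannot resample a waveform with fewer than 2 points", call. = FALSE)
  }
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  t_last <- wf$times[length(wf$times)]
  if (is.null(t_end)) t_end <- floor(t_last / dt) * dt
  if (t_end > t_last + dt + 1e-12) {
    stop(sprintf(
      "t_end = %g extends more than one step beyond the last sample at %g s",
      t_end, t_last), call. = FALSE)
  }
  grid <- seq(0, t_end, by = dt)
  vals <- stats::approx(wf$times, wf$values, xout = grid, method = "linear",
                        rule = 2)$y
  waveform(grid, vals, kind = wf$kind, assay = wf$assay, sample_id = wf$sample_id)
}

#' Smoothed derivative of a uniformly sampled waveform
#'
#' Savitzky-Golay local-polynomial differentiation: within each window of
#' `window` samples a polynomial of degree `polyorder` is fit and its
#' derivative of the requested order evaluated, so the result is exact (to
#' machine precision) for polynomial signals of degree at most `polyorder`
#' and noise-robust otherwise. Units are the input units divided by
#' s^`order`.
#'
#' @param wf A uniformly sampled [waveform]; resample first if needed.
#' @param order Derivative order, 1 or 2.
#' @param window Odd window length in samples (default 5).
#' @param polyorder Local polynomial degree, `>= order` and `< window`
#'   (default 2).
#' @return A [waveform] of the same length and grid holding the derivative;
#'   its `kind` is preserved (units are implied by context).
#' @export
waveform_derivative <- function(wf, order, window = 5L, polyorder = 2L) {
  stopifnot(inherits(wf, "waveform"))
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("`order` must be 1 or 2", call. = FALSE)
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L != 1L) stop("`window` must be odd", call. = FALSE)
  if (polyorder >= window) stop("`polyorder` must be < `window`", call. = FALSE)
  if (polyorder < order) stop("`polyorder` must be >= `order`", call. = FALSE)
  if (length(wf$times) < window) {
    stop("waveform shorter than the smoothing window", call. = FALSE)
  }
  dt <- uniform_dt(wf)
  dv <- signal::sgolayfilt(wf$values, p = polyorder, n = window, m = order, ts = dt)
  # derivative values may be negative regardless of the parent signal's
  # sign constraints, so bypass the constructor's kind checks
  out <- wf
  out$values <- as.numeric(dv)
  out
}

#' Extract the four clot-waveform features
#'
#' The features feeding the regression and neural-network fibrinogen
#' estimators, computed from a transparency waveform and its smoothed first
#' and second time derivatives:
#' minimum transparency (`t_min`, mA), maximum absolute transparency gradient
#' (`g_max`, mA/s), and the maximum and minimum second derivative of
#' transparency (`d2_max`, `d2_min`, mA/s^2).
#'
#' @param wf A uniformly sampled transparency [waveform].
#' @param window,polyorder Savitzky-Golay settings passed to
#'   [waveform_derivative()].
#' @return An object of class `feature_vector`: named numeric vector
#'   `c(t_min, g_max, d2_max, d2_min)`.
#' @export
extract_features <- function(wf, window = 5L, polyorder = 2L) {
  stopifnot(inherits(wf, "waveform"))
  if (wf$kind != "transparency") {
    stop("features are defined on transparency waveforms", call. = FALSE)
  }
  d1 <- waveform_derivative(wf, 1L, window, polyorder)
  d2 <- waveform_derivative(wf, 2L, window, polyorder)
  fv <- c(t_min = min(wf$values),
          g_max = max(abs(d1$values)),
          d2_max = max(d2$values),
          d2_min = min(d2$values))
  structure(fv, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector>\n")
  print(unclass(x))
  invisible(x)
}

feature_names <- c("t_min", "g_max", "d2_max", "d2_min")

#' Convert transparency to attenuance and back
#'
#' Decadic attenuance relative to the well's own baseline:
#' `A(t) = log10(T_ref / T(t))` with `T_ref = T(0)` under the default policy,
#' so `A(0) = 0` and a falling transmitted-light trace maps to a rising
#' attenuance trace. `transparency_from_attenuance()` is the exact algebraic
#' inverse given the same reference.
#'
#' @param wf A transparency [waveform] with strictly positive values
#'   (attenuance waveform for the inverse).
#' @param t_ref Reference transparency in mA; default the first sample.
#' @return A [waveform] of kind `"attenuance"` (resp. `"transparency"`).
#' @export
attenuance_from_transparency <- function(wf, t_ref = NULL) {
  stopifnot(inherits(wf, "waveform"))
  if (wf$kind != "transparency") stop("input must be a transparency waveform", call. = FALSE)
  if (any(wf$values <= 0)) stop("transparency must be > 0 to form attenuance", call. = FALSE)
  if (is.null(t_ref)) t_ref <- wf$values[1]
  waveform(wf$times, log10(t_ref / wf$values), kind = "attenuance",
           assay = wf$assay, sample_id = wf$sample_id)
}

#' @rdname attenuance_from_transparency
#' @export
transparency_from_attenuance <- function(wf, t_ref) {
  stopifnot(inherits(wf, "waveform"))
  if (wf$kind != "attenuance") stop("input must be an attenuance waveform", call. = FALSE)
  waveform(wf$times, t_ref * 10^(-wf$values), kind = "transparency",
           assay = wf$assay, sample_id = wf$sample_id)
}

#' Maximum attenuance increase of a waveform
#'
#' `max over t of A(t) - A(0)`: the quantity projected onto the simulated
#' reference curve in the thrombin-generation route.
#'
#' @param wf An attenuance [waveform].
#' @return Nonnegative scalar.
#' @export
max_attenuance_increase <- function(wf) {
  stopifnot(inherits(wf, "waveform"))
  if (wf$kind != "attenuance") stop("input must be an attenuance waveform", call. = FALSE)
  max(wf$values - wf$values[1])
}

#' Sample record: waveforms plus clinical metadata
#'
#' Bundles the per-sample waveforms (thrombin-generation thrombin and
#' turbidity traces, PT and RT transparency traces) with the metadata used
#' for stratification: reference (Clauss or synthetic-truth) fibrinogen in
#' g/L, INR, anti-Xa activity in U/mL and D-dimer in mg/L. Any metadata field
#' may be `NA` when unmeasured.
#'
#' @param sample_id Sample label.
#' @param fibrinogen_ref Reference fibrinogen, g/L.
#' @param inr International normalized ratio.
#' @param anti_xa Anti-Xa activity, U/mL.
#' @param d_dimer D-dimer, mg/L.
#' @param waveforms Named list of [waveform]s; recognised keys are
#'   `tg_thrombin`, `tg_turbidity`, `pt`, `rt`.
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(sample_id, fibrinogen_ref = NA_real_, inr = NA_real_,
                          anti_xa = NA_real_, d_dimer = NA_real_,
                          waveforms = list()) {
  for (nm in c("fibrinogen_ref", "inr", "anti_xa", "d_dimer")) {
    v <- get(nm)
    if (!is.na(v) && v < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
  }
  if (!all(vapply(waveforms, inherits, logical(1), "waveform"))) {
    stop("`waveforms` must be a named list of waveform objects", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id),
         fibrinogen_ref = as.numeric(fibrinogen_ref),
         inr = as.numeric(inr), anti_xa = as.numeric(anti_xa),
         d_dimer = as.numeric(d_dimer), waveforms = waveforms),
    class = "sample_record"
  )
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample_record> %s fib_ref=%s g/L INR=%s anti-Xa=%s D-dimer=%s wfs={%s}\n",
              x$sample_id, format(x$fibrinogen_ref), format(x$inr),
              format(x$anti_xa), format(x$d_dimer),
              paste(names(x$waveforms), collapse = ",")))
  invisible(x)
}

#' Classify a sample into anticoagulation strata
#'
#' INR strata follow the printed closed intervals: regular 0.9-1.1,
#' intermediate 1.2-1.5, high > 1.5 (INR rounded to one decimal first, so
#' values in the open gap (1.1, 1.2) fall into the nearest printed band).
#' Anti-Xa is positive iff strictly > 0.10 U/mL; D-dimer elevated iff
#' > 0.5 mg/L. A sample is "challenging" if its INR stratum is above regular,
#' or it is anti-Xa positive, or D-dimer elevated; otherwise standard.
#' Missing fields map to the `"unknown"` stratum / `FALSE` flags.
#'
#' @param rec A [sample_record], or a single INR value via `inr =` etc.
#' @return A list with elements `inr_stratum` (one of `"regular"`,
#'   `"intermediate"`, `"high"`, `"unknown"`), `anti_xa_positive`,
#'   `d_dimer_elevated` and `challenging` (logicals).
#' @export
classify_sample <- function(rec) {
  stopifnot(inherits(rec, "sample_record"))
  inr <- rec$inr
  axa <- rec$anti_xa
  dd <- rec$d_dimer
  for (v in list(inr, axa, dd)) {
    if (!is.na(v) && v < 0) stop("metadata values must be >= 0", call. = FALSE)
  }
  stratum <- "unknown"
  if (!is.na(inr)) {
    # high is strict on the raw value; rounding to one decimal only resolves
    # the open gap (1.1, 1.2) between the printed closed bands
    r <- round(inr, 1)
    stratum <- if (inr > 1.5) "high"
               else if (r >= 0.9 && r <= 1.1) "regular"
               else if (r >= 1.2) "intermediate"
               else "unknown"
  }
  axa_pos <- !is.na(axa) && axa > 0.10
  dd_elev <- !is.na(dd) && dd > 0.5
  list(inr_stratum = stratum,
       anti_xa_positive = axa_pos,
       d_dimer_elevated = dd_elev,
       challenging = (stratum %in% c("intermediate", "high")) || axa_pos || dd_elev)
}
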