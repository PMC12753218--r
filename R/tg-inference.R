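#' Simulated reference curve: maximum attenuance increase vs fibrinogen
#'
#' Runs one forward simulation per fibrinogen grid point, each driven by the
#' same thrombin curve, and records the maximum attenuance increase. The
#' curve must come out strictly increasing in fibrinogen — that is the
#' property its inversion relies on — and construction fails naming the
#' offending interval otherwise.
#'
#' @param thrombin A thrombin [waveform] (nM) driving every simulation.
#' @param params A [kinetic_parameters] object.
#' @param fib_grid Strictly increasing fibrinogen grid in g/L, at least 4
#'   points (default 0.5 to 12 by 0.5).
#' @param t_grid Simulation output times (s).
#' @param rtol,atol Solver tolerances passed to [simulate_polymerization()].
#' @return An object of class `reference_curve`: list with `fib_grid`,
#'   `max_dA` and a `provenance` string.
#' @export
build_reference_curve <- function(thrombin, params = kinetic_parameters(),
                                  fib_grid = seq(0.5, 12, by = 0.5),
                                  t_grid = seq(0, 600, by = 5),
                                  rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(thrombin, "waveform"))
  if (thrombin$kind != "thrombin") stop("`thrombin` must be a thrombin waveform", call. = FALSE)
  if (length(fib_grid) < 4L) stop("fibrinogen grid needs at least 4 points", call. = FALSE)
  if (any(diff(fib_grid) <= 0) || any(fib_grid <= 0)) {
    stop("fibrinogen grid must be positive and strictly increasing", call. = FALSE)
  }
  ez <- enzyme_input("TG_driven", curve = thrombin)
  max_dA <- vapply(fib_grid, function(fib) {
    sim <- simulate_polymerization(fib, ez, params, t_grid, rtol = rtol, atol = atol)
    max_attenuance_increase(sim$attenuance)
  }, numeric(1))
  bad <- which(diff(max_dA) <= 0)
  if (length(bad)) {
    stop(sprintf(
      "reference curve not strictly increasing between %g and %g g/L (dA %g -> %g)",
      fib_grid[bad[1]], fib_grid[bad[1] + 1], max_dA[bad[1]], max_dA[bad[1] + 1]),
      call. = FALSE)
  }
  structure(
    list(fib_grid = fib_grid, max_dA = max_dA,
         provenance = sprintf(
           "clotwave reference curve | thrombin id=%s peak=%.3g nM | C_geom=%g k_poly=%g k_nuc=%g k_lat=%g",
           thrombin$sample_id, max(thrombin$values), params$C_geom,
           params$k_poly, params$k_nuc, params$k_lat)),
    class = "reference_curve"
  )
}

#' @export
print.reference_curve <- function(x, ...) {
  cat(sprintf("<reference_curve> %d points, fib %g-%g g/L, max dA %.4f-%.4f\n",
              length(x$fib_grid), min(x$fib_grid), max(x$fib_grid),
              min(x$max_dA), max(x$max_dA)))
  invisible(x)
}

#' Invert a reference curve at a measured attenuance increase
#'
#' Monotone shape-preserving interpolation (Fritsch-Carlson, via
#' `stats::splinefun(method = "monoH.FC")`) of fibrinogen as a function of
#' maximum attenuance increase. Values outside the simulated range are not
#' extrapolated: the estimator was not built for concentrations beyond its
#' grid, so these return status `"out_of_range"` instead of a number.
#'
#' @param ref A [build_reference_curve()] result.
#' @param measured_dA Measured maximum attenuance increase.
#' @return List with `fibrinogen` (g/L, `NA` when out of range) and `status`
#'   (`"ok"` or `"out_of_range"`).
#' @export
invert_reference <- function(ref, measured_dA) {
  stopifnot(inherits(ref, "reference_curve"))
  if (!is.finite(measured_dA)) stop("`measured_dA` must be finite", call. = FALSE)
  if (measured_dA < min(ref$max_dA) || measured_dA > max(ref$max_dA)) {
    return(list(fibrinogen = NA_real_, status = "out_of_range"))
  }
  fn <- stats::splinefun(ref$max_dA, ref$fib_grid, method = "monoH.FC")
  list(fibrinogen = as.numeric(fn(measured_dA)), status = "ok")
}

#' Quality control of thrombin-generation and turbidity curves
#'
#' Flags the atypical, very low curves that cannot support a reference-curve
#' estimate: a thrombin peak below `theta_peak` (e.g. heavily anticoagulated
#' samples) or a maximum attenuance increase below `theta_dA` (no measurable
#' clot signal). Thresholds are configuration, not measurements.
#'
#' @param tg Thrombin [waveform] (nM).
#' @param turb Turbidity [waveform]; transparency is converted to attenuance
#'   against its own baseline.
#' @param theta_peak Minimum acceptable thrombin peak, nM (default 10).
#' @param theta_dA Minimum acceptable attenuance increase (default 0.02).
#' @return One of `"ok"`, `"atypical_low_tg"`, `"atypical_low_turbidity"`.
#' @export
qc_atypical <- function(tg, turb, theta_peak = 10, theta_dA = 0.02) {
  if (missing(tg) || is.null(tg) || missing(turb) || is.null(turb)) {
    stop("both a thrombin and a turbidity waveform are required", call. = FALSE)
  }
  stopifnot(inherits(tg, "waveform"), inherits(turb, "waveform"))
  if (tg$kind != "thrombin") stop("`tg` must be a thrombin waveform", call. = FALSE)
  if (max(tg$values) < theta_peak) return("atypical_low_tg")
  A <- if (turb$kind == "transparency") attenuance_from_transparency(turb) else turb
  if (max_attenuance_increase(A) < theta_dA) return("atypical_low_turbidity")
  "ok"
}

#' Infer fibrinogen from thrombin-generation and turbidity waveforms
#'
#' The thrombin-generation route: the sample's own measured thrombin curve
#' drives forward simulations over a fibrinogen grid to build a per-sample
#' reference curve of maximum attenuance increase; the measured turbidity
#' waveform's maximum attenuance increase is then projected onto that curve.
#' Atypical samples (QC flags) and measurements outside the simulated range
#' yield no numeric estimate — they are flagged, never extrapolated.
#'
#' @param rec A [sample_record] with `tg_thrombin` and `tg_turbidity`
#'   waveforms.
#' @param params A [kinetic_parameters] object.
#' @param fib_grid Fibrinogen grid (g/L) for the reference curve.
#' @param t_grid Simulation output times (s).
#' @param theta_peak,theta_dA QC thresholds, see [qc_atypical()].
#' @param reference Optional precomputed [build_reference_curve()] result to
#'   reuse (e.g. when thrombin input is shared across calls).
#' @return An object of class `tg_estimate`: list with `fibrinogen` (g/L or
#'   `NA`), `qc` (`"ok"`, `"atypical_low_tg"`, `"atypical_low_turbidity"`,
#'   `"out_of_range"`) and `diagnostics` (peak thrombin nM, measured max dA).
#' @export
infer_fibrinogen_tg <- function(rec, params = kinetic_parameters(),
                                fib_grid = seq(0.5, 12, by = 0.5),
                                t_grid = seq(0, 600, by = 5),
                                theta_peak = 10, theta_dA = 0.02,
                                reference = NULL) {
  stopifnot(inherits(rec, "sample_record"))
  tg <- rec$waveforms$tg_thrombin
  turb <- rec$waveforms$tg_turbidity
  if (is.null(tg) || is.null(turb)) {
    stop(sprintf("sample %s lacks tg_thrombin and/or tg_turbidity waveforms",
                 rec$sample_id), call. = FALSE)
  }
  A <- if (turb$kind == "transparency") attenuance_from_transparency(turb) else turb
  diag <- list(peak_thrombin_nM = max(tg$values),
               measured_dA = max_attenuance_increase(A))
  qc <- qc_atypical(tg, turb, theta_peak, theta_dA)
  if (qc != "ok") {
    return(structure(list(fibrinogen = NA_real_, qc = qc, diagnostics = diag),
                     class = "tg_estimate"))
  }
  ref <- if (is.null(reference)) {
    build_reference_curve(tg, params, fib_grid, t_grid)
  } else reference
  inv <- invert_reference(ref, diag$measured_dA)
  if (inv$status != "ok") {
    return(structure(list(fibrinogen = NA_real_, qc = "out_of_range",
                          diagnostics = diag, reference = ref),
                     class = "tg_estimate"))
  }
  structure(list(fibrinogen = inv$fibrinogen, qc = "ok", diagnostics = diag,
                 reference = ref),
            class = "tg_estimate")
}

#' @export
print.tg_estimate <- function(x, ...) {
  cat(sprintf("<tg_estimate> qc=%s fibrinogen=%s g/L (peak thrombin %.1f nM, max dA %.4f)\n",
              x$qc, ifelse(is.na(x$fibrinogen), "--", sprintf("%.2f", x$fibrinogen)),
              x$diagnostics$peak_thrombin_nM, x$diagnostics$measured_dA))
  invisible(x)
}
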