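#' Read and write waveform CSV files
#'
#' Two-column CSV (`time_s,value`) preceded by `#`-prefixed metadata headers
#' `# kind=`, `# assay=`, `# sample_id=`, `# units=`. Writing then reading a
#' waveform reproduces it bit-for-bit; malformed rows and unsorted times are
#' rejected with the offending line named.
#'
#' @param path File path.
#' @param wf A [waveform] to write.
#' @return `read_waveform_csv()` returns a [waveform];
#'   `write_waveform_csv()` returns `path` invisibly.
#' @export
read_waveform_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1, nchar(kv)))
  }
  if (is.null(meta$kind)) stop("missing '# kind=' header", call. = FALSE)
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data rows", call. = FALSE)
  if (!identical(trimws(body[1]), "time_s,value")) {
    stop("expected column header 'time_s,value'", call. = FALSE)
  }
  parts <- strsplit(body[-1], ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed row at data line %d", bad[1] + 1L), call. = FALSE)
  }
  times <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1)))
  values <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  nn <- which(is.na(times) | is.na(values))
  if (length(nn)) stop(sprintf("non-numeric value at data line %d", nn[1] + 1L), call. = FALSE)
  inv <- which(diff(times) <= 0)
  if (length(inv)) {
    stop(sprintf("times not strictly increasing at data line %d (t=%g then t=%g)",
                 inv[1] + 2L, times[inv[1]], times[inv[1] + 1L]), call. = FALSE)
  }
  waveform(times, values, kind = meta$kind,
           assay = if (is.null(meta$assay)) "none" else meta$assay,
           sample_id = if (is.null(meta$sample_id)) "" else meta$sample_id)
}

#' @rdname read_waveform_csv
#' @export
write_waveform_csv <- function(wf, path) {
  stopifnot(inherits(wf, "waveform"))
  units <- switch(wf$kind, transparency = "mA", thrombin = "nM",
                  attenuance = "dimensionless", fluorescence = "au")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind=%s", wf$kind),
               sprintf("# assay=%s", wf$assay),
               sprintf("# sample_id=%s", wf$sample_id),
               sprintf("# units=%s", units),
               "time_s,value",
               sprintf("%.17g,%.17g", wf$times, wf$values)), con)
  invisible(path)
}

#' Read and write reference-curve CSV files
#'
#' Columns `fib_g_per_L,max_dA` with the provenance string as a `#` header.
#' @param ref A [build_reference_curve()] result.
#' @param path File path.
#' @return `read_reference_curve_csv()` returns a `reference_curve`.
#' @export
write_reference_curve_csv <- function(ref, path) {
  stopifnot(inherits(ref, "reference_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# provenance=%s", ref$provenance),
               "fib_g_per_L,max_dA",
               sprintf("%.17g,%.17g", ref$fib_grid, ref$max_dA)), con)
  invisible(path)
}

#' @rdname write_reference_curve_csv
#' @export
read_reference_curve_csv <- function(path) {
  lines <- readLines(path)
  prov <- sub("^#\\s*provenance=", "", grep("^#\\s*provenance=", lines, value = TRUE))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  structure(list(fib_grid = as.numeric(df$fib_g_per_L),
                 max_dA = as.numeric(df$max_dA),
                 provenance = if (length(prov)) prov else ""),
            class = "reference_curve")
}

#' Write a prediction set as CSV
#'
#' @param preds A [loo_evaluate()] prediction set.
#' @param path File path.
#' @export
write_predictions_csv <- function(preds, path) {
  stopifnot(inherits(preds, "prediction_set"))
  utils::write.csv(as.data.frame(preds), path, row.names = FALSE)
  invisible(path)
}

#' Serialize fitted models to JSON
#'
#' Stores the linear coefficients and/or network weights, the standardizer
#' constants, and the seed, so a prediction can be reproduced without
#' retraining.
#'
#' @param model A `linear_model` or `nn_model`.
#' @param path File path.
#' @return `read_model_json()` returns the model object.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "linear_model")) {
    obj <- list(type = "linear", intercept = model$intercept,
                coefficients = as.list(model$coefficients))
  } else if (inherits(model, "nn_model")) {
    obj <- list(type = "nn", W1 = model$W1, b1 = model$b1,
                W2 = model$W2, b2 = model$b2, seed = model$seed,
                standardizer = list(means = as.list(model$standardizer$means),
                                    sds = as.list(model$standardizer$sds)))
  } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "linear")) {
    structure(list(intercept = obj$intercept,
                   coefficients = unlist(obj$coefficients)),
              class = "linear_model")
  } else if (identical(obj$type, "nn")) {
    std <- structure(list(means = unlist(obj$standardizer$means),
                          sds = unlist(obj$standardizer$sds)),
                     class = "standardizer")
    structure(list(W1 = matrix(obj$W1, 3, 4), b1 = as.numeric(obj$b1),
                   W2 = matrix(obj$W2, 1, 3), b2 = as.numeric(obj$b2),
                   standardizer = std, seed = obj$seed),
              class = "nn_model")
  } else stop("unknown model type in JSON", call. = FALSE)
}

#' Axis calibration of a rasterized clot-waveform plot
#'
#' Maps the pixel box of the plot area to data coordinates. The printed
#' clot-waveform axes are fixed: time 0-60 s and transmitted light
#' 0-4000 mA.
#'
#' @param left,top,right,bottom Pixel bounds of the plot area (columns
#'   left/right, rows top/bottom, 1-based, inclusive).
#' @param t_range Time axis range, s.
#' @param light_range Transmitted-light axis range, mA.
#' @param y_increases_downward Raster row 1 is the top of the image.
#' @return An object of class `axis_calibration`.
#' @export
axis_calibration <- function(left, top, right, bottom,
                             t_range = c(0, 60), light_range = c(0, 4000),
                             y_increases_downward = TRUE) {
  if (right <= left || bottom <= top) stop("degenerate plot box", call. = FALSE)
  if (diff(t_range) <= 0 || diff(light_range) <= 0) {
    stop("axis ranges must be increasing", call. = FALSE)
  }
  structure(list(left = left, top = top, right = right, bottom = bottom,
                 t_range = t_range, light_range = light_range,
                 y_increases_downward = y_increases_downward),
            class = "axis_calibration")
}

#' Otsu threshold of a grayscale image
#'
#' Maximizes between-class variance over a 256-bin histogram; used as the
#' automatic dark-pixel threshold for curve extraction.
#'
#' @param img Numeric matrix in `[0, 1]`, 0 = black.
#' @return Scalar threshold in `[0, 1]`.
#' @export
otsu_threshold <- function(img) {
  v <- as.numeric(img)
  if (!length(v) || any(!is.finite(v))) stop("invalid image", call. = FALSE)
  h <- tabulate(pmin(pmax(floor(v * 256) + 1L, 1L), 256L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 0.5) / 256)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) / 256
}

#' Extract a clot waveform from a rasterized plot
#'
#' Re-implementation of the purpose-made curve-extraction step: for each
#' second t = 0..60 the corresponding pixel column inside the calibrated
#' plot box is scanned, the darkness-weighted centroid row of pixels darker
#' than the threshold is taken, and the row is mapped back to transmitted
#' light in mA. Columns with no dark pixel are filled by linear
#' interpolation from their neighbours, up to at most 20% of columns.
#'
#' @param img Numeric matrix in `[0, 1]`, 0 = black (rows = image rows).
#'   PNG files can be loaded with [read_raster_png()].
#' @param cal An [axis_calibration]; box must lie within the image.
#' @param dark_threshold Intensity below which a pixel counts as curve;
#'   `NULL` (default) uses [otsu_threshold()].
#' @return A transparency [waveform] on t = 0..60 s, values in the
#'   calibrated mA range.
#' @export
extract_curve <- function(img, cal, dark_threshold = NULL) {
  stopifnot(is.matrix(img), inherits(cal, "axis_calibration"))
  if (cal$left < 1 || cal$top < 1 || cal$right > ncol(img) || cal$bottom > nrow(img)) {
    stop("plot box exceeds image bounds", call. = FALSE)
  }
  if (is.null(dark_threshold)) dark_threshold <- otsu_threshold(img)
  t_out <- seq(cal$t_range[1], cal$t_range[2], by = 1)
  n_col <- cal$right - cal$left
  vals <- rep(NA_real_, length(t_out))
  for (i in seq_along(t_out)) {
    fx <- (t_out[i] - cal$t_range[1]) / diff(cal$t_range)
    px <- round(cal$left + fx * n_col)
    col <- img[cal$top:cal$bottom, px]
    dark <- which(col < dark_threshold)
    if (length(dark)) {
      w <- dark_threshold - col[dark]
      if (sum(w) <= 0) w <- rep(1, length(dark))
      centroid <- sum(dark * w) / sum(w)          # row offset within box
      fy <- (centroid - 1) / (cal$bottom - cal$top)
      if (cal$y_increases_downward) fy <- 1 - fy
      vals[i] <- cal$light_range[1] + fy * diff(cal$light_range)
    }
  }
  n_empty <- sum(is.na(vals))
  if (n_empty == length(vals)) stop("no curve pixels found (all-light image?)", call. = FALSE)
  if (n_empty > 0.2 * length(vals)) {
    stop(sprintf("curve extraction failed: %d of %d columns empty",
                 n_empty, length(vals)), call. = FALSE)
  }
  if (n_empty > 0) {
    ok <- !is.na(vals)
    vals <- stats::approx(t_out[ok], vals[ok], xout = t_out, rule = 2)$y
  }
  vals <- pmin(pmax(vals, cal$light_range[1]), cal$light_range[2])
  waveform(t_out, vals, kind = "transparency", assay = "none")
}

#' Load a PNG image as a grayscale matrix
#'
#' Averages color channels; returns intensities in `[0, 1]` with 0 = black.
#' @param path PNG file path.
#' @return Numeric matrix.
#' @export
read_raster_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  a
}

#' Read and write kinetic-parameter configurations
#'
#' Parameter sets serialize to YAML or JSON (by file extension) so model
#' variants can be versioned alongside analyses. Unknown keys are rejected.
#'
#' @param params A [kinetic_parameters] object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_kinetic_parameters()` returns a [kinetic_parameters].
#' @export
write_kinetic_parameters <- function(params, path) {
  stopifnot(inherits(params, "kinetic_parameters"))
  obj <- unclass(params)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported config extension (use .yaml or .json)", call. = FALSE)
  invisible(path)
}

#' @rdname write_kinetic_parameters
#' @export
read_kinetic_parameters <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config extension (use .yaml or .json)", call. = FALSE)
  known <- names(formals(kinetic_parameters))
  extra <- setdiff(names(obj), known)
  if (length(extra)) {
    stop(sprintf("unknown parameter(s) in config: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  do.call(kinetic_parameters, obj)
}
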