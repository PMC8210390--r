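#' Saturation-recovery series container
#'
#' Bundles an image stack acquired at increasing saturation-recovery delays
#' with its timing metadata. Each frame is a numeric matrix of signal
#' intensities; frame `i` was acquired at delay `delays[i]`.
#'
#' @param frames list of numeric matrices (one per delay), identical dims,
#'   finite and non-negative.
#' @param delays numeric vector of saturation-recovery delay times TD (ms),
#'   strictly increasing, all positive, length >= 3.
#' @param mask optional logical matrix of pixels to fit; defaults to all.
#' @param pixel_spacing pixel size in mm (scalar), metadata only.
#' @return object of class `recovery_series`.
#' @export
recovery_series <- function(frames, delays, mask = NULL, pixel_spacing = NA_real_) {
  stopifnot(is.list(frames), length(frames) >= 3L)
  if (length(frames) != length(delays))
    stop("number of frames (", length(frames), ") must equal number of delays (",
         length(delays), ")")
  if (any(!is.finite(delays)) || any(delays <= 0))
    stop("all delays must be finite and > 0")
  if (any(diff(delays) <= 0)) stop("delays must be strictly increasing")
  dims <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), dims)) stop("all frames must share dimensions")
    if (any(!is.finite(f)) || any(f < 0))
      stop("signal values must be finite and >= 0")
  }
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  stopifnot(identical(dim(mask), dims))
  structure(list(frames = frames, delays = as.numeric(delays),
                 mask = mask, pixel_spacing = pixel_spacing),
            class = "recovery_series")
}

#' Multi-echo series container
#'
#' @param frames list of numeric matrices, one per echo time.
#' @param echoes numeric vector of echo times TE (ms), strictly increasing,
#'   positive, length >= 2.
#' @param mask optional logical matrix of pixels to fit.
#' @return object of class `echo_series`.
#' @export
echo_series <- function(frames, echoes, mask = NULL) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  if (length(frames) != length(echoes))
    stop("number of frames must equal number of echoes")
  if (any(!is.finite(echoes)) || any(echoes <= 0))
    stop("all echoes must be finite and > 0")
  if (any(diff(echoes) <= 0)) stop("echoes must be strictly increasing")
  dims <- dim(frames[[1]])
  for (f in frames) if (!identical(dim(f), dims)) stop("all frames must share dimensions")
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  structure(list(frames = frames, echoes = as.numeric(echoes), mask = mask),
            class = "echo_series")
}

# Residual sum of squares of the saturation-recovery model at a fixed T1,
# with the scale factors (A, B) profiled out by closed-form linear LS:
# M = A - B * exp(-TD/T1) is linear in (A, B) once T1 is fixed.
.t1_profile <- function(t1, signal, delays) {
  e <- exp(-delays / t1)
  n <- length(signal)
  # normal equations for design [1, -e]
  s_e <- sum(e); s_ee <- sum(e * e)
  s_y <- sum(signal); s_ey <- sum(e * signal)
  det <- n * s_ee - s_e * s_e
  if (abs(det) < .Machine$double.eps * n) return(list(rss = Inf, A = NA_real_, B = NA_real_))
  A <- (s_ee * s_y - s_e * s_ey) / det
  B <- (s_e * s_y - n * s_ey) / det   # coefficient on -e
  r <- signal - (A - B * e)
  list(rss = sum(r * r), A = A, B = B)
}

#' Fit the three-parameter saturation-recovery model to one pixel
#'
#' Estimates (A, B, T1) in the signal model M(TD) = A - B * exp(-TD/T1) by
#' separable nonlinear least squares: for each candidate T1 the scale factors
#' are the exact linear least-squares solution, and T1 itself is found by a
#' coarse log-spaced grid followed by bounded 1-D minimisation of the
#' profiled residual sum of squares.
#'
#' @param signal numeric vector of observed intensities M.
#' @param delays numeric vector of saturation delays TD (ms), strictly
#'   increasing, same length as `signal`, length >= 3.
#' @param t1_bounds admissible T1 range in ms.
#' @return list of class `t1_fit` with elements `A`, `B`, `T1` (ms), `rmse`
#'   and `converged`. A failed fit (degenerate signal, negative recovery
#'   amplitude, or T1 pinned at a bound) has `converged = FALSE` and `NA`
#'   parameter values.
#' @export
fit_t1_pixel <- function(signal, delays, t1_bounds = c(1, 10000)) {
  if (length(signal) != length(delays))
    stop("signal and delays must have the same length")
  if (length(signal) < 3L) stop("at least 3 (signal, delay) pairs are required")
  if (any(delays <= 0)) stop("delays must be positive")
  if (any(diff(delays) <= 0)) stop("delays must be strictly increasing")
  signal <- as.numeric(signal); delays <- as.numeric(delays)

  bad <- list(A = NA_real_, B = NA_real_, T1 = NA_real_, rmse = NA_real_,
              converged = FALSE)
  class(bad) <- "t1_fit"
  if (all(signal == signal[1])) return(bad)   # flat signal carries no T1 information

  grid <- exp(seq(log(t1_bounds[1]), log(t1_bounds[2]), length.out = 60))
  rss <- vapply(grid, function(t1) .t1_profile(t1, signal, delays)$rss, numeric(1))
  i <- which.min(rss)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(t1) .t1_profile(t1, signal, delays)$rss,
                         interval = c(lo, hi), tol = 1e-10)
  t1 <- opt$minimum
  # polish with a second pass on a tight bracket (guards golden-section stalls)
  opt2 <- stats::optimize(function(t1) .t1_profile(t1, signal, delays)$rss,
                          interval = c(t1 * 0.98, t1 * 1.02), tol = 1e-12)
  if (opt2$objective < opt$objective) t1 <- opt2$minimum
  pr <- .t1_profile(t1, signal, delays)
  at_bound <- t1 <= t1_bounds[1] * 1.001 || t1 >= t1_bounds[2] * 0.999
  if (!is.finite(pr$rss) || pr$B <= 0 || at_bound) return(bad)
  structure(list(A = pr$A, B = pr$B, T1 = t1,
                 rmse = sqrt(pr$rss / length(signal)), converged = TRUE),
            class = "t1_fit")
}

#' Fit T1 pixel-by-pixel over a saturation-recovery series
#'
#' Applies [fit_t1_pixel()] to every pixel in the mask. Failed fits are kept
#' as `NA` (the invalid-pixel sentinel) — never interpolated.
#'
#' @param series a [recovery_series()].
#' @return a `parametric_map` (list with `values`, `quality` = per-pixel
#'   RMSE, `kind = "T1"`).
#' @export
fit_t1_map <- function(series) {
  stopifnot(inherits(series, "recovery_series"))
  if (!any(series$mask)) stop("mask is empty: no pixels to fit")
  dims <- dim(series$frames[[1]])
  sig <- vapply(series$frames, as.numeric, numeric(prod(dims)))  # pixels x delays
  values <- matrix(NA_real_, dims[1], dims[2])
  quality <- matrix(NA_real_, dims[1], dims[2])
  idx <- which(series$mask)
  for (p in idx) {
    ft <- fit_t1_pixel(sig[p, ], series$delays)
    if (ft$converged) { values[p] <- ft$T1; quality[p] <- ft$rmse }
  }
  structure(list(values = values, quality = quality, kind = "T1"),
            class = "parametric_map")
}

# Profiled RSS for mono-exponential decay S = S0 * exp(-TE/T2) at fixed T2.
.t2_profile <- function(t2, signal, echoes) {
  e <- exp(-echoes / t2)
  s0 <- sum(e * signal) / sum(e * e)
  r <- signal - s0 * e
  list(rss = sum(r * r), S0 = s0)
}

#' Fit the mono-exponential decay model to one pixel
#'
#' Estimates (S0, T2) in S(TE) = S0 * exp(-TE/T2). The primary path is
#' weighted log-linear least squares (weights proportional to signal^2,
#' which undoes the variance distortion of the log transform); if any signal
#' is non-positive the fit falls back to separable nonlinear least squares
#' on the raw signal.
#'
#' @param signal numeric vector of echo intensities.
#' @param echoes numeric vector of echo times TE (ms), strictly increasing.
#' @param t2_bounds admissible T2 range (ms) for the nonlinear path.
#' @return list of class `t2_fit` with `S0`, `T2` (ms), `rmse`, `converged`.
#' @export
fit_t2_pixel <- function(signal, echoes, t2_bounds = c(0.1, 1000)) {
  if (length(signal) != length(echoes))
    stop("signal and echoes must have the same length")
  if (length(signal) < 2L) stop("at least 2 echoes are required")
  if (any(echoes <= 0)) stop("echoes must be positive")
  signal <- as.numeric(signal); echoes <- as.numeric(echoes)

  bad <- structure(list(S0 = NA_real_, T2 = NA_real_, rmse = NA_real_,
                        converged = FALSE), class = "t2_fit")
  if (all(signal == 0)) return(bad)

  if (all(signal > 0)) {
    w <- signal^2
    fit <- stats::lm.wfit(cbind(1, echoes), log(signal), w)
    slope <- fit$coefficients[2]
    if (is.finite(slope) && slope < 0) {
      t2 <- -1 / slope
      s0 <- exp(fit$coefficients[1])
      r <- signal - s0 * exp(-echoes / t2)
      return(structure(list(S0 = unname(s0), T2 = unname(t2),
                            rmse = sqrt(mean(r^2)), converged = TRUE),
                       class = "t2_fit"))
    }
  }
  # nonlinear fallback: profile S0 out, 1-D search over T2
  grid <- exp(seq(log(t2_bounds[1]), log(t2_bounds[2]), length.out = 60))
  rss <- vapply(grid, function(t2) .t2_profile(t2, signal, echoes)$rss, numeric(1))
  i <- which.min(rss)
  opt <- stats::optimize(function(t2) .t2_profile(t2, signal, echoes)$rss,
                         interval = c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)]),
                         tol = 1e-10)
  pr <- .t2_profile(opt$minimum, signal, echoes)
  at_bound <- opt$minimum <= t2_bounds[1] * 1.001 || opt$minimum >= t2_bounds[2] * 0.999
  if (!is.finite(pr$rss) || pr$S0 <= 0 || at_bound) return(bad)
  structure(list(S0 = pr$S0, T2 = opt$minimum,
                 rmse = sqrt(pr$rss / length(signal)), converged = TRUE),
            class = "t2_fit")
}

#' Fit T2 pixel-by-pixel over a multi-echo series
#'
#' @param series an [echo_series()].
#' @return a `parametric_map` with `kind = "T2"`.
#' @export
fit_t2_map <- function(series) {
  stopifnot(inherits(series, "echo_series"))
  if (!any(series$mask)) stop("mask is empty: no pixels to fit")
  dims <- dim(series$frames[[1]])
  sig <- vapply(series$frames, as.numeric, numeric(prod(dims)))
  values <- matrix(NA_real_, dims[1], dims[2])
  quality <- matrix(NA_real_, dims[1], dims[2])
  for (p in which(series$mask)) {
    ft <- fit_t2_pixel(sig[p, ], series$echoes)
    if (ft$converged) { values[p] <- ft$T2; quality[p] <- ft$rmse }
  }
  structure(list(values = values, quality = quality, kind = "T2"),
            class = "parametric_map")
}

#' ROI statistics over a parametric map
#'
#' Mean, sample SD and count over the valid (non-sentinel) pixels of a
#' region of interest.
#'
#' @param map a `parametric_map`.
#' @param roi logical matrix, same dims as the map.
#' @return list with `mean`, `sd`, `n`.
#' @export
map_roi_stats <- function(map, roi) {
  stopifnot(inherits(map, "parametric_map"), is.logical(roi),
            identical(dim(roi), dim(map$values)))
  v <- map$values[roi]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("ROI contains no valid pixels")
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("%s map: %d x %d pixels, %d valid; range %.1f-%.1f ms\n",
              x$kind, nrow(x$values), ncol(x$values), length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}
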