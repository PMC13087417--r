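#' Fluorescence kinetic trace
#'
#' A pyrene-fluorescence time series from an actin polymerization
#' (rising signal) or dilution-induced depolymerization (falling signal)
#' assay.
#'
#' @param time Strictly increasing times in seconds.
#' @param signal Fluorescence values (arbitrary units), finite.
#' @param mode `"polymerization"` (rising) or `"depolymerization"`
#'   (falling).
#' @param actin_conc_uM,label_fraction Optional assay metadata (the
#'   reference conditions are 10 uM G-actin with a 5% pyrene-labeled tracer
#'   for polymerization, and 20 uM F-actin rapidly diluted for
#'   depolymerization).
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time, signal,
                          mode = c("polymerization", "depolymerization"),
                          actin_conc_uM = NA_real_, label_fraction = NA_real_) {
  mode <- match.arg(mode)
  if (length(time) < 8L) stop("kinetic trace needs >= 8 points")
  if (length(signal) != length(time)) stop("time/signal length mismatch")
  if (any(!is.finite(time)) || any(!is.finite(signal)))
    stop("kinetic trace contains non-finite values")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(list(time = as.numeric(time), signal = as.numeric(signal),
                 mode = mode, actin_conc_uM = actin_conc_uM,
                 label_fraction = label_fraction),
            class = "kinetic_trace")
}

#' Fit a single exponential to a kinetic trace
#'
#' Nonlinear least-squares fit of `F(t) = F0 + A (1 - exp(-k t))` (rising)
#' or `F(t) = F0 + A exp(-k t)` (falling) to the trace; the apparent
#' half-time is `t_half = ln 2 / k`. Initial guesses: `F0` from the
#' first-quartile signal, `A` from the signal range, `k` from a log-linear
#' regression of the normalized tail. An optional fit-window start allows
#' excluding a nucleation lag phase; the default window is the full trace.
#'
#' @param trace A [kinetic_trace()].
#' @param window_start Earliest time included in the fit (default: full
#'   trace).
#' @return A list of class `exponential_fit`: `A`, `k` (1/s), `F0`,
#'   `t_half` (s), `rms` (residual root-mean-square), `mode`, `window`,
#'   `n_points`.
#' @export
fit_half_time <- function(trace, window_start = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$time; y <- trace$signal
  if (!is.null(window_start)) {
    keep <- t >= window_start
    if (sum(keep) < 8L) stop("fit window retains fewer than 8 points")
    t <- t[keep]; y <- y[keep]
  }
  rng <- diff(range(y))
  if (rng == 0 || rng < 1e-9 * max(abs(y), 1))
    stop("rejected fit: constant signal (zero amplitude)")
  t <- t - t[1L]  # shift absorbed into F0/A; improves conditioning
  rising <- trace$mode == "polymerization"

  A0 <- rng
  F0_0 <- as.numeric(stats::quantile(y, 0.25))
  # log-linear slope of the normalized approach to plateau
  z <- if (rising) (max(y) - y) / A0 else (y - min(y)) / A0
  ok <- z > 0.02
  k0 <- if (sum(ok) >= 3L) {
    sl <- stats::coef(stats::lm(log(z[ok]) ~ t[ok]))[2L]
    if (is.finite(sl) && sl < 0) -sl else 1 / max(t[length(t)], 1e-9)
  } else 1 / max(t[length(t)], 1e-9)
  if (rising) F0_0 <- min(y)

  form <- if (rising) y ~ F0 + A * (1 - exp(-k * t))
          else y ~ F0 + A * exp(-k * t)
  fit <- tryCatch(
    stats::nls(form, data = data.frame(t = t, y = y),
               start = list(F0 = F0_0, A = A0, k = k0),
               lower = c(F0 = -Inf, A = 1e-12, k = 1e-12),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) stop("exponential fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  k <- unname(cf["k"])
  if (k <= 0) stop("rejected fit: non-positive rate estimate")
  structure(list(A = unname(cf["A"]), k = k, F0 = unname(cf["F0"]),
                 t_half = log(2) / k,
                 rms = sqrt(mean(stats::resid(fit)^2)),
                 mode = trace$mode,
                 window = c(min(trace$time[trace$time >= (window_start %||% -Inf)]),
                            max(trace$time)),
                 n_points = length(t)),
            class = "exponential_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("<exponential_fit> %s: k = %.4g /s, t1/2 = %.4g s, rms = %.3g\n",
              x$mode, x$k, x$t_half, x$rms))
  invisible(x)
}

#' Fit an exponential rate to a trace
#'
#' Same model and fitting route as [fit_half_time()], returning the rate
#' constant `k` directly (the generic exponential-rate readout used for
#' nucleotide-exchange assays).
#'
#' @inheritParams fit_half_time
#' @return The fitted rate `k` in 1/s, with the full `exponential_fit` as
#'   attribute `"fit"`.
#' @export
fit_rate <- function(trace, window_start = NULL) {
  f <- fit_half_time(trace, window_start = window_start)
  structure(f$k, fit = f)
}

#' Half-time by threshold crossing (sensitivity-check alternative)
#'
#' Reads the time at which the signal crosses halfway between its initial
#' and plateau levels by linear interpolation. Provided as a
#' non-parametric cross-check of the exponential-fit route.
#'
#' @param trace A [kinetic_trace()].
#' @return The crossing time in seconds.
#' @export
half_time_crossing <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$time; y <- trace$signal
  y0 <- if (trace$mode == "polymerization") min(y) else max(y)
  y1 <- if (trace$mode == "polymerization") max(y) else min(y)
  half <- (y0 + y1) / 2
  above <- if (trace$mode == "polymerization") y >= half else y <= half
  i <- which(above)[1L]
  if (is.na(i)) stop("signal never reaches the half level")
  if (i == 1L) return(t[1L] - t[1L])
  t0 <- t[i - 1L]; t1 <- t[i]
  f <- (half - y[i - 1L]) / (y[i] - y[i - 1L])
  (t0 + f * (t1 - t0)) - t[1L]
}

#' Thermal melt curve
#'
#' Fluorescence versus temperature from a dye-based thermal-shift
#' (Thermofluor) assay run over a linear temperature gradient.
#'
#' @param temperature Monotone increasing temperature grid in degrees C.
#' @param signal Fluorescence values.
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, signal) {
  if (length(temperature) < 10L) stop("melt curve needs >= 10 points")
  if (length(signal) != length(temperature))
    stop("temperature/signal length mismatch")
  if (any(!is.finite(temperature)) || any(!is.finite(signal)))
    stop("melt curve contains non-finite values")
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing")
  structure(list(temperature = as.numeric(temperature),
                 signal = as.numeric(signal)),
            class = "melt_curve")
}

# Centered moving polynomial (Savitzky-Golay style) smoother on a uniform
# grid; width must be odd, order < width. Ends keep shrunken windows.
poly_smooth <- function(y, width = 5L, order = 2L) {
  n <- length(y)
  if (width < 3L || width %% 2L == 0L) stop("smoothing width must be odd >= 3")
  half <- width %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    xs <- seq(lo, hi) - i
    ord <- min(order, length(xs) - 1L)
    fit <- stats::lm.fit(outer(xs, 0:ord, `^`), y[lo:hi])
    out[i] <- fit$coefficients[1L]
  }
  out
}

#' Melting temperature from the first-derivative peak
#'
#' Smooths the melt curve with a centered moving polynomial window
#' (default width 5, order 2), differentiates on the temperature grid
#' (central differences), and reports the melting temperature Tm as the
#' temperature at the peak of the first derivative of the melting function
#' (ties broken to the lower temperature). A derivative maximum sitting on
#' the grid boundary is flagged unreliable with a warning.
#'
#' @param curve A [melt_curve()].
#' @param smooth_width,smooth_order Smoothing window parameters.
#' @return A list of class `melt_result`: `Tm` (degrees C),
#'   `derivative` (data.frame `temperature`, `dFdT`), `peak_prominence`,
#'   `reliable` (FALSE when the peak is at a boundary).
#' @export
melt_tm <- function(curve, smooth_width = 5L, smooth_order = 2L) {
  stopifnot(inherits(curve, "melt_curve"))
  tp <- curve$temperature
  ys <- poly_smooth(curve$signal, smooth_width, smooth_order)
  n <- length(tp)
  # central differences (one-sided at the ends)
  d <- numeric(n)
  d[1L] <- (ys[2L] - ys[1L]) / (tp[2L] - tp[1L])
  d[n] <- (ys[n] - ys[n - 1L]) / (tp[n] - tp[n - 1L])
  mid <- 2:(n - 1L)
  d[mid] <- (ys[mid + 1L] - ys[mid - 1L]) / (tp[mid + 1L] - tp[mid - 1L])
  # ties (within numerical noise) broken to the lower temperature
  tol <- 1e-9 * max(abs(d), .Machine$double.eps)
  peak <- which(d >= max(d) - tol)[1L]
  reliable <- !(peak %in% c(1L, n))
  if (!reliable)
    warning("derivative peak at the grid boundary; Tm flagged unreliable")
  prom <- max(d) - stats::median(d)
  structure(list(Tm = tp[peak],
                 derivative = data.frame(temperature = tp, dFdT = d),
                 peak_prominence = prom, reliable = reliable),
            class = "melt_result")
}

#' @export
print.melt_result <- function(x, ...) {
  cat(sprintf("<melt_result> Tm = %.2f degC%s\n", x$Tm,
              if (x$reliable) "" else " (unreliable: boundary peak)"))
  invisible(x)
}

#' Read kinetic traces / melt curves from CSV
#'
#' Long-format CSV: columns `trace_id`, `time_s` (or `temp_C`), `signal`.
#'
#' @param path CSV path.
#' @param mode Trace mode for [kinetic_trace()].
#' @return A named list of `kinetic_trace` objects.
#' @export
read_traces <- function(path, mode = "polymerization") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trace_id", "time_s", "signal") %in% names(df)))
  lapply(split(df, df$trace_id), function(g)
    kinetic_trace(g$time_s, g$signal, mode = mode))
}

#' @rdname read_traces
#' @export
read_melts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trace_id", "temp_C", "signal") %in% names(df)))
  lapply(split(df, df$trace_id), function(g) melt_curve(g$temp_C, g$signal))
}

#' Fit a batch of traces / melt curves and tabulate results
#'
#' @param traces Named list of [kinetic_trace()] objects.
#' @return A data.frame of fitted parameters, one row per trace; traces
#'   whose fit is rejected carry `NA` parameters and the error message in
#'   `flag`.
#' @export
fit_traces <- function(traces) {
  rows <- lapply(names(traces), function(id) {
    f <- tryCatch(fit_half_time(traces[[id]]), error = function(e) e)
    if (inherits(f, "error"))
      data.frame(trace_id = id, A = NA_real_, k = NA_real_, F0 = NA_real_,
                 t_half = NA_real_, rms = NA_real_,
                 flag = conditionMessage(f), stringsAsFactors = FALSE)
    else
      data.frame(trace_id = id, A = f$A, k = f$k, F0 = f$F0,
                 t_half = f$t_half, rms = f$rms, flag = "",
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname fit_traces
#' @param curves Named list of [melt_curve()] objects.
#' @export
fit_melts <- function(curves) {
  rows <- lapply(names(curves), function(id) {
    m <- tryCatch(withCallingHandlers(
      melt_tm(curves[[id]]),
      warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(m, "error"))
      data.frame(trace_id = id, Tm = NA_real_, reliable = FALSE,
                 flag = conditionMessage(m), stringsAsFactors = FALSE)
    else
      data.frame(trace_id = id, Tm = m$Tm, reliable = m$reliable,
                 flag = if (m$reliable) "" else "boundary_peak",
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
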