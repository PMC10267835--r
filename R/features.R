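# Classifier inputs: video-wide min-max normalized intensity and the
# normalized empirical autocorrelation of each trace.

#' Min-max normalize all traces of one video
#'
#' The extrema are global over the video (all spots, all frames), so
#' relative brightness between spots is preserved:
#' `I_norm = (I - I_min) / (I_max - I_min)`.
#'
#' @param traces Matrix (spots x frames) of intensities from one video.
#' @param extrema Optional `c(min, max)` from a training video, re-applied
#'   so test data share the training scaling.
#' @return Matrix of the same shape in `[0, 1]` (values can exceed the unit
#'   interval when foreign extrema are applied); the extrema used are in
#'   `attr(, "extrema")`.
#' @export
#' @examples
#' m <- rbind(c(2, 6), c(10, 4))
#' minmax_normalize(m)[1, 2]  # (6-2)/(10-2) = 0.5
minmax_normalize <- function(traces, extrema = NULL) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  if (is.null(extrema)) extrema <- range(traces, na.rm = TRUE)
  if (!(extrema[2] > extrema[1]))
    stopf("degenerate video: intensity max equals min")
  out <- (traces - extrema[1]) / (extrema[2] - extrema[1])
  attr(out, "extrema") <- extrema
  out
}

#' Normalized empirical autocorrelation of one trace
#'
#' `G(tau) = 1/(T-1-tau) * sum_t z_t z_{t+tau}` for `tau = 0..T-2`, with
#' `z_t = (I_t - mu) / sigma` and `mu`, `sigma` the trace's own mean and
#' population (divide-by-T) standard deviation. Under this convention
#' `G(0) = T / (T - 1)` exactly.
#'
#' @param x Numeric trace of length `T >= 2`.
#' @param on_constant What to do for a constant trace (`sigma = 0`):
#'   `"error"` (default) or `"na"` (return all-`NA`, flagged with
#'   `attr(, "degenerate")`; such spots belong in the noise-class pathway).
#' @return Numeric vector `G` of length `T - 1` (lags `0..T-2`).
#' @export
#' @examples
#' trace_autocorrelation(c(1, 2, 3))  # G(0) = 1.5, G(1) = 0
trace_autocorrelation <- function(x, on_constant = c("error", "na")) {
  on_constant <- match.arg(on_constant)
  T <- length(x)
  if (T < 2) stopf("autocorrelation needs at least 2 frames")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) {
    if (on_constant == "error") stopf("constant trace: sigma = 0")
    out <- rep(NA_real_, T - 1)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  z <- (x - mu) / sigma
  vapply(0:(T - 2), function(tau)
    sum(z[1:(T - tau)] * z[(1 + tau):T]) / (T - 1 - tau), numeric(1))
}

#' Build the classifier feature pair for a set of traces
#'
#' @param traces Matrix (spots x frames) from one video (or already pooled
#'   with shared extrema).
#' @param extrema Optional stored min-max extrema (training-video scaling).
#' @return A list of class `feature_set`: `intensity` (spots x T,
#'   normalized), `acf` (spots x T-1), `extrema`, and per-trace `mu`,
#'   `sigma`. Constant traces get an all-zero ACF row (flagged in
#'   `degenerate`).
#' @export
build_features <- function(traces, extrema = NULL) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  norm <- minmax_normalize(traces, extrema)
  T <- ncol(traces)
  acf_m <- matrix(0, nrow(traces), T - 1)
  degenerate <- logical(nrow(traces))
  for (i in seq_len(nrow(traces))) {
    g <- trace_autocorrelation(traces[i, ], on_constant = "na")
    if (isTRUE(attr(g, "degenerate"))) degenerate[i] <- TRUE
    else acf_m[i, ] <- g
  }
  structure(list(intensity = norm, acf = acf_m,
                 extrema = attr(norm, "extrema"),
                 mu = rowMeans(traces),
                 sigma = sqrt(rowMeans(sweep(traces, 1,
                                             rowMeans(traces))^2)),
                 degenerate = degenerate),
            class = "feature_set")
}

#' Concatenate feature sets (e.g. across cells)
#' @param ... `feature_set` objects with equal trace length.
#' @return A single `feature_set` (extrema from the first set).
#' @export
bind_features <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "feature_set")) sets <- sets[[1]]
  structure(list(intensity = do.call(rbind, lapply(sets, `[[`, "intensity")),
                 acf = do.call(rbind, lapply(sets, `[[`, "acf")),
                 extrema = sets[[1]]$extrema,
                 mu = unlist(lapply(sets, `[[`, "mu")),
                 sigma = unlist(lapply(sets, `[[`, "sigma")),
                 degenerate = unlist(lapply(sets, `[[`, "degenerate"))),
            class = "feature_set")
}

#' Subset a feature set by row
#' @param fs A `feature_set`.
#' @param i Row indices.
#' @return A `feature_set` with the selected spots.
#' @export
subset_features <- function(fs, i) {
  structure(list(intensity = fs$intensity[i, , drop = FALSE],
                 acf = fs$acf[i, , drop = FALSE],
                 extrema = fs$extrema, mu = fs$mu[i], sigma = fs$sigma[i],
                 degenerate = fs$degenerate[i]),
            class = "feature_set")
}

#' Slice full-resolution traces to an imaging condition
#'
#' Takes 1-s resolution traces and returns the `(FI, n_F)` view: frames
#' `t0, t0+FI, ...`, as when a long video is re-imaged more slowly.
#'
#' @param traces Matrix (spots x frames at 1 s).
#' @param frame_interval Frame interval in seconds (integer multiple of the
#'   source resolution).
#' @param n_frames Number of frames to keep.
#' @param t0 Index offset of the first frame (1-based).
#' @return Matrix (spots x n_frames) with a `times` attribute.
#' @export
slice_traces <- function(traces, frame_interval, n_frames, t0 = 1L) {
  times <- attr(traces, "times") %||% (seq_len(ncol(traces)) - 1)
  dt <- if (ncol(traces) > 1) times[2] - times[1] else 1
  step <- frame_interval / dt
  if (abs(step - round(step)) > 1e-9)
    stopf("frame_interval must be a multiple of the source resolution (%g s)",
          dt)
  idx <- t0 + round(step) * (seq_len(n_frames) - 1)
  if (max(idx) > ncol(traces))
    stopf("source traces too short: need %d frames at %g s", n_frames,
          frame_interval)
  out <- traces[, idx, drop = FALSE]
  attr(out, "times") <- times[idx] - times[t0]
  out
}
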