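# Synthetic NCT video: parametric cell background, Brownian spot motion,
# Gaussian PSF rendering, SNR calibration, photobleaching hook.

#' Imaging configuration
#'
#' @param frame_interval Seconds between frames (FI).
#' @param n_frames Number of frames (n_F).
#' @param pixel_size_nm Pixel size (default 130 nm/pixel).
#' @param frame_dim Frame shape in pixels, `c(rows, cols)`.
#' @param snr Target signal-to-noise ratio for the reference species: mean
#'   disk-and-doughnut readout at the species' mean intensity divided by the
#'   sd of the same readout on spot-free background (see [calibrate_gain()]).
#' @param psf_sigma PSF standard deviation in pixels (isotropic Gaussian,
#'   truncated to the rendered 3x3 patch).
#' @param diffusion Spot diffusion coefficient in pixel^2/s.
#' @return An object of class `imaging_config`.
#' @export
#' @examples
#' imaging_config(frame_interval = 5, n_frames = 64, snr = 6.2)
imaging_config <- function(frame_interval = 5, n_frames = 64,
                           pixel_size_nm = 130, frame_dim = c(512L, 512L),
                           snr = 6.2, psf_sigma = 1.0, diffusion = 0.21) {
  if (frame_interval <= 0 || n_frames < 1) stopf("need FI > 0 and n_F >= 1")
  structure(list(frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 pixel_size_nm = pixel_size_nm,
                 frame_dim = as.integer(frame_dim), snr = snr,
                 psf_sigma = psf_sigma, diffusion = diffusion),
            class = "imaging_config")
}

# separable Gaussian blur with edge replication (diffraction-like smoothing)
blur_gauss <- function(mat, sigma = 3) {
  hw <- ceiling(3 * sigma)
  k <- stats::dnorm(-hw:hw, sd = sigma); k <- k / sum(k)
  pad <- function(m) rbind(m[rep(1, hw), , drop = FALSE], m,
                           m[rep(nrow(m), hw), , drop = FALSE])
  conv1 <- function(m) {
    p <- pad(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * p[j:(j + nrow(m) - 1), ]
    out
  }
  t(conv1(t(conv1(mat))))
}

# smooth random surface: coarse iid Gaussian grid, bilinearly upsampled
smooth_field <- function(dim, n_knots = 8, sd = 1) {
  coarse <- matrix(stats::rnorm(n_knots^2, sd = sd), n_knots, n_knots)
  rows <- seq(1, n_knots, length.out = dim[1])
  cols <- seq(1, n_knots, length.out = dim[2])
  r0 <- pmin(floor(rows), n_knots - 1); fr <- rows - r0
  c0 <- pmin(floor(cols), n_knots - 1); fc <- cols - c0
  a <- coarse[cbind(rep(r0, length(c0)), rep(c0, each = length(r0)))]
  b <- coarse[cbind(rep(r0 + 1, length(c0)), rep(c0, each = length(r0)))]
  d <- coarse[cbind(rep(r0, length(c0)), rep(c0 + 1, each = length(r0)))]
  e <- coarse[cbind(rep(r0 + 1, length(c0)), rep(c0 + 1, each = length(r0)))]
  frm <- rep(fr, length(c0)); fcm <- rep(fc, each = length(r0))
  v <- (1 - frm) * (1 - fcm) * a + frm * (1 - fcm) * b +
    (1 - frm) * fcm * d + frm * fcm * e
  matrix(v, dim[1], dim[2])
}

#' Synthesize a parametric cell-background model
#'
#' Emulates the per-pixel Gaussian background procedure used on real blank
#' cell videos: each simulated frame draws every pixel independently from a
#' Normal with a spatially varying mean field `M` (elliptical cell over a
#' dim camera floor, optional brighter nucleus, smooth lumpiness) and sd
#' field `S = floor + 0.5 * sqrt(M)` (shot-noise-like scaling).
#'
#' @param shape Frame dimensions `c(rows, cols)`.
#' @param seed Integer seed (same seed, bit-identical model).
#' @param nucleus Include a brighter nuclear region.
#' @return An object of class `background_model` with fields `M`, `S`,
#'   `mask` (logical cell mask).
#' @export
#' @examples
#' bg <- synth_background(c(64, 64), seed = 1)
#' mean(bg$mask)
synth_background <- function(shape = c(512L, 512L), seed = NULL,
                             nucleus = TRUE) {
  shape <- as.integer(shape)
  with_seed(seed, {
    r <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1])
    cl <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1])
    cy <- shape[1] / 2; cx <- shape[2] / 2
    ell <- ((r - cy) / (0.42 * shape[1]))^2 + ((cl - cx) / (0.45 * shape[2]))^2
    mask <- ell <= 1
    nuc <- ((r - cy * 0.9) / (0.16 * shape[1]))^2 +
      ((cl - cx * 1.05) / (0.18 * shape[2]))^2 <= 1
    lump <- smooth_field(shape, n_knots = 8, sd = 1)
    M <- 20 + ifelse(mask, 90 * (1 + 0.25 * lump), 0)
    if (nucleus) M <- M + ifelse(nuc & mask, 70, 0)
    # diffraction-like smoothing so cell/nucleus boundaries are not hard steps
    M <- blur_gauss(M, sigma = 4)
    M <- pmax(M, 5)
    S <- 2 + 0.5 * sqrt(M)
    structure(list(M = M, S = S, mask = mask, shape = shape),
              class = "background_model")
  })
}

#' Draw one background frame
#' @param bg A [synth_background()] model.
#' @return Matrix of pixel intensities.
#' @export
draw_background <- function(bg) {
  bg$M + bg$S * matrix(stats::rnorm(length(bg$M)), nrow(bg$M))
}

#' Simulate a Brownian spot track inside the cell mask
#'
#' Per-axis Gaussian displacements with variance `2 * D * FI`; steps that
#' would leave the mask (or come within `margin` pixels of the frame edge)
#' are mirrored, approximating a reflecting boundary.
#'
#' @param config An [imaging_config()]; supplies `diffusion`, FI and n_F
#'   unless overridden.
#' @param mask Logical matrix (cell mask) the track must stay inside.
#' @param D Diffusion coefficient (pixel^2/s); default from `config`.
#' @param seed Optional seed.
#' @param start Optional starting `c(row, col)`; default a uniform draw
#'   inside the mask.
#' @param margin Minimum distance from the frame edge in pixels (keeps the
#'   9x9 quantification patch inside the frame).
#' @return An object of class `spot_track`: data.frame with columns
#'   `frame`, `row`, `col` (continuous pixel coordinates).
#' @export
brownian_track <- function(config, mask, D = NULL, seed = NULL,
                           start = NULL, margin = 5) {
  D <- D %||% config$diffusion
  if (D < 0) stopf("diffusion coefficient must be >= 0")
  n <- config$n_frames
  sd_step <- sqrt(2 * D * config$frame_interval)
  inside <- function(p) {
    r <- round(p[1]); c <- round(p[2])
    r >= 1 + margin && c >= 1 + margin && r <= nrow(mask) - margin &&
      c <= ncol(mask) - margin && mask[r, c]
  }
  with_seed(seed, {
    if (is.null(start)) {
      ok <- which(mask &
                    row(mask) > margin & row(mask) <= nrow(mask) - margin &
                    col(mask) > margin & col(mask) <= ncol(mask) - margin)
      pick <- ok[sample.int(length(ok), 1)]
      start <- c((pick - 1) %% nrow(mask) + 1, (pick - 1) %/% nrow(mask) + 1)
    }
    out <- matrix(NA_real_, n, 2)
    out[1, ] <- start
    if (n > 1) {
      steps <- matrix(stats::rnorm(2 * (n - 1), sd = sd_step), n - 1, 2)
      for (i in 2:n) {
        prop <- out[i - 1, ] + steps[i - 1, ]
        if (!inside(prop)) prop <- out[i - 1, ] - steps[i - 1, ]  # mirror
        if (!inside(prop)) prop <- out[i - 1, ]                   # stuck
        out[i, ] <- prop
      }
    }
    structure(data.frame(frame = seq_len(n) - 1L, row = out[, 1],
                         col = out[, 2]),
              class = c("spot_track", "data.frame"))
  })
}

# Gaussian PSF mass integrated over the 3x3 pixel patch around the rounded
# center, for a spot at sub-pixel offset (dr, dc) from that center.
# Returns a 3x3 matrix summing to < 1 (truncation).
psf_patch <- function(dr, dc, sigma) {
  px <- -1:1
  mr <- stats::pnorm(px + 0.5, mean = dr, sd = sigma) -
    stats::pnorm(px - 0.5, mean = dr, sd = sigma)
  mc <- stats::pnorm(px + 0.5, mean = dc, sd = sigma) -
    stats::pnorm(px - 0.5, mean = dc, sd = sigma)
  outer(mr, mc)
}

# Disk-and-doughnut response to a unit-mass PSF centered in the disk:
# mean over the 3x3 disk minus (0: the doughnut sees only truncation spill,
# which rendering discards). Used for gain calibration.
psf_disk_response <- function(sigma) {
  sum(psf_patch(0, 0, sigma)) / 9
}

# sd of the disk-and-doughnut readout for spot-free probes moving through
# the background like real spots (captures both pixel noise and readout
# fluctuations from motion across the heterogeneous mean field)
background_readout_sd <- function(bg, config, seed = 1L, n_probes = 40L) {
  z <- simulate_nct_traces(matrix(0, n_probes, config$n_frames), bg, config,
                           gain = 0, seed = seed)
  stats::sd(as.vector(z))
}

#' Calibrate rendering gain from a target SNR
#'
#' Solves for the photon gain `g` (counts per UMP of PSF mass) such that a
#' spot at `mean_intensity` UMP yields
#' `SNR = (mean disk-and-doughnut readout) / (background readout sd)`,
#' where the background readout sd is measured on spot-free probes moving
#' through the background with the configured diffusion (so it includes
#' both pixel noise and motion across background structure). Species
#' sharing one video share the gain, so their individual SNRs scale with
#' their mean intensities.
#'
#' @param bg A [synth_background()] model.
#' @param config An [imaging_config()] (uses `snr`, `psf_sigma`,
#'   `diffusion`).
#' @param mean_intensity Reference mean spot intensity in UMP.
#' @param seed Seed for the spot-free probe draws.
#' @return Gain in counts/UMP.
#' @export
calibrate_gain <- function(bg, config, mean_intensity, seed = 1L) {
  if (mean_intensity <= 0) stopf("mean_intensity must be positive")
  sig_b <- background_readout_sd(bg, config, seed = seed)
  config$snr * sig_b / (psf_disk_response(config$psf_sigma) * mean_intensity)
}

#' Render intensity traces into a synthetic video
#'
#' Each frame is an independent background draw plus, per spot, a 2D
#' Gaussian PSF integrated over the 3x3 pixel patch centered at the
#' (rounded) spot position, with amplitude `gain * intensity_UMP`.
#'
#' @param bg A [synth_background()] model.
#' @param traces Matrix (spots x frames) of UMP intensities.
#' @param tracks List of [brownian_track()] results, one per spot.
#' @param config An [imaging_config()].
#' @param gain Counts per UMP (see [calibrate_gain()]).
#' @return An object of class `video_stack`: array `(rows, cols, n_frames)`
#'   plus the rendering metadata.
#' @export
render_video <- function(bg, traces, tracks, config, gain) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  if (length(tracks) != nrow(traces))
    stopf("need one track per trace (%d traces, %d tracks)",
          nrow(traces), length(tracks))
  if (ncol(traces) != config$n_frames)
    stopf("traces have %d frames but config expects %d",
          ncol(traces), config$n_frames)
  frames <- array(0, c(bg$shape, config$n_frames))
  for (t in seq_len(config$n_frames)) {
    fr <- draw_background(bg)
    for (s in seq_len(nrow(traces))) {
      r <- tracks[[s]]$row[t]; c <- tracks[[s]]$col[t]
      r0 <- round(r); c0 <- round(c)
      if (r0 < 2 || c0 < 2 || r0 > bg$shape[1] - 1 || c0 > bg$shape[2] - 1)
        next
      amp <- gain * traces[s, t]
      fr[r0 + (-1:1), c0 + (-1:1)] <- fr[r0 + (-1:1), c0 + (-1:1)] +
        amp * psf_patch(r - r0, c - c0, config$psf_sigma)
    }
    frames[, , t] <- fr
  }
  structure(list(frames = frames, config = config, gain = gain),
            class = "video_stack")
}

#' Apply exponential photobleaching
#'
#' Multiplies the signal by `exp(-rate * t)`; for traces this acts on the
#' UMP values, leaving any later background addition unaffected.
#'
#' @param x An `intensity_trace`, a traces matrix with a `times` attribute,
#'   or a numeric vector with `times`.
#' @param rate Bleach rate (1/s), `>= 0`.
#' @param times Frame times, required for plain vectors/matrices without a
#'   `times` attribute.
#' @return Same type as `x`.
#' @export
apply_photobleach <- function(x, rate, times = NULL) {
  if (rate < 0) stopf("bleach rate must be >= 0")
  if (inherits(x, "intensity_trace")) {
    x$values <- x$values * exp(-rate * x$times)
    return(x)
  }
  times <- times %||% attr(x, "times")
  if (is.null(times)) stopf("supply frame times for photobleaching")
  if (is.matrix(x)) {
    out <- sweep(x, 2, exp(-rate * times), `*`)
    attr(out, "times") <- times
    out
  } else x * exp(-rate * times)
}

#' Simulate corrupted NCT traces without materializing full frames
#'
#' Statistically exact shortcut through render-then-quantify: for every
#' spot and frame it draws only the 9x9 background neighborhood used by the
#' disk-and-doughnut readout, adds the PSF patch, and extracts the readout.
#' Identical in distribution to [render_video()] followed by
#' [extract_intensity()] at the same coordinates.
#'
#' @param traces Matrix (spots x frames) of UMP intensities.
#' @param bg A [synth_background()] model.
#' @param config An [imaging_config()].
#' @param gain Counts per UMP.
#' @param seed Master seed; each spot gets a child stream (motion + noise).
#' @param tracks Optional list of precomputed tracks (else Brownian tracks
#'   are drawn inside the mask).
#' @return Matrix (spots x frames) of extracted readouts (counts), with
#'   frame times in `attr(, "times")` and the tracks in `attr(, "tracks")`.
#' @export
simulate_nct_traces <- function(traces, bg, config, gain, seed = 1,
                                tracks = NULL) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  n_spots <- nrow(traces); n_fr <- ncol(traces)
  stopifnot(n_fr == config$n_frames)
  off <- -4:4
  disk_sel <- as.vector(abs(rep(off, 9)) <= 1 & abs(rep(off, each = 9)) <= 1)
  out <- matrix(NA_real_, n_spots, n_fr)
  trks <- vector("list", n_spots)
  for (s in seq_len(n_spots)) {
    trk <- if (is.null(tracks)) {
      brownian_track(config, bg$mask, seed = child_seed(seed, 2L * s))
    } else tracks[[s]]
    trks[[s]] <- trk
    r0 <- round(trk$row); c0 <- round(trk$col)
    # 81 x n_frames linear pixel indices of each frame's neighborhood
    rows <- outer(rep(off, 9), r0, `+`)
    cols <- outer(rep(off, each = 9), c0, `+`)
    idx <- (cols - 1L) * nrow(bg$M) + rows
    Mv <- matrix(bg$M[idx], 81, n_fr)
    Sv <- matrix(bg$S[idx], 81, n_fr)
    patch <- with_seed(child_seed(seed, 2L * s + 1L),
                       Mv + Sv * matrix(stats::rnorm(81 * n_fr), 81, n_fr))
    # PSF contribution lands in the 3x3 disk around the rounded center
    for (t in seq_len(n_fr)) {
      amp <- gain * traces[s, t]
      if (amp != 0)
        patch[disk_sel, t] <- patch[disk_sel, t] +
          amp * as.vector(psf_patch(trk$row[t] - r0[t], trk$col[t] - c0[t],
                                    config$psf_sigma))
    }
    out[s, ] <- colMeans(patch[disk_sel, , drop = FALSE]) -
      colMeans(patch[!disk_sel, , drop = FALSE])
  }
  attr(out, "times") <- (seq_len(n_fr) - 1) * config$frame_interval
  attr(out, "tracks") <- trks
  out
}

#' Write / read a video stack as multi-page 16-bit TIFF
#'
#' @param video A [render_video()] result.
#' @param path TIFF path.
#' @return `write_video_tiff`: the path invisibly (plus the scale used, as
#'   an attribute); `read_video_tiff`: an array `(rows, cols, frames)` in
#'   the original intensity scale.
#' @export
write_video_tiff <- function(video, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("TIFF export needs the 'tiff' package")
  fr <- video$frames
  lo <- min(fr); hi <- max(fr)
  scaled <- (fr - lo) / max(hi - lo, .Machine$double.eps)
  pages <- lapply(seq_len(dim(fr)[3]), function(t) scaled[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  attr(path, "scale") <- c(lo = lo, hi = hi)
  invisible(path)
}

#' @rdname write_video_tiff
#' @param scale `c(lo, hi)` used when writing (to undo the 16-bit scaling).
#' @export
read_video_tiff <- function(path, scale = c(0, 1)) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("TIFF import needs the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(pages)
  scale[1] + arr * (scale[2] - scale[1])
}

#' Export spot tracks as CSV
#' @param tracks List of [brownian_track()] results.
#' @param path Output CSV (`spot_id, frame, row, col`).
#' @return The path, invisibly.
#' @export
tracks_to_csv <- function(tracks, path) {
  df <- do.call(rbind, lapply(seq_along(tracks), function(i)
    cbind(spot_id = sprintf("spot%03d", i),
          as.data.frame(tracks[[i]])[, c("frame", "row", "col")])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
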