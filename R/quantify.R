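# Disk-and-doughnut spot quantification at known (perfect-tracking)
# coordinates.

#' Disk-and-doughnut configuration
#'
#' @param disk Disk side length in pixels (odd; default 3).
#' @param doughnut Outer patch side length in pixels (odd; default 9). The
#'   doughnut is the outer patch minus the disk.
#' @return An object of class `disk_doughnut_config`.
#' @export
disk_doughnut_config <- function(disk = 3L, doughnut = 9L) {
  disk <- as.integer(disk); doughnut <- as.integer(doughnut)
  if (disk %% 2 == 0 || doughnut %% 2 == 0 || doughnut <= disk)
    stopf("need odd sizes with doughnut > disk")
  structure(list(disk = disk, doughnut = doughnut),
            class = "disk_doughnut_config")
}

#' Extract a spot intensity trace from video
#'
#' Per frame: mean of the disk patch centered at the rounded spot position
#' minus the mean of the surrounding doughnut. Frames whose outer patch
#' falls outside the frame are flagged missing (`NA`).
#'
#' @param video A [render_video()] result or a plain array
#'   `(rows, cols, frames)`.
#' @param track A [brownian_track()] result (or data.frame with `row`,
#'   `col`).
#' @param cfg A [disk_doughnut_config()].
#' @param spot_id Identifier for the returned trace.
#' @return An `intensity_trace` whose `values` are readout counts (same
#'   CSV schema as simulated traces, so the feature/classifier path accepts
#'   either).
#' @export
#' @examples
#' fr <- array(5, c(32, 32, 2)); fr[16, 16, ] <- 14   # +9 single pixel
#' tr <- extract_intensity(fr, data.frame(row = c(16, 16), col = c(16, 16)))
#' tr$values  # 1, 1
extract_intensity <- function(video, track, cfg = disk_doughnut_config(),
                              spot_id = "spot1") {
  frames <- if (inherits(video, "video_stack")) video$frames else video
  stopifnot(length(dim(frames)) == 3)
  n_fr <- dim(frames)[3]
  stopifnot(nrow(track) >= n_fr)
  hd <- (cfg$disk - 1L) %/% 2L
  ho <- (cfg$doughnut - 1L) %/% 2L
  vals <- rep(NA_real_, n_fr)
  for (t in seq_len(n_fr)) {
    r0 <- round(track$row[t]); c0 <- round(track$col[t])
    if (r0 - ho < 1 || c0 - ho < 1 ||
        r0 + ho > dim(frames)[1] || c0 + ho > dim(frames)[2]) next
    outer_patch <- frames[r0 + (-ho:ho), c0 + (-ho:ho), t]
    disk <- frames[r0 + (-hd:hd), c0 + (-hd:hd), t]
    n_out <- cfg$doughnut^2 - cfg$disk^2
    vals[t] <- mean(disk) - (sum(outer_patch) - sum(disk)) / n_out
  }
  fi <- if (inherits(video, "video_stack")) video$config$frame_interval else 1
  structure(list(times = (seq_len(n_fr) - 1) * fi, values = vals,
                 spot_id = spot_id, construct = NA_character_),
            class = "intensity_trace")
}
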