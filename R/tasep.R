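# Codon-dependent TASEP simulation of translation and the sparse-loading
# (collision-free) analytic calculators.

#' Translation parameters
#'
#' @param k_i Initiation attempt rate (1/s). Attempts succeed only when the
#'   entry footprint is clear; blocked attempts are discarded.
#' @param k_e Genome-average elongation rate (aa/s).
#' @param footprint Ribosome exclusion footprint in codons (default 9).
#' @param burn_in Seconds of pre-equilibration before recording (default
#'   1000 s, enough for several ribosome transits at typical rates).
#' @return An object of class `translation_params`.
#' @export
#' @examples
#' translation_params(k_i = 0.06, k_e = 5.33)
translation_params <- function(k_i = 0.06, k_e = 5.33, footprint = 9L,
                               burn_in = 1000) {
  if (k_i < 0 || k_e <= 0) stopf("rates must satisfy k_i >= 0, k_e > 0")
  if (footprint < 1L) stopf("footprint must be >= 1 codon")
  structure(list(k_i = k_i, k_e = k_e, footprint = as.integer(footprint),
                 burn_in = burn_in),
            class = "translation_params")
}

#' Assign per-codon stepping rates
#'
#' @param construct An [build_construct()] result.
#' @param k_e Genome-average elongation rate (aa/s).
#' @param usage_weights Codon usage weights (see [human_codon_usage()]).
#' @param mode `"construct_normalized"` scales codon-proportional rates so
#'   the construct's sparse transit time is exactly
#'   `total_codons / k_e`; `"uniform"` sets every rate to `k_e`;
#'   `"genome_normalized"` scales so the usage-weighted genome-mean stepping
#'   rate is `k_e` (per-construct transit time then depends on composition).
#' @return An object of class `codon_rates`: numeric vector `lambda` plus
#'   the implied sparse transit (dwell) time `tau = sum(1/lambda)`.
#' @export
#' @examples
#' g <- generate_synthetic_gene(1200, seed = 1)
#' con <- build_construct(g, tag_design())
#' r <- assign_codon_rates(con, k_e = 5.33, mode = "uniform")
#' all.equal(r$tau, con$total_codons / 5.33)
assign_codon_rates <- function(construct, k_e,
                               usage_weights = human_codon_usage(),
                               mode = c("construct_normalized", "uniform",
                                        "genome_normalized")) {
  mode <- match.arg(mode)
  stopifnot(inherits(construct, "nct_construct"))
  if (k_e <= 0) stopf("k_e must be positive")
  n <- construct$total_codons
  if (mode == "uniform") {
    lambda <- rep(k_e, n)
  } else {
    w <- usage_weights[construct$codons]
    if (anyNA(w) || any(w <= 0))
      stopf("construct contains codon(s) with zero/missing usage weight")
    w <- unname(w)
    if (mode == "construct_normalized") {
      # lambda = c*w with sum(1/lambda) = n/k_e
      cc <- sum(1 / w) * k_e / n
      lambda <- cc * w
    } else {
      p <- usage_weights / sum(usage_weights)
      wbar <- sum(p * usage_weights)
      lambda <- k_e * w / wbar
    }
  }
  structure(list(lambda = lambda, mode = mode, k_e = k_e,
                 tau = sum(1 / lambda)),
            class = "codon_rates")
}

#' Construct codon rates from raw per-codon values
#'
#' Escape hatch for analyses that prescribe stepping rates directly (e.g.
#' comparing against exact small-instance calculations).
#'
#' @param lambda Positive numeric vector of per-codon stepping rates (1/s).
#' @return A `codon_rates` object.
#' @export
codon_rates <- function(lambda) {
  if (any(lambda <= 0)) stopf("stepping rates must be positive")
  structure(list(lambda = as.numeric(lambda), mode = "manual",
                 k_e = NA_real_, tau = sum(1 / lambda)),
            class = "codon_rates")
}

#' Simulate one spot with the codon-dependent TASEP
#'
#' Exact event-driven stochastic simulation. Initiation attempts arrive at
#' rate `k_i` and succeed only when codons `1..footprint` are clear; a
#' ribosome at codon `j` steps at rate `lambda[j]` unless the ribosome
#' ahead is within the footprint; the last codon terminates at its stepping
#' rate. Spot intensity is the sum of the epitope profile over ribosome
#' positions, in UMP. Recording starts after `params$burn_in` seconds.
#'
#' @param construct An [build_construct()] result.
#' @param rates A [assign_codon_rates()] result (or `NULL` to use
#'   construct-normalized rates at `params$k_e`).
#' @param params A [translation_params()].
#' @param duration Recording window length in seconds (post burn-in).
#' @param record_times Frame times in `[0, duration]` relative to the end of
#'   burn-in; default a 1-s grid.
#' @param seed Optional integer seed.
#' @param snapshots If `TRUE`, keep the ribosome position vector at every
#'   frame (memory heavy for long runs).
#' @param spot_id Identifier stored on the trace.
#' @return An object of class `intensity_trace`: `times`, `values` (UMP),
#'   `n_ribosomes`, `spot_id`, bookkeeping counts, and (optionally)
#'   `snapshots`.
#' @export
#' @examples
#' g <- generate_synthetic_gene(600, seed = 1)
#' con <- build_construct(g, tag_design())
#' tr <- simulate_tasep(con, params = translation_params(burn_in = 200),
#'                      duration = 50, seed = 7)
#' length(tr$values)  # 51 frames
simulate_tasep <- function(construct, rates = NULL, params = translation_params(),
                           duration = 3000, record_times = NULL, seed = NULL,
                           snapshots = FALSE, spot_id = "spot1") {
  stopifnot(inherits(construct, "nct_construct"),
            inherits(params, "translation_params"))
  if (is.null(rates)) rates <- assign_codon_rates(construct, params$k_e)
  stopifnot(inherits(rates, "codon_rates"),
            length(rates$lambda) == construct$total_codons)
  if (duration < 0) stopf("duration must be >= 0")
  if (is.null(record_times)) record_times <- seq(0, duration, by = 1)
  if (any(record_times < 0 | record_times > duration))
    stopf("record_times must lie in [0, duration]")
  abs_times <- params$burn_in + sort(record_times)
  res <- with_seed(seed,
    tasep_simulate_cpp(rates$lambda, params$k_i, params$footprint,
                       construct$epitope_profile, abs_times,
                       params$burn_in + duration, snapshots))
  structure(list(times = sort(record_times), values = res$intensity,
                 n_ribosomes = res$n_ribosomes,
                 snapshots = if (snapshots) res$snapshots else NULL,
                 final_positions = res$final_positions,
                 n_initiated = res$n_initiated,
                 n_terminated = res$n_terminated,
                 n_blocked_attempts = res$n_blocked_attempts,
                 spot_id = spot_id, construct = construct$name),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %s (%s): %d frames, mean %.2f UMP\n",
              x$spot_id, x$construct, length(x$values), mean(x$values)))
  invisible(x)
}

#' Simulate an ensemble of independent spots
#'
#' Each spot gets its own reproducible child stream of the master seed.
#'
#' @inheritParams simulate_tasep
#' @param n_spots Number of independent spots.
#' @return A matrix (`n_spots` rows, one column per frame) of UMP
#'   intensities, with the frame times in `attr(, "times")`.
#' @export
simulate_spot_ensemble <- function(construct, rates = NULL,
                                   params = translation_params(),
                                   n_spots = 50, duration = 3000,
                                   record_times = NULL, seed = 1) {
  if (is.null(rates)) rates <- assign_codon_rates(construct, params$k_e)
  if (is.null(record_times)) record_times <- seq(0, duration, by = 1)
  out <- matrix(NA_real_, nrow = n_spots, ncol = length(record_times))
  for (i in seq_len(n_spots)) {
    tr <- simulate_tasep(construct, rates, params, duration, record_times,
                         seed = child_seed(seed, i),
                         spot_id = sprintf("spot%03d", i))
    out[i, ] <- tr$values
  }
  attr(out, "times") <- sort(record_times)
  out
}

# ---------------------------------------------------------------------------
# Sparse-loading (collision-free) calculators

#' Sparse-loading mean spot intensity
#'
#' Under sparse loading (`k_i * footprint / k_e << 1`) ribosome arrivals are
#' an unobstructed Poisson stream and the mean UMP intensity of an
#' N-terminally tagged construct is `(1 - L_tag/(2L)) * tau * k_i`, with
#' `L`, `L_tag` the construct and tag lengths in NT and `tau` the ribosome
#' transit time.
#'
#' @param construct An [build_construct()] result.
#' @param k_i Initiation rate (1/s).
#' @param tau Transit (dwell) time in seconds; default `total_codons / k_e`
#'   cannot be inferred here, so pass the value from [assign_codon_rates()].
#' @return Mean intensity in UMP.
#' @export
#' @examples
#' # 1886-codon construct at k_i = 0.06/s, tau = 353.8 s -> about 19.3 UMP
sparse_mean_intensity <- function(construct, k_i, tau) {
  stopifnot(inherits(construct, "nct_construct"))
  L <- construct$L_mRNA_nt + construct$L_tag_nt
  (1 - construct$L_tag_nt / (2 * L)) * tau * k_i
}

#' Sparse-loading spot intensity variance (filtered-Poisson)
#'
#' Treats the spot as a shot-noise (Campbell) superposition of independent
#' ribosomes, each contributing the epitope profile `f` along its transit:
#' `Var = k_i * tau * mean(f^2)` over codons.
#'
#' @inheritParams sparse_mean_intensity
#' @return Variance in UMP^2.
#' @export
sparse_intensity_variance <- function(construct, k_i, tau) {
  stopifnot(inherits(construct, "nct_construct"))
  k_i * tau * mean(construct$epitope_profile^2)
}

#' Critical initiation-rate ratio for equal mean intensity
#'
#' Ratio `k_i,A / k_i,B` at which two constructs' sparse-loading mean
#' intensities coincide: `[(1 - L_tag/(2 L_B)) tau_B] / [(1 - L_tag/(2 L_A))
#' tau_A]`. On this manifold the species can only be told apart through
#' fluctuation frequency content.
#'
#' @param construct_a,construct_b Two [build_construct()] results (the
#'   returned ratio is `k_i` of `a` over `k_i` of `b`).
#' @param tau_a,tau_b Their sparse transit times (s).
#' @return Dimensionless initiation-rate ratio.
#' @export
critical_ki_ratio <- function(construct_a, construct_b, tau_a, tau_b) {
  stopifnot(inherits(construct_a, "nct_construct"),
            inherits(construct_b, "nct_construct"))
  La <- construct_a$L_mRNA_nt + construct_a$L_tag_nt
  Lb <- construct_b$L_mRNA_nt + construct_b$L_tag_nt
  ((1 - construct_b$L_tag_nt / (2 * Lb)) * tau_b) /
    ((1 - construct_a$L_tag_nt / (2 * La)) * tau_a)
}

#' Critical elongation-rate ratio for identical statistics
#'
#' Ratio `k_e,A / k_e,B` at which two constructs sharing one initiation rate
#' attain identical mean intensity and dwell time (uniform rates): the ratio
#' of their codon counts. Near this manifold no amount of extra video
#' resolves the pair; the remedy is construct redesign
#' ([make_tag_variant()]).
#'
#' @param construct_a,construct_b Two [build_construct()] results.
#' @return Dimensionless elongation-rate ratio.
#' @export
critical_ke_ratio <- function(construct_a, construct_b) {
  stopifnot(inherits(construct_a, "nct_construct"),
            inherits(construct_b, "nct_construct"))
  construct_a$total_codons / construct_b$total_codons
}

# ---------------------------------------------------------------------------
# Trace IO

#' Export intensity traces as CSV
#'
#' Long format: `spot_id, frame, time_s, intensity_ump`. The same schema is
#' produced by the video quantification path, so the classifier consumes
#' either source.
#'
#' @param traces A list of `intensity_trace` objects or a matrix from
#'   [simulate_spot_ensemble()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
traces_to_csv <- function(traces, path) {
  df <- traces_to_df(traces)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname traces_to_csv
#' @export
traces_to_df <- function(traces) {
  if (is.matrix(traces)) {
    times <- attr(traces, "times") %||% (seq_len(ncol(traces)) - 1)
    ids <- rownames(traces) %||% sprintf("spot%03d", seq_len(nrow(traces)))
    df <- data.frame(
      spot_id = rep(ids, each = ncol(traces)),
      frame = rep(seq_len(ncol(traces)) - 1L, nrow(traces)),
      time_s = rep(times, nrow(traces)),
      intensity_ump = as.vector(t(traces)))
  } else {
    df <- do.call(rbind, lapply(traces, function(tr) {
      data.frame(spot_id = tr$spot_id,
                 frame = seq_along(tr$values) - 1L,
                 time_s = tr$times, intensity_ump = tr$values)
    }))
  }
  df
}

#' Read traces written by [traces_to_csv()]
#'
#' @param path CSV path.
#' @return A matrix (spots x frames) with frame times in `attr(, "times")`.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$spot_id)
  frames <- sort(unique(df$frame))
  m <- matrix(NA_real_, length(ids), length(frames),
              dimnames = list(ids, NULL))
  m[cbind(match(df$spot_id, ids), match(df$frame, frames))] <- df$intensity_ump
  attr(m, "times") <- df$time_s[match(frames, df$frame)]
  m
}
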