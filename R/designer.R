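# Experiment-design orchestration: baseline condition, dataset generation
# through the full simulate -> render -> quantify -> featurize pipeline,
# sweep runners, parameter-mismatch robustness, and the two-color
# multiplexing demonstration.

#' Fold change between two construct lengths
#'
#' @param l_a,l_b Lengths in NT (either convention - with or without tag -
#'   as long as both use the same one).
#' @return `max(l_a, l_b) / min(l_a, l_b)`.
#' @export
#' @examples
#' length_fold_change(7257, 4647)  # 1.562
length_fold_change <- function(l_a, l_b) {
  if (any(c(l_a, l_b) <= 0)) stopf("lengths must be positive")
  pmax(l_a, l_b) / pmin(l_a, l_b)
}

#' Gene length ladder used in the length sweeps
#'
#' Twelve human genes with approximately evenly spaced coding lengths
#' (NT, without tag), spanning about half the human CCDS length range.
#'
#' @return Named integer vector of lengths.
#' @export
table_gene_lengths <- function() {
  c(RRAGC = 1200L, ORC2 = 1734L, LONRF2 = 2265L, EDEM3 = 2799L,
    TRIM33 = 3333L, MAP3K6 = 3867L, COL3A1 = 4401L, KDM5B = 4647L,
    KDM6B = 4932L, PHIP = 5466L, DOCK8 = 6000L, P300 = 7257L)
}

#' Build a tagged construct for a ladder gene
#'
#' Synthesizes a gene of the named ladder length with human codon usage
#' (deterministic per gene name) and attaches the given tag.
#'
#' @param name Gene name from [table_gene_lengths()].
#' @param tag A [tag_design()].
#' @return An `nct_construct`.
#' @export
ladder_construct <- function(name, tag = tag_design()) {
  lens <- table_gene_lengths()
  if (!name %in% names(lens)) stopf("unknown ladder gene '%s'", name)
  gene <- generate_synthetic_gene(lens[[name]], seed = lens[[name]],
                                  name = name)
  build_construct(gene, tag)
}

#' The baseline two-species experiment configuration
#'
#' KDM5B (4647 NT) vs P300 (7257 NT), each with the N-terminal 10x FLAG
#' tag (1011 NT), shared `k_i = 0.06` 1/s and `k_e = 5.33` aa/s, imaged for
#' 64 frames at a 5-s interval, diffusion 0.21 pixel^2/s, SNR 6.2 for the
#' KDM5B reference (the shared gain then puts P300 near 8.9).
#'
#' @return A list of class `experiment_config`: `species` (named construct
#'   list), `params` (per-species [translation_params()]), `imaging`,
#'   `rates` (per-species [assign_codon_rates()]), and the analytic
#'   sparse-loading summary `stats` (dwell times, means, variances).
#' @export
#' @examples
#' cfg <- baseline_experiment()
#' round(cfg$stats$dwell_s)  # 354 517
baseline_experiment <- function() {
  experiment_config(
    species = list(KDM5B = ladder_construct("KDM5B"),
                   P300 = ladder_construct("P300")),
    params = translation_params(k_i = 0.06, k_e = 5.33),
    imaging = imaging_config(frame_interval = 5, n_frames = 64, snr = 6.2,
                             diffusion = 0.21))
}

#' Assemble an experiment configuration
#'
#' @param species Named list of `nct_construct` objects sharing one video.
#' @param params One [translation_params()] (shared) or a list, one per
#'   species.
#' @param imaging One [imaging_config()] shared by every species.
#' @return An `experiment_config` (see [baseline_experiment()]).
#' @export
experiment_config <- function(species, params, imaging) {
  if (inherits(params, "translation_params"))
    params <- stats::setNames(rep(list(params), length(species)),
                              names(species))
  stopifnot(length(params) == length(species))
  rates <- mapply(function(con, pa)
    assign_codon_rates(con, pa$k_e), species, params, SIMPLIFY = FALSE)
  stats <- data.frame(
    species = names(species),
    codons = vapply(species, `[[`, 0, "total_codons"),
    dwell_s = vapply(rates, `[[`, 0, "tau"),
    mean_ump = mapply(function(con, pa, r)
      sparse_mean_intensity(con, pa$k_i, r$tau), species, params, rates),
    var_ump2 = mapply(function(con, pa, r)
      sparse_intensity_variance(con, pa$k_i, r$tau), species, params, rates),
    row.names = NULL)
  structure(list(species = species, params = params, imaging = imaging,
                 rates = rates, stats = stats),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %d species, FI=%gs, n_F=%d, SNR=%g\n",
              length(x$species), x$imaging$frame_interval,
              x$imaging$n_frames, x$imaging$snr))
  print(x$stats)
  invisible(x)
}

#' Named initiation-rate testbeds
#'
#' Three KDM5B/P300 comparison presets in which the initiation-rate pair
#' makes the two species' mean intensities identical, similar, or clearly
#' different while dwell times stay distinct.
#'
#' @return Named list with `k_i_KDM5B` and `k_i_P300` per preset.
#' @export
testbed_presets <- function() {
  list(identical_mu = c(k_i_KDM5B = 0.014139, k_i_P300 = 0.009676),
       similar_mu   = c(k_i_KDM5B = 0.01860,  k_i_P300 = 0.009676),
       different_mu = c(k_i_KDM5B = 0.04242,  k_i_P300 = 0.009676))
}

# ---------------------------------------------------------------------------
# Dataset generation

#' Generate a labeled NCT dataset through the full pipeline
#'
#' For each simulated cell: a fresh synthetic background, per-species TASEP
#' intensity traces recorded on the imaging frame grid after burn-in,
#' Brownian motion inside the cell mask, PSF rendering with the SNR
#' calibrated gain, disk-and-doughnut re-quantification, and (optionally) a
#' class of non-translating spots extracted from the spot-free channel at
#' the same motion. Each cell's video is min-max normalized by its own
#' extrema; the pooled extrema are recorded for normalizing later test
#' videos.
#'
#' @param config An [experiment_config()].
#' @param n_cells Number of simulated cells.
#' @param spots_per_species Spots per species per cell.
#' @param seed Master seed; cells and spots use child streams.
#' @param include_noise Add a `"noise"` class of non-translating spots
#'   (same count per cell).
#' @param extrema Optional fixed min-max extrema (a stored training
#'   scaling) applied to every cell instead of each cell's own.
#' @return A list: `features` (a `feature_set`), `labels` (factor),
#'   `cell` (integer), `extrema` (pooled training extrema), `gain` used
#'   per cell.
#' @export
generate_nct_dataset <- function(config, n_cells = 4, spots_per_species = 25,
                                 seed = 1, include_noise = FALSE,
                                 extrema = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  im <- config$imaging
  duration <- (im$n_frames - 1) * im$frame_interval
  rec <- seq(0, duration, by = im$frame_interval)
  ref <- config$stats$mean_ump[1]
  sets <- list(); labels <- list(); cells <- list(); gains <- numeric(n_cells)
  for (ci in seq_len(n_cells)) {
    cseed <- child_seed(seed, ci)
    bg <- synth_background(im$frame_dim, seed = cseed)
    gain <- calibrate_gain(bg, im, ref, seed = child_seed(cseed, 5L))
    gains[ci] <- gain
    raw <- list(); labs <- list()
    for (si in seq_along(config$species)) {
      m <- simulate_spot_ensemble(config$species[[si]], config$rates[[si]],
                                  config$params[[si]],
                                  n_spots = spots_per_species,
                                  duration = duration, record_times = rec,
                                  seed = child_seed(cseed, 10L + si))
      raw[[si]] <- m
      labs[[si]] <- rep(names(config$species)[si], spots_per_species)
    }
    if (include_noise) {
      raw <- c(raw, list(matrix(0, spots_per_species, im$n_frames)))
      labs <- c(labs, list(rep("noise", spots_per_species)))
    }
    ump <- do.call(rbind, raw)
    corrupted <- simulate_nct_traces(ump, bg, im, gain,
                                     seed = child_seed(cseed, 99L))
    sets[[ci]] <- build_features(corrupted, extrema = extrema)
    labels[[ci]] <- unlist(labs)
    cells[[ci]] <- rep(ci, nrow(corrupted))
  }
  pooled <- c(min(vapply(sets, function(s) s$extrema[1], 0)),
              max(vapply(sets, function(s) s$extrema[2], 0)))
  list(features = bind_features(sets), labels = factor(unlist(labels)),
       cell = unlist(cells), extrema = pooled, gain = gains)
}

#' Run one classification condition end to end
#'
#' Generates training cells, trains the classifier with the standard
#' protocol, then generates fresh test cells (normalized with the pooled
#' training extrema) and reports withheld accuracy on them.
#'
#' @param config An [experiment_config()].
#' @param n_train_cells,n_test_cells Simulated cells for each stage.
#' @param spots_per_species Spots per species per cell.
#' @param seed Master seed.
#' @param include_noise Add the non-translating class.
#' @param ... Passed to [train_classifier()] (`spec`, `search_budget`,
#'   `cv_epoch_cap`, ...).
#' @return A list: `classifier`, `internal_accuracy` (20% split of the
#'   training pool), `test_accuracy` (fresh cells), `evaluation` (full
#'   [evaluate_classifier()] output), `n_train`, `n_test`.
#' @export
run_condition <- function(config, n_train_cells = 8, n_test_cells = 4,
                          spots_per_species = 25, seed = 1,
                          include_noise = FALSE,
                          test_spots_per_species = spots_per_species, ...) {
  train <- generate_nct_dataset(config, n_train_cells, spots_per_species,
                                seed = child_seed(seed, 1L),
                                include_noise = include_noise)
  clf <- train_classifier(train$features, train$labels,
                          seed = child_seed(seed, 2L), ...)
  clf$extrema <- train$extrema
  test <- generate_test_features(config, n_test_cells,
                                 test_spots_per_species,
                                 seed = child_seed(seed, 3L),
                                 include_noise = include_noise)
  ev <- evaluate_classifier(clf, test$features, test$labels,
                            exclude_class = if (include_noise) "noise")
  list(classifier = clf, internal_accuracy = clf$test_accuracy,
       test_accuracy = if (include_noise) ev$accuracy_excluding else
         ev$accuracy,
       evaluation = ev, n_train = length(train$labels),
       n_test = length(test$labels))
}

#' Generate test-video features with the training normalization procedure
#'
#' Applies the same per-video min-max scaling used on the training videos:
#' each test video is normalized by its own global extrema, so test and
#' training features share one distributional scale. (Re-applying the raw
#' pooled training extrema instead would compress every test feature by
#' whatever margin the pooled range exceeds a single video's range and
#' systematically shift spots toward their dimmer neighbor class.)
#'
#' @inheritParams generate_nct_dataset
#' @param extrema Optional fixed scaling constants; when supplied they are
#'   applied verbatim instead of per-video normalization.
#' @return List with `features` and `labels`.
#' @export
generate_test_features <- function(config, n_cells, spots_per_species, seed,
                                   extrema = NULL, include_noise = FALSE) {
  ds <- generate_nct_dataset(config, n_cells, spots_per_species, seed,
                             include_noise = include_noise,
                             extrema = extrema)
  list(features = ds$features, labels = ds$labels, cell = ds$cell)
}

# ---------------------------------------------------------------------------
# Sweeps

#' Sweep classification accuracy over a parameter grid
#'
#' Generic sweep runner: `builder(row)` maps one grid row to an
#' [experiment_config()]; each cell is run with fresh child seeds via
#' [run_condition()] and its withheld accuracy recorded.
#'
#' @param grid Data.frame of grid axes (one row per cell).
#' @param builder Function taking one grid row (as a one-row data.frame)
#'   and returning an `experiment_config`.
#' @param seed Master seed.
#' @param budget Maximum number of cells to run; remaining cells are
#'   returned with `completed = FALSE`.
#' @param ... Passed to [run_condition()] (replication and training knobs).
#' @return `grid` with `accuracy`, `seed`, `completed` columns appended
#'   (class `sweep_result`).
#' @export
sweep_accuracy <- function(grid, builder, seed = 1, budget = Inf, ...) {
  acc <- rep(NA_real_, nrow(grid))
  seeds <- integer(nrow(grid))
  done <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (i > budget) break
    seeds[i] <- child_seed(seed, i)
    cfg <- builder(grid[i, , drop = FALSE])
    res <- run_condition(cfg, seed = seeds[i], ...)
    acc[i] <- res$test_accuracy
    done[i] <- TRUE
  }
  out <- cbind(grid, accuracy = acc, seed = seeds, completed = done)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Classify one ladder length pair at baseline imaging
#'
#' Both species share the baseline rates and the 10x tag; only their gene
#' lengths differ.
#'
#' @param name_a,name_b Ladder gene names (see [table_gene_lengths()]).
#' @param snr Reference-species SNR (reference = shorter gene).
#' @param ... Passed to [run_condition()].
#' @return The [run_condition()] result plus `fold_change` (tag included).
#' @export
length_pair_condition <- function(name_a, name_b, snr = 6.2, ...) {
  lens <- table_gene_lengths()
  ord <- c(name_a, name_b)[order(lens[c(name_a, name_b)])]
  species <- stats::setNames(lapply(ord, ladder_construct), ord)
  cfg <- experiment_config(
    species, translation_params(k_i = 0.06, k_e = 5.33),
    imaging_config(frame_interval = 5, n_frames = 64, snr = snr,
                   diffusion = 0.21))
  res <- run_condition(cfg, ...)
  res$fold_change <- length_fold_change(lens[[name_a]] + 1011,
                                        lens[[name_b]] + 1011)
  res
}

#' Robustness of a classifier to wrong parameter assumptions
#'
#' Trains once at `train_params` and evaluates the frozen classifier on
#' data generated at every cell of `test_grid` (columns `k_i`, `k_e`),
#' re-using the training normalization.
#'
#' @param train_params Named list/vector with `k_i`, `k_e` used for
#'   training data generation.
#' @param test_grid Data.frame with columns `k_i`, `k_e`.
#' @param species Named list of constructs (default baseline pair).
#' @param imaging An [imaging_config()].
#' @param n_train_cells,n_test_cells,spots_per_species Replication.
#' @param seed Master seed.
#' @param ... Passed to [train_classifier()].
#' @return List: `grid` (test grid with per-cell accuracy),
#'   `average_accuracy`, `classifier`.
#' @export
mismatch_robustness <- function(train_params, test_grid,
                                species = baseline_experiment()$species,
                                imaging = baseline_experiment()$imaging,
                                n_train_cells = 6, n_test_cells = 2,
                                spots_per_species = 25, seed = 1, ...) {
  cfg_tr <- experiment_config(
    species, translation_params(k_i = train_params[["k_i"]],
                                k_e = train_params[["k_e"]]), imaging)
  train <- generate_nct_dataset(cfg_tr, n_train_cells, spots_per_species,
                                seed = child_seed(seed, 1L))
  clf <- train_classifier(train$features, train$labels,
                          seed = child_seed(seed, 2L), ...)
  acc <- numeric(nrow(test_grid))
  for (i in seq_len(nrow(test_grid))) {
    cfg_te <- experiment_config(
      species, translation_params(k_i = test_grid$k_i[i],
                                  k_e = test_grid$k_e[i]), imaging)
    te <- generate_test_features(cfg_te, n_test_cells, spots_per_species,
                                 seed = child_seed(seed, 100L + i))
    acc[i] <- evaluate_classifier(clf, te$features, te$labels)$accuracy
  }
  list(grid = cbind(test_grid, accuracy = acc),
       average_accuracy = mean(acc), classifier = clf)
}

# ---------------------------------------------------------------------------
# Multiplexing demonstration

multiplex_channel_config <- function(channel = c("green", "blue")) {
  channel <- match.arg(channel)
  genes <- if (channel == "green") c("RRAGC", "LONRF2", "MAP3K6", "DOCK8")
           else c("ORC2", "TRIM33", "PHIP")
  snr <- if (channel == "green") 3.7 else 5.2   # reference = shortest gene
  species <- stats::setNames(lapply(genes, ladder_construct), genes)
  experiment_config(species, translation_params(k_i = 0.06, k_e = 5.33),
                    imaging_config(frame_interval = 5, n_frames = 64,
                                   snr = snr, diffusion = 0.21))
}

#' Two-color multiplexing demonstration
#'
#' Seven identically tagged species split over two channels (green: RRAGC,
#' LONRF2, MAP3K6, DOCK8; blue: ORC2, TRIM33, PHIP), each channel with an
#' extra class of non-translating spots extracted from the spot-free
#' channel. Trains one multiclass classifier per channel and evaluates on
#' fresh cells, reporting confusion matrices, accuracies excluding the
#' noise class, and the confidence-discard curves.
#'
#' @param n_train_cells,n_test_cells Cells for training pool / fresh test.
#' @param train_spots_per_species Spots per species per training cell; the
#'   published training pool comes from length-sweep cells with 25 spots
#'   per species, so 25 is the default.
#' @param spots_per_species Spots per species per *test* cell (10 in the
#'   full protocol).
#' @param seed Master seed.
#' @param ... Passed to [train_classifier()].
#' @return A list with one entry per channel: the `run_condition` result
#'   plus `confusion` and `discard_curve`.
#' @export
multiplex_demo <- function(n_train_cells = 16, n_test_cells = 10,
                           spots_per_species = 10,
                           train_spots_per_species = 25, seed = 1, ...) {
  out <- list()
  for (ch in c("green", "blue")) {
    cfg <- multiplex_channel_config(ch)
    res <- run_condition(cfg, n_train_cells = n_train_cells,
                         n_test_cells = n_test_cells,
                         spots_per_species = train_spots_per_species,
                         test_spots_per_species = spots_per_species,
                         seed = child_seed(seed, match(ch, c("green", "blue"))),
                         include_noise = TRUE, ...)
    res$confusion <- res$evaluation$confusion
    res$discard_curve <- res$evaluation$discard_curve
    out[[ch]] <- res
  }
  out
}
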