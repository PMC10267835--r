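# Independent oracles and shared fixtures for the test suite.

# --- exact CTMC oracle for small TASEP instances -------------------------
# Enumerates every exclusion-respecting ribosome configuration on L codons
# with footprint fp, builds the generator of the continuous-time Markov
# chain (initiation, stepping, termination), solves the stationary
# distribution, and returns per-codon occupancy probabilities.
ctmc_enumerate_states <- function(L, fp) {
  states <- list(integer(0))
  grow <- function(cfg, nextmin) {
    for (p in nextmin:L) {
      cfg2 <- c(cfg, p)
      states[[length(states) + 1]] <<- cfg2
      if (p + fp <= L) grow(cfg2, p + fp)
    }
  }
  grow(integer(0), 1L)
  states
}

ctmc_occupancy <- function(L, fp, ki, lambda) {
  st <- ctmc_enumerate_states(L, fp)
  key <- vapply(st, paste, "", collapse = ",")
  n <- length(st)
  Q <- matrix(0, n, n)
  idx <- function(cfg) match(paste(cfg, collapse = ","), key)
  for (i in seq_len(n)) {
    cfg <- st[[i]]
    if (length(cfg) == 0 || min(cfg) > fp) {
      j <- idx(sort(c(cfg, 1L)))
      Q[i, j] <- Q[i, j] + ki
    }
    for (r in seq_along(cfg)) {
      p <- cfg[r]
      if (p == L) {
        j <- idx(setdiff(cfg, p))
        Q[i, j] <- Q[i, j] + lambda[p]
      } else if (!any(cfg > p & cfg <= p + fp)) {
        j <- idx(sort(replace(cfg, r, p + 1L)))
        Q[i, j] <- Q[i, j] + lambda[p]
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  pi_st <- qr.solve(rbind(t(Q), rep(1, n)), c(rep(0, n), 1))
  occ <- numeric(L)
  for (i in seq_len(n)) for (p in st[[i]]) occ[p] <- occ[p] + pi_st[i]
  occ
}

# --- brute-force autocorrelation oracle (double loop) --------------------
acf_bruteforce <- function(x) {
  T <- length(x)
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / T)
  G <- numeric(T - 1)
  for (tau in 0:(T - 2)) {
    s <- 0
    for (t in 0:(T - 1 - tau)) {
      s <- s + ((x[t + 1] - mu) / sigma) * ((x[t + tau + 1] - mu) / sigma)
    }
    G[tau + 1] <- s / (T - 1 - tau)
  }
  G
}

# --- tiny uniform-rate constructs for simulation tests -------------------
toy_construct <- function(n_codons, tag = tag_design()) {
  gene_nt <- 3L * n_codons - tag$length_nt
  build_construct(generate_synthetic_gene(gene_nt, seed = n_codons), tag)
}

# bare construct with no tag (epitope profile identically zero)
bare_construct <- function(n_codons) {
  build_construct(generate_synthetic_gene(3L * n_codons, seed = n_codons),
                  tag_design(n_epitopes = 0L, length_nt = 0L))
}

# --- cached shared fixtures (built once per test run) --------------------
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

baseline_cfg <- function() fixture("baseline_cfg", baseline_experiment)

# Gaussian pseudo-trace feature sets for fast classifier tests: class means
# mu1/mu2 (counts), white noise sd, T frames.
gaussian_feature_data <- function(n_per_class, T, mu1, mu2, sd, seed) {
  set.seed(seed)
  tr <- rbind(matrix(stats::rnorm(n_per_class * T, mu1, sd), n_per_class),
              matrix(stats::rnorm(n_per_class * T, mu2, sd), n_per_class))
  labels <- factor(rep(c("A", "B"), each = n_per_class))
  list(features = build_features(tr), labels = labels)
}
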