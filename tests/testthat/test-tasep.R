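test_that("uniform-rate dwell times reproduce the baseline constructs", {
  cfg <- baseline_cfg()
  r_k <- assign_codon_rates(cfg$species$KDM5B, 5.33, mode = "uniform")
  r_p <- assign_codon_rates(cfg$species$P300, 5.33, mode = "uniform")
  expect_equal(r_k$tau, 1886 / 5.33, tolerance = 1e-12)
  expect_equal(round(r_k$tau), 354)
  expect_equal(round(r_p$tau), 517)
  # construct-normalized mode preserves the transit time by construction
  r_cn <- assign_codon_rates(cfg$species$KDM5B, 5.33,
                             mode = "construct_normalized")
  expect_equal(r_cn$tau, r_k$tau, tolerance = 1e-12)
  # degenerate all-equal weights collapse to the uniform mode
  w <- human_codon_usage(uniform = TRUE)
  r_eq <- assign_codon_rates(cfg$species$KDM5B, 5.33, usage_weights = w,
                             mode = "construct_normalized")
  expect_equal(r_eq$lambda, r_k$lambda, tolerance = 1e-12)
})

test_that("codon rate assignment rejects zero-weight codons", {
  con <- toy_construct(400)
  w <- human_codon_usage()
  w[con$codons[50]] <- 0
  expect_error(assign_codon_rates(con, 5, usage_weights = w,
                                  mode = "construct_normalized"),
               "zero/missing")
})

test_that("sparse-loading calculators match their closed forms", {
  cfg <- baseline_cfg()
  kdm5b <- cfg$species$KDM5B; p300 <- cfg$species$P300
  tau_k <- 1886 / 5.33; tau_p <- 2756 / 5.33
  expect_equal(sparse_mean_intensity(kdm5b, 0.06, tau_k),
               (1 - 1011 / 11316) * tau_k * 0.06, tolerance = 1e-12)
  expect_equal(sparse_mean_intensity(kdm5b, 0.06, tau_k), 19.33,
               tolerance = 1e-3)
  expect_equal(sparse_mean_intensity(kdm5b, 0, tau_k), 0)
  # ratio of sparse means at equal k_i
  expect_equal(sparse_mean_intensity(p300, 0.06, tau_p) /
                 sparse_mean_intensity(kdm5b, 0.06, tau_k),
               1.507, tolerance = 1e-3)
  # Campbell variance: k_i * tau * mean(f^2), and the tagless-limit Poisson
  expect_equal(sparse_intensity_variance(kdm5b, 0.06, tau_k),
               0.06 * tau_k * mean(kdm5b$epitope_profile^2),
               tolerance = 1e-12)
  f1 <- kdm5b; f1$epitope_profile <- rep(1, f1$total_codons)
  expect_equal(sparse_intensity_variance(f1, 0.06, tau_k),
               0.06 * tau_k)                       # variance = mean
})

test_that("critical ratios match the analytic manifolds", {
  cfg <- baseline_cfg()
  kdm5b <- cfg$species$KDM5B; p300 <- cfg$species$P300
  r_ki <- critical_ki_ratio(p300, kdm5b, tau_a = 517, tau_b = 353)
  expect_equal(round(r_ki, 3), 0.662)
  expect_equal(critical_ki_ratio(kdm5b, kdm5b, 354, 354), 1)
  # plugging the ratio back makes the sparse intensity ratio exactly 1
  expect_equal(sparse_mean_intensity(p300, 0.06 * r_ki, 517) /
                 sparse_mean_intensity(kdm5b, 0.06, 353), 1,
               tolerance = 1e-12)

  r_ke <- critical_ke_ratio(p300, kdm5b)
  expect_equal(round(r_ke, 5), 1.46129)
  expect_equal(critical_ke_ratio(kdm5b, kdm5b), 1)
  # at this k_e ratio both sparse means and dwell times coincide
  ke <- 5.33
  tau_k2 <- kdm5b$total_codons / ke
  tau_p2 <- p300$total_codons / (ke * r_ke)
  expect_equal(tau_k2, tau_p2, tolerance = 1e-12)
  expect_equal(sparse_mean_intensity(p300, 0.06, tau_p2) /
                 sparse_mean_intensity(kdm5b, 0.06, tau_k2),
               (1 - 1011 / 16536) / (1 - 1011 / 11316), tolerance = 1e-12)
})

test_that("TASEP simulation honors exclusion, conservation and seeds", {
  con <- toy_construct(400)
  pars <- translation_params(k_i = 0.1, k_e = 5, burn_in = 300)
  rates <- assign_codon_rates(con, pars$k_e)
  tr <- simulate_tasep(con, rates, pars, duration = 400, seed = 5,
                       snapshots = TRUE)
  # exclusion: ordered gaps >= footprint in every recorded snapshot
  for (s in tr$snapshots) {
    if (length(s) > 1) expect_true(all(diff(s) >= pars$footprint))
    if (length(s) > 0) expect_true(all(s >= 1 & s <= con$total_codons))
  }
  # conservation over the whole run: initiations = terminations + on board
  expect_equal(tr$n_initiated,
               tr$n_terminated + length(tr$final_positions))
  # seeded reproducibility
  tr2 <- simulate_tasep(con, rates, pars, duration = 400, seed = 5)
  expect_identical(tr$values, tr2$values)
  # k_i = 0 is legal and dark
  tr0 <- simulate_tasep(con, rates, translation_params(k_i = 0, k_e = 5,
                                                       burn_in = 10),
                        duration = 50, seed = 1)
  expect_true(all(tr0$values == 0))
})

test_that("3-codon instance matches exact master-equation occupancies", {
  L <- 3; fp <- 1; ki <- 0.6
  lambda <- c(1.2, 0.8, 1.0)
  occ_exact <- ctmc_occupancy(L, fp, ki, lambda)
  con <- bare_construct(L)
  tr <- simulate_tasep(con, codon_rates(lambda),
                       translation_params(k_i = ki, k_e = 1, footprint = fp,
                                          burn_in = 100),
                       duration = 1.2e5, record_times = seq(0, 1.2e5, 2),
                       seed = 17, snapshots = TRUE)
  occ_ssa <- numeric(L)
  for (s in tr$snapshots) for (p in s) occ_ssa[p] <- occ_ssa[p] + 1
  occ_ssa <- occ_ssa / length(tr$snapshots)
  # 3 sd Monte-Carlo tolerance with a conservative effective sample size
  n_eff <- length(tr$snapshots) / 8
  tol <- 3 * sqrt(occ_exact * (1 - occ_exact) / n_eff)
  expect_true(all(abs(occ_ssa - occ_exact) <= tol))
})

test_that("sparse-limit mean intensity approaches the analytic value", {
  cfg <- baseline_cfg()
  pars <- translation_params(k_i = 0.005, k_e = 5.33)
  m <- simulate_spot_ensemble(cfg$species$KDM5B, cfg$rates$KDM5B, pars,
                              n_spots = 40, duration = 1500, seed = 9)
  target <- 0.005 * cfg$rates$KDM5B$tau *
    mean(cfg$species$KDM5B$epitope_profile)
  n_eff <- 40 * 1500 / (2 * cfg$rates$KDM5B$tau)
  mc_sd <- sd(as.vector(m)) / sqrt(n_eff)
  expect_lt(abs(mean(m) - target), 3 * mc_sd)
})

test_that("intensity autocovariance decays over the dwell time", {
  cfg <- baseline_cfg()
  m <- simulate_spot_ensemble(cfg$species$KDM5B, cfg$rates$KDM5B,
                              cfg$params$KDM5B, n_spots = 30,
                              duration = 3000, seed = 21)
  G <- colMeans(t(apply(m, 1, trace_autocorrelation)))
  tau_dwell <- cfg$rates$KDM5B$tau
  # sparse-theory oracle for the normalized autocovariance: the 1/e
  # crossing of sum_j f_j f_{j+s} / sum_j f_j^2 at s = tau * k_e codons
  f <- cfg$species$KDM5B$epitope_profile
  n <- length(f)
  a <- vapply(0:(n - 1), function(s)
    sum(f[1:(n - s)] * f[(1 + s):n]), numeric(1)) / sum(f^2)
  cross_theory <- (which(a < exp(-1))[1] - 1) / cfg$params$KDM5B$k_e
  cross <- which(G < exp(-1))[1] - 1
  expect_gt(cross, 0.6 * cross_theory)
  expect_lt(cross, 1.4 * cross_theory)
  # the crossing sits at the dwell-time scale, and the ACF has decayed to
  # about zero a few dwell times out
  expect_gt(cross, 0.3 * tau_dwell)
  expect_lt(cross, 1.1 * tau_dwell)
  far <- G[seq(round(3 * tau_dwell), round(5 * tau_dwell))]
  expect_lt(abs(mean(far)), 0.15)
})

test_that("trace CSV round-trip preserves the ensemble", {
  con <- toy_construct(360)
  m <- simulate_spot_ensemble(con, params = translation_params(burn_in = 100),
                              n_spots = 3, duration = 30, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  traces_to_csv(m, path)
  back <- read_traces_csv(path)
  expect_equal(unname(back[, ]), unname(m[, ]), tolerance = 1e-8)
  expect_equal(attr(back, "times"), attr(m, "times"))
})
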