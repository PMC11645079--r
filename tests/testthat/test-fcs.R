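# Lattice diffusion, photon traces, multi-tau correlation and model fitting.

test_that("configuration invariants are enforced", {
  expect_error(diffusion_sim_config(box_um = 2.43), "integer")
  expect_error(diffusion_sim_config(D_um2_s = 100, dt_s = 1e-5), "0.25")
  expect_error(diffusion_sim_config(duration_s = 0.001), "1e4 bins")
  expect_error(diffusion_sim_config(bin_time_s = 1.5e-6), "multiple")
})

test_that("zero diffusion leaves molecules stationary", {
  cfg <- diffusion_sim_config(n_molecules = 5, D_um2_s = 0,
                              duration_s = 0.05, seed = 2)
  tr <- simulate_trajectories(cfg, n_steps = 200)
  expect_equal(apply(tr, c(2, 3), function(v) length(unique(v))),
               matrix(1L, 5, 3))
})

test_that("lattice MSD follows the Einstein relation within 5% per axis", {
  cfg <- diffusion_sim_config(n_molecules = 300, duration_s = 0.05, seed = 5)
  tr <- simulate_trajectories(cfg, n_steps = 1e4)
  for (lag in c(50, 200)) {
    msd <- msd_per_axis(tr, lag, cfg$box_um)
    expect_rel(msd, 2 * cfg$D_um2_s * lag * cfg$dt_s, 0.05)
  }
})

test_that("equilibrium occupancy of a sub-box is Poisson-consistent", {
  cfg <- diffusion_sim_config(n_molecules = 300, duration_s = 0.05, seed = 8)
  tr <- simulate_trajectories(cfg, n_steps = 4000)
  sub <- 0.3  # um, sub-box half-width: occupancy ~ Poisson (v/V small)
  inside <- apply(abs(tr) < sub, c(1, 2), all)
  counts <- rowSums(inside)[seq(1, 4000, by = 400)]
  mu <- 300 * (2 * sub / cfg$box_um)^3
  expect_equal(mean(counts), mu, tolerance = 4 * sqrt(mu / length(counts)) / mu)
  # index of dispersion near 1 (snapshots are only partly decorrelated, so
  # the bound is generous but still excludes clumped or frozen occupancy)
  ratio <- stats::var(counts) / mean(counts)
  expect_gt(ratio, 0.3); expect_lt(ratio, 2.2)
})

test_that("concentration follows the box volume and molecule count", {
  expect_equal(concentration(diffusion_sim_config()), 36.04, tolerance = 0.001)
  small <- diffusion_sim_config(n_molecules = 300, box_um = 1.2)
  expect_equal(concentration(small), 8 * concentration(diffusion_sim_config()),
               tolerance = 1e-9)
  # definition check: 1 nM corresponds to one molecule per ~1.66 um^3
  one <- diffusion_sim_config(n_molecules = 1, box_um = 1.1845,
                              cell_nm = 59.225)
  expect_equal(concentration(one), 1, tolerance = 0.001)
})

test_that("photon trace mean matches rate * bin for a uniformly detected molecule", {
  cfg <- diffusion_sim_config(n_molecules = 1, duration_s = 0.1, seed = 4)
  flat <- array(1, dim = rep(cfg$n_cells, 3))
  tr <- fcs_experiment(cfg, flat, peak_rate = 2e5)
  expect_rel(mean(tr$counts), 2e5 * cfg$bin_time_s, 0.02)
  # empty box: all-zero trace
  cfg0 <- diffusion_sim_config(n_molecules = 0, duration_s = 0.1, seed = 4)
  expect_true(all(fcs_experiment(cfg0, flat, 2e5)$counts == 0))
})

test_that("fused photon trace equals the trajectory-based path stream for stream", {
  cfg <- diffusion_sim_config(n_molecules = 12, duration_s = 0.04, seed = 31)
  mde <- gaussian_mde(0.3, 0.9)
  tr <- simulate_trajectories(cfg, n_steps = cfg$n_steps)
  a <- photon_trace(tr, mde, 5e4, cfg)
  b <- fcs_experiment(cfg, mde, 5e4)
  expect_identical(a$counts, b$counts)
  # changing the molecule count leaves existing streams untouched
  cfg2 <- diffusion_sim_config(n_molecules = 20, duration_s = 0.04, seed = 31)
  tr2 <- simulate_trajectories(cfg2, n_steps = 200)
  expect_equal(tr2[, 1:12, ], simulate_trajectories(cfg, n_steps = 200))
})

test_that("trace mean matches the ergodic MDE average within 3 standard errors", {
  cfg <- diffusion_sim_config(n_molecules = 100, duration_s = 0.5, seed = 12)
  mde <- gaussian_mde(0.3, 0.9)
  rate <- 1e5
  tr <- fcs_experiment(cfg, mde, rate)
  expected_rate <- rate * cfg$n_molecules * mean(mde)
  se <- stats::sd(tr$counts / cfg$bin_time_s) / sqrt(length(tr$counts) / 1000)
  expect_lt(abs(tr$mean_rate - expected_rate), 3 * max(se, 0.01 * expected_rate))
})

test_that("multi-tau equals the brute-force direct correlation at every lag", {
  set.seed(77)
  # correlated toy trace: smoothed Poisson
  raw <- stats::rpois(1e4, 2) + rep(stats::rpois(1e3, 3), each = 10)
  curve <- autocorrelate(raw, m = 16, n_stages = 4, bin_time_s = 1)
  series <- as.numeric(raw)
  bin <- 1
  k <- 0
  for (stage in 0:3) {
    lags <- if (stage == 0) 1:16 else 9:16
    for (l in lags) {
      k <- k + 1
      ref <- oracle_direct_G(series, l)
      expect_equal(curve$G[k], ref, tolerance = 1e-12)
      expect_equal(curve$lag_s[k], l * bin)
    }
    series <- oracle_rebin2(series)
    bin <- bin * 2
  }
})

test_that("constant and uncorrelated traces give flat correlation", {
  flat <- autocorrelate(rep(7, 5000), bin_time_s = 1e-6)
  expect_true(all(abs(flat$G) < 1e-12))
  set.seed(21)
  pois <- autocorrelate(stats::rpois(2e5, 5), bin_time_s = 1e-6)
  ok <- is.finite(pois$se) & pois$se > 0
  expect_true(all(abs(pois$G[ok]) < 4 * pois$se[ok]))
  expect_error(autocorrelate(rep(0, 5000)), "zero")
})

test_that("the 3D-diffusion fit recovers noise-free model curves to 1e-6", {
  tau <- 10^seq(-6, -1, length.out = 60)
  N <- 4; tauD <- 4e-5; s <- 5; Ginf <- 2e-4
  G <- Ginf + (1 / N) / ((1 + tau / tauD) * sqrt(1 + tau / (s^2 * tauD)))
  curve <- structure(data.frame(lag_s = tau, G = G, se = NA_real_),
                     class = c("correlation_curve", "data.frame"))
  fit <- fit_3d_diffusion(curve)
  expect_rel(fit$N, N, 1e-6)
  expect_rel(fit$tau_D_s, tauD, 1e-6)
  expect_rel(fit$s_ratio, s, 1e-4)
  # amplitude limit: G(0+) = G_inf + 1/N
  expect_equal(fit$G_inf + 1 / fit$N, Ginf + 1 / N, tolerance = 1e-6)
})

test_that("occupancy and diffusion time are recovered through a Gaussian volume", {
  w_xy <- 0.18; w_z <- 0.9423  # pi^1.5 w_xy^2 w_z = 0.17 fl
  cfg <- diffusion_sim_config(n_molecules = 300, duration_s = 3, seed = 19)
  mde <- gaussian_mde(w_xy, w_z)
  trace <- fcs_experiment(cfg, mde, 2e4)
  fit <- fit_3d_diffusion(autocorrelate(trace),
                          init = list(s_ratio = w_z / w_xy), fix_s = TRUE)
  v_eff_L <- pi^1.5 * w_xy^2 * w_z * 1e-15
  n_expected <- concentration(cfg) * 1e-9 * 6.02214076e23 * v_eff_L
  expect_rel(fit$N, n_expected, 0.2)
  expect_rel(fit$tau_D_s, w_xy^2 / (4 * cfg$D_um2_s), 0.2)
})

test_that("correlation noise is reproducible and decreases with brightness", {
  cfg <- diffusion_sim_config(n_molecules = 300, duration_s = 2, seed = 6)
  mde <- gaussian_mde(0.18, 0.9423)
  tab <- snr_vs_brightness(cfg, mde, rates = c(5e3, 5e3, 5e4))
  # identical seed and rate: identical noise
  expect_identical(tab$rms_residual[1], tab$rms_residual[2])
  # 10x brighter molecules: substantially quieter correlation
  expect_lt(tab$rms_residual[3], tab$rms_residual[1] / 2)
  expect_error(snr_vs_brightness(cfg, mde, rates = c(0, 100)), "degenerate")
  expect_error(snr_vs_brightness(cfg, mde, rates = 100), "length")
})

test_that("trace and correlation artifacts round-trip through CSV", {
  cfg <- diffusion_sim_config(n_molecules = 5, duration_s = 0.02, seed = 1)
  tr <- fcs_experiment(cfg, gaussian_mde(0.3, 0.9), 1e5)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, p1)
  back <- utils::read.csv(p1)
  expect_equal(back$counts, tr$counts)
  expect_equal(names(back), c("time_s", "counts"))
})
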