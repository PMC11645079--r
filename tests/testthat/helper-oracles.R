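# Independent oracles used across the suite. Each re-derives its quantity
# by a route separate from the implementation it checks.

# Luke et al. silicon nitride Sellmeier fit: independent cross-check of the
# packaged SiN dispersion table (different source, same film family).
oracle_n_sin_luke <- function(lambda_um) {
  l2 <- lambda_um^2
  sqrt(1 + 3.0249 * l2 / (l2 - 0.1353406^2) +
         40314 * l2 / (l2 - 1239.842^2))
}

# Brute-force dense-grid root scan of the slab dispersion relation:
# midpoint of the first sign-change bracket on an n_eff grid of step `step`.
oracle_slab_neff <- function(lambda_nm, d_nm, n_core, n_sub, n_clad,
                             mode = "TE", step = 1e-6) {
  k0 <- 2 * pi / lambda_nm
  qs <- if (mode == "TM") (n_core / n_sub)^2 else 1
  qc <- if (mode == "TM") (n_core / n_clad)^2 else 1
  lo <- max(n_sub, n_clad) + step
  ne <- seq(lo, n_core - step, by = step)
  kap <- k0 * sqrt(n_core^2 - ne^2)
  gs <- k0 * sqrt(pmax(ne^2 - n_sub^2, 0))
  gc <- k0 * sqrt(pmax(ne^2 - n_clad^2, 0))
  f <- kap * d_nm - atan2(qs * gs, kap) - atan2(qc * gc, kap)
  i <- which(f[-length(f)] > 0 & f[-1] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  (ne[i] + ne[i + 1]) / 2
}

# Direct-sum correlation with the multi-tau normalization: the brute-force
# reference for one lag of a (possibly rebinned) series.
oracle_direct_G <- function(series, lag) {
  n <- length(series)
  M <- n - lag
  s <- sum(series[1:M] * series[(1 + lag):n])
  ml <- mean(series[1:M]); mr <- mean(series[(1 + lag):n])
  (s / M) / (ml * mr) - 1
}

# Rebin a series by 2 (pair means, truncating a trailing odd sample),
# matching the correlator's stage rebinning.
oracle_rebin2 <- function(series) {
  half <- length(series) %/% 2
  0.5 * (series[2 * (1:half) - 1] + series[2 * (1:half)])
}

# Dense-scan meta-atom placement: zero crossings of the wrapped phase
# mismatch on a 0.5 nm grid, refined by linear interpolation, thinned by
# the same minimum-spacing rule as the implementation.
oracle_scan_atoms <- function(y, lam, bet, lens, ipm, D_nm, diameter_nm,
                              step = 0.5) {
  x <- seq(-D_nm / 2, D_nm / 2, by = step)
  w <- wrap_phase(waveguide_phase(x, y, bet, ipm) -
                    lens_phase(x, y, lam, lens))
  i <- which(w[-length(w)] < 0 & w[-1] >= 0 &
               abs(w[-1] - w[-length(w)]) < pi)
  roots <- x[i] + step * (-w[i]) / (w[i + 1] - w[i])
  keep <- numeric(0)
  for (r in roots) {
    if (!length(keep) || r - keep[length(keep)] >= diameter_nm)
      keep <- c(keep, r)
  }
  keep
}

# Construct a field whose angular spectrum is a uniform disk of transverse
# wavenumber NA*k0 converging to a focus a distance F away: its focal-plane
# intensity is the scalar Airy pattern (jinc^2).
oracle_airy_field <- function(lambda_nm, na_val, n_medium, dx_nm, n, F_um) {
  f <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * dx_nm)
  kt <- 2 * pi * f
  k <- 2 * pi * n_medium / lambda_nm
  kt2 <- outer(kt^2, kt^2, `+`)
  disk <- kt2 <= (na_val * 2 * pi / lambda_nm)^2
  kz <- sqrt(as.complex(k^2 - kt2))
  # evaluate the converging phase only inside the disk: outside it kz is
  # imaginary and exp(-i kz F) overflows
  A <- matrix(0 + 0i, n, n)
  A[disk] <- exp(-1i * kz[disk] * F_um * 1000)
  U0 <- stats::fft(A, inverse = TRUE) / n^2
  # shift the FFT origin to the grid center so the focus forms on-axis
  m <- floor(n / 2)
  idx <- ((seq_len(n) - 1 - m) %% n) + 1
  scalar_field(U0[idx, idx], dx_nm, lambda_nm, n_medium)
}

# A band-limited random field (spectrum confined well inside the
# propagating circle) for energy-conservation checks.
oracle_bandlimited_field <- function(lambda_nm, n_medium, dx_nm, n, seed) {
  set.seed(seed)
  f <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * dx_nm)
  kt <- 2 * pi * f
  k <- 2 * pi * n_medium / lambda_nm
  kt2 <- outer(kt^2, kt^2, `+`)
  A <- matrix(stats::rnorm(n^2) + 1i * stats::rnorm(n^2), n, n)
  A[kt2 > (0.5 * k)^2] <- 0
  U0 <- stats::fft(A, inverse = TRUE) / n^2
  scalar_field(U0, dx_nm, lambda_nm, n_medium)
}

# Fabricate a psf_volume from a raw intensity array (photophysics tests).
fake_psf_volume <- function(arr, dx_nm = 50, z_um = NULL, lambda_nm = 570) {
  n <- dim(arr)[1]
  ax <- (seq_len(n) - 1 - floor(n / 2)) * dx_nm
  if (is.null(z_um)) z_um <- seq(5, by = 0.025, length.out = dim(arr)[3])
  structure(list(intensity = arr / max(arr),
                 x_nm = ax, y_nm = (seq_len(dim(arr)[2]) - 1 -
                                      floor(dim(arr)[2] / 2)) * dx_nm,
                 z_um = z_um, lambda_nm = lambda_nm, peak_raw = max(arr),
                 aperture_power = 1, h_SOG_um = 2),
            class = "psf_volume")
}

# Fabricate an mde_map from a raw array on given axes.
fake_mde_map <- function(arr, x_nm, y_nm, z_um) {
  structure(list(mde = arr, x_nm = x_nm, y_nm = y_nm, z_um = z_um,
                 peak_mde = max(arr), peak_mde_percent = 100 * max(arr),
                 p_max = 1 / 3),
            class = "mde_map")
}

# Strict relative-error expectation: |actual/expected - 1| < tol, regardless
# of magnitude (expect_equal's tolerance goes absolute for values near or
# below 1, which would make checks on quantities like tau_D or V_eff vacuous).
expect_rel <- function(actual, expected, tol) {
  testthat::expect_lt(max(abs(actual / expected - 1)), tol)
}
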