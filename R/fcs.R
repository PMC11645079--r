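# Monte Carlo diffusion FCS: lattice Brownian motion through an MDE volume,
# Poisson photon traces, multi-tau autocorrelation and 3D-diffusion fitting.

#' Diffusion simulation configuration
#'
#' Molecules hop on a cubic lattice (cell constant `cell_nm`) with per-axis
#' probability p = D dt / cell^2 of moving one cell in each direction per
#' step (variance 2 D dt per axis), with periodic wrapping at the box faces.
#' Defaults follow the simulated experiment: 300 molecules in a
#' (2.4 um)^3 box of 50 nm cells observed for 30 s.
#'
#' @param n_molecules Number of molecules (default 300).
#' @param box_um Box edge in um (default 2.4; must be a multiple of the cell).
#' @param cell_nm Lattice constant in nm (default 50).
#' @param D_um2_s Diffusion coefficient in um^2/s (default 100, a small dye).
#' @param dt_s Time step in s (default 1e-6).
#' @param duration_s Acquisition time in s (default 30).
#' @param bin_time_s Photon bin width in s (default 2e-6, a multiple of dt).
#' @param seed Master seed; expands to independent per-molecule streams.
#' @return An object of class `diffusion_sim_config`.
#' @export
diffusion_sim_config <- function(n_molecules = 300, box_um = 2.4,
                                 cell_nm = 50, D_um2_s = 100, dt_s = 1e-6,
                                 duration_s = 30, bin_time_s = 2e-6,
                                 seed = 1) {
  n_cells <- box_um * 1000 / cell_nm
  if (abs(n_cells - round(n_cells)) > 1e-9)
    stop("box edge must be an integer number of lattice cells")
  p <- D_um2_s * dt_s / (cell_nm / 1000)^2
  if (p > 0.25)
    stop(sprintf("time step too large: p = D*dt/cell^2 = %.3f > 0.25", p))
  spb <- bin_time_s / dt_s
  if (abs(spb - round(spb)) > 1e-9 || spb < 1)
    stop("bin_time must be a positive integer multiple of dt")
  n_bins <- duration_s / bin_time_s
  if (n_bins < 1e4)
    stop("duration must cover at least 1e4 bins")
  structure(list(n_molecules = n_molecules, box_um = box_um,
                 cell_nm = cell_nm, n_cells = as.integer(round(n_cells)),
                 D_um2_s = D_um2_s, dt_s = dt_s, duration_s = duration_s,
                 bin_time_s = bin_time_s, steps_per_bin = as.integer(round(spb)),
                 n_steps = as.integer(round(duration_s / dt_s)),
                 p_hop = p, seed = seed),
            class = "diffusion_sim_config")
}

#' Molecule concentration of a simulation box
#'
#' n_molecules / (box volume * Avogadro), in nanomolar.
#'
#' @param cfg A [diffusion_sim_config()].
#' @return Concentration in nM.
#' @export
concentration <- function(cfg) {
  stopifnot(inherits(cfg, "diffusion_sim_config"))
  box_L <- (cfg$box_um * 1e-6)^3 * 1e3  # m^3 -> L
  cfg$n_molecules / (6.02214076e23 * box_L) * 1e9
}

#' Simulate lattice-diffusion trajectories
#'
#' Explicit per-step positions for analysis-scale runs (moments, occupancy
#' statistics); the photon-trace generator uses a fused path with the same
#' per-molecule random streams, so a molecule's trajectory is identical in
#' both. Positions are cell-center coordinates in um, box centered on 0.
#'
#' @param cfg A [diffusion_sim_config()].
#' @param n_steps Number of steps (default the full configured run; keep
#'   small here, the full array must fit in memory).
#' @return Array `[step, molecule, axis]` of positions in um.
#' @export
simulate_trajectories <- function(cfg, n_steps = cfg$n_steps) {
  stopifnot(inherits(cfg, "diffusion_sim_config"))
  idx <- .fcs_trajectories(cfg$n_molecules, cfg$n_cells, cfg$p_hop,
                           as.integer(n_steps), as.double(cfg$seed))
  (idx + 0.5) * (cfg$cell_nm / 1000) - cfg$box_um / 2
}

# Unwrapped displacement variance needs raw hops; recover per-axis MSD from
# wrapped positions is wrong once molecules wrap, so Einstein-relation
# checks should use lags short enough that displacements stay < box/2;
# displacements are minimal-image corrected here.
#' Mean-squared displacement per axis
#'
#' Minimal-image displacement MSD at a given step lag, averaged over
#' molecules and all time origins.
#'
#' @param traj Trajectory array from [simulate_trajectories()].
#' @param lag_steps Step lag.
#' @param box_um Box edge (for minimal-image unwrapping).
#' @return Numeric length-3 vector: MSD per axis in um^2.
#' @export
msd_per_axis <- function(traj, lag_steps, box_um) {
  n <- dim(traj)[1]
  stopifnot(lag_steps < n)
  d <- traj[(1 + lag_steps):n, , , drop = FALSE] -
    traj[1:(n - lag_steps), , , drop = FALSE]
  d <- d - box_um * round(d / box_um)
  apply(d^2, 3, mean)
}

#' Synthetic Gaussian MDE on the simulation lattice
#'
#' A 3D Gaussian detection profile exp(-2 r_xy^2 / w_xy^2 - 2 z^2 / w_z^2)
#' sampled at the lattice cell centers, peak-normalized; its effective
#' volume is pi^1.5 w_xy^2 w_z by construction.
#'
#' @param w_xy_um Lateral 1/e^2 radius in um.
#' @param w_z_um Axial 1/e^2 radius in um.
#' @param box_um,cell_nm Lattice geometry (defaults 2.4 um, 50 nm).
#' @return A numeric 3D array `[x, y, z]`, values in [0, 1].
#' @export
gaussian_mde <- function(w_xy_um, w_z_um, box_um = 2.4, cell_nm = 50) {
  n <- round(box_um * 1000 / cell_nm)
  cc <- ((seq_len(n) - 0.5) * cell_nm / 1000) - box_um / 2
  r2 <- outer(cc^2, cc^2, `+`)
  lat <- exp(-2 * r2 / w_xy_um^2)
  ax <- exp(-2 * cc^2 / w_z_um^2)
  array(outer(lat, ax), dim = c(n, n, n))
}

#' Resample an MDE map onto the simulation lattice
#'
#' Samples a computed [mde_map()] (peak-normalized) at the lattice cell
#' centers of the diffusion box, centered on the MDE peak; nearest-cell
#' lookup by default, optionally trilinear.
#'
#' @param mde An `mde_map`.
#' @param box_um,cell_nm Lattice geometry.
#' @param interp `"nearest"` (default) or `"trilinear"`.
#' @return A numeric 3D array on the lattice, peak-normalized.
#' @export
mde_to_lattice <- function(mde, box_um = 2.4, cell_nm = 50,
                           interp = c("nearest", "trilinear")) {
  interp <- match.arg(interp)
  stopifnot(inherits(mde, "mde_map"))
  n <- round(box_um * 1000 / cell_nm)
  pk <- arrayInd(which.max(mde$mde), dim(mde$mde))
  cc <- ((seq_len(n) - 0.5) * cell_nm / 1000) - box_um / 2
  xq <- cc * 1000 + mde$x_nm[pk[1]]
  yq <- cc * 1000 + mde$y_nm[pk[2]]
  zq <- cc + mde$z_um[pk[3]]
  m <- mde$mde / max(mde$mde)
  samp_axis <- function(ax, q) {
    if (interp == "nearest") {
      i <- round(stats::approx(ax, seq_along(ax), xout = q, rule = 2)$y)
      list(i0 = i, i1 = i, w = rep(0, length(q)),
        inside = q >= ax[1] & q <= ax[length(ax)])
    } else {
      f <- stats::approx(ax, seq_along(ax), xout = pmin(pmax(q, ax[1]),
                                                        ax[length(ax)]))$y
      i0 <- pmin(floor(f), length(ax) - 1)
      list(i0 = i0, i1 = i0 + 1, w = f - i0,
        inside = q >= ax[1] & q <= ax[length(ax)])
    }
  }
  sx <- samp_axis(mde$x_nm, xq); sy <- samp_axis(mde$y_nm, yq)
  sz <- samp_axis(mde$z_um, zq)
  out <- array(0, dim = c(n, n, n))
  for (k in seq_len(n)) {
    if (!sz$inside[k]) next
    sl0 <- m[, , sz$i0[k]]; sl1 <- m[, , sz$i1[k]]
    sl <- (1 - sz$w[k]) * sl0 + sz$w[k] * sl1
    gx0 <- sl[sx$i0, ]; gx1 <- sl[sx$i1, ]
    gx <- (1 - sx$w) * gx0 + sx$w * gx1
    g <- (1 - rep(sy$w, each = n)) * gx[, sy$i0] +
      rep(sy$w, each = n) * gx[, sy$i1]
    g[!sx$inside, ] <- 0
    g[, !sy$inside] <- 0
    out[, , k] <- g
  }
  out / max(out)
}

#' Photon trace from explicit trajectories
#'
#' Expected counts per bin sum peak_rate * MDE(position) * dt over the
#' molecules and the steps inside each bin (nearest-cell MDE lookup);
#' emitted counts are Poisson draws. Molecules outside the MDE support
#' contribute nothing.
#'
#' @param traj Trajectory array from [simulate_trajectories()] (um).
#' @param mde_lattice MDE array on the simulation lattice, peak 1.
#' @param peak_rate Detected counts/s for a molecule at the MDE peak
#'   (N_F from the photon-budget model).
#' @param cfg The [diffusion_sim_config()] used for `traj`.
#' @return An `intensity_trace`: list with `bin_time_s`, `counts`,
#'   `mean_rate`.
#' @export
photon_trace <- function(traj, mde_lattice, peak_rate, cfg) {
  stopifnot(inherits(cfg, "diffusion_sim_config"))
  if (cfg$bin_time_s < cfg$dt_s) stop("bin_time must be >= dt")
  n_steps <- dim(traj)[1] - 1
  n_bins <- n_steps %/% cfg$steps_per_bin
  if (n_bins < 1) stop("trajectory shorter than one bin")
  idx <- round((traj + cfg$box_um / 2) / (cfg$cell_nm / 1000) - 0.5) + 1
  n <- cfg$n_cells
  expected <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    steps <- ((b - 1) * cfg$steps_per_bin + 2):(b * cfg$steps_per_bin + 1)
    ii <- idx[steps, , , drop = FALSE]
    lin <- (ii[, , 3] - 1) * n * n + (ii[, , 2] - 1) * n + ii[, , 1]
    expected[b] <- peak_rate * cfg$dt_s * sum(mde_lattice[lin])
  }
  set.seed(cfg$seed)
  make_trace(stats::rpois(n_bins, expected), cfg$bin_time_s)
}

make_trace <- function(counts, bin_time_s) {
  structure(list(bin_time_s = bin_time_s, counts = counts,
                 mean_rate = mean(counts) / bin_time_s),
            class = "intensity_trace")
}

#' Fused Monte Carlo FCS experiment
#'
#' Runs the full lattice diffusion and photon-trace generation in one pass
#' (no trajectory storage), suitable for the 30 s production runs.
#' Identical per-molecule streams to [simulate_trajectories()].
#'
#' @param cfg A [diffusion_sim_config()].
#' @param mde_lattice MDE array on the simulation lattice, peak 1.
#' @param peak_rate Peak-molecule count rate in counts/s.
#' @return An `intensity_trace`.
#' @export
fcs_experiment <- function(cfg, mde_lattice, peak_rate) {
  stopifnot(inherits(cfg, "diffusion_sim_config"))
  stopifnot(all(dim(mde_lattice) == cfg$n_cells))
  expected <- .fcs_expected_trace(cfg$n_molecules, cfg$n_cells, cfg$p_hop,
                                  cfg$n_steps, cfg$steps_per_bin,
                                  as.numeric(mde_lattice), peak_rate,
                                  cfg$dt_s, as.double(cfg$seed))
  set.seed(cfg$seed)
  make_trace(stats::rpois(length(expected), expected), cfg$bin_time_s)
}

#' Multi-tau autocorrelation
#'
#' Quasi-logarithmic autocorrelation G(tau) = <dI(t) dI(t+tau)> / <I>^2 with
#' `m` linear channels per stage and binning doubled per stage, symmetric
#' normalization, and block-averaged standard errors.
#'
#' @param trace An `intensity_trace` (or bare numeric count vector with
#'   `bin_time_s` given).
#' @param m Channels per stage (default 16).
#' @param n_stages Number of stages (default 12).
#' @param n_blocks Blocks for the error estimate (default 16).
#' @param bin_time_s Bin width when `trace` is a bare vector.
#' @return A `correlation_curve`: data.frame with `lag_s`, `G`, `se`.
#' @export
autocorrelate <- function(trace, m = 16, n_stages = 12, n_blocks = 16,
                          bin_time_s = NULL) {
  if (inherits(trace, "intensity_trace")) {
    counts <- trace$counts; bt <- trace$bin_time_s
  } else {
    counts <- as.numeric(trace)
    bt <- if (is.null(bin_time_s)) 1 else bin_time_s
  }
  res <- .multitau_cpp(as.numeric(counts), as.integer(m),
                       as.integer(n_stages), as.integer(n_blocks))
  out <- data.frame(lag_s = res$lag_bins * bt, G = res$G, se = res$se)
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Fit the 3D-diffusion FCS model
#'
#' Weighted nonlinear least squares of
#'   G(tau) = G_inf + (1/N) (1 + tau/tau_D)^-1 (1 + tau/(s^2 tau_D))^-1/2
#' using Levenberg-Marquardt; weights 1/se^2 where standard errors are
#' available. Deterministic given the curve and start values.
#'
#' @param curve A `correlation_curve`.
#' @param init Optional named list of start values (`N`, `tau_D_s`,
#'   `s_ratio`, `G_inf`); sensible data-driven defaults otherwise.
#' @param fix_s Fix the axial/lateral aspect ratio at its start value
#'   (standard practice when the detection-volume geometry is known).
#' @return An `fcs_fit`: list with the estimates, their covariance and the
#'   underlying `nls` object.
#' @export
fit_3d_diffusion <- function(curve, init = NULL, fix_s = FALSE) {
  stopifnot(inherits(curve, "correlation_curve"), nrow(curve) >= 10)
  tau <- curve$lag_s; G <- curve$G
  amp <- max(G[seq_len(min(5, length(G)))])
  if (is.null(init)) init <- list()
  if (is.null(init$N)) init$N <- max(1 / max(amp, 1e-6), 1e-3)
  if (is.null(init$tau_D_s)) {
    ih <- which(G <= amp / 2)[1]
    init$tau_D_s <- if (is.na(ih)) tau[round(length(tau) / 2)] else tau[ih]
  }
  if (is.null(init$s_ratio)) init$s_ratio <- 5
  if (is.null(init$G_inf)) init$G_inf <- 0
  w <- if (all(is.finite(curve$se)) && all(curve$se > 0)) 1 / curve$se^2
       else rep(1, length(tau))
  sw <- sqrt(w / mean(w))
  s_fix <- init$s_ratio
  model_fn <- function(par) {
    s <- if (fix_s) s_fix else par$s
    par$G_inf + (1 / par$N) /
      ((1 + tau / par$tauD) * sqrt(1 + tau / (s^2 * par$tauD)))
  }
  start <- list(N = init$N, tauD = init$tau_D_s, G_inf = init$G_inf)
  lower <- c(N = 1e-6, tauD = min(tau) / 10, G_inf = -1)
  upper <- c(N = Inf, tauD = max(tau) * 10, G_inf = 1)
  if (!fix_s) {
    start$s <- init$s_ratio
    lower <- c(lower, s = 1); upper <- c(upper, s = 100)
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(par) sw * (model_fn(par) - G),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4)
    stop(sprintf("3D-diffusion fit did not converge (nls.lm info %d: %s)",
                 fit$info, fit$message))
  co <- fit$par
  dof <- max(length(tau) - length(co), 1)
  covariance <- tryCatch(
    solve(fit$hessian / 2) * (fit$deviance / dof),
    error = function(e) NULL)
  structure(list(N = co[["N"]], tau_D_s = co[["tauD"]],
                 s_ratio = if (fix_s) s_fix else co[["s"]],
                 G_inf = co[["G_inf"]],
                 covariance = covariance,
                 fitted = model_fn(co), nls = fit),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("3D-diffusion FCS fit: N = %.3f, tau_D = %.3g s, s = %.2f, G_inf = %.2e\n",
              x$N, x$tau_D_s, x$s_ratio, x$G_inf))
  invisible(x)
}

#' Correlation noise versus molecular brightness
#'
#' Repeats the simulation at several peak count rates (same master seed, so
#' trajectories are identical and only shot noise changes), fits each curve
#' and reports the rms residual of G about its fit. Under shot-noise-limited
#' conditions the residual scales inversely with the rate.
#'
#' @param cfg A [diffusion_sim_config()].
#' @param mde_lattice MDE array on the simulation lattice.
#' @param rates Vector (length >= 2) of peak count rates in counts/s.
#' @return data.frame with `rate`, `mean_rate`, `rms_residual`, `N`,
#'   `tau_D_s`.
#' @export
snr_vs_brightness <- function(cfg, mde_lattice, rates) {
  stopifnot(length(rates) >= 2)
  if (any(rates <= 0)) stop("rates must be positive (zero rate is degenerate)")
  rows <- lapply(rates, function(r) {
    tr <- fcs_experiment(cfg, mde_lattice, r)
    curve <- autocorrelate(tr)
    fit <- fit_3d_diffusion(curve)
    data.frame(rate = r, mean_rate = tr$mean_rate,
               rms_residual = sqrt(mean((curve$G - fit$fitted)^2)),
               N = fit$N, tau_D_s = fit$tau_D_s)
  })
  do.call(rbind, rows)
}

#' Write trace / correlation / fit artifacts
#'
#' Traces as CSV (`time_s`, `counts`), correlation curves as CSV (`lag_s`,
#' `G`, `se`), fits as JSON.
#'
#' @param trace An `intensity_trace`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(
    time_s = (seq_along(trace$counts) - 1) * trace$bin_time_s,
    counts = trace$counts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param curve A `correlation_curve`.
#' @export
write_correlation_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param fit An `fcs_fit`.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(N = fit$N, tau_D_s = fit$tau_D_s,
                            s_ratio = fit$s_ratio, G_inf = fit$G_inf,
                            covariance = fit$covariance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
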