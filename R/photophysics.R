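# Molecule detection efficiency under epi-fluorescence: spectrum-weighted
# collection efficiency, MDE maps, effective detection volume and the
# per-molecule photon budget of the two-level emission model.

#' Fluorophore photophysics
#'
#' Absorption and emission spectra with quantum yield and fluorescence
#' lifetime. Spectra are data.frames with columns `wavelength_nm` and
#' `intensity` (relative, >= 0); the emission peak must lie red of the
#' absorption peak (positive Stokes shift).
#'
#' @param name Dye label.
#' @param absorption,emission Spectrum data.frames.
#' @param quantum_yield psi in (0, 1].
#' @param lifetime_ns Fluorescence lifetime tau_fl in ns.
#' @return An object of class `fluorophore_spec` with derived `k_fl` (1/s).
#' @export
fluorophore_spec <- function(name, absorption, emission, quantum_yield,
                             lifetime_ns) {
  stopifnot(all(absorption$intensity >= 0), all(emission$intensity >= 0),
            quantum_yield > 0, quantum_yield <= 1, lifetime_ns > 0)
  pk_abs <- absorption$wavelength_nm[which.max(absorption$intensity)]
  pk_em <- emission$wavelength_nm[which.max(emission$intensity)]
  if (pk_em <= pk_abs) stop("emission peak must be red-shifted (Stokes shift > 0)")
  structure(list(name = name, absorption = absorption, emission = emission,
                 quantum_yield = quantum_yield, lifetime_ns = lifetime_ns,
                 k_fl = 1 / (lifetime_ns * 1e-9),
                 peak_abs_nm = pk_abs, peak_em_nm = pk_em),
            class = "fluorophore_spec")
}

#' Read a fluorophore from CSV
#'
#' CSV columns `wavelength_nm`, `absorbance`, `emission` (either of the last
#' two may be blank per row); quantum yield and lifetime are passed as
#' arguments (sidecar metadata).
#'
#' @param path CSV path.
#' @param quantum_yield,lifetime_ns Photophysical constants.
#' @param name Dye label (defaults to the file name).
#' @return A [fluorophore_spec()].
#' @export
read_fluorophore_csv <- function(path, quantum_yield, lifetime_ns,
                                 name = basename(path)) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("wavelength_nm", "absorbance", "emission") %in% names(tab)))
  ab <- tab[!is.na(tab$absorbance), c("wavelength_nm", "absorbance")]
  em <- tab[!is.na(tab$emission), c("wavelength_nm", "emission")]
  names(ab)[2] <- "intensity"; names(em)[2] <- "intensity"
  fluorophore_spec(name, ab, em, quantum_yield, lifetime_ns)
}

#' Detection band
#'
#' Wavelength samples over which detection PSFs are averaged, centered on
#' the detection wavelength (typically the design emission wavelength).
#'
#' @param center_nm Band center in nm.
#' @param half_width_nm Half width (default 20 nm).
#' @param n_samples Number of wavelength samples (default 5).
#' @return List with `lambda_nm` sample vector.
#' @export
detection_band <- function(center_nm, half_width_nm = 20, n_samples = 5) {
  stopifnot(half_width_nm > 0, n_samples >= 1)
  lam <- if (n_samples == 1) center_nm else
    seq(center_nm - half_width_nm, center_nm + half_width_nm,
        length.out = n_samples)
  list(center_nm = center_nm, half_width_nm = half_width_nm, lambda_nm = lam)
}

# Linear interpolation of a spectrum at given wavelengths (0 outside).
spectrum_at <- function(spectrum, lambda_nm) {
  stats::approx(spectrum$wavelength_nm, spectrum$intensity, xout = lambda_nm,
                yleft = 0, yright = 0)$y
}

#' Collection efficiency function (CEF)
#'
#' Spectrum-weighted average of the normalized detection PSFs over the
#' detection band, scaled by P_max:
#'   CEF = P_max * int F(lambda) I_det(lambda) dlambda / int F(lambda) dlambda
#' with trapezoidal quadrature over the sampled wavelengths. P_max is the
#' peak fraction of an isotropic emitter's photons coupled back into the
#' waveguide; a single TE0 mode bounds it at 1/3.
#'
#' @param det_psfs Named list of `psf_volume`s; names are wavelengths in nm.
#' @param emission Emission spectrum data.frame (`wavelength_nm`, `intensity`),
#'   or a `fluorophore_spec` whose emission spectrum is used.
#' @param p_max Peak collection fraction, in (0, 1/3].
#' @return A `cef_grid`: array on the PSF grid with attributes.
#' @export
collection_efficiency <- function(det_psfs, emission, p_max) {
  if (inherits(emission, "fluorophore_spec")) emission <- emission$emission
  if (!length(det_psfs)) stop("empty detection band: no detection PSFs")
  if (!(p_max > 0 && p_max <= 1 / 3))
    stop("P_max must lie in (0, 1/3]: a single TE0 mode collects at most 1/3")
  lam <- as.numeric(names(det_psfs))
  stopifnot(!any(is.na(lam)))
  ord <- order(lam); lam <- lam[ord]; det_psfs <- det_psfs[ord]
  Fw <- spectrum_at(emission, lam)
  if (max(Fw) < 1e-9)
    stop("detection band lies outside the emission spectrum support")
  # trapezoid weights (single sample collapses to the plain value)
  tw <- if (length(lam) == 1) 1 else {
    d <- diff(lam)
    c(d[1] / 2, (d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
  }
  w <- tw * Fw
  acc <- 0
  for (i in seq_along(det_psfs)) {
    v <- det_psfs[[i]]
    stopifnot(inherits(v, "psf_volume"))
    if (i > 1 && !isTRUE(all.equal(dim(v$intensity), dim0)))
      stop("detection PSF grids do not match")
    dim0 <- dim(v$intensity)
    acc <- acc + w[i] * v$intensity
  }
  cef <- p_max * acc / sum(w)
  structure(cef, class = "cef_grid", p_max = p_max, lambda_nm = lam,
            x_nm = det_psfs[[1]]$x_nm, y_nm = det_psfs[[1]]$y_nm,
            z_um = det_psfs[[1]]$z_um)
}

#' Molecule detection efficiency map
#'
#' MDE(x, y, z) = I_exc(x, y, z) * CEF(x, y, z), the pointwise product of
#' the normalized excitation PSF and the collection efficiency function.
#'
#' @param i_exc Excitation `psf_volume` (normalized, peak 1).
#' @param cef A `cef_grid` from [collection_efficiency()] on the same grid.
#' @return An object of class `mde_map`: `mde` array, axes, `peak_mde`
#'   (fraction) and `peak_mde_percent`.
#' @export
mde_map <- function(i_exc, cef) {
  stopifnot(inherits(i_exc, "psf_volume"), inherits(cef, "cef_grid"))
  if (!isTRUE(all.equal(dim(i_exc$intensity), dim(unclass(cef)))))
    stop("excitation PSF and CEF grids do not match")
  m <- array(as.numeric(i_exc$intensity) * as.numeric(unclass(cef)),
             dim = dim(i_exc$intensity))
  structure(list(mde = m, x_nm = i_exc$x_nm, y_nm = i_exc$y_nm,
                 z_um = i_exc$z_um, peak_mde = max(m),
                 peak_mde_percent = 100 * max(m),
                 p_max = attr(cef, "p_max")),
            class = "mde_map")
}

# 1/e^2 radius of a profile through its peak by least-squares Gaussian fit
# I = A exp(-2 (u - u0)^2 / w^2), restricted to the contiguous region around
# the peak above `floor_frac` of the peak (excludes sidelobes).
fit_e2_radius <- function(coord, profile, floor_frac = 0.01) {
  ip <- which.max(profile)
  above <- profile >= floor_frac * profile[ip]
  lo <- ip; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- ip; while (hi < length(profile) && above[hi + 1]) hi <- hi + 1
  u <- coord[lo:hi]; p <- profile[lo:hi]
  w0 <- profile_fwhm(coord, profile) / sqrt(2 * log(2))
  if (is.na(w0)) stop("cannot fit 1/e^2 radius: profile has no half crossings")
  # plain Levenberg-Marquardt on the residuals (robust to the exact-fit
  # case, where a wrapped nls object would reject the zero residual)
  fit <- minpack.lm::nls.lm(
    par = list(A = profile[ip], u0 = coord[ip], w = w0),
    fn = function(par) par$A * exp(-2 * (u - par$u0)^2 / par$w^2) - p,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 9)) stop("1/e^2 radius fit did not converge")
  abs(fit$par$w)
}

#' Effective detection volume
#'
#' `method = "gaussian_fit"` (the headline definition) fits 1/e^2 radii to
#' the MDE profiles through the peak -- lateral w_xy as the mean of the x
#' and y fits, axial w_z along z -- and reports
#'   V_eff = pi^(3/2) * w_xy^2 * w_z  (in femtoliters; 1 um^3 = 1 fl).
#' `method = "integral"` reports (sum MDE)^2 / sum(MDE^2) * dV instead. On a
#' Gaussian-fit failure the integral value is returned with a warning.
#'
#' @param mde An `mde_map`.
#' @param method `"gaussian_fit"` (default) or `"integral"`.
#' @return List with `v_eff_fl`, `w_xy_um`, `w_z_um` (NA for integral
#'   method), and `method`.
#' @export
effective_volume <- function(mde, method = c("gaussian_fit", "integral")) {
  method <- match.arg(method)
  stopifnot(inherits(mde, "mde_map"))
  m <- mde$mde
  pk <- arrayInd(which.max(m), dim(m))
  if (any(pk == 1) || any(pk == dim(m)))
    stop("MDE peak must be interior to the grid")
  dx <- (mde$x_nm[2] - mde$x_nm[1]) / 1000
  dz <- (mde$z_um[2] - mde$z_um[1])
  if (method == "integral") {
    v <- (sum(m))^2 / sum(m^2) * dx * dx * dz
    return(list(v_eff_fl = v, w_xy_um = NA_real_, w_z_um = NA_real_,
                method = method))
  }
  res <- try({
    wx <- fit_e2_radius(mde$x_nm / 1000, m[, pk[2], pk[3]])
    wy <- fit_e2_radius(mde$y_nm / 1000, m[pk[1], , pk[3]])
    wz <- fit_e2_radius(mde$z_um, m[pk[1], pk[2], ])
    w_xy <- (wx + wy) / 2
    list(v_eff_fl = pi^1.5 * w_xy^2 * wz, w_xy_um = w_xy, w_z_um = wz,
         method = "gaussian_fit")
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    warning("Gaussian fit failed; falling back to the integral estimator")
    return(effective_volume(mde, "integral"))
  }
  res
}

#' Steady-state excited singlet population
#'
#' S1_bar = k_ex / (k_fl + k_ex) of the two-level emission model at low
#' excitation intensity; bounded in (0, 1) and increasing in k_ex.
#'
#' @param k_ex Excitation rate constant (1/s).
#' @param k_fl Fluorescence rate constant (1/s).
#' @return The dimensionless population.
#' @export
excited_state_population <- function(k_ex, k_fl) {
  stopifnot(k_ex > 0, k_fl > 0)
  k_ex / (k_fl + k_ex)
}

#' Per-molecule photon count rate
#'
#' N_F = MDE * psi * S1_bar * k_fl: detected photons per second from one
#' molecule at the MDE peak, in the absence of photobleaching.
#'
#' @param mde_peak Peak molecule detection efficiency (fraction, in (0, 1)).
#' @param fluor A [fluorophore_spec()] providing psi and k_fl.
#' @param k_ex Excitation rate constant (1/s).
#' @return Counts per second.
#' @export
count_rate <- function(mde_peak, fluor, k_ex) {
  stopifnot(mde_peak > 0, mde_peak < 1, inherits(fluor, "fluorophore_spec"))
  s1 <- excited_state_population(k_ex, fluor$k_fl)
  mde_peak * fluor$quantum_yield * s1 * fluor$k_fl
}
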