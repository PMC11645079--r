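# Scalar angular-spectrum propagation: aperture synthesis from the atom
# layout, two-layer SOG/water propagation, PSF volumes and their metrics.

#' Complex scalar field on a transverse grid
#'
#' @param values Complex matrix (x along rows, y along columns).
#' @param dx_nm Sample spacing in nm (same in x and y).
#' @param lambda_nm Vacuum wavelength in nm.
#' @param n_medium Refractive index of the propagation medium.
#' @param z_um Plane height above the metalens in um.
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(values, dx_nm, lambda_nm, n_medium, z_um = 0) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  n <- nrow(values)
  ax <- (seq_len(n) - 1 - floor(n / 2)) * dx_nm
  structure(list(values = values, dx_nm = dx_nm, x_nm = ax, y_nm = ax,
                 lambda_nm = lambda_nm, n_medium = n_medium, z_um = z_um),
            class = "scalar_field")
}

# FFT spatial frequencies (rad/nm) for an n-point grid with spacing dx.
k_grid <- function(n, dx_nm) {
  f <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * dx_nm)
  2 * pi * f
}

#' Synthesize the outcoupled aperture field of a design
#'
#' Every meta-atom (both segment families) radiates a Gaussian blob of 1/e
#' radius equal to the atom radius, carrying the local accumulated waveguide
#' phase phi_wg(x_j, y_j) evaluated at the requested wavelength (not the
#' atom's design wavelength). Atom amplitudes are uniform by default; an
#' exponential depletion exp(-gamma * (x + D/2)) along the propagation
#' direction is available.
#'
#' @param design A [metalens_design()].
#' @param lambda_nm Working wavelength in nm.
#' @param dx_nm Grid spacing (default 50 nm).
#' @param extent_um Grid extent (default 30 um, at least 1.5 D).
#' @param r0_nm Blob 1/e radius (default half the atom diameter).
#' @param gamma_per_nm Depletion constant gamma (default 0, uniform).
#' @return A [scalar_field()] at z = 0 in the SOG cladding.
#' @export
synthesize_aperture_field <- function(design, lambda_nm, dx_nm = 50,
                                      extent_um = 30, r0_nm = NULL,
                                      gamma_per_nm = 0) {
  stopifnot(inherits(design, "metalens_design"))
  if (extent_um < 1.5 * design$lens$D_um)
    stop("grid extent must be at least 1.5x the lens size")
  n <- round(extent_um * 1000 / dx_nm)
  n_sog <- refractive_index(design$waveguide$cladding, lambda_nm)
  if (dx_nm > lambda_nm / (4 * n_sog))
    stop("grid spacing too coarse: must be <= lambda / (4 n_medium)")
  U <- matrix(0 + 0i, n, n)
  fld <- scalar_field(U, dx_nm, lambda_nm, n_sog, z_um = 0)
  atoms <- design$atoms
  if (!nrow(atoms)) return(fld)
  if (is.null(r0_nm)) r0_nm <- atoms$diameter_nm[1] / 2
  beta <- design$beta_fun(lambda_nm)
  phase <- waveguide_phase(atoms$x_nm, atoms$y_nm, beta, design$ipm)
  amp <- exp(-gamma_per_nm * (atoms$x_nm + design$lens$D_um * 1000 / 2))
  ax <- fld$x_nm
  halfw <- ceiling(3 * r0_nm / dx_nm)
  for (j in seq_len(nrow(atoms))) {
    ix <- round(atoms$x_nm[j] / dx_nm) + floor(n / 2) + 1
    iy <- round(atoms$y_nm[j] / dx_nm) + floor(n / 2) + 1
    xi <- max(1, ix - halfw):min(n, ix + halfw)
    yi <- max(1, iy - halfw):min(n, iy + halfw)
    gx <- exp(-((ax[xi] - atoms$x_nm[j]) / r0_nm)^2)
    gy <- exp(-((ax[yi] - atoms$y_nm[j]) / r0_nm)^2)
    U[xi, yi] <- U[xi, yi] + (amp[j] * exp(1i * phase[j])) * outer(gx, gy)
  }
  fld$values <- U
  fld
}

#' Angular-spectrum propagation over a homogeneous slab
#'
#' Exact scalar transfer-function propagation: each plane-wave component is
#' multiplied by exp(i kz dz) with kz = sqrt((n k0)^2 - kx^2 - ky^2);
#' evanescent components (kz imaginary) decay and are never amplified.
#' Energy is conserved exactly for purely propagating fields.
#'
#' @param field A [scalar_field()].
#' @param dz_um Propagation distance in um (>= 0).
#' @return The propagated `scalar_field`.
#' @export
angular_spectrum_propagate <- function(field, dz_um) {
  stopifnot(inherits(field, "scalar_field"), dz_um >= 0)
  if (field$dx_nm > field$lambda_nm / (4 * field$n_medium))
    stop("grid spacing too coarse: must be <= lambda / (4 n_medium)")
  if (dz_um == 0) return(field)
  n <- nrow(field$values)
  k <- 2 * pi * field$n_medium / field$lambda_nm
  kt <- k_grid(n, field$dx_nm)
  kz <- sqrt(as.complex(outer(k^2 - kt^2, kt^2, `-`)))
  H <- exp(1i * kz * (dz_um * 1000))
  field$values <- stats::fft(stats::fft(field$values) * H, inverse = TRUE) / n^2
  field$z_um <- field$z_um + dz_um
  field
}

#' Propagate through the SOG/water stack into a PSF volume
#'
#' Starting from the aperture field at z = 0 (inside the SOG cladding), each
#' requested plane is reached by multiplying the aperture's angular spectrum
#' with the combined SOG (up to `h_SOG_um`) and water transfer functions --
#' the planar interface enters only through the change of medium index (no
#' Fresnel amplitude factors). The |U|^2 stack is cropped laterally to
#' `crop_um` and normalized to unit peak.
#'
#' @param field Aperture [scalar_field()] at z = 0.
#' @param h_SOG_um SOG thickness (default 2).
#' @param z_min_um,z_max_um,z_step_nm Axial sampling (defaults 5, 9, 25).
#' @param crop_um Lateral extent kept in the stored volume (default 12).
#' @param sog,water Dispersion tables for the two media.
#' @return An object of class `psf_volume`: normalized intensity array
#'   `[x, y, z]`, axes, wavelength, the raw peak intensity and the aperture
#'   power (for encircled-fraction metrics).
#' @export
propagate_stack <- function(field, h_SOG_um = 2, z_min_um = 5, z_max_um = 9,
                            z_step_nm = 25, crop_um = 12,
                            sog = material_table("SOG"),
                            water = material_table("water")) {
  stopifnot(inherits(field, "scalar_field"), z_max_um > h_SOG_um,
            z_max_um > z_min_um)
  n <- nrow(field$values)
  lam <- field$lambda_nm
  n_s <- refractive_index(sog, lam)
  n_w <- refractive_index(water, lam)
  if (field$dx_nm > lam / (4 * max(n_s, n_w)))
    stop("grid spacing too coarse: must be <= lambda / (4 n_medium)")
  kt2 <- outer(k_grid(n, field$dx_nm)^2, k_grid(n, field$dx_nm)^2, `+`)
  kz_s <- sqrt(as.complex((2 * pi * n_s / lam)^2 - kt2))
  kz_w <- sqrt(as.complex((2 * pi * n_w / lam)^2 - kt2))
  F0 <- stats::fft(field$values)
  zs <- seq(z_min_um, z_max_um, by = z_step_nm / 1000)
  keep <- which(abs(field$x_nm) <= crop_um * 1000 / 2)
  vol <- array(0, dim = c(length(keep), length(keep), length(zs)))
  for (i in seq_along(zs)) {
    z_nm <- zs[i] * 1000
    d_s <- min(z_nm, h_SOG_um * 1000)
    d_w <- max(z_nm - h_SOG_um * 1000, 0)
    U <- stats::fft(F0 * exp(1i * (kz_s * d_s + kz_w * d_w)),
                    inverse = TRUE) / n^2
    vol[, , i] <- abs(U[keep, keep])^2
  }
  peak <- max(vol)
  structure(list(intensity = vol / peak,
                 x_nm = field$x_nm[keep], y_nm = field$y_nm[keep],
                 z_um = zs, lambda_nm = lam, peak_raw = peak,
                 aperture_power = sum(abs(field$values)^2) * field$dx_nm^2,
                 h_SOG_um = h_SOG_um),
            class = "psf_volume")
}

# FWHM of a sampled profile around its peak by linear interpolation of the
# half-maximum crossings; coords and profile are equal-length vectors.
profile_fwhm <- function(coord, profile) {
  ip <- which.max(profile)
  half <- profile[ip] / 2
  if (ip == 1 || ip == length(profile)) return(NA_real_)
  li <- which(profile[1:ip] < half)
  ri <- which(profile[ip:length(profile)] < half)
  if (!length(li) || !length(ri)) return(NA_real_)
  l2 <- max(li); r1 <- ip + min(ri) - 1
  xl <- coord[l2] + (half - profile[l2]) / (profile[l2 + 1] - profile[l2]) *
    (coord[l2 + 1] - coord[l2])
  xr <- coord[r1 - 1] + (half - profile[r1 - 1]) / (profile[r1] - profile[r1 - 1]) *
    (coord[r1] - coord[r1 - 1])
  xr - xl
}

# Parabolic interpolation of an extremum position from three samples.
parabolic_vertex <- function(x, y) {
  denom <- (y[1] - 2 * y[2] + y[3])
  if (abs(denom) < .Machine$double.eps) return(x[2])
  x[2] + 0.5 * (y[1] - y[3]) / denom * (x[3] - x[2])
}

#' Focal-spot metrics of a PSF volume
#'
#' Locates the focal plane as the z of the in-plane intensity maximum
#' (parabolically interpolated), then measures the lateral FWHM along x and
#' y through the peak, the axial FWHM of the on-peak z profile, and the
#' encircled fraction: the fraction of the aperture power contained within a
#' radius of `radius_factor` times the mean lateral FWHM at the focal plane.
#'
#' @param vol A `psf_volume`.
#' @param radius_factor Encircled-energy radius in FWHM units (default 3).
#' @return List with `fwhm_x_nm`, `fwhm_y_nm`, `z_focus_um`, `axial_fwhm_nm`,
#'   `encircled_fraction`, `peak_x_nm`, `peak_y_nm`.
#' @export
psf_metrics <- function(vol, radius_factor = 3) {
  stopifnot(inherits(vol, "psf_volume"))
  plane_max <- apply(vol$intensity, 3, max)
  iz <- which.max(plane_max)
  if (iz == 1 || iz == length(vol$z_um)) {
    cond <- structure(class = c("focus_not_contained", "error", "condition"),
                      list(message = "intensity maximum on the volume z boundary",
                           call = sys.call()))
    stop(cond)
  }
  z_focus <- parabolic_vertex(vol$z_um[(iz - 1):(iz + 1)],
                              plane_max[(iz - 1):(iz + 1)])
  plane <- vol$intensity[, , iz]
  pk <- arrayInd(which.max(plane), dim(plane))
  ix <- pk[1]; iy <- pk[2]
  fwhm_x <- profile_fwhm(vol$x_nm, plane[, iy])
  fwhm_y <- profile_fwhm(vol$y_nm, plane[ix, ])
  axial <- profile_fwhm(vol$z_um * 1000, vol$intensity[ix, iy, ])
  rad <- radius_factor * mean(c(fwhm_x, fwhm_y), na.rm = TRUE)
  r2 <- outer((vol$x_nm - vol$x_nm[ix])^2, (vol$y_nm - vol$y_nm[iy])^2, `+`)
  dx <- vol$x_nm[2] - vol$x_nm[1]
  enc <- sum(plane[r2 <= rad^2]) * vol$peak_raw * dx^2 / vol$aperture_power
  list(fwhm_x_nm = fwhm_x, fwhm_y_nm = fwhm_y, z_focus_um = z_focus,
       axial_fwhm_nm = axial, encircled_fraction = enc,
       peak_x_nm = vol$x_nm[ix], peak_y_nm = vol$y_nm[iy])
}

#' Focal overlap of two PSF volumes
#'
#' Reports the axial focal mismatch |dz| (parabolically interpolated), the
#' lateral offset between the focal-lobe intensity centroids (computed over
#' samples above `lobe_threshold` of each focal plane's maximum, so the
#' centroid tracks the dominant lobe wherever it forms), and the normalized
#' volume-overlap integral sum(min(I1, I2)) / sum(max(I1, I2)) over the
#' region within +-1 um of the mean focal plane.
#'
#' @param vol1,vol2 `psf_volume` objects on identical grids.
#' @param lobe_threshold Relative intensity cut defining the focal lobe
#'   (default 0.5, the half-maximum contour).
#' @return List with `delta_z_nm`, `delta_r_nm`, `overlap`.
#' @export
focal_overlap <- function(vol1, vol2, lobe_threshold = 0.5) {
  stopifnot(inherits(vol1, "psf_volume"), inherits(vol2, "psf_volume"))
  if (!isTRUE(all.equal(vol1$x_nm, vol2$x_nm)) ||
      !isTRUE(all.equal(vol1$z_um, vol2$z_um)))
    stop("PSF volumes are on different grids")
  m1 <- psf_metrics(vol1); m2 <- psf_metrics(vol2)
  cent <- function(vol) {
    iz <- which.max(apply(vol$intensity, 3, max))
    plane <- vol$intensity[, , iz]
    w <- plane * (plane >= lobe_threshold * max(plane))
    c(sum(outer(vol$x_nm, rep(1, length(vol$y_nm))) * w),
      sum(outer(rep(1, length(vol$x_nm)), vol$y_nm) * w)) / sum(w)
  }
  c1 <- cent(vol1); c2 <- cent(vol2)
  zbar <- (m1$z_focus_um + m2$z_focus_um) / 2
  sel <- abs(vol1$z_um - zbar) <= 1
  i1 <- vol1$intensity[, , sel]; i2 <- vol2$intensity[, , sel]
  list(delta_z_nm = abs(m1$z_focus_um - m2$z_focus_um) * 1000,
       delta_r_nm = sqrt(sum((c1 - c2)^2)),
       overlap = sum(pmin(i1, i2)) / sum(pmax(i1, i2)))
}

#' Save / load a PSF volume
#'
#' Volumes are persisted with R's native serialization (`.rds`), keeping the
#' intensity array, axes and attributes intact.
#'
#' @param vol A `psf_volume` (or `mde_map`).
#' @param path Output path.
#' @return `save_volume()` the path invisibly; `load_volume()` the object.
#' @export
save_volume <- function(vol, path) {
  saveRDS(vol, path)
  invisible(path)
}

#' @rdname save_volume
#' @export
load_volume <- function(path) readRDS(path)
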