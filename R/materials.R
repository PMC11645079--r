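# Refractive-index dispersion, slab modes, V parameter, grating relation and
# taper geometry for the silicon nitride / silica-on-glass / water stack.

#' Material dispersion table
#'
#' A tabulated refractive index n(lambda) with linear interpolation between
#' grid points. Tables must cover at least 450--800 nm so that all design and
#' detection wavelengths of the visible/NIR dyes are interpolable.
#'
#' @param name Label for the material.
#' @param wavelength_nm Strictly increasing wavelength grid in nm.
#' @param n Refractive index values (all >= 1), same length as the grid.
#' @return An object of class `material_dispersion`.
#' @export
material_dispersion <- function(name, wavelength_nm, n) {
  stopifnot(length(wavelength_nm) == length(n), length(n) >= 2)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(n < 1))
    stop("refractive index values must all be >= 1")
  if (wavelength_nm[1] > 450 || wavelength_nm[length(wavelength_nm)] < 800)
    stop("dispersion table must cover at least 450-800 nm")
  structure(list(name = name, wavelength_nm = wavelength_nm, n = n),
            class = "material_dispersion")
}

# Sellmeier fits used to build the packaged tables (lambda in micrometres).
# SiN: H. R. Philipp's silicon nitride data (single-oscillator fit).
.n_sin_philipp <- function(lambda_um) {
  sqrt(1 + 2.8939 * lambda_um^2 / (lambda_um^2 - 0.13967^2))
}
# Fused silica: Malitson three-term Sellmeier (used for the SOG cladding).
.n_silica_malitson <- function(lambda_um) {
  l2 <- lambda_um^2
  sqrt(1 + 0.6961663 * l2 / (l2 - 0.0684043^2) +
         0.4079426 * l2 / (l2 - 0.1162414^2) +
         0.8974794 * l2 / (l2 - 9.896161^2))
}
# Water at 20 C: Daimon & Masumura four-term Sellmeier.
.n_water_daimon <- function(lambda_um) {
  l2 <- lambda_um^2
  sqrt(1 + 5.684027565e-1 * l2 / (l2 - 5.101829712e-3) +
         1.726177391e-1 * l2 / (l2 - 1.821153936e-2) +
         2.086189578e-2 * l2 / (l2 - 2.620722293e-2) +
         1.130748688e-1 * l2 / (l2 - 1.069792721e1))
}

#' Packaged dispersion tables
#'
#' Returns one of the packaged materials as a [material_dispersion] table
#' sampled on a 1 nm grid over 400--900 nm: `"SiN"` (silicon nitride core),
#' `"SOG"` (silica-on-glass cladding, fused-silica dispersion), `"water"`
#' (sample medium, 20 C), or `"vacuum"` (n identically 1, for tests).
#'
#' @param name One of `"SiN"`, `"SOG"`, `"water"`, `"vacuum"`.
#' @return A `material_dispersion` object.
#' @export
material_table <- function(name = c("SiN", "SOG", "water", "vacuum")) {
  name <- match.arg(name)
  wl <- seq(400, 900, by = 1)
  n <- switch(name,
    SiN    = .n_sin_philipp(wl / 1000),
    SOG    = .n_silica_malitson(wl / 1000),
    water  = .n_water_daimon(wl / 1000),
    vacuum = rep(1, length(wl)))
  material_dispersion(name, wl, n)
}

#' Read a dispersion table from CSV
#'
#' Two-column CSV with header `wavelength_nm,n`.
#'
#' @param path Path to the CSV file.
#' @param name Optional material label (defaults to the file name).
#' @return A `material_dispersion` object.
#' @export
read_material_csv <- function(path, name = basename(path)) {
  tab <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "n") %in% names(tab)))
    stop("material CSV must have columns 'wavelength_nm' and 'n'")
  material_dispersion(name, tab$wavelength_nm, tab$n)
}

#' Interpolated refractive index
#'
#' Linear interpolation of a dispersion table; refuses to extrapolate.
#'
#' @param material A [material_dispersion] object.
#' @param lambda_nm Wavelength(s) in nm, inside the table's grid.
#' @return Refractive index value(s).
#' @export
refractive_index <- function(material, lambda_nm) {
  stopifnot(inherits(material, "material_dispersion"))
  rng <- range(material$wavelength_nm)
  if (any(lambda_nm < rng[1] | lambda_nm > rng[2]))
    stop(sprintf("wavelength outside dispersion table of '%s' (%g-%g nm)",
                 material$name, rng[1], rng[2]))
  stats::approx(material$wavelength_nm, material$n, xout = lambda_nm)$y
}

#' TE0/TM0 effective index of an asymmetric slab waveguide
#'
#' Solves the transcendental dispersion equation of a three-layer dielectric
#' slab for the fundamental guided mode by bracketed root finding,
#'   kappa*d = atan(q_sub * gamma_sub / kappa) + atan(q_clad * gamma_clad / kappa),
#' with q = 1 for TE and q = (n_core/n_x)^2 for TM. Returns the effective
#' index, or signals a cutoff condition (class `slab_cutoff`) when no guided
#' fundamental mode exists -- distinct from a numerical failure.
#'
#' @param lambda_nm Wavelength in nm.
#' @param thickness_nm Core thickness in nm.
#' @param n_core Core index (must exceed both claddings).
#' @param n_sub,n_clad Substrate and cladding indices.
#' @param mode `"TE"` (default) or `"TM"`.
#' @param tol Root tolerance on the effective index (default 1e-9).
#' @return Effective index n_eff with `n_max_clad < n_eff < n_core`.
#' @export
slab_effective_index <- function(lambda_nm, thickness_nm, n_core, n_sub, n_clad,
                                 mode = c("TE", "TM"), tol = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(thickness_nm > 0, lambda_nm > 0)
  if (n_core <= max(n_sub, n_clad))
    stop("slab requires n_core > max(n_sub, n_clad)")
  k0 <- 2 * pi / lambda_nm
  f <- slab_dispersion_fn(k0, thickness_nm, n_core, n_sub, n_clad, mode)
  lo <- max(n_sub, n_clad) * (1 + 1e-12) + 1e-12
  hi <- n_core * (1 - 1e-12) - 1e-12
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo <= 0) {
    cond <- structure(class = c("slab_cutoff", "error", "condition"),
                      list(message = sprintf(
                        "no guided fundamental %s mode at %g nm (below cutoff)",
                        mode, lambda_nm), call = sys.call()))
    stop(cond)
  }
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

# Phase-mismatch function for the fundamental (m = 0) slab mode; positive at
# the lower bracket when the mode is guided, negative near n_core.
slab_dispersion_fn <- function(k0, d, n_core, n_sub, n_clad, mode) {
  qs <- if (mode == "TM") (n_core / n_sub)^2 else 1
  qc <- if (mode == "TM") (n_core / n_clad)^2 else 1
  function(neff) {
    kap <- k0 * sqrt(pmax(n_core^2 - neff^2, 0))
    gs <- k0 * sqrt(pmax(neff^2 - n_sub^2, 0))
    gc <- k0 * sqrt(pmax(neff^2 - n_clad^2, 0))
    kap * d - atan2(qs * gs, kap) - atan2(qc * gc, kap)
  }
}

#' Waveguide geometry and materials
#'
#' Container for the planar waveguide and taper geometry: narrow width `w1`,
#' wide width `w2`, layer thickness `w_h` (all nm), taper length and exponent,
#' SOG top-cladding thickness, and the three material dispersion tables.
#' Defaults follow the designed device: a 600 nm wide, 100 nm thick SiN core
#' tapering to 20 um over 40 um with exponent 1.15 under 2 um of SOG.
#'
#' @param w1_nm Narrow-section width (default 600).
#' @param w2_nm Wide-section width (default 20000).
#' @param w_h_nm SiN layer thickness (default 100).
#' @param L_taper_um Taper length in um (default 40).
#' @param m Taper shape exponent (default 1.15).
#' @param h_SOG_um Upper cladding thickness in um (default 2).
#' @param core,substrate,cladding Dispersion tables (`material_dispersion`).
#' @return An object of class `waveguide_spec`.
#' @export
waveguide_spec <- function(w1_nm = 600, w2_nm = 20000, w_h_nm = 100,
                           L_taper_um = 40, m = 1.15, h_SOG_um = 2,
                           core = material_table("SiN"),
                           substrate = material_table("SOG"),
                           cladding = material_table("SOG")) {
  stopifnot(w1_nm < w2_nm, w_h_nm > 0, m > 0, h_SOG_um >= 0, L_taper_um > 0)
  structure(list(w1_nm = w1_nm, w2_nm = w2_nm, w_h_nm = w_h_nm,
                 L_taper_um = L_taper_um, m = m, h_SOG_um = h_SOG_um,
                 core = core, substrate = substrate, cladding = cladding),
            class = "waveguide_spec")
}

#' Single-mode V parameter of the narrow waveguide section
#'
#' V = (2 pi / lambda) * w * sqrt(n_wg^2 - n_clad^2) with the width taken as
#' the geometric mean w = sqrt(w1 * w_h) of the narrow rectangular section,
#' and n_wg by default the TE0 effective index of the thin SiN slab clad in
#' SOG (`n_wg = "effective"`); `n_wg = "material"` uses the bulk core index
#' instead. Values below ~2.4 indicate single-mode guidance.
#'
#' @param lambda_nm Wavelength in nm.
#' @param spec A [waveguide_spec].
#' @param n_wg `"effective"` (default) or `"material"`.
#' @return The dimensionless V value.
#' @export
v_parameter <- function(lambda_nm, spec, n_wg = c("effective", "material")) {
  n_wg <- match.arg(n_wg)
  stopifnot(inherits(spec, "waveguide_spec"), lambda_nm > 0)
  nc <- refractive_index(spec$core, lambda_nm)
  ncl <- refractive_index(spec$cladding, lambda_nm)
  nw <- switch(n_wg,
    material = nc,
    effective = slab_effective_index(lambda_nm, spec$w_h_nm, nc,
                                     refractive_index(spec$substrate, lambda_nm),
                                     ncl))
  w <- sqrt(spec$w1_nm * spec$w_h_nm)
  (2 * pi / lambda_nm) * w * sqrt(max(nw^2 - ncl^2, 0))
}

#' Outcoupling grating model
#'
#' Holds the grating period, the top-cladding index and one consistent pair
#' of (beta, theta) tied by the first-order grating relation
#' beta = (2 pi n_top / lambda) sin(theta) + 2 pi / Lambda.
#'
#' @param period_nm Grating period Lambda in nm (default 365).
#' @param n_top Top-cladding refractive index at the working wavelength.
#' @return An object of class `grating_model`.
#' @export
grating_model <- function(period_nm = 365, n_top) {
  stopifnot(period_nm > 0, n_top >= 1)
  structure(list(period_nm = period_nm, n_top = n_top), class = "grating_model")
}

#' Propagation constant from the outcoupling angle
#'
#' beta(lambda) = (2 pi n_top / lambda) sin(theta) + 2 pi / Lambda.
#'
#' @param lambda_nm Wavelength in nm.
#' @param grating A [grating_model].
#' @param theta_rad Far-field outcoupling angle in radians.
#' @return beta in rad/nm.
#' @seealso [outcoupling_angle()] for the inverse.
#' @export
propagation_constant <- function(lambda_nm, grating, theta_rad) {
  stopifnot(inherits(grating, "grating_model"))
  if (abs(sin(theta_rad)) > 1) stop("invalid angle")
  2 * pi * grating$n_top * sin(theta_rad) / lambda_nm + 2 * pi / grating$period_nm
}

#' Outcoupling angle from the propagation constant
#'
#' Inverse of [propagation_constant()]:
#' sin(theta) = (beta - 2 pi / Lambda) * lambda / (2 pi n_top). An
#' `evanescent_order` error is raised when |sin(theta)| > 1 (no radiating
#' first diffraction order).
#'
#' @param beta Propagation constant in rad/nm.
#' @param lambda_nm Wavelength in nm.
#' @param grating A [grating_model].
#' @return theta in radians.
#' @export
outcoupling_angle <- function(beta, lambda_nm, grating) {
  stopifnot(inherits(grating, "grating_model"))
  s <- (beta - 2 * pi / grating$period_nm) * lambda_nm / (2 * pi * grating$n_top)
  if (abs(s) > 1 + 1e-12) {
    cond <- structure(class = c("evanescent_order", "error", "condition"),
                      list(message = sprintf(
                        "first grating order is evanescent (sin theta = %.4f)", s),
                        call = sys.call()))
    stop(cond)
  }
  asin(min(max(s, -1), 1))
}

#' Guided-mode propagation constant of the loaded slab
#'
#' Design value of beta(lambda) computed from the TE0 effective index of the
#' SiN layer clad in SOG: beta = 2 pi n_eff / lambda. An optional
#' user-supplied table (wavelength_nm, beta) overrides the slab model.
#'
#' @param lambda_nm Wavelength(s) in nm.
#' @param spec A [waveguide_spec].
#' @param beta_table Optional data.frame with columns `wavelength_nm`, `beta`.
#' @return beta in rad/nm.
#' @export
beta_slab <- function(lambda_nm, spec, beta_table = NULL) {
  if (!is.null(beta_table)) {
    return(stats::approx(beta_table$wavelength_nm, beta_table$beta,
                         xout = lambda_nm)$y)
  }
  vapply(lambda_nm, function(wl) {
    neff <- slab_effective_index(
      wl, spec$w_h_nm,
      refractive_index(spec$core, wl),
      refractive_index(spec$substrate, wl),
      refractive_index(spec$cladding, wl))
    2 * pi * neff / wl
  }, numeric(1))
}

#' Taper half-width profile
#'
#' y(x) = alpha * (L/2 - x)^m + w2/2 with alpha = (w1 - w2) / (2 L^m), for x
#' in [-L/2, L/2] (x in um along the taper, narrow end at -L/2). Returns the
#' half-width in um.
#'
#' @param x_um Position(s) along the taper in um.
#' @param spec A [waveguide_spec].
#' @return Half-width y in um.
#' @export
taper_half_width <- function(x_um, spec) {
  stopifnot(inherits(spec, "waveguide_spec"))
  L <- spec$L_taper_um
  if (any(x_um < -L / 2 - 1e-12 | x_um > L / 2 + 1e-12))
    stop("x outside [-L_taper/2, L_taper/2]")
  w1 <- spec$w1_nm / 1000; w2 <- spec$w2_nm / 1000
  alpha <- (w1 - w2) / (2 * L^spec$m)
  alpha * pmax(L / 2 - x_um, 0)^spec$m + w2 / 2
}
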