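# Segmented dual-wavelength metalens design: lens phase, guided-wave phase,
# stripe segmentation and phase-matched meta-atom placement.

#' Wrap a phase to (-pi, pi]
#' @param phi Phase(s) in radians.
#' @return Wrapped phase(s).
#' @export
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  # map -pi (from exact multiples) to +pi-side consistently
  out[out <= -pi + 1e-15] <- pi
  out
}

#' Lens phase specification
#'
#' Dual-wavelength hyperbolic lens phase parameters: aperture size D, focal
#' distance F, numerical aperture NA and the two design wavelengths. The
#' three geometric quantities are tied by NA = n * sin(arctan(D / 2F)); give
#' either `F_um` or `NA` and the other is derived. `n_na` is the index used
#' in that relation (the focal medium, water by default); the per-wavelength
#' focus-medium index used in the phase equation comes from `n_focus`.
#'
#' @param D_um Metalens size in um (default 20).
#' @param lambda1_nm,lambda2_nm The two design wavelengths in nm.
#' @param na Numerical aperture (give this or `F_um`).
#' @param F_um Focal distance in um (give this or `NA`).
#' @param n_na Index in the NA relation (default 1.33).
#' @param n_focus Focus-medium dispersion table (default packaged water).
#' @return An object of class `lens_phase_spec`.
#' @export
lens_phase_spec <- function(D_um = 20, lambda1_nm, lambda2_nm,
                            na = NULL, F_um = NULL, n_na = 1.33,
                            n_focus = material_table("water")) {
  stopifnot(D_um > 0, lambda1_nm != lambda2_nm)
  if (is.null(F_um) && is.null(na)) stop("give either F_um or na")
  if (is.null(F_um)) F_um <- focal_length_from_na(na, D_um, n_na)
  if (is.null(na)) na <- na_from_focal(F_um, D_um, n_na)
  stopifnot(abs(na - n_na * sin(atan(D_um / (2 * F_um)))) < 1e-6)
  structure(list(D_um = D_um, F_um = F_um, na = na, n_na = n_na,
                 lambda1_nm = lambda1_nm, lambda2_nm = lambda2_nm,
                 n_focus = n_focus),
            class = "lens_phase_spec")
}

#' Focal length from numerical aperture
#'
#' Inverts NA = n sin(arctan(D / 2F)): F = D / (2 tan(arcsin(NA / n))).
#'
#' @param na Numerical aperture, 0 < na < n.
#' @param D_um Aperture size in um.
#' @param n Focal-medium refractive index.
#' @return Focal length in um.
#' @export
focal_length_from_na <- function(na, D_um, n) {
  if (na >= n) stop("unphysical NA: NA must be < n of the focal medium")
  if (na <= 0) stop("NA must be positive")
  D_um / (2 * tan(asin(na / n)))
}

#' Numerical aperture from focal length
#'
#' NA = n sin(arctan(D / 2F)); inverse of [focal_length_from_na()].
#'
#' @param F_um Focal length in um.
#' @param D_um Aperture size in um.
#' @param n Focal-medium refractive index.
#' @return Numerical aperture.
#' @export
na_from_focal <- function(F_um, D_um, n) {
  stopifnot(F_um > 0, D_um > 0)
  n * sin(atan(D_um / (2 * F_um)))
}

#' Hyperbolic lens phase
#'
#' phi_lens(x, y, lambda) = (2 pi n / lambda) * (F - sqrt(F^2 + x^2 + y^2)),
#' radially symmetric and <= 0 everywhere, with n the focus-medium index at
#' lambda.
#'
#' @param x_nm,y_nm Coordinates on the lens plane in nm (origin at center).
#' @param lambda_nm Wavelength in nm.
#' @param spec A [lens_phase_spec].
#' @return Phase in radians.
#' @export
lens_phase <- function(x_nm, y_nm, lambda_nm, spec) {
  stopifnot(inherits(spec, "lens_phase_spec"))
  n <- refractive_index(spec$n_focus, lambda_nm)
  F_nm <- spec$F_um * 1000
  (2 * pi * n / lambda_nm) * (F_nm - sqrt(F_nm^2 + x_nm^2 + y_nm^2))
}

#' Input-phase models for the taper wavefront
#'
#' The wavefront arriving at the first meta-atoms is curved by the taper; a
#' cylindrical-wave model with an effective source a distance R behind the
#' lens places phi_input(y, lambda) = beta(lambda) (sqrt(R^2 + y^2) - R).
#' `model = "none"` disables the correction; `model = "table"` interpolates a
#' user-supplied (y_nm, phase_rad) table (wavelength-independent).
#'
#' @param model `"cylindrical"`, `"none"`, or `"table"`.
#' @param R_um Effective source distance for the cylindrical model, um.
#' @param table data.frame with `y_nm`, `phase_rad` for `model = "table"`.
#' @return An object of class `input_phase_model`.
#' @export
input_phase_model <- function(model = c("cylindrical", "none", "table"),
                              R_um = 40, table = NULL) {
  model <- match.arg(model)
  if (model == "table" && is.null(table)) stop("table model needs a table")
  if (model == "cylindrical") stopifnot(R_um > 0)
  structure(list(model = model, R_um = R_um, table = table),
            class = "input_phase_model")
}

# Evaluate phi_input(y, lambda) given beta at that lambda.
input_phase <- function(y_nm, beta, ipm) {
  switch(ipm$model,
    none = rep(0, length(y_nm)),
    cylindrical = {
      R <- ipm$R_um * 1000
      beta * (sqrt(R^2 + y_nm^2) - R)
    },
    table = stats::approx(ipm$table$y_nm, ipm$table$phase_rad, xout = y_nm,
                          rule = 2)$y)
}

#' Accumulated waveguide phase
#'
#' phi_wg(x, y) = beta(lambda) * x + phi_input(y, lambda), strictly
#' increasing in x (the guided-propagation direction) for fixed y.
#'
#' @param x_nm,y_nm Coordinates in nm.
#' @param beta Propagation constant at the working wavelength, rad/nm.
#' @param ipm An [input_phase_model].
#' @return Phase in radians.
#' @export
waveguide_phase <- function(x_nm, y_nm, beta, ipm = input_phase_model("none")) {
  stopifnot(beta > 0)
  beta * x_nm + input_phase(y_nm, beta, ipm)
}

#' Stripe segmentation of the aperture
#'
#' The aperture is tiled by `2 * n_pairs` rectangular stripes that run along
#' the propagation direction x and alternate along y between the two
#' wavelength families; 2 * n_pairs * stripe_width = D exactly. Stripes are
#' half-open in y (a boundary belongs to the stripe on its +y side) and the
#' stripe starting at y = -D/2 serves lambda1.
#'
#' @param D_um Aperture size in um.
#' @param n_pairs Number of (lambda1, lambda2) stripe pairs (default 5).
#' @return An object of class `segment_layout`.
#' @export
segment_layout <- function(D_um = 20, n_pairs = 5) {
  stopifnot(n_pairs >= 1, D_um > 0)
  structure(list(D_um = D_um, n_pairs = n_pairs,
                 stripe_width_um = D_um / (2 * n_pairs)),
            class = "segment_layout")
}

#' Segment selector Loc_i(y)
#'
#' Indicator of the i-th wavelength family at height y: alternating stripes
#' of width `stripe_width_um`; the two families are complementary,
#' Loc_1(y) + Loc_2(y) = 1 for every in-aperture y.
#'
#' @param y_nm Height(s) in nm, |y| <= D/2.
#' @param layout A [segment_layout].
#' @param family 1 or 2.
#' @return 0/1 vector.
#' @export
segment_selector <- function(y_nm, layout, family) {
  stopifnot(inherits(layout, "segment_layout"), family %in% c(1, 2))
  D_nm <- layout$D_um * 1000
  if (any(y_nm < -D_nm / 2 - 1e-9 | y_nm > D_nm / 2 + 1e-9))
    stop("y outside the aperture")
  sw <- layout$stripe_width_um * 1000
  idx <- floor((y_nm + D_nm / 2) / sw)  # half-open: boundary -> +y stripe
  idx[idx == 2 * layout$n_pairs] <- 2 * layout$n_pairs - 1  # top edge point
  as.integer(idx %% 2 == (family - 1))
}

#' Place meta-atoms by phase matching
#'
#' For each row of the stripe layout (rows on a global y grid with pitch
#' `row_pitch_nm`), finds every x in [-D/2, D/2] where the wrapped phase
#' mismatch wrap(phi_wg - phi_lens) vanishes at the stripe's design
#' wavelength, by bracketed root finding per 2 pi branch of the (strictly
#' increasing) mismatch. Roots closer than one atom diameter to the
#' previously kept atom are dropped (the later root of the pair).
#'
#' @param spec A [lens_phase_spec].
#' @param layout A [segment_layout] (must share D with `spec`).
#' @param beta1,beta2 Propagation constants at the two design wavelengths.
#' @param ipm An [input_phase_model].
#' @param row_pitch_nm Row pitch along y (default 365, the grating period).
#' @param tol Phase tolerance in rad for accepted atoms (default 1e-3).
#' @param diameter_nm,height_nm Meta-atom cylinder size (defaults 200/500).
#' @return data.frame with columns `x_nm`, `y_nm`, `diameter_nm`,
#'   `height_nm`, `segment_lambda_nm`, `family`.
#' @export
place_meta_atoms <- function(spec, layout, beta1, beta2,
                             ipm = input_phase_model("none"),
                             row_pitch_nm = 365, tol = 1e-3,
                             diameter_nm = 200, height_nm = 500) {
  stopifnot(inherits(spec, "lens_phase_spec"), inherits(layout, "segment_layout"),
            row_pitch_nm > 0, abs(spec$D_um - layout$D_um) < 1e-9)
  D_nm <- spec$D_um * 1000
  betas <- c(beta1, beta2)
  lams <- c(spec$lambda1_nm, spec$lambda2_nm)
  # degenerate design: beta must exceed the largest lens-phase slope
  for (i in 1:2) {
    slope_max <- 2 * pi * spec$na / lams[i]
    if (betas[i] <= slope_max)
      stop("degenerate design: beta does not exceed the lens-phase slope (n_eff <= NA)")
  }
  n_rows <- floor(D_nm / row_pitch_nm)
  y_rows <- -D_nm / 2 + (seq_len(n_rows) - 0.5) * row_pitch_nm
  out <- vector("list", n_rows)
  for (r in seq_len(n_rows)) {
    y <- y_rows[r]
    fam <- if (segment_selector(y, layout, 1) == 1) 1L else 2L
    lam <- lams[fam]; bet <- betas[fam]
    xs <- solve_phase_matches(y, lam, bet, spec, ipm, D_nm, diameter_nm, tol)
    if (length(xs))
      out[[r]] <- data.frame(x_nm = xs, y_nm = y, diameter_nm = diameter_nm,
                             height_nm = height_nm, segment_lambda_nm = lam,
                             family = fam)
  }
  atoms <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(atoms))
    atoms <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                        diameter_nm = numeric(0), height_nm = numeric(0),
                        segment_lambda_nm = numeric(0), family = integer(0))
  rownames(atoms) <- NULL
  atoms
}

# All phase-matching roots along one row: the mismatch d(x) = phi_wg -
# phi_lens is strictly increasing in x, so each 2*pi branch holds exactly
# one root, bracketed on a coarse grid and refined by uniroot.
solve_phase_matches <- function(y, lam, bet, spec, ipm, D_nm, diameter_nm, tol) {
  mism <- function(x) waveguide_phase(x, y, bet, ipm) - lens_phase(x, y, lam, spec)
  lo <- -D_nm / 2; hi <- D_nm / 2
  klo <- ceiling(mism(lo) / (2 * pi))
  khi <- floor(mism(hi) / (2 * pi))
  if (khi < klo) return(numeric(0))
  grid <- seq(lo, hi, length.out = max(64, ceiling((hi - lo) / 40)))
  mg <- mism(grid)
  xs <- numeric(khi - klo + 1)
  for (j in seq_along(xs)) {
    target <- 2 * pi * (klo + j - 1)
    i2 <- which(mg >= target)[1]
    bl <- if (i2 > 1) grid[i2 - 1] else lo
    bh <- grid[i2]
    root <- stats::uniroot(function(x) mism(x) - target, c(bl, bh),
                           tol = 1e-6)$root
    stopifnot(abs(wrap_phase(mism(root))) <= tol)
    xs[j] <- root
  }
  # enforce minimum center spacing: drop the later root of a violating pair
  keep <- numeric(0)
  for (x in xs) {
    if (!length(keep) || x - keep[length(keep)] >= diameter_nm) keep <- c(keep, x)
  }
  keep
}

#' Construct a full metalens design
#'
#' Builds the segmented (or unsegmented control) dual-wavelength metalens:
#' derives beta at both design wavelengths from the waveguide slab model
#' (or an override table), places the meta-atoms, and validates that every
#' atom satisfies the phase-matching condition within `tol`.
#'
#' With `segmented = FALSE` every stripe is assigned to lambda1 (the
#' single-wavelength control of the two-wavelength comparison).
#'
#' @param lambda1_nm,lambda2_nm Design wavelengths in nm.
#' @param D_um Metalens size in um (default 20).
#' @param na Numerical aperture (default 1.1); alternatively give `F_um`.
#' @param F_um Optional focal length in um.
#' @param waveguide A [waveguide_spec] (default packaged geometry).
#' @param layout A [segment_layout] (default 5 stripe pairs).
#' @param ipm An [input_phase_model] (default cylindrical, R = L_taper).
#' @param segmented If FALSE, all stripes serve lambda1 (control design).
#' @param row_pitch_nm,tol,diameter_nm,height_nm Passed to
#'   [place_meta_atoms()].
#' @param beta_table Optional beta(lambda) override table (see [beta_slab()]).
#' @param n_na Index for the NA relation (default 1.33).
#' @return An object of class `metalens_design` with elements `lens`,
#'   `layout`, `atoms`, `ipm`, `beta_fun`, `waveguide`, `segmented`.
#' @export
metalens_design <- function(lambda1_nm, lambda2_nm, D_um = 20, na = 1.1,
                            F_um = NULL, waveguide = waveguide_spec(),
                            layout = segment_layout(D_um),
                            ipm = NULL, segmented = TRUE,
                            row_pitch_nm = 365, tol = 1e-3,
                            diameter_nm = 200, height_nm = 500,
                            beta_table = NULL, n_na = 1.33) {
  lens <- lens_phase_spec(D_um, lambda1_nm, lambda2_nm,
                          na = if (is.null(F_um)) na else NULL,
                          F_um = F_um, n_na = n_na)
  if (is.null(ipm)) ipm <- input_phase_model("cylindrical",
                                             R_um = waveguide$L_taper_um)
  beta_fun <- function(lambda_nm) beta_slab(lambda_nm, waveguide, beta_table)
  lay <- layout
  if (!segmented) {
    # control: a single full-aperture stripe, all of family 1 (lambda1)
    lay <- structure(list(D_um = D_um, n_pairs = 1L, stripe_width_um = D_um),
                     class = "segment_layout")
  }
  b1 <- beta_fun(lambda1_nm); b2 <- beta_fun(lambda2_nm)
  atoms <- place_meta_atoms(lens, lay, b1, b2, ipm, row_pitch_nm, tol,
                            diameter_nm, height_nm)
  design <- structure(list(lens = lens, layout = lay, atoms = atoms,
                           ipm = ipm, beta_fun = beta_fun,
                           waveguide = waveguide, segmented = segmented,
                           row_pitch_nm = row_pitch_nm, tol = tol),
                      class = "metalens_design")
  validate_design(design)
  design
}

# Assert the phase-matching residual of every placed atom.
validate_design <- function(design) {
  a <- design$atoms
  if (!nrow(a)) return(invisible(TRUE))
  for (lam in unique(a$segment_lambda_nm)) {
    sel <- a$segment_lambda_nm == lam
    bet <- design$beta_fun(lam)
    res <- wrap_phase(
      waveguide_phase(a$x_nm[sel], a$y_nm[sel], bet, design$ipm) -
        lens_phase(a$x_nm[sel], a$y_nm[sel], lam, design$lens))
    if (any(abs(res) > design$tol))
      stop("phase-matching residual exceeds tolerance for some atoms")
  }
  invisible(TRUE)
}

#' @export
print.metalens_design <- function(x, ...) {
  cat(sprintf(
    "metalens_design: D = %g um, F = %.3f um, NA = %.3f\n  lambda = %g / %g nm, %s, %d meta-atoms\n",
    x$lens$D_um, x$lens$F_um, x$lens$na, x$lens$lambda1_nm, x$lens$lambda2_nm,
    if (x$segmented) sprintf("%d stripe pairs", x$layout$n_pairs) else "unsegmented control",
    nrow(x$atoms)))
  invisible(x)
}

#' Export / read a meta-atom layout
#'
#' Writes the atom table as CSV with columns `x_nm, y_nm, diameter_nm,
#' height_nm, segment_lambda_nm`; an empty design produces a header-only
#' file. `read_layout()` reads it back.
#'
#' @param design A `metalens_design` (or a bare atom data.frame).
#' @param path Output CSV path.
#' @return `export_layout()` the path, invisibly; `read_layout()` the atom
#'   data.frame.
#' @export
export_layout <- function(design, path) {
  atoms <- if (inherits(design, "metalens_design")) design$atoms else design
  cols <- c("x_nm", "y_nm", "diameter_nm", "height_nm", "segment_lambda_nm")
  stopifnot(all(cols %in% names(atoms)))
  utils::write.csv(atoms[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_layout
#' @export
read_layout <- function(path) {
  utils::read.csv(path)
}
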