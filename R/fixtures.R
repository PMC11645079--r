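# Synthetic fluorophore fixtures: Gaussian band profiles at the documented
# peak positions of the three model dyes, with packaged photophysical
# constants. Real measured spectra can be loaded with read_fluorophore_csv().

# Packaged constants: band peaks (nm), relative band heights, quantum yield
# and fluorescence lifetime. Peak positions follow the dyes' published
# excitation/emission maxima; psi and tau_fl are the commonly tabulated
# values for ATTO 490LS, Alexa Fluor 555 and (APC-based) APC-Cy7.
.fluor_constants <- list(
  atto490ls = list(label = "ATTO 490LS",
                   abs_peaks_nm = 496, abs_heights = 1,
                   em_peak_nm = 661,
                   quantum_yield = 0.30, lifetime_ns = 2.6),
  alexa555 = list(label = "Alexa Fluor 555",
                  abs_peaks_nm = c(520, 553), abs_heights = c(0.75, 1),
                  sigma_abs_nm = 10,  # sharp vibronic bands: keeps the two
                                      # excitation maxima distinct
                  em_peak_nm = 568,
                  quantum_yield = 0.10, lifetime_ns = 0.3),
  apc_cy7 = list(label = "APC-Cy7",
                 abs_peaks_nm = 651, abs_heights = 1,
                 em_peak_nm = 779,
                 quantum_yield = 0.68, lifetime_ns = 1.8)
)

#' Synthetic fluorophore fixtures
#'
#' Builds a [fluorophore_spec()] for one of the three model dyes with
#' Gaussian absorption/emission bands at the documented peak wavelengths
#' (ATTO 490LS: 496 / 661 nm, a 165 nm Stokes shift; Alexa Fluor 555: 520
#' and 553 / 568 nm; APC-Cy7: 651 / 779 nm), peak-normalized to 1, plus the
#' packaged quantum yield and lifetime.
#'
#' @param name One of `"atto490ls"`, `"alexa555"`, `"apc_cy7"`.
#' @param sigma_abs_nm Gaussian width of absorption bands (default 25 nm, or
#'   a narrower packaged per-dye value where the dye has resolved bands).
#' @param sigma_em_nm Gaussian width of the emission band (default 30 nm).
#' @return A `fluorophore_spec`.
#' @export
generate_fluorophore <- function(name, sigma_abs_nm = NULL, sigma_em_nm = 30) {
  if (!name %in% names(.fluor_constants))
    stop(sprintf("unknown fluorophore '%s'; available fixtures: %s",
                 name, paste(names(.fluor_constants), collapse = ", ")))
  k <- .fluor_constants[[name]]
  if (is.null(sigma_abs_nm))
    sigma_abs_nm <- if (!is.null(k$sigma_abs_nm)) k$sigma_abs_nm else 25
  wl <- seq(350, 950, by = 1)
  ab <- rowSums(vapply(seq_along(k$abs_peaks_nm), function(i)
    k$abs_heights[i] * exp(-(wl - k$abs_peaks_nm[i])^2 / (2 * sigma_abs_nm^2)),
    numeric(length(wl))))
  em <- exp(-(wl - k$em_peak_nm)^2 / (2 * sigma_em_nm^2))
  fluorophore_spec(
    k$label,
    absorption = data.frame(wavelength_nm = wl, intensity = ab / max(ab)),
    emission = data.frame(wavelength_nm = wl, intensity = em / max(em)),
    quantum_yield = k$quantum_yield, lifetime_ns = k$lifetime_ns)
}

#' The three packaged dye/design presets
#'
#' Maps each model fluorophore to its dual-wavelength metalens design pair
#' (excitation / collection wavelength in nm).
#'
#' @return data.frame with `fluorophore`, `lambda1_nm`, `lambda2_nm`.
#' @export
design_presets <- function() {
  data.frame(fluorophore = c("atto490ls", "alexa555", "apc_cy7"),
             lambda1_nm = c(500, 520, 650),
             lambda2_nm = c(660, 570, 780))
}
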