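# Configuration handling and end-to-end pipeline orchestration:
# design -> dual-wavelength PSFs -> overlap -> MDE/V_eff -> photon budget
# -> Monte Carlo FCS, with all artifacts written to an output directory.

#' Read and validate a pipeline configuration
#'
#' YAML configuration with sections `design`, `waveguide`, `fluorophore`,
#' `detection_band`, `psf`, `fcs`, plus top-level `output_dir` and `seed`.
#' Unknown keys are rejected; all physical values are checked positive
#' before any stage runs. Units are embedded in key names (`*_nm`, `*_um`,
#' `*_s`).
#'
#' @param path YAML file path, or a list already in config shape.
#' @return Validated config list (class `pipeline_config`).
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  validate_config(cfg)
}

default_config <- function() {
  list(
    design = list(lambda1_nm = 520, lambda2_nm = 570, D_um = 20, na = 1.1,
                  n_pairs = 5, row_pitch_nm = 365, segmented = TRUE,
                  atom_diameter_nm = 200, atom_height_nm = 500,
                  input_phase = list(model = "cylindrical", R_um = 40)),
    waveguide = list(w1_nm = 600, w2_nm = 20000, w_h_nm = 100,
                     L_taper_um = 40, m = 1.15, h_SOG_um = 2),
    fluorophore = "alexa555",
    detection_band = list(half_width_nm = 20, n_samples = 5),
    psf = list(dx_nm = 50, extent_um = 30, z_min_um = 5, z_max_um = 9,
               z_step_nm = 25, crop_um = 12),
    fcs = list(enabled = TRUE, n_molecules = 300, box_um = 2.4, cell_nm = 50,
               D_um2_s = 100, dt_s = 1e-6, duration_s = 30, bin_time_s = 2e-6,
               k_ex_over_k_fl = 0.1),
    output_dir = "metafcs-output", seed = 1)
}

validate_config <- function(cfg) {
  def <- default_config()
  extra <- setdiff(names(cfg), names(def))
  if (length(extra))
    stop("unknown config sections: ", paste(extra, collapse = ", "))
  full <- utils::modifyList(def, cfg)
  with(full$design, {
    stopifnot(lambda1_nm > 0, lambda2_nm > 0, D_um > 0, na > 0,
              n_pairs >= 1, row_pitch_nm > 0)
  })
  with(full$waveguide, stopifnot(w1_nm > 0, w1_nm < w2_nm, w_h_nm > 0,
                                 m > 0, h_SOG_um >= 0))
  if (!is.list(full$fluorophore))
    stopifnot(is.character(full$fluorophore))
  with(full$psf, stopifnot(dx_nm > 0, extent_um > 0, z_max_um > z_min_um))
  with(full$fcs, stopifnot(n_molecules >= 1, box_um > 0, D_um2_s > 0,
                           duration_s > 0))
  structure(full, class = c("pipeline_config", "list"))
}

#' Write a configuration to YAML
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full design-to-FCS pipeline
#'
#' Executes, in order: metalens design (layout CSV), dual-wavelength PSF
#' propagation (overlap metrics), MDE construction (detection band, CEF with
#' the reciprocity-proxy P_max, effective volume), the photon budget N_F at
#' k_ex = 0.1 k_fl, and -- when enabled -- the Monte Carlo FCS experiment
#' with multi-tau correlation and 3D-diffusion fit. A machine-readable
#' summary (JSON) collects the headline numbers. Fully reproducible from
#' config + seed; a stage failure aborts with the stage name, keeping the
#' artifacts of completed stages on disk.
#'
#' @param config A `pipeline_config`, a config list, or a YAML path.
#' @param quiet Suppress stage logging.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- read_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    log_stage("stage %s ...", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  summary <- list(seed = cfg$seed)

  wg <- with(cfg$waveguide, waveguide_spec(w1_nm, w2_nm, w_h_nm, L_taper_um,
                                           m, h_SOG_um))
  des <- stage("design", {
    d <- cfg$design
    ipm <- if (identical(d$input_phase$model, "cylindrical"))
      input_phase_model("cylindrical", R_um = d$input_phase$R_um)
    else input_phase_model("none")
    dd <- metalens_design(d$lambda1_nm, d$lambda2_nm, D_um = d$D_um,
                          na = d$na, waveguide = wg,
                          layout = segment_layout(d$D_um, d$n_pairs),
                          ipm = ipm, segmented = isTRUE(d$segmented),
                          row_pitch_nm = d$row_pitch_nm,
                          diameter_nm = d$atom_diameter_nm,
                          height_nm = d$atom_height_nm)
    export_layout(dd, file.path(cfg$output_dir, "layout.csv"))
    dd
  })
  summary$design <- list(lambda1_nm = des$lens$lambda1_nm,
                         lambda2_nm = des$lens$lambda2_nm,
                         D_um = des$lens$D_um, F_um = des$lens$F_um,
                         na = des$lens$na, n_atoms = nrow(des$atoms))

  p <- cfg$psf
  prop <- function(lam) {
    f <- synthesize_aperture_field(des, lam, dx_nm = p$dx_nm,
                                   extent_um = p$extent_um)
    propagate_stack(f, h_SOG_um = wg$h_SOG_um, z_min_um = p$z_min_um,
                    z_max_um = p$z_max_um, z_step_nm = p$z_step_nm,
                    crop_um = p$crop_um)
  }
  vols <- stage("propagate", {
    v1 <- prop(des$lens$lambda1_nm)
    v2 <- prop(des$lens$lambda2_nm)
    save_volume(v1, file.path(cfg$output_dir, "psf_lambda1.rds"))
    save_volume(v2, file.path(cfg$output_dir, "psf_lambda2.rds"))
    list(v1 = v1, v2 = v2)
  })
  m1 <- psf_metrics(vols$v1); m2 <- psf_metrics(vols$v2)
  ov <- focal_overlap(vols$v1, vols$v2)
  summary$psf <- list(
    fwhm_x_lambda1_nm = m1$fwhm_x_nm, fwhm_y_lambda1_nm = m1$fwhm_y_nm,
    fwhm_x_lambda2_nm = m2$fwhm_x_nm, fwhm_y_lambda2_nm = m2$fwhm_y_nm,
    z_focus_lambda1_um = m1$z_focus_um, z_focus_lambda2_um = m2$z_focus_um,
    delta_z_focus_nm = ov$delta_z_nm, delta_r_nm = ov$delta_r_nm,
    overlap = ov$overlap)

  fl <- if (is.character(cfg$fluorophore)) generate_fluorophore(cfg$fluorophore)
        else cfg$fluorophore
  mde_res <- stage("mde", {
    band <- detection_band(des$lens$lambda2_nm,
                           cfg$detection_band$half_width_nm,
                           cfg$detection_band$n_samples)
    det <- list()
    for (lam in band$lambda_nm) {
      det[[as.character(lam)]] <-
        if (lam == des$lens$lambda2_nm) vols$v2 else prop(lam)
    }
    p_max <- m2$encircled_fraction / 3
    cef <- collection_efficiency(det, fl, p_max)
    mm <- mde_map(vols$v1, cef)
    save_volume(mm, file.path(cfg$output_dir, "mde.rds"))
    # control designs can leave a degenerate MDE (no overlap); report NA
    # rather than aborting the run
    ev <- tryCatch(suppressWarnings(effective_volume(mm)),
                   error = function(e) list(v_eff_fl = NA_real_,
                                            w_xy_um = NA_real_,
                                            w_z_um = NA_real_,
                                            method = "failed"))
    list(mm = mm, p_max = p_max, ev = ev)
  })
  k_ex <- cfg$fcs$k_ex_over_k_fl * fl$k_fl
  n_f <- count_rate(mde_res$mm$peak_mde, fl, k_ex)
  summary$mde <- list(p_max = mde_res$p_max,
                      peak_mde_percent = mde_res$mm$peak_mde_percent,
                      v_eff_fl = mde_res$ev$v_eff_fl,
                      w_xy_um = mde_res$ev$w_xy_um,
                      w_z_um = mde_res$ev$w_z_um)
  summary$photon_budget <- list(
    fluorophore = fl$name, quantum_yield = fl$quantum_yield,
    lifetime_ns = fl$lifetime_ns,
    s1_bar = excited_state_population(k_ex, fl$k_fl), n_f_cps = n_f)

  if (isTRUE(cfg$fcs$enabled)) {
    fcs_res <- stage("fcs", {
      f <- cfg$fcs
      sim <- diffusion_sim_config(f$n_molecules, f$box_um, f$cell_nm,
                                  f$D_um2_s, f$dt_s, f$duration_s,
                                  f$bin_time_s, seed = cfg$seed)
      lattice <- mde_to_lattice(mde_res$mm, f$box_um, f$cell_nm)
      trace <- fcs_experiment(sim, lattice, n_f)
      curve <- autocorrelate(trace)
      fit <- fit_3d_diffusion(curve)
      write_correlation_csv(curve,
                            file.path(cfg$output_dir, "correlation.csv"))
      write_fit_json(fit, file.path(cfg$output_dir, "fcs_fit.json"))
      list(sim = sim, trace = trace, fit = fit)
    })
    summary$fcs <- list(
      concentration_nM = concentration(fcs_res$sim),
      mean_rate_cps = fcs_res$trace$mean_rate,
      N = fcs_res$fit$N, tau_D_s = fcs_res$fit$tau_D_s,
      s_ratio = fcs_res$fit$s_ratio, G_inf = fcs_res$fit$G_inf)
  }

  jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done; summary at %s", file.path(cfg$output_dir, "summary.json"))
  invisible(summary)
}
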