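#' Default pipeline configuration
#'
#' All analysis parameters with their standard values: 2 um / 300 s
#' mobility rule, 10 s pause exclusion, 1 um Sholl shells, 3 pA initial
#' PSC threshold with the 5 x SD(noise) floor, 1 kHz low-pass, 20-80 Hz
#' gamma band with 49-51 Hz mains exclusion, 33-100% colocalization
#' overlap, rolling-ball radii 50 (trafficking/MitoSholl) and 7
#' (synapse channels). Override any entry via the `config` argument of
#' [run_pipeline()] or a YAML file.
#'
#' @return nested named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1,
    tracks = list(n = 50, duration = 500, frame_dt = 5, speed = 0.17,
                  mobile_fraction = 0.25, mobility_um = 2,
                  mobility_window_s = 300, pause_exclusion_s = 10,
                  immobility_step_um = 0.1),
    morphology = list(n_branch_axon = 5, n_branch_dend = 5,
                      sholl_step_um = 1, voxel_size_um = 0.5,
                      n_mito = 150, proximity_radius_um = 1),
    soma = list(size_px = 128, soma_area_px = 10000, mito_fraction = 0.39,
                clustered = TRUE),
    boutons = list(n = 100, frac_with_mito = 0.74, axon_length_um = 300,
                   pixel_size_um = 0.2),
    lfp = list(frequency_hz = 31, amplitude_mv = 0.1, noise_sd_mv = 0.05,
               duration_s = 300, sample_rate_hz = 5000,
               band_hz = c(20, 80), mains_exclusion_hz = c(49, 51)),
    psc = list(rate_hz = 5, duration_s = 20, amplitude_pa = 50,
               noise_sd_pa = 2, sample_rate_hz = 10000,
               init_threshold_pa = 3, noise_mult = 5, lp_cutoff_hz = 1000),
    behavior = list(n_frames = 1000, frame_rate_hz = 25,
                    occupancy = c(closed = 0.76, open = 0.18, center = 0.06))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full simulate-quantify-summarize pipeline
#'
#' Generates every synthetic input, runs each analysis module on it,
#' writes per-module CSV outputs plus a JSON run report echoing every
#' effective parameter (no hidden defaults) and the package version.
#' Deterministic given the seed: rerunning a config yields byte-identical
#' outputs.
#'
#' @param config named list of parameter overrides (see
#'   [default_config()]), or `NULL`.
#' @param config_file optional YAML file with overrides, merged after
#'   `config`.
#' @param output_dir directory for outputs (created if needed).
#' @param seed overrides the config seed when non-`NULL`.
#' @return (invisibly) the run summary list, also written to
#'   `summary.json`.
#' @export
run_pipeline <- function(config = NULL, config_file = NULL,
                         output_dir = tempfile("mitodyn_run_"),
                         seed = NULL) {
  cfg <- default_config()
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  if (!is.null(config_file)) cfg <- merge_config(cfg, yaml::read_yaml(config_file))
  if (!is.null(seed)) cfg$seed <- seed
  validate_config(cfg)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(output_dir, f)
  results <- list()

  # trafficking
  tc <- cfg$tracks
  g <- gen_tracks(tc$n, tc$duration, tc$frame_dt, tc$speed,
                  tc$mobile_fraction, seed = cfg$seed)
  st <- track_stats(g$tracks, tc$mobility_um, tc$mobility_window_s,
                    tc$pause_exclusion_s, tc$immobility_step_um)
  write.csv(st, out("track_stats.csv"), row.names = FALSE)
  results$trafficking <- list(
    mobile_percent = movie_mobile_fraction(st),
    median_velocity_um_s = median(st$velocity_um_s, na.rm = TRUE),
    mean_path_length_um = mean(st$path_length_um)
  )

  # morphometry + mitochondrial distribution
  mc <- cfg$morphology
  m <- gen_morphology(mc$n_branch_axon, mc$n_branch_dend, seed = cfg$seed)
  sh <- sholl_intersections(m, "all", mc$sholl_step_um)
  write.csv(sh, out("sholl.csv"), row.names = FALSE)
  stk <- gen_mito_stack(m, mc$n_mito, voxel_size = mc$voxel_size_um,
                        seed = cfg$seed)
  bp <- branch_points(m)
  prox <- min_branch_mito_distance(bp, voxel_stack(
    binarize(stk$stack$data), stk$stack$voxel_size, stk$stack$origin))
  write.csv(prox, out("proximity.csv"), row.names = FALSE)
  norm <- normalize_distances(list(run = prox), reference = "run")$run
  results$morphometry <- list(
    total_length_um = total_length(m),
    n_processes = count_processes(m),
    n_branch_points = nrow(bp),
    normalized_distance_mean = mean(norm),
    p_within_radius = prob_within_radius(prox, mc$proximity_radius_um)
  )

  # image quantification
  sc <- cfg$soma
  soma <- gen_soma_image(sc$size_px, sc$soma_area_px, sc$mito_fraction,
                         sc$clustered, seed = cfg$seed)
  bc <- cfg$boutons
  ax <- gen_axon_boutons(bc$n, bc$frac_with_mito, bc$axon_length_um,
                         bc$pixel_size_um, seed = cfg$seed)
  pn <- detect_puncta(ax$biocytin, ax$pixel_size, channels = list(mito = ax$mito))
  content <- bouton_mito_content(pn, ax$mito, ax$shaft_mask)
  write.csv(as.data.frame(pn), out("puncta.csv"), row.names = FALSE)
  results$image_quant <- list(
    soma_mito_percent = soma_mito_area_fraction(soma$mito_mask, soma$soma_mask),
    soma_clustered = detect_soma_cluster(soma$mito_mask, soma$soma_mask),
    n_boutons = nrow(pn),
    bouton_occupancy_per_10um = bouton_occupancy(pn, bc$axon_length_um),
    bouton_mito_percent = content$fraction_containing
  )

  # electrophysiology
  lc <- cfg$lfp
  lfp <- gen_lfp(lc$frequency_hz, lc$amplitude_mv, lc$noise_sd_mv,
                 lc$duration_s, lc$sample_rate_hz, seed = cfg$seed)
  spec <- power_spectrum(lfp, window = lc$duration_s,
                         mains_exclusion = lc$mains_exclusion_hz)
  write.csv(spec, out("power_spectrum.csv"), row.names = FALSE)
  gm <- gamma_metrics(spec, lc$band_hz)
  results$ephys_gamma <- list(
    peak_frequency_hz = gm$peak_frequency,
    peak_power = gm$peak_power,
    power_area = gm$power_area,
    width50_hz = as.numeric(spectrum_width50(spec, lc$band_hz))
  )

  pc <- cfg$psc
  ev_true <- gen_psc_events(pc$rate_hz, pc$duration_s, pc$amplitude_pa,
                            seed = cfg$seed)
  vtr <- gen_psc_trace(ev_true$time_s, ev_true$amplitude_pA,
                       noise_sd = pc$noise_sd_pa, duration = pc$duration_s,
                       sample_rate = pc$sample_rate_hz, seed = cfg$seed)
  ev <- detect_pscs(vtr, init_threshold = pc$init_threshold_pa,
                    noise_mult = pc$noise_mult, lp_cutoff = pc$lp_cutoff_hz)
  write.csv(as.data.frame(ev), out("psc_events.csv"), row.names = FALSE)
  results$ephys_psc <- c(n_true = nrow(ev_true), summary(ev))

  # behavior
  bh <- cfg$behavior
  zones <- epm_zone_map()
  traj <- gen_trajectory(zones[names(bh$occupancy)], bh$occupancy,
                         bh$n_frames, bh$frame_rate_hz, seed = cfg$seed)
  occ <- zone_occupancy(traj, zones)
  kin <- traj_kinematics(traj)
  write.csv(traj, out("trajectory.csv"), row.names = FALSE)
  results$behavior <- list(occupancy_percent = as.list(occ),
                           total_distance_cm = kin$total_distance_cm,
                           mean_velocity_cm_s = kin$mean_velocity_cm_s)

  summary <- list(
    package = "mitodyn",
    version = as.character(utils::packageVersion("mitodyn")),
    parameters = cfg,
    results = results,
    outputs = list.files(output_dir)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

validate_config <- function(cfg) {
  need <- names(default_config())
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    mito_stop("config is missing sections: ", paste(missing, collapse = ", "))
  }
  with(cfg$tracks, {
    if (mobile_fraction < 0 || mobile_fraction > 1) {
      mito_stop("tracks$mobile_fraction must be in [0, 1]")
    }
  })
  if (abs(sum(cfg$behavior$occupancy) - 1) > 1e-8) {
    mito_stop("behavior$occupancy must sum to 1")
  }
  invisible(cfg)
}
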