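# Declarative configuration and the end-to-end pipeline driver:
# simulate -> reconstruct (6 steps) -> track -> segment -> mesh -> solve ->
# summarize, on synthetic data with known ground truth.

#' Default pipeline configuration
#'
#' One nested list drives the whole pipeline; [small_config()] is a reduced
#' variant used for fast validation runs. Every randomized stage draws its
#' seed from `seed`; rerunning with the same seed gives identical outputs.
#'
#' The experiment emulated is a contractile cell in a bead-seeded soft
#' hydrogel (1.6e8 beads/mL, ~18 um spacing; E = 90 Pa, nu = 0.45),
#' imaged as a time-lapse of full-FOV volumes plus 8-repeat reduced-FOV
#' bursts. Traction follows `schedule`: it peaks and then ramps down to
#' zero (contractility inhibition), and the final time point is the relaxed
#' reference state.
#'
#' @param seed integer master seed.
#' @return a `tfocm_config` list.
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    geometry = list(
      center_wavelength_nm = 800, bandwidth_nm = 160,
      n_k_samples = 256L, fov_um = c(320, 160, 160),
      n_voxels = c(256L, 96L, 96L), refractive_index = 1.34,
      transverse_resolution_um = 3.4, na = 0.2,
      focal_plane = c(c = 160, x1y0 = 0.8, x0y1 = -0.6),
      coherence_gate = c(c = 0, x2y0 = 2, x0y2 = 1.5),
      carrier = c(0.3, -0.2), phase_jitter_std = 0.5,
      noise_floor_db = -45, falloff_db_per_mm = 5),
    scene = list(
      bead_concentration = 1.6e8, coverslip_depth = 10,
      phantom = list(center = c(160, 80, 80), semiaxes = c(16, 24, 18),
                     scatterer_density = 0.06, amplitude = 0.5)),
    schedule = list(t_minutes = c(0, 15, 30, 45, 60),
                    amplitude = c(0.6, 0.9, 1.0, 0.4, 0),
                    peak_traction_pa = 15),
    elastic = list(youngs_modulus = 90, poisson_ratio = 0.45),
    burst = list(n_repeats = 8L, factor = 2L),
    tracking = list(min_voxels = 6L, max_size_quantile = 0.99,
                    k_neighbors = 10L, far_field_radius = 110,
                    near_radius = 50),
    segmentation = list(n_clusters = 2L, smooth_sigma = 1),
    mesh = list(h_target_um = 13, target_faces = 450, smoothing_iters = 8),
    solver = list(lambda = "auto", u_char = 1),
    output_dir = NULL)
  class(cfg) <- c("tfocm_config", "list")
  cfg
}

#' @rdname default_config
#' @export
small_config <- function(seed = 1L) {
  cfg <- default_config(seed)
  cfg$geometry$n_k_samples <- 128L
  cfg$geometry$fov_um <- c(160, 106.68, 106.68)
  cfg$geometry$n_voxels <- c(128L, 64L, 64L)
  cfg$geometry$focal_plane <- c(c = 80, x1y0 = 0.8, x0y1 = -0.6)
  cfg$scene$phantom <- list(center = c(80, 53, 53), semiaxes = c(13, 19, 15),
                            scatterer_density = 0.06, amplitude = 0.5)
  cfg$scene$coverslip_depth <- 8
  cfg$tracking$far_field_radius <- 55
  cfg$mesh$h_target_um <- 11
  cfg$mesh$target_faces <- 350
  cfg
}

#' Load / save a pipeline configuration as YAML
#'
#' Values are validated on load; the resolved configuration is frozen to
#' `config.yaml` in the output directory on every run.
#'
#' @param path YAML file path.
#' @return a validated `tfocm_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(raw)) {
    if (is.list(cfg[[k]]) && is.list(raw[[k]])) {
      for (k2 in names(raw[[k]])) cfg[[k]][[k2]] <- .cfg_coerce(raw[[k]][[k2]])
    } else cfg[[k]] <- .cfg_coerce(raw[[k]])
  }
  validate_config(cfg)
  cfg
}

.cfg_coerce <- function(x) {
  if (is.list(x) && length(x) && all(vapply(x, is.numeric, logical(1))) &&
      !is.null(names(x)))
    return(unlist(x))
  x
}

#' @rdname load_config
#' @param config a `tfocm_config`.
#' @export
save_config <- function(config, path) {
  to_yaml <- function(x) {
    if (is.list(x)) lapply(x, to_yaml)
    else if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(to_yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname load_config
#' @export
validate_config <- function(config) {
  g <- config$geometry
  stopifnot(g$bandwidth_nm < g$center_wavelength_nm,
            all(g$fov_um > 0), all(g$n_voxels > 0),
            g$refractive_index >= 1,
            config$scene$bead_concentration > 0,
            config$elastic$youngs_modulus > 0,
            config$elastic$poisson_ratio > -1,
            config$elastic$poisson_ratio < 0.5,
            length(config$schedule$t_minutes) ==
              length(config$schedule$amplitude),
            config$schedule$amplitude[length(config$schedule$amplitude)] == 0,
            config$burst$n_repeats >= 2)
  invisible(config)
}

# Geometry object from a config.
config_geometry <- function(config) {
  do.call(acquisition_geometry, config$geometry)
}

# Ground-truth cell surface mesh from the phantom implicit function.
.phantom_truth_mesh <- function(phantom, fov, target_faces = 450,
                                res_um = 3) {
  ell <- phantom$ellipsoids[[1]]
  lo <- pmax(ell$center - ell$semiaxes - 4 * res_um, 0)
  hi <- pmin(ell$center + ell$semiaxes + 4 * res_um, fov)
  dims <- pmax(ceiling((hi - lo) / res_um) + 1, 8)
  gr <- as.matrix(expand.grid(iz = seq_len(dims[1]), ix = seq_len(dims[2]),
                              iy = seq_len(dims[3])))
  pts <- sweep(sweep(gr - 1, 2, rep(res_um, 3), "*"), 2, lo, "+")
  d <- sweep(sweep(pts, 2, ell$center), 2, ell$semiaxes, "/")
  fld <- array(1 - sqrt(rowSums(d^2)), dims)
  s <- marching_tetrahedra(fld, 0, rep(res_um, 3), lo)
  s <- taubin_smooth(s, 5L)
  decimate_mesh(s, target_faces)
}

#' Run the full TF-OCM pipeline on synthetic data
#'
#' Executes, per time point: scene deformation through the forward elastic
#' solver, raw-spectra simulation (full FOV plus burst), six-step image
#' formation, bead localization; then tracking with drift correction across
#' time, and per time point: speckle reduction, segmentation, meshing, and
#' regularized CTF inversion; finally a time-course summary. A manifest
#' records seeds, per-stage timings, and output checksums.
#'
#' @param config a `tfocm_config`.
#' @param output_dir directory for artifacts (tracks, meshes, tractions,
#'   manifest); NULL keeps everything in memory only.
#' @param verbose print stage progress.
#' @return list with `tracks`, `profile`, `near`, `masks`, `meshes`,
#'   `ctf` (per-time `tfocm_ctf`), `summary` (time-course data.frame),
#'   `ground_truth` (schedule, true near-cell displacement scale, true
#'   total force per time), and `manifest`.
#' @export
run_pipeline <- function(config = default_config(), output_dir = config$output_dir,
                         verbose = TRUE) {
  validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  stage_t <- c()
  geometry <- config_geometry(config)
  model <- elastic_model(config$elastic$youngs_modulus,
                         config$elastic$poisson_ratio)
  ph <- config$scene$phantom
  phantom <- cell_phantom(list(list(center = ph$center,
                                    semiaxes = ph$semiaxes)),
                          scatterer_density = ph$scatterer_density,
                          amplitude = ph$amplitude)
  t0 <- tic()
  scene0 <- make_scene(geometry, config$scene$bead_concentration, phantom,
                       seed = config$seed,
                       coverslip_depth = config$scene$coverslip_depth)
  # ground-truth mesh and peak deformation (linearity: scale by amplitude)
  gt_surf <- .phantom_truth_mesh(phantom, geometry$fov_um,
                                 config$mesh$target_faces)
  grid_n <- pmax(4L, round(geometry$fov_um / config$mesh$h_target_um))
  gt_mesh <- make_volume_mesh(gt_surf, geometry$fov_um, n = grid_n,
                              inside = function(p) phantom_inside(phantom, p))
  peak_tr <- normal_traction(gt_mesh, config$schedule$peak_traction_pa)
  def <- deform_scene(scene0, peak_tr, model, gt_mesh)
  du_beads <- def$scene$bead_positions - scene0$bead_positions
  du_scat <- if (!is.null(scene0$phantom_scatterers))
    def$scene$phantom_scatterers$positions -
    scene0$phantom_scatterers$positions else NULL
  f_true_peak <- total_force(peak_tr)$total_force_nn
  stage_t["setup"] <- tic() - t0
  say("setup: %d beads, truth mesh %d facets (%.1f s)",
      nrow(scene0$bead_positions), nrow(gt_mesh$cell_facets),
      stage_t["setup"])

  amps <- config$schedule$amplitude
  nt <- length(amps)
  bead_sets <- vector("list", nt)
  std_vols <- vector("list", nt)
  burst_offsets <- vector("list", nt)
  masks <- vector("list", nt)
  bpitch <- voxel_pitch(burst_geometry(geometry,
                                       factor = config$burst$factor))
  zf_ref <- NULL
  cg_map <- NULL
  zf_map <- NULL
  for (t in seq_len(nt)) {
    t0 <- tic()
    sc_t <- scene0
    sc_t$bead_positions <- scene0$bead_positions + amps[t] * du_beads
    if (!is.null(du_scat))
      sc_t$phantom_scatterers$positions <-
        scene0$phantom_scatterers$positions + amps[t] * du_scat
    raw <- simulate_spectra(sc_t, geometry,
                            noise_seed = config$seed + 1000L + t)
    vol <- reconstruct_volume(raw, window = "hann")
    # the coherence-gate and focal-depth maps are instrument properties:
    # estimate them on the first volume and reuse them for the whole time
    # lapse, so estimation noise cannot masquerade as bead motion
    cg <- remove_cg_curvature(vol, map = cg_map)
    vol <- cg$volume
    cg_map <- cg$map
    if (is.null(zf_map)) {
      vol <- register_focal_plane(vol, half_range = 10)
      zf_map <- vol$maps$focal_plane
    } else {
      vol <- register_focal_plane(vol, map = zf_map)
    }
    zf_ref <- vol$focal_depth
    vol <- phase_register(vol)$volume
    vol <- bulk_demodulate(vol)$volume
    vol <- apply_cao(vol)
    bead_sets[[t]] <- localize_beads(
      vol, min_voxels = config$tracking$min_voxels,
      max_size_quantile = config$tracking$max_size_quantile)
    stage_t[sprintf("image_t%d", t - 1L)] <- tic() - t0
    say("t=%d: volume formed (%s), %d beads (%.1f s)", t - 1L,
        paste(vol$corrections_applied, collapse = ","),
        nrow(bead_sets[[t]]), stage_t[sprintf("image_t%d", t - 1L)])
    # burst for segmentation
    t0 <- tic()
    burst <- simulate_burst(sc_t, geometry, n_repeats = config$burst$n_repeats,
                            factor = config$burst$factor)
    bvols <- lapply(burst, function(b) {
      v <- reconstruct_volume(b, window = "hann")
      v <- remove_cg_curvature(v)$volume
      v <- phase_register(v)$volume
      v <- bulk_demodulate(v)$volume
      apply_cao(v, focal_depth = zf_ref, force = TRUE)
    })
    std_vols[[t]] <- speckle_reduce(bvols)
    burst_offsets[[t]] <- burst[[1]]$geometry$offset_um
    masks[[t]] <- segment_cell(std_vols[[t]],
                               n_clusters = config$segmentation$n_clusters,
                               smooth_sigma = config$segmentation$smooth_sigma,
                               pitch = bpitch, offset_um = burst_offsets[[t]],
                               time_index = t - 1L)
    # dynamic intracellular speckle can masquerade as beads and hop between
    # time points; discard detections inside the dilated cell body, as the
    # size filters do for the connected cell at full scale
    inmask <- .points_in_mask(as.matrix(bead_sets[[t]][, c("z", "x", "y")]),
                              masks[[t]], dilate = 2L)
    bead_sets[[t]] <- bead_sets[[t]][!inmask, ]
    stage_t[sprintf("burst_t%d", t - 1L)] <- tic() - t0
  }

  t0 <- tic()
  tracks <- build_tracks(bead_sets,
                         far_field_radius = config$tracking$far_field_radius,
                         cell_centroid = ph$center,
                         t_minutes = config$schedule$t_minutes,
                         k_neighbors = config$tracking$k_neighbors)
  prof <- displacement_profile(tracks, cell_centroid = ph$center,
                               near_radius = config$tracking$near_radius)
  stage_t["tracking"] <- tic() - t0
  say("tracking: %d beads tracked (%.1f s)",
      length(unique(tracks$bead_id)), stage_t["tracking"])

  meshes <- vector("list", nt)
  ctf <- vector("list", nt)
  lambda_used <- config$solver$lambda
  # reference bead positions (complete tracks only)
  ref <- tracks[tracks$t_index == nt - 1L, ]
  complete <- table(tracks$bead_id[!is.na(tracks$uz)])
  keep_ids <- as.integer(names(complete)[complete == nt])
  ref <- ref[match(keep_ids, ref$bead_id), ]   # row order = keep_ids order
  bead_ref <- as.matrix(ref[, c("z", "x", "y")])
  # solve the largest-deformation time point first so the L-curve lambda
  # selected there can be reused across the series
  t_order <- order(-amps)
  for (t in t_order) {
    t0 <- tic()
    if (sum(masks[[t]]$voxels) < 8L) {
      say("t=%d: empty segmentation; skipping CTF", t - 1L)
      next
    }
    surf <- make_surface_mesh(masks[[t]],
                              smoothing_iters = config$mesh$smoothing_iters,
                              target_faces = config$mesh$target_faces)
    mesh_t <- make_volume_mesh(surf, geometry$fov_um, n = grid_n,
                               inside = .mask_inside_fn(masks[[t]], surf))
    meshes[[t]] <- mesh_t
    tt <- tracks[tracks$t_index == t - 1L & tracks$bead_id %in% keep_ids, ]
    tt <- tt[match(keep_ids, tt$bead_id), ]
    u_t <- as.matrix(tt[, c("uz", "ux", "uy")])
    prob <- build_forward_operator(mesh_t, bead_ref, model)
    u_use <- u_t[prob$bead_ok, , drop = FALSE]
    ctf[[t]] <- solve_tikhonov(prob, u_use, lambda = lambda_used,
                               u_char = config$solver$u_char)
    if (identical(lambda_used, "auto")) lambda_used <- ctf[[t]]$lambda
    stage_t[sprintf("ctf_t%d", t - 1L)] <- tic() - t0
    say("t=%d: %d facets, lambda %.3g, F = %.2f nN (%.1f s)", t - 1L,
        nrow(mesh_t$cell_facets), ctf[[t]]$lambda, ctf[[t]]$total_force_nn,
        stage_t[sprintf("ctf_t%d", t - 1L)])
  }
  ok_t <- !vapply(ctf, is.null, logical(1))
  summary_df <- summarize_timecourse(ctf[ok_t],
                                     t_minutes = config$schedule$t_minutes[ok_t])
  summary_df$t_index <- which(ok_t) - 1L
  summary_df$mean_u_near <- prof$near$mean_u_near[match(summary_df$t_index,
                                                        prof$near$t_index)]
  summary_df$schedule_amplitude <- amps[ok_t]

  ground_truth <- list(schedule = config$schedule,
                       total_force_true_nn = amps * f_true_peak,
                       du_beads_peak = du_beads,
                       bead_positions_ref = scene0$bead_positions,
                       phantom = phantom)
  manifest <- list(seed = config$seed, stages_sec = as.list(stage_t),
                   n_time_points = nt, lambda = lambda_used,
                   created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  out <- list(config = config, tracks = tracks, profile = prof$profile,
              near = prof$near, masks = masks, meshes = meshes, ctf = ctf,
              summary = summary_df, ground_truth = ground_truth,
              manifest = manifest)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    save_config(config, file.path(output_dir, "config.yaml"))
    write_tracks(tracks, file.path(output_dir, "tracks.csv"))
    utils::write.csv(prof$profile, file.path(output_dir, "profile.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_df, file.path(output_dir, "summary.csv"),
                     row.names = FALSE)
    for (t in which(ok_t)) {
      write_traction(ctf[[t]]$traction,
                     file.path(output_dir, sprintf("traction_t%02d.csv", t - 1L)))
      write_msh(meshes[[t]], file.path(output_dir, sprintf("mesh_t%02d.msh", t - 1L)))
    }
    files <- list.files(output_dir, full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$manifest <- manifest
  }
  out
}

# Fast inside test for the volume mesher: nearest-voxel lookup in the
# segmentation mask, with the surface mesh settling points near the boundary.
.mask_inside_fn <- function(mask, surf) {
  d <- dim(mask$voxels)
  function(p) {
    idx <- round(sweep(sweep(p, 2, mask$offset_um), 2, mask$pitch, "/")) + 1
    idx <- pmin(pmax(idx, 1), matrix(d, nrow(p), 3, byrow = TRUE))
    mask$voxels[cbind(idx[, 1], idx[, 2], idx[, 3])]
  }
}

# Points inside a (dilated) binary mask; points outside the mask crop are
# outside by definition.
.points_in_mask <- function(points, mask, dilate = 0L) {
  vox <- mask$voxels
  for (i in seq_len(dilate)) vox <- morph_dilate3(vox)
  d <- dim(vox)
  idx <- round(sweep(sweep(points, 2, mask$offset_um), 2, mask$pitch, "/")) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- rep(FALSE, nrow(points))
  out[ok] <- vox[idx[ok, , drop = FALSE]]
  out
}
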