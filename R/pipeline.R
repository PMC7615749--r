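#' Pipeline configuration
#'
#' Flat, typed key-value configuration; every analysis threshold is a key
#' whose default is the standard value used throughout the package.
#'
#' @param n_template_frames registration template frames.
#' @param upsample registration sub-pixel upsampling factor.
#' @param n_passes registration passes.
#' @param denoise logical; apply the two-step SVD denoiser to both channels.
#' @param patch_size,stride,group_size,rank1,rank2 denoiser settings.
#' @param baseline_window,stimulus_window 0-based inclusive frame ranges
#'   (NULL: baseline = frames before stimulus onset; stimulus = last two
#'   thirds).
#' @param soma_diameter,soma_offset soma detection settings (px, intensity).
#' @param smooth_sigma,threshold_k,min_consecutive,mad_to_sd transient
#'   detector settings.
#' @param r_max polar sampling radius (NULL: 2.5x the baseline vessel
#'   radius estimate).
#' @param kymo_min_amplitude,kymo_min_area endfoot event thresholds.
#' @param band_halfwidth kymograph radial averaging half-width, px.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_template_frames = 20, upsample = 10,
                            n_passes = 2, denoise = TRUE, patch_size = 8,
                            stride = 4, group_size = 4, rank1 = 4, rank2 = 8,
                            baseline_window = NULL, stimulus_window = NULL,
                            soma_diameter = 30, soma_offset = 10,
                            smooth_sigma = 1, threshold_k = 2.5,
                            min_consecutive = 3, mad_to_sd = 1.4826,
                            r_max = NULL, kymo_min_amplitude = 0.05,
                            kymo_min_area = 64, band_halfwidth = 2) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on a two-channel movie
#'
#' Register (vascular-channel template), optionally denoise both channels,
#' extract the vessel diameter trace and response metrics along the line
#' scan, detect somata and their Ca2+ transients, track the endfoot and
#' detect kymograph events, and aggregate a recording summary.
#'
#' @param movie a [two_channel_movie()].
#' @param line a [line_scan()] across the vessel.
#' @param config a [pipeline_config()].
#' @param recording_id identifier used in output tables.
#' @param roi_mask optional manual ROI label image overriding automatic soma
#'   detection (manual curation hook).
#' @return list with `registered`, `shifts`, `diameter`, `vessel_metrics`,
#'   `rois`, `soma`, `kymograph`, `endfoot_events`, `summary`.
#' @export
run_pipeline <- function(movie, line, config = pipeline_config(),
                         recording_id = "recording", roi_mask = NULL) {
  cfg <- config
  T <- n_frames(movie)
  sw <- cfg$stimulus_window %||% c(floor(T / 3), T - 1)
  bw <- cfg$baseline_window %||% c(0, max(0, sw[1] - 1))

  reg <- register_movie(movie, n_template_frames = cfg$n_template_frames,
                        upsample = cfg$upsample, n_passes = cfg$n_passes)
  work <- reg$movie
  if (isTRUE(cfg$denoise)) {
    d <- dim(work)
    grid <- patch_grid(d[1], d[2], cfg$patch_size, cfg$stride, cfg$group_size)
    work$vascular <- two_step_denoise(work$vascular, grid, cfg$rank1, cfg$rank2)
    work$activity <- two_step_denoise(work$activity, grid, cfg$rank1, cfg$rank2)
  }

  diam <- diameter_timeseries(work, line, baseline_window = bw,
                              stimulus_window = sw)
  vm <- response_metrics(diam)

  # lumen mask (baseline frame), dilated to cover the perivascular ring, is
  # excluded from soma detection
  centers <- attr(diam, "centers")
  base_r <- vm$baseline_px / 2
  r_max <- cfg$r_max %||% ceiling(2.5 * base_r)
  ref <- apply(work$activity, c(1, 2), mean)
  lumen_full <- matrix(0, dim(work)[1], dim(work)[2])
  m1 <- attr(diam, "masks")[[which(diam$valid)[1]]]
  off <- attr(diam, "crop_origin")
  lumen_full[off[1] + seq_len(nrow(m1)), off[2] + seq_len(ncol(m1))] <- m1
  excl <- as_matrix(EBImage::dilate(
    lumen_full != 0,
    EBImage::makeBrush(2 * ceiling(r_max / 2) + 1, shape = "disc")))
  rois <- roi_mask %||% detect_somata(ref, soma_diameter = cfg$soma_diameter,
                                      offset = cfg$soma_offset,
                                      lumen_mask = excl)
  soma <- if (max(rois) > 0) {
    detect_all_transients(work$activity, rois,
                          detection_params(cfg$smooth_sigma, cfg$threshold_k,
                                           cfg$min_consecutive, cfg$mad_to_sd),
                          baseline_window = bw)
  } else NULL

  kymo <- build_kymograph(work$activity, centers, r_max = r_max,
                          baseline_window = bw,
                          band_halfwidth = cfg$band_halfwidth)
  ef_events <- detect_kymo_events(kymo, cfg$kymo_min_amplitude,
                                  cfg$kymo_min_area)

  summ <- summarize_recording(recording_id, vessel_metrics = vm,
                              diameter_trace = diam, soma = soma,
                              endfoot_events = ef_events,
                              stimulus_window = sw, n_frames = T)
  list(registered = reg$movie, shifts = reg$shifts, diameter = diam,
       vessel_metrics = vm, rois = rois, soma = soma, kymograph = kymo,
       endfoot_events = ef_events, summary = summ)
}

#' Write all pipeline outputs to a directory
#'
#' Tidy CSVs (shifts, diameter trace, per-ROI table, soma events, endfoot
#' events, kymograph dF/F and tracked radius) plus a summary JSON and a file
#' manifest; deterministic content for fixed inputs.
#'
#' @param result list from [run_pipeline()].
#' @param out_dir output directory.
#' @return invisibly, the manifest data frame.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kdff <- as.data.frame(round(result$kymograph$dff, 6))
  names(kdff) <- paste0("t", seq_len(ncol(kdff)) - 1)
  krad <- as.data.frame(result$kymograph$radius)
  names(krad) <- names(kdff)
  tabs <- list(
    shifts = result$shifts,
    diameters = as.data.frame(result$diameter),
    rois = result$summary$rois,
    soma_events = result$summary$soma_events,
    endfoot_events = result$summary$endfoot_events,
    kymograph_dff = kdff,
    kymograph_radius = krad
  )
  manifest <- write_tables(tabs, out_dir)
  jsonlite::write_json(result$summary$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

#' Write generator ground truth as plain-text tables
#'
#' @param truth ground-truth list from [simulate_movie()].
#' @param out_dir output directory.
#' @return invisibly, the manifest data frame.
#' @export
write_ground_truth <- function(truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  er <- as.data.frame(truth$endfoot_radius)
  names(er) <- paste0("t", seq_len(ncol(er)) - 1)
  idx <- which(truth$soma_masks > 0, arr.ind = TRUE)
  write_tables(list(
    drift = data.frame(frame = seq_len(nrow(truth$drift)) - 1,
                       dy = truth$drift[, 1], dx = truth$drift[, 2]),
    diameter = data.frame(frame = seq_along(truth$diameter_px) - 1,
                          diameter_px = truth$diameter_px),
    soma_events = truth$soma_events,
    endfoot_events = truth$endfoot_events,
    endfoot_radius = er,
    soma_masks = data.frame(row = idx[, 1] - 1, col = idx[, 2] - 1,
                            label = truth$soma_masks[idx])
  ), out_dir)
}
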