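#' Detect astrocyte cell bodies by adaptive thresholding
#'
#' Local-mean adaptive threshold on a 2-D reference image (typically the
#' temporal mean of the activity channel), followed by connected-component
#' labelling, an area filter, exclusion of components touching the vessel
#' lumen, and a watershed split (on the distance transform) of components
#' more than twice the median soma area, which separates somata merged by
#' blur.
#'
#' @param reference 2-D reference image.
#' @param soma_diameter expected soma diameter, px; the adaptive window is
#'   about twice this.
#' @param offset additive offset of the local-mean threshold (intensity
#'   units).
#' @param area_range acceptable component area, px^2; default derived from
#'   `soma_diameter` (0.25x to 2.5x the nominal disc area).
#' @param lumen_mask optional binary mask of the vessel lumen; components
#'   touching it are removed.
#' @return `H x W` integer label matrix (0 = background) of class `roi_mask`
#'   with attribute `provenance = "detected"`. Empty (all-zero) with a
#'   warning when nothing is found.
#' @export
detect_somata <- function(reference, soma_diameter = 30, offset = 10,
                          area_range = NULL, lumen_mask = NULL) {
  nominal <- pi * (soma_diameter / 2)^2
  if (is.null(area_range)) area_range <- c(0.25, 2.5) * nominal
  w <- max(3L, round(soma_diameter))  # half-width => window ~2x diameter
  bin <- as_matrix(EBImage::thresh(reference / max(reference),
                                   w = w, h = w,
                                   offset = offset / max(reference)))
  bin <- as_matrix(EBImage::fillHull(bin != 0))
  if (!is.null(lumen_mask)) {
    lab0 <- as_matrix(EBImage::bwlabel(bin != 0))
    drop <- setdiff(unique(lab0[lumen_mask != 0]), 0)
    bin[lab0 %in% drop] <- 0
  }
  lab <- as_matrix(EBImage::bwlabel(bin != 0))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= area_range[1] & areas <= area_range[2])
  # split unusually large components (likely merged somata); the reference
  # area is the median detected soma, or the nominal disc when too few
  med_area <- if (length(keep) >= 3) median(areas[keep]) else nominal
  big <- which(areas > area_range[2] | areas > 2 * med_area)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nxt <- 0L
  for (k in keep[!(keep %in% big)]) {
    nxt <- nxt + 1L
    out[lab == k] <- nxt
  }
  for (k in big) {
    comp <- lab == k
    dm <- EBImage::distmap(comp)
    ws <- as_matrix(EBImage::watershed(dm, tolerance = 1))
    for (s in setdiff(unique(ws[comp]), 0)) {
      piece <- ws == s & comp
      a <- sum(piece)
      if (a >= area_range[1] && a <= area_range[2]) {
        nxt <- nxt + 1L
        out[piece] <- nxt
      }
    }
  }
  if (nxt == 0L) warning("no somata detected", call. = FALSE)
  structure(out, class = c("roi_mask", class(out)), provenance = "detected")
}

#' Mean-intensity traces of labelled ROIs
#'
#' @param channel `H x W x T` array (activity channel).
#' @param roi_mask integer label image (0 = background).
#' @return `T x n_roi` matrix; column `i` is the unweighted mean over the
#'   pixels of label `i`.
#' @export
roi_traces <- function(channel, roi_mask) {
  labs <- sort(setdiff(unique(as.integer(roi_mask)), 0L))
  T <- dim(channel)[3]
  out <- matrix(NA_real_, T, length(labs))
  colnames(out) <- labs
  flat <- matrix(channel, ncol = T)
  for (j in seq_along(labs)) {
    idx <- which(roi_mask == labs[j])
    out[, j] <- colMeans(flat[idx, , drop = FALSE])
  }
  out
}

#' Fractional fluorescence change of a raw trace
#'
#' `dF/F = (F - F0) / F0` with `F0` the median of the baseline window
#' (default) or a percentile of the whole trace.
#'
#' @param raw_trace numeric vector of raw intensities.
#' @param baseline_window 0-based inclusive frame range used for `F0`
#'   (default: whole trace).
#' @param f0_method `"baseline_median"` or `"percentile"`.
#' @param percentile percentile of the whole trace used when
#'   `f0_method = "percentile"`.
#' @param roi_id optional label carried through.
#' @return list of class `dff_trace`: `dff`, `baseline_f0`, `roi_id`.
#' @export
compute_dff <- function(raw_trace, baseline_window = NULL,
                        f0_method = c("baseline_median", "percentile"),
                        percentile = 0.2, roi_id = NA_integer_) {
  f0_method <- match.arg(f0_method)
  n <- length(raw_trace)
  f0 <- if (f0_method == "baseline_median") {
    bw <- baseline_window %||% c(0, n - 1)
    median(raw_trace[(bw[1]:bw[2]) + 1])
  } else {
    as.numeric(quantile(raw_trace, percentile))
  }
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline F0 must be positive", call. = FALSE)
  structure(list(dff = (raw_trace - f0) / f0, baseline_f0 = f0,
                 roi_id = roi_id), class = "dff_trace")
}

#' Transient detection parameters
#'
#' @param smooth_sigma Gaussian smoothing SD, frames (default 1).
#' @param threshold_k threshold in robust SD units (default 2.5).
#' @param min_consecutive minimum suprathreshold run, frames (default 3).
#' @param mad_to_sd MAD-to-SD scale constant (default 1.4826, consistent with
#'   a Gaussian).
#' @return list of class `detection_params`.
#' @export
detection_params <- function(smooth_sigma = 1, threshold_k = 2.5,
                             min_consecutive = 3, mad_to_sd = 1.4826) {
  stopifnot(smooth_sigma > 0, threshold_k > 0, min_consecutive > 0,
            mad_to_sd > 0)
  structure(list(smooth_sigma = smooth_sigma, threshold_k = threshold_k,
                 min_consecutive = min_consecutive, mad_to_sd = mad_to_sd),
            class = "detection_params")
}

#' Detect Ca2+ transients in a dF/F trace
#'
#' The trace is Gaussian-smoothed (`smooth_sigma` frames); the noise scale is
#' the MAD of the raw (unsmoothed) baseline scaled by `mad_to_sd`; an event
#' is a maximal run of frames with smoothed dF/F above `threshold_k` robust
#' SDs lasting at least `min_consecutive` frames. Estimating the scale on the
#' raw trace keeps the threshold calibrated: the smoothed noise is strongly
#' autocorrelated and its own SD would admit chance runs of three frames far
#' more often than the nominal 2.5-SD level suggests.
#'
#' @param dff a `dff_trace` from [compute_dff()] or a numeric vector.
#' @param params a [detection_params()].
#' @param baseline_window 0-based inclusive frame range on which the noise
#'   scale is estimated (default: whole trace).
#' @return data frame with `roi_id`, `onset_frame`, `offset_frame` (0-based,
#'   inclusive), `peak_dff`, `peak_frame`, sorted by onset; attribute
#'   `degenerate` is TRUE when the noise scale was zero (noiseless input), in
#'   which case the threshold falls back to dF/F > 0.
#' @export
detect_transients <- function(dff, params = detection_params(),
                              baseline_window = NULL) {
  x <- if (inherits(dff, "dff_trace")) dff$dff else as.numeric(dff)
  roi <- if (inherits(dff, "dff_trace")) dff$roi_id else NA_integer_
  n <- length(x)
  if (n <= params$min_consecutive)
    stop("trace shorter than min_consecutive", call. = FALSE)
  sm <- smooth_gauss(x, params$smooth_sigma)
  bw <- baseline_window %||% c(0, n - 1)
  base <- x[(bw[1]:bw[2]) + 1]
  sigma_hat <- params$mad_to_sd * median(abs(base - median(base)))
  degenerate <- sigma_hat == 0
  thr <- if (degenerate) 0 else params$threshold_k * sigma_hat
  runs <- true_runs(sm > thr)
  runs <- runs[runs$end - runs$start + 1 >= params$min_consecutive, , drop = FALSE]
  ev <- data.frame(roi_id = rep(roi, nrow(runs)),
                   onset_frame = runs$start - 1L,
                   offset_frame = runs$end - 1L,
                   peak_dff = numeric(nrow(runs)),
                   peak_frame = integer(nrow(runs)))
  for (i in seq_len(nrow(runs))) {
    seg <- runs$start[i]:runs$end[i]
    ev$peak_dff[i] <- max(sm[seg])
    ev$peak_frame[i] <- seg[which.max(sm[seg])] - 1L
  }
  structure(ev[order(ev$onset_frame), , drop = FALSE],
            degenerate = degenerate, sigma_hat = sigma_hat, threshold = thr)
}

#' Detect transients for every ROI of a movie
#'
#' Convenience wrapper: extracts ROI mean traces, converts them to dF/F and
#' runs the transient detector per ROI.
#'
#' @param channel `H x W x T` activity array.
#' @param roi_mask integer label image.
#' @param params a [detection_params()].
#' @param baseline_window 0-based inclusive frame range for F0 and the noise
#'   scale.
#' @return list with `events` (row-bound event table), `dff` (`T x n_roi`
#'   matrix) and `roi_ids`.
#' @export
detect_all_transients <- function(channel, roi_mask,
                                  params = detection_params(),
                                  baseline_window = NULL) {
  tr <- roi_traces(channel, roi_mask)
  ids <- as.integer(colnames(tr))
  dmat <- matrix(NA_real_, nrow(tr), ncol(tr))
  evs <- list()
  for (j in seq_along(ids)) {
    d <- compute_dff(tr[, j], baseline_window = baseline_window,
                     roi_id = ids[j])
    dmat[, j] <- d$dff
    evs[[j]] <- detect_transients(d, params, baseline_window = baseline_window)
  }
  events <- do.call(rbind, evs)
  colnames(dmat) <- ids
  list(events = events, dff = dmat, roi_ids = ids)
}

#' Time-binned fraction of active ROIs
#'
#' An ROI counts as active in a bin if at least one of its event frames falls
#' inside the bin (an event spanning two bins counts in both). Also reports
#' the overall responder fraction: ROIs with at least one event frame inside
#' the stimulus window.
#'
#' @param events event table from [detect_transients()] /
#'   [detect_all_transients()].
#' @param roi_ids integer vector of all ROI labels (including silent ones).
#' @param n_frames recording length.
#' @param bin_width bin width, frames.
#' @param stimulus_window 0-based inclusive frame range of the stimulus
#'   (default: whole recording).
#' @return list with `bins` (data frame `bin_start`, `bin_end`,
#'   `fraction_active`) and `responder_fraction`.
#' @export
active_fraction <- function(events, roi_ids, n_frames, bin_width = 10,
                            stimulus_window = NULL) {
  if (length(roi_ids) == 0) stop("empty ROI set", call. = FALSE)
  sw <- stimulus_window %||% c(0, n_frames - 1)
  starts <- seq(0, n_frames - 1, by = bin_width)
  ends <- pmin(starts + bin_width - 1, n_frames - 1)
  frac <- vapply(seq_along(starts), function(b) {
    act <- events$roi_id[events$onset_frame <= ends[b] &
                         events$offset_frame >= starts[b]]
    length(intersect(unique(act), roi_ids)) / length(roi_ids)
  }, numeric(1))
  resp <- events$roi_id[events$onset_frame <= sw[2] &
                        events$offset_frame >= sw[1]]
  list(bins = data.frame(bin_start = starts, bin_end = ends,
                         fraction_active = frac),
       responder_fraction = length(intersect(unique(resp), roi_ids)) /
         length(roi_ids))
}
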