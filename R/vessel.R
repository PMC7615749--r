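#' Line scan across a vessel
#'
#' Two endpoints in the global 0-based `(row, col)` pixel-centre convention,
#' drawn across the widest part of the vessel.
#'
#' @param p0,p1 numeric `(row, col)` endpoints.
#' @param frame_dim optional `(H, W)` for bounds checking.
#' @return object of class `line_scan`.
#' @export
line_scan <- function(p0, p1, frame_dim = NULL) {
  if (all(p0 == p1)) stop("line endpoints must be distinct", call. = FALSE)
  if (!is.null(frame_dim)) {
    for (p in list(p0, p1))
      if (any(p < 0) || p[1] > frame_dim[1] - 1 || p[2] > frame_dim[2] - 1)
        stop("line endpoints must lie inside the frame", call. = FALSE)
  }
  structure(list(p0 = as.numeric(p0), p1 = as.numeric(p1)), class = "line_scan")
}

line_midpoint <- function(line) (line$p0 + line$p1) / 2

# --- morphological Chan-Vese -------------------------------------------------

dilate3 <- function(u) {
  out <- u
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- pmax(out, shift_mat(u, dr, dc))
  out
}

erode3 <- function(u) {
  out <- u
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- pmin(out, shift_mat(u, dr, dc))
  out
}

# Curvature-like smoothing operators built from sup/inf along the four
# 3-pixel line segments through each pixel.
seg_ops <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))

sup_inf <- function(u) {
  res <- matrix(-Inf, nrow(u), ncol(u))
  for (s in seg_ops) {
    m <- pmin(shift_mat(u, s[1], s[2]), u, shift_mat(u, -s[1], -s[2]))
    res <- pmax(res, m)
  }
  res
}

inf_sup <- function(u) {
  res <- matrix(Inf, nrow(u), ncol(u))
  for (s in seg_ops) {
    m <- pmax(shift_mat(u, s[1], s[2]), u, shift_mat(u, -s[1], -s[2]))
    res <- pmin(res, m)
  }
  res
}

#' Two-phase Chan-Vese segmentation (morphological level set)
#'
#' Minimizes the region-mean (piecewise-constant) Chan-Vese energy: pixels are
#' attached to the foreground or background mean intensity, with the contour
#' length penalty realized by alternating morphological sup-inf/inf-sup
#' smoothing of the level-set indicator.
#'
#' @param img numeric matrix.
#' @param init logical/0-1 matrix, the initial foreground.
#' @param max_iter iteration cap.
#' @param smoothing smoothing sweeps per iteration (contour regularity).
#' @param lambda1,lambda2 weights of the inside/outside variance terms.
#' @return binary matrix (1 = foreground).
#' @export
chan_vese <- function(img, init, max_iter = 40, smoothing = 1,
                      lambda1 = 1, lambda2 = 1) {
  u <- (init > 0) * 1
  for (it in seq_len(max_iter)) {
    inside <- u > 0
    if (!any(inside) || all(inside)) break
    c1 <- mean(img[inside]); c2 <- mean(img[!inside])
    grad <- dilate3(u) - erode3(u)
    aux <- grad * (lambda1 * (img - c1)^2 - lambda2 * (img - c2)^2)
    u_new <- u
    u_new[aux < 0] <- 1
    u_new[aux > 0] <- 0
    for (s in seq_len(smoothing))
      u_new <- if (it %% 2 == 0) sup_inf(inf_sup(u_new)) else inf_sup(sup_inf(u_new))
    if (all(u_new == u)) { u <- u_new; break }
    u <- u_new
  }
  u
}

#' Segment the vessel lumen around a line scan
#'
#' Chan-Vese active-contour segmentation of the bright lumen, initialized from
#' an intensity threshold in a band around the line and constrained to the
#' single connected component intersecting the line (hole-filled).
#'
#' @param frame vascular-channel frame (matrix).
#' @param line a [line_scan()].
#' @param init optional binary matrix initializing the contour (e.g. the
#'   previous frame's mask, for temporal coherence).
#' @param band_halfwidth half-width of the initialization band around the
#'   line, px.
#' @param max_iter,smoothing passed to [chan_vese()].
#' @return list with `mask` (binary matrix) and `valid` (FALSE when no
#'   component intersects the line; the mask is then empty).
#' @export
segment_lumen <- function(frame, line, init = NULL, band_halfwidth = 10,
                          max_iter = 40, smoothing = 1) {
  H <- nrow(frame); W <- ncol(frame)
  if (is.null(init)) {
    # threshold at the midpoint of the intensity range within a band
    # around the line
    s <- seq(0, 1, length.out = 200)
    pr <- outer(1 - s, line$p0[1]) + outer(s, line$p1[1])
    pc <- outer(1 - s, line$p0[2]) + outer(s, line$p1[2])
    band <- matrix(FALSE, H, W)
    for (o in seq(-band_halfwidth, band_halfwidth, by = 1)) {
      # offset the line along its normal
      dr <- line$p1 - line$p0
      nrm <- c(-dr[2], dr[1]) / sqrt(sum(dr^2))
      rr <- round(pr + o * nrm[1]) + 1
      cc <- round(pc + o * nrm[2]) + 1
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      band[cbind(rr[ok], cc[ok])] <- TRUE
    }
    vals <- frame[band]
    thr <- (max(vals) + min(vals)) / 2
    init <- (frame > thr) & band
  }
  if (!any(init != 0)) {
    return(list(mask = matrix(0, H, W), valid = FALSE))
  }
  mask <- chan_vese(frame, init, max_iter = max_iter, smoothing = smoothing)
  if (!any(mask > 0)) return(list(mask = matrix(0, H, W), valid = FALSE))
  mask <- as_matrix(EBImage::fillHull(mask != 0))
  lab <- as_matrix(EBImage::bwlabel(mask != 0))
  # component intersecting the line midpoint, else any component the line hits
  mid <- round(line_midpoint(line)) + 1
  keep <- if (mid[1] >= 1 && mid[1] <= H && mid[2] >= 1 && mid[2] <= W)
    lab[mid[1], mid[2]] else 0
  if (keep == 0) {
    s <- seq(0, 1, length.out = 400)
    rr <- round((1 - s) * line$p0[1] + s * line$p1[1]) + 1
    cc <- round((1 - s) * line$p0[2] + s * line$p1[2]) + 1
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    hits <- lab[cbind(rr[ok], cc[ok])]
    hits <- hits[hits > 0]
    if (length(hits) == 0) return(list(mask = matrix(0, H, W), valid = FALSE))
    keep <- as.integer(names(sort(table(hits), decreasing = TRUE))[1])
  }
  list(mask = (lab == keep) * 1, valid = TRUE)
}

#' Vessel diameter from a lumen mask along a line scan
#'
#' The mask is sampled bilinearly along the line at 0.25-px steps; the
#' diameter is the length of the longest contiguous run with interpolated
#' coverage at least 0.5.
#'
#' @param mask binary lumen mask.
#' @param line a [line_scan()].
#' @param pixel_size micrometres per pixel (for the `um` element).
#' @param step sampling step along the line, px.
#' @return list `px`, `um`, `valid`.
#' @export
diameter_from_mask <- function(mask, line, pixel_size = 1, step = 0.25) {
  L <- sqrt(sum((line$p1 - line$p0)^2))
  n <- max(2L, floor(L / step) + 1L)
  s <- seq(0, L, length.out = n)
  u <- (line$p1 - line$p0) / L
  rr <- line$p0[1] + s * u[1] + 1
  cc <- line$p0[2] + s * u[2] + 1
  v <- bilinear_sample(mask, rr, cc, fill = 0)
  runs <- true_runs(v >= 0.5)
  if (nrow(runs) == 0) return(list(px = NA_real_, um = NA_real_, valid = FALSE))
  len <- (runs$end - runs$start) * (s[2] - s[1])
  px <- max(len)
  list(px = px, um = px * pixel_size, valid = TRUE)
}

#' Per-frame vessel diameter time series
#'
#' Segments the lumen in every frame of the (registered) vascular channel,
#' initializing each frame's contour from the previous frame's mask, and
#' measures the diameter along the line scan. Frames whose mask area jumps by
#' more than `max_area_change` relative to the previous accepted frame are
#' flagged invalid and the previous mask is carried forward.
#'
#' @param movie a [two_channel_movie()] (registered).
#' @param line a [line_scan()].
#' @param baseline_window,stimulus_window 0-based inclusive frame ranges
#'   `c(first, last)`; defaults: baseline = all frames before
#'   `stimulus_window[1]`, stimulus = last two thirds of the recording.
#' @param max_area_change per-frame fractional area-change cap (default 0.3).
#' @param crop_margin margin around the previous mask used to crop the
#'   working window, px.
#' @param ... passed to [segment_lumen()].
#' @return object of class `diameter_trace`: data frame with `frame`, `time`,
#'   `diameter_px`, `diameter_um`, `valid`, plus attributes `baseline_window`,
#'   `stimulus_window`, `masks` (list of lumen masks) and `centers`
#'   (`T x 2` lumen centroids, 0-based).
#' @export
diameter_timeseries <- function(movie, line, baseline_window = NULL,
                                stimulus_window = NULL, max_area_change = 0.3,
                                crop_margin = 25, ...) {
  stopifnot(inherits(movie, "two_channel_movie"))
  T <- n_frames(movie)
  if (is.null(stimulus_window)) stimulus_window <- c(floor(T / 3), T - 1)
  if (is.null(baseline_window)) baseline_window <- c(0, max(0, stimulus_window[1] - 1))
  H <- dim(movie)[1]; W <- dim(movie)[2]
  diam <- rep(NA_real_, T)
  valid <- logical(T)
  masks <- vector("list", T)
  centers <- matrix(NA_real_, T, 2)
  prev_mask <- NULL
  prev_area <- NA_real_
  # fixed working window around the line (the vessel cannot leave it after
  # registration); keeps the per-frame contour evolution cheap
  r0 <- max(1, floor(min(line$p0[1], line$p1[1])) + 1 - crop_margin)
  r1 <- min(H, ceiling(max(line$p0[1], line$p1[1])) + 1 + crop_margin)
  c0 <- max(1, floor(min(line$p0[2], line$p1[2])) + 1 - crop_margin)
  c1 <- min(W, ceiling(max(line$p0[2], line$p1[2])) + 1 + crop_margin)
  line_c <- line_scan(line$p0 - c(r0 - 1, c0 - 1), line$p1 - c(r0 - 1, c0 - 1))
  for (t in seq_len(T)) {
    frame <- movie$vascular[r0:r1, c0:c1, t]
    seg <- segment_lumen(frame, line_c, init = prev_mask, ...)
    ok <- seg$valid
    area <- sum(seg$mask)
    if (ok && !is.na(prev_area) && prev_area > 0) {
      if (abs(area - prev_area) / prev_area > max_area_change) ok <- FALSE
    }
    if (ok) {
      d <- diameter_from_mask(seg$mask, line_c, movie$pixel_size)
      ok <- d$valid
      if (ok) {
        diam[t] <- d$px
        masks[[t]] <- seg$mask
        prev_mask <- seg$mask
        prev_area <- area
        idx <- which(seg$mask > 0, arr.ind = TRUE)
        centers[t, ] <- colMeans(idx) - 1 + c(r0 - 1, c0 - 1)
      }
    }
    if (!ok && !is.null(prev_mask)) {
      masks[[t]] <- prev_mask  # carry forward for downstream stages
      idx <- which(prev_mask > 0, arr.ind = TRUE)
      centers[t, ] <- colMeans(idx) - 1 + c(r0 - 1, c0 - 1)
    }
    valid[t] <- ok
  }
  if (mean(valid) < 0.5)
    stop("more than 50% of frames could not be segmented", call. = FALSE)
  df <- data.frame(frame = 0:(T - 1), time = (0:(T - 1)) * movie$frame_interval,
                   diameter_px = diam,
                   diameter_um = diam * movie$pixel_size, valid = valid)
  structure(df, class = c("diameter_trace", "data.frame"),
            baseline_window = baseline_window,
            stimulus_window = stimulus_window,
            masks = masks, centers = centers,
            crop_origin = c(r0 - 1, c0 - 1),
            frame_interval = movie$frame_interval)
}

#' Peak and area-under-curve response metrics of a diameter trace
#'
#' Computes the fractional change `f(t) = (d(t) - mean_baseline) /
#' mean_baseline` on valid frames; `peak_percent` is `100 * max f` over the
#' response window and `auc` the trapezoidal integral of `f` over the
#' response window divided by the window duration (so values are
#' scale-comparable across recordings; only relative comparisons across
#' conditions are meaningful).
#'
#' @param trace a [diameter_trace()] result, or a data frame with `frame`,
#'   `time`, `diameter_px`, `valid`.
#' @param baseline_window,response_window 0-based inclusive frame ranges;
#'   defaults come from the trace attributes (response = stimulus onset to
#'   end of recording).
#' @param median_filter odd window (frames) of a running median applied to
#'   the diameter trace before the metrics, suppressing single-frame
#'   segmentation jitter; `1` disables it.
#' @return list `peak_percent`, `auc`, `baseline_px`, plus the fractional
#'   change series `f` and windows used.
#' @export
response_metrics <- function(trace, baseline_window = NULL,
                             response_window = NULL, median_filter = 3) {
  bw <- baseline_window %||% attr(trace, "baseline_window")
  sw <- attr(trace, "stimulus_window")
  rw <- response_window %||% c(sw[1] %||% 0, max(trace$frame))
  if (is.null(bw)) stop("baseline_window must be supplied", call. = FALSE)
  dpx <- trace$diameter_px
  if (median_filter > 1 && sum(trace$valid) > median_filter) {
    dpx[trace$valid] <- stats::runmed(dpx[trace$valid], k = median_filter,
                                      endrule = "median")
  }
  base <- dpx[trace$valid & trace$frame >= bw[1] & trace$frame <= bw[2]]
  if (length(base) == 0 || mean(base) <= 0)
    stop("baseline window has no valid frames or non-positive diameter", call. = FALSE)
  d0 <- mean(base)
  sel <- trace$valid & trace$frame >= rw[1] & trace$frame <= rw[2]
  f <- (dpx[sel] - d0) / d0
  tt <- trace$time[sel]
  if (length(f) < 2) stop("response window has too few valid frames", call. = FALSE)
  auc <- pracma::trapz(tt, f) / (tt[length(tt)] - tt[1])
  list(peak_percent = 100 * max(f), auc = auc, baseline_px = d0,
       f = f, time = tt, baseline_window = bw, response_window = rw)
}

#' Full width at half maximum diameter estimate along a line scan
#'
#' Secondary estimator: the intensity profile along the line is sampled at
#' 0.25-px steps and the diameter is the width of the longest run above the
#' half-maximum level (baseline taken as the profile minimum).
#'
#' @param frame vascular-channel frame.
#' @param line a [line_scan()].
#' @param pixel_size micrometres per pixel.
#' @return list `px`, `um`, `valid`.
#' @export
diameter_fwhm <- function(frame, line, pixel_size = 1) {
  L <- sqrt(sum((line$p1 - line$p0)^2))
  n <- max(2L, floor(L / 0.25) + 1L)
  s <- seq(0, L, length.out = n)
  u <- (line$p1 - line$p0) / L
  prof <- bilinear_sample(frame, line$p0[1] + s * u[1] + 1,
                          line$p0[2] + s * u[2] + 1, fill = NA)
  prof[is.na(prof)] <- min(prof, na.rm = TRUE)
  half <- (max(prof) + min(prof)) / 2
  runs <- true_runs(prof >= half)
  if (nrow(runs) == 0) return(list(px = NA_real_, um = NA_real_, valid = FALSE))
  px <- max((runs$end - runs$start) * (s[2] - s[1]))
  list(px = px, um = px * pixel_size, valid = TRUE)
}
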