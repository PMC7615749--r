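#' Smooth dilation pulse profile
#'
#' Per-frame fractional diameter change emulating a brief systemic stimulus:
#' baseline, half-cosine rise, plateau, half-cosine recovery. Units are
#' fractional change (0.36 = +36 percent).
#'
#' @param n_frames recording length in frames.
#' @param onset first frame of the rise (0-based).
#' @param rise,plateau,fall segment durations in frames.
#' @param peak peak fractional diameter change.
#' @return numeric vector of length `n_frames`.
#' @export
dilation_pulse <- function(n_frames, onset = round(n_frames / 3),
                           rise = 25, plateau = 30, fall = 60, peak = 0.36) {
  t <- seq_len(n_frames) - 1
  p <- numeric(n_frames)
  up <- t >= onset & t < onset + rise
  p[up] <- peak * 0.5 * (1 - cos(pi * (t[up] - onset) / rise))
  flat <- t >= onset + rise & t < onset + rise + plateau
  p[flat] <- peak
  dn <- t >= onset + rise + plateau & t < onset + rise + plateau + fall
  p[dn] <- peak * 0.5 * (1 + cos(pi * (t[dn] - onset - rise - plateau) / fall))
  attr(p, "stimulus_window") <- c(onset, min(n_frames - 1, onset + rise + plateau + fall))
  p
}

#' Simulation parameters for the synthetic two-channel movie generator
#'
#' Defaults emulate a ~5 min recording at 1 Hz of a penetrating arteriole
#' (bright tube in the vascular channel) dilating by 36 percent in response
#' to a ~1 min stimulus, wrapped by an astrocyte endfoot annulus and
#' surrounded by somata with exponential-decay Ca2+ transients, under rigid
#' in-plane drift and mixed Gaussian/Poisson noise.
#'
#' @param height,width frame size in pixels.
#' @param n_frames number of frames.
#' @param frame_interval seconds per frame.
#' @param pixel_size micrometres per pixel.
#' @param vessel_center `(row, col)` 0-based pixel-centre coordinates.
#' @param baseline_radius vessel lumen radius at rest, px; the default
#'   (16 px at 0.25 um/px) renders the ~8 um resting penetrating arteriole
#'   with enough spatial sampling for sub-pixel diameter recovery.
#' @param dilation_profile per-frame fractional diameter change (length
#'   `n_frames`); default [dilation_pulse()].
#' @param endfoot_gap gap between lumen edge and endfoot annulus, px.
#' @param endfoot_thickness annulus full width (FWHM of its Gaussian radial
#'   cross-section), px.
#' @param n_somata number of astrocyte cell bodies.
#' @param soma_radius_range min/max soma radius, px.
#' @param event_rate expected Ca2+ transients per soma per recording.
#' @param transient_amplitude transient peak, dF/F units.
#' @param transient_decay_tau transient decay constant, seconds.
#' @param endfoot_event_rate expected endfoot Ca2+ events per recording.
#' @param endfoot_event_amplitude endfoot event peak, dF/F units.
#' @param drift_amplitude maximum rigid drift excursion, px.
#' @param drift_mode `"smooth"` (low-pass-filtered random walk, fractional)
#'   or `"integer"` (same walk rounded to whole pixels).
#' @param noise_sigma Gaussian noise SD, intensity units.
#' @param photon_gain intensity per photon for the optional Poisson component;
#'   `0` disables it (Gaussian-only default).
#' @param seed RNG seed (all randomness in the generator derives from it).
#' @param noise_seed optional separate seed for the noise stream; with a fixed
#'   `seed` and varying `noise_seed`, movies share drift, geometry and event
#'   schedules and differ in the noise realization only. Default
#'   `seed + 500000`.
#' @param vessel_intensity,background,endfoot_intensity,soma_intensity,
#'   activity_background baseline intensity levels.
#' @param texture_sd SD of the static, spatially smooth background texture
#'   (out-of-focus capillaries and plasma fluorescence) rendered into the
#'   vascular channel; it drifts with the field and is what anchors rigid
#'   registration in real recordings, where the scene is never a bare
#'   symmetric tube. The activity channel receives a 0.3x weaker copy:
#'   Ca2+-indicator neuropil staining is diffuse and low-contrast compared
#'   with an intravascular dye.
#' @return a list of class `sim_params`, validated.
#' @export
sim_params <- function(height = 256, width = 256, n_frames = 300,
                       frame_interval = 1, pixel_size = 0.25,
                       vessel_center = c((height - 1) / 2, (width - 1) / 2),
                       baseline_radius = 16,
                       dilation_profile = dilation_pulse(n_frames),
                       endfoot_gap = 2, endfoot_thickness = 6,
                       n_somata = 10, soma_radius_range = c(12, 20),
                       event_rate = 2, transient_amplitude = 0.5,
                       transient_decay_tau = 4,
                       endfoot_event_rate = 2, endfoot_event_amplitude = 0.3,
                       drift_amplitude = 2, drift_mode = c("smooth", "integer"),
                       noise_sigma = 5, photon_gain = 0, seed = 1,
                       noise_seed = NULL,
                       vessel_intensity = 200, background = 20,
                       endfoot_intensity = 150, soma_intensity = 120,
                       activity_background = 15, texture_sd = 10) {
  p <- list(height = height, width = width, n_frames = n_frames,
            frame_interval = frame_interval, pixel_size = pixel_size,
            vessel_center = vessel_center, baseline_radius = baseline_radius,
            dilation_profile = as.numeric(dilation_profile),
            endfoot_gap = endfoot_gap, endfoot_thickness = endfoot_thickness,
            n_somata = n_somata, soma_radius_range = soma_radius_range,
            event_rate = event_rate, transient_amplitude = transient_amplitude,
            transient_decay_tau = transient_decay_tau,
            endfoot_event_rate = endfoot_event_rate,
            endfoot_event_amplitude = endfoot_event_amplitude,
            drift_amplitude = drift_amplitude,
            drift_mode = match.arg(drift_mode),
            noise_sigma = noise_sigma, photon_gain = photon_gain, seed = seed,
            noise_seed = noise_seed %||% (seed + 500000L),
            vessel_intensity = vessel_intensity, background = background,
            endfoot_intensity = endfoot_intensity,
            soma_intensity = soma_intensity,
            activity_background = activity_background,
            texture_sd = texture_sd)
  sw <- attr(dilation_profile, "stimulus_window")
  p$stimulus_window <- sw %||% c(0, n_frames - 1)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  num <- unlist(p[!(names(p) %in% c("drift_mode"))])
  if (!all(is.finite(num))) stop("simulation parameters must be finite", call. = FALSE)
  if (length(p$dilation_profile) != p$n_frames)
    stop("dilation_profile must have length n_frames", call. = FALSE)
  if (any(c(p$event_rate, p$endfoot_event_rate, p$transient_amplitude,
            p$endfoot_event_amplitude, p$noise_sigma, p$drift_amplitude,
            p$photon_gain) < 0))
    stop("rates and amplitudes must be non-negative", call. = FALSE)
  max_r <- p$baseline_radius * (1 + max(p$dilation_profile)) +
    p$endfoot_gap + p$endfoot_thickness
  if (max_r + p$drift_amplitude >= min(p$height, p$width) / 2)
    stop("dilated vessel plus endfoot annulus would leave the frame", call. = FALSE)
  invisible(p)
}

# Low-pass-filtered random walk anchored at zero, scaled to a maximum
# absolute excursion of `amplitude`.
drift_trajectory <- function(n_frames, amplitude, mode = "smooth") {
  if (amplitude == 0 || n_frames < 2) return(matrix(0, n_frames, 2))
  d <- sapply(1:2, function(i) {
    w <- cumsum(rnorm(n_frames))
    w <- smooth_gauss(w, sigma = 5)
    w <- w - w[1]
    m <- max(abs(w))
    if (m > 0) w * amplitude / m else w
  })
  if (mode == "integer") d <- round(d)
  d
}

# dF/F time course of one transient: instantaneous rise at onset, exponential
# decay with time constant tau (frames), truncated at offset. tau = Inf gives
# a boxcar.
transient_shape <- function(onset, offset, amplitude, tau_frames, n_frames) {
  tr <- numeric(n_frames)
  idx <- (onset:offset) + 1L
  dt <- (onset:offset) - onset
  tr[idx] <- if (is.infinite(tau_frames)) amplitude else
    amplitude * exp(-dt / tau_frames)
  tr
}

# Schedule non-overlapping events on [0, n_frames): data.frame(onset, offset,
# amplitude). Count ~ Poisson(rate), onsets uniform, rejection on overlap.
schedule_events <- function(n_frames, rate, amplitude, dur_frames) {
  n <- rpois(1, rate)
  ev <- data.frame(onset = integer(), offset = integer(), amplitude = numeric())
  tries <- 0
  while (nrow(ev) < n && tries < 50 * (n + 1)) {
    tries <- tries + 1
    onset <- sample.int(max(1, n_frames - dur_frames), 1) - 1L
    offset <- min(n_frames - 1L, onset + dur_frames)
    if (!any(onset <= ev$offset & offset >= ev$onset)) {
      ev <- rbind(ev, data.frame(onset = onset, offset = offset,
                                 amplitude = amplitude))
    }
  }
  ev[order(ev$onset), , drop = FALSE]
}

# Anti-aliased disc coverage at distance `d` from the centre for radius `rad`:
# 1 inside, 0 outside, linear ramp across the pixel-wide edge.
disc_coverage <- function(d, rad) pmin(pmax(rad + 0.5 - d, 0), 1)

# Separable 2-D Gaussian blur with periodic edges (texture synthesis only).
blur2d <- function(m, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  m <- stats::filter(m, k, circular = TRUE)
  t(stats::filter(t(m), k, circular = TRUE))
}

#' Simulate a two-channel movie with full ground truth
#'
#' Renders a penetrating arteriole (anti-aliased disc of the per-frame
#' diameter) in the vascular channel and, in the activity channel, an endfoot
#' annulus tracking the vessel wall plus soma discs whose intensity follows
#' `baseline * (1 + dF/F(t))`. The same rigid drift is applied to both
#' channels; noise is added last. Identical `(params, seed)` give bit-identical
#' output.
#'
#' @param params a [sim_params()] object.
#' @return a list with elements `movie` (a [two_channel_movie()]) and `truth`
#'   (drift `T x 2`, per-frame `diameter_px`, `soma_masks` label image at the
#'   drift-free reference position, `soma_events`, `soma_dff` `T x n` matrix,
#'   `endfoot_radius` 360 x T centreline radius field, `endfoot_events`,
#'   `soma_centers`, `soma_radii`, `stimulus_window`).
#' @export
simulate_movie <- function(params) {
  p <- validate_sim_params(params)
  with_seed(p$seed, {
    H <- p$height; W <- p$width; T <- p$n_frames
    radius_t <- p$baseline_radius * (1 + p$dilation_profile)
    drift <- drift_trajectory(T, p$drift_amplitude, p$drift_mode)
    ef_center_r <- radius_t + p$endfoot_gap + p$endfoot_thickness / 2
    sigma_a <- p$endfoot_thickness / 2.355  # FWHM = endfoot_thickness

    # --- soma placement (reference, drift-free coordinates) ---
    max_reach <- max(ef_center_r) + 2 * sigma_a
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    guard <- 0
    while (nrow(centers) < p$n_somata && guard < 2000) {
      guard <- guard + 1
      sr <- runif(1, p$soma_radius_range[1], p$soma_radius_range[2])
      m <- sr + p$drift_amplitude + 2
      cand <- c(runif(1, m, H - 1 - m), runif(1, m, W - 1 - m))
      d_vessel <- sqrt(sum((cand - p$vessel_center)^2))
      if (d_vessel < max_reach + sr + 3) next
      if (nrow(centers) > 0) {
        dd <- sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                             byrow = TRUE))^2))
        if (any(dd < radii + sr + 3)) next
      }
      centers <- rbind(centers, cand)
      radii <- c(radii, sr)
    }
    if (nrow(centers) < p$n_somata)
      stop("could not place all somata; reduce n_somata or soma radius", call. = FALSE)

    # --- soma event schedules and dF/F traces ---
    tau_f <- p$transient_decay_tau / p$frame_interval
    dur <- max(3L, ceiling(3 * tau_f))
    soma_events <- data.frame(roi = integer(), onset = integer(),
                              offset = integer(), amplitude = numeric())
    soma_dff <- matrix(0, T, p$n_somata)
    for (i in seq_len(p$n_somata)) {
      ev <- schedule_events(T, p$event_rate, p$transient_amplitude, dur)
      if (nrow(ev) > 0) {
        soma_events <- rbind(soma_events, cbind(roi = i, ev))
        for (j in seq_len(nrow(ev)))
          soma_dff[, i] <- soma_dff[, i] +
            transient_shape(ev$onset[j], ev$offset[j], ev$amplitude[j], tau_f, T)
      }
    }

    # --- endfoot event schedule (angle span x frame span) ---
    ef_ev <- schedule_events(T, p$endfoot_event_rate,
                             p$endfoot_event_amplitude, dur)
    endfoot_events <- if (nrow(ef_ev) > 0) {
      data.frame(ef_ev,
                 angle_start = sample.int(360, nrow(ef_ev)) - 1L,
                 angle_span = round(runif(nrow(ef_ev), 40, 90)))
    } else {
      data.frame(onset = integer(), offset = integer(), amplitude = numeric(),
                 angle_start = integer(), angle_span = integer())
    }

    # --- ground-truth label image for somata ---
    rows <- matrix(0:(H - 1), H, W)
    cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
    soma_masks <- matrix(0L, H, W)
    for (i in seq_len(p$n_somata)) {
      d <- sqrt((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2)
      soma_masks[disc_coverage(d, radii[i]) >= 0.5] <- i
    }

    # --- static background texture, drifting with the field ---
    mg <- ceiling(p$drift_amplitude) + 2L
    tex_v <- tex_a <- NULL
    if (p$texture_sd > 0) {
      mk_tex <- function() {
        tb <- blur2d(matrix(rnorm((H + 2 * mg) * (W + 2 * mg)), H + 2 * mg), 1.2)
        tb * (p$texture_sd / sd(tb))
      }
      tex_v <- mk_tex()
      tex_a <- mk_tex() * 0.3
    }

    # --- render frames ---
    vascular <- array(0, c(H, W, T))
    activity <- array(0, c(H, W, T))
    endfoot_radius <- matrix(0, 360, T)
    deg <- 0:359
    for (t in seq_len(T)) {
      cy <- p$vessel_center[1] + drift[t, 1]
      cx <- p$vessel_center[2] + drift[t, 2]
      d <- sqrt((rows - cy)^2 + (cols - cx)^2)
      vascular[, , t] <- p$background +
        p$vessel_intensity * disc_coverage(d, radius_t[t])
      if (!is.null(tex_v)) {
        vascular[, , t] <- vascular[, , t] + matrix(
          bilinear_sample(tex_v, rows + 1 + mg - drift[t, 1],
                          cols + 1 + mg - drift[t, 2]), H, W)
      }

      act <- p$activity_background +
        p$endfoot_intensity * exp(-(d - ef_center_r[t])^2 / (2 * sigma_a^2))
      if (!is.null(tex_a)) {
        act <- act + matrix(
          bilinear_sample(tex_a, rows + 1 + mg - drift[t, 1],
                          cols + 1 + mg - drift[t, 2]), H, W)
      }
      endfoot_radius[, t] <- ef_center_r[t]
      # endfoot events modulate the annulus over an angular span
      ev_now <- endfoot_events[endfoot_events$onset <= t - 1 &
                               endfoot_events$offset >= t - 1, , drop = FALSE]
      if (nrow(ev_now) > 0) {
        ang <- (atan2(-(rows - cy), cols - cx) * 180 / pi) %% 360
        near <- abs(d - ef_center_r[t]) < 3 * sigma_a
        for (j in seq_len(nrow(ev_now))) {
          a0 <- ev_now$angle_start[j]
          a1 <- (a0 + ev_now$angle_span[j]) %% 360
          in_span <- if (a0 <= a1) ang >= a0 & ang <= a1 else ang >= a0 | ang <= a1
          dt <- (t - 1) - ev_now$onset[j]
          gain <- ev_now$amplitude[j] * exp(-dt / tau_f)
          sel <- in_span & near
          act[sel] <- act[sel] + p$endfoot_intensity * gain *
            exp(-(d[sel] - ef_center_r[t])^2 / (2 * sigma_a^2))
        }
      }
      # somata (drifting with the field)
      for (i in seq_len(p$n_somata)) {
        sc <- centers[i, ] + drift[t, ]
        r0 <- max(1, floor(sc[1] - radii[i] - 1) + 1)
        r1 <- min(H, ceiling(sc[1] + radii[i] + 1) + 1)
        c0 <- max(1, floor(sc[2] - radii[i] - 1) + 1)
        c1 <- min(W, ceiling(sc[2] + radii[i] + 1) + 1)
        dl <- sqrt((rows[r0:r1, c0:c1] - sc[1])^2 +
                   (cols[r0:r1, c0:c1] - sc[2])^2)
        act[r0:r1, c0:c1] <- act[r0:r1, c0:c1] +
          p$soma_intensity * (1 + soma_dff[t, i]) * disc_coverage(dl, radii[i])
      }
      activity[, , t] <- act
    }

    # --- noise, added last, on its own RNG stream ---
    with_seed(p$noise_seed, {
      if (p$photon_gain > 0) {
        vascular[] <- rpois(length(vascular), pmax(vascular, 0) / p$photon_gain) *
          p$photon_gain
        activity[] <- rpois(length(activity), pmax(activity, 0) / p$photon_gain) *
          p$photon_gain
      }
      if (p$noise_sigma > 0) {
        vascular[] <- vascular + rnorm(length(vascular), 0, p$noise_sigma)
        activity[] <- activity + rnorm(length(activity), 0, p$noise_sigma)
      }
    })

    movie <- two_channel_movie(vascular, activity,
                               pixel_size = p$pixel_size,
                               frame_interval = p$frame_interval)
    truth <- list(drift = drift, diameter_px = 2 * radius_t,
                  soma_masks = soma_masks, soma_events = soma_events,
                  soma_dff = soma_dff, soma_centers = centers,
                  soma_radii = radii, endfoot_radius = endfoot_radius,
                  endfoot_events = endfoot_events,
                  stimulus_window = p$stimulus_window)
    list(movie = movie, truth = truth)
  })
}

#' Simulate a single dF/F trace with scheduled transients
#'
#' Unit-test fixture for the transient detector: the trace is the sum of
#' scheduled transients (step onset, exponential decay, truncated at the
#' event offset) plus Gaussian noise.
#'
#' @param n_frames trace length.
#' @param noise_sigma Gaussian noise SD (dF/F units).
#' @param events data frame with columns `onset`, `offset` (0-based, inclusive)
#'   and `amplitude`; must be non-overlapping and within `[0, n_frames)`.
#' @param decay_tau decay constant in frames; `Inf` gives boxcar events.
#' @param seed RNG seed.
#' @return list with `dff` (numeric vector) and `events` (the schedule).
#' @export
simulate_trace <- function(n_frames, noise_sigma = 0, events = NULL,
                           decay_tau = Inf, seed = NULL) {
  if (is.null(events))
    events <- data.frame(onset = integer(), offset = integer(),
                         amplitude = numeric())
  if (nrow(events) > 0) {
    if (any(events$onset < 0 | events$offset >= n_frames |
            events$onset > events$offset))
      stop("events must lie within [0, n_frames) with onset <= offset", call. = FALSE)
    ev <- events[order(events$onset), ]
    if (nrow(ev) > 1 && any(ev$onset[-1] <= ev$offset[-nrow(ev)]))
      stop("events must not overlap", call. = FALSE)
  }
  with_seed(seed, {
    dff <- numeric(n_frames)
    for (j in seq_len(nrow(events)))
      dff <- dff + transient_shape(events$onset[j], events$offset[j],
                                   events$amplitude[j], decay_tau, n_frames)
    if (noise_sigma > 0) dff <- dff + rnorm(n_frames, 0, noise_sigma)
    list(dff = dff, events = events)
  })
}
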