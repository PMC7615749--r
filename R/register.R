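#' Build a registration template from the first frames
#'
#' Pixel-wise mean of the first `n_template_frames` vascular frames.
#'
#' @param movie a [two_channel_movie()].
#' @param n_template_frames number of leading frames to average (default 20).
#' @return template matrix `H x W`.
#' @export
build_template <- function(movie, n_template_frames = 20) {
  stopifnot(inherits(movie, "two_channel_movie"))
  T <- n_frames(movie)
  if (n_template_frames < 1) stop("n_template_frames must be >= 1", call. = FALSE)
  if (T < n_template_frames)
    stop(sprintf("movie has %d frames, fewer than n_template_frames = %d",
                 T, n_template_frames), call. = FALSE)
  apply(movie$vascular[, , seq_len(n_template_frames), drop = FALSE],
        c(1, 2), mean)
}

# Upsampled discrete Fourier transform of `x` (complex matrix) on an
# `nor x noc` grid with spacing 1/usfac px, offset by (roff, coff) samples
# in upsampled units (matrix-multiply implementation).
dft_upsample <- function(x, nor, noc, usfac, roff, coff) {
  nr <- nrow(x); nc <- ncol(x)
  fr <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1))
  fc <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1))
  kr <- exp((-2i * pi / (nr * usfac)) * outer((0:(nor - 1)) - roff, fr))
  kc <- exp((-2i * pi / (nc * usfac)) * outer(fc, (0:(noc - 1)) - coff))
  kr %*% x %*% kc
}

#' Estimate the rigid translation between a frame and a template
#'
#' Cross-correlation in the Fourier domain; the integer peak is refined to
#' sub-pixel precision with a locally upsampled discrete Fourier transform
#' (default x10, i.e. 0.1 px steps). Sign convention: the returned
#' `(dy, dx)` is the displacement of the frame relative to the template, so
#' applying the negated shift to the frame aligns it to the template.
#'
#' @param frame,template matrices of identical shape.
#' @param upsample upsampling factor for sub-pixel refinement; `1` returns the
#'   integer-pixel estimate.
#' @return numeric `c(dy, dx)` in pixels.
#' @export
estimate_shift <- function(frame, template, upsample = 10) {
  if (!identical(dim(frame), dim(template)))
    stop("frame and template must have the same shape", call. = FALSE)
  if (all(frame == 0)) {
    warning("all-zero frame; returning (0, 0)", call. = FALSE)
    return(c(dy = 0, dx = 0))
  }
  phase_shift(fft(frame - mean(frame)), fft(template - mean(template)),
              upsample)
}

# Core correlation-peak search on pre-computed FFTs.
phase_shift <- function(F1, F2, upsample) {
  nr <- nrow(F1); nc <- ncol(F1)
  R <- F1 * Conj(F2)
  cc <- Re(fft(R, inverse = TRUE))
  pk <- which.max(cc) - 1L
  py <- pk %% nr
  px <- pk %/% nr
  if (py > nr / 2) py <- py - nr
  if (px > nc / 2) px <- px - nc
  if (upsample > 1) {
    # refine in a 1.5-px neighbourhood of the integer peak
    reg <- ceiling(upsample * 1.5)
    off <- floor(reg / 2)
    ccu <- Mod(dft_upsample(Conj(R), reg, reg, upsample,
                            off - py * upsample, off - px * upsample))
    pu <- which.max(ccu) - 1L
    py <- py + ((pu %% reg) - off) / upsample
    px <- px + ((pu %/% reg) - off) / upsample
  }
  c(dy = py, dx = px)
}

#' Rigid registration of both channels against an early-frame template
#'
#' Per-frame translations are estimated on the vascular channel against the
#' mean of the first `n_template_frames` frames; both channels are then warped
#' with the vascular-channel shifts (the activity channel is never registered
#' independently). Pixels dragged in from outside the frame are filled with
#' the template mean and flagged in the validity mask.
#'
#' @param movie a [two_channel_movie()].
#' @param n_template_frames frames averaged into the template (default 20).
#' @param upsample sub-pixel upsampling factor passed to [estimate_shift()];
#'   `1` restricts shifts to whole pixels.
#' @param n_passes `2` rebuilds the template from the aligned first frames and
#'   re-estimates once, removing the blur a drifting template window causes.
#' @details Shifts are re-referenced to the first frame (`dy = dx = 0` at
#'   frame 0), so the trajectory is the displacement of each frame relative to
#'   the start of the recording rather than relative to the template's mean
#'   position; the template serves only as the correlation reference.
#' @return list with `movie` (aligned), `shifts` (data frame `frame`, `dy`,
#'   `dx`; `frame` 0-based), `valid` (`H x W` logical, pixels valid in every
#'   frame) and `template`.
#' @export
register_movie <- function(movie, n_template_frames = 20, upsample = 10,
                           n_passes = 1) {
  stopifnot(inherits(movie, "two_channel_movie"))
  T <- n_frames(movie)
  template <- build_template(movie, n_template_frames)
  shifts <- matrix(0, T, 2)
  for (pass in seq_len(n_passes)) {
    Ft <- fft(template - mean(template))
    for (t in seq_len(T)) {
      fr <- movie$vascular[, , t]
      shifts[t, ] <- if (all(fr == 0)) c(0, 0) else
        phase_shift(fft(fr - mean(fr)), Ft, upsample)
    }
    if (pass < n_passes) {
      fill <- mean(template)
      aligned1 <- array(0, c(dim(template), n_template_frames))
      for (t in seq_len(n_template_frames))
        aligned1[, , t] <- translate_frame(movie$vascular[, , t],
                                           -shifts[t, 1], -shifts[t, 2], fill)
      template <- apply(aligned1, c(1, 2), mean)
    }
  }
  shifts <- sweep(shifts, 2, shifts[1, ])
  fill_v <- mean(template)
  fill_a <- mean(movie$activity[, , seq_len(n_template_frames)])
  H <- nrow(template); W <- ncol(template)
  vas <- array(0, dim(movie$vascular))
  act <- array(0, dim(movie$activity))
  valid <- matrix(TRUE, H, W)
  for (t in seq_len(T)) {
    dy <- shifts[t, 1]; dx <- shifts[t, 2]
    vas[, , t] <- translate_frame(movie$vascular[, , t], -dy, -dx, fill_v)
    act[, , t] <- translate_frame(movie$activity[, , t], -dy, -dx, fill_a)
    # rows/cols exposed by the warp are invalid
    if (dy > 0) valid[H - seq_len(min(H, ceiling(dy))) + 1, ] <- FALSE
    if (dy < 0) valid[seq_len(min(H, ceiling(-dy))), ] <- FALSE
    if (dx > 0) valid[, W - seq_len(min(W, ceiling(dx))) + 1] <- FALSE
    if (dx < 0) valid[, seq_len(min(W, ceiling(-dx)))] <- FALSE
  }
  aligned <- two_channel_movie(vas, act, pixel_size = movie$pixel_size,
                               frame_interval = movie$frame_interval,
                               channel_names = movie$channel_names)
  list(movie = aligned,
       shifts = data.frame(frame = 0:(T - 1), dy = shifts[, 1], dx = shifts[, 2]),
       valid = valid, template = template)
}
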