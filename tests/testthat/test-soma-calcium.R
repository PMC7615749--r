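test_that("adaptive thresholding finds generator somata with good overlap", {
  p <- tiny_params(height = 160, width = 160, n_somata = 5, n_frames = 20,
                   noise_sigma = 3, seed = 27)
  sim <- simulate_movie(p)
  ref <- apply(sim$movie$activity, c(1, 2), mean)
  # exclusion disc over the vessel + endfoot ring
  rows <- matrix(0:159, 160, 160); cols <- t(rows)
  lum <- sqrt((rows - 79.5)^2 + (cols - 79.5)^2) < 25
  rois <- detect_somata(ref, soma_diameter = 18, lumen_mask = lum)
  expect_equal(max(rois), 5)
  for (i in 1:5) {
    gt <- sim$truth$soma_masks == i
    jac <- max(vapply(seq_len(max(rois)), function(k) {
      dk <- rois == k
      sum(gt & dk) / sum(gt | dk)
    }, numeric(1)))
    expect_gt(jac, 0.5)
  }
  # uniform image: empty mask with a warning
  expect_warning(u <- detect_somata(matrix(50, 64, 64)), "no somata")
  expect_equal(max(u), 0)
})

test_that("touching somata merged by blur are split by the watershed", {
  # three isolated somata set the median area; a touching pair exceeds twice
  # that and must be split on the distance transform
  img <- disc_frame(160, 160, c(30, 30), 9, amp = 100, bg = 10) +
    disc_frame(160, 160, c(30, 100), 9, amp = 100, bg = 0) +
    disc_frame(160, 160, c(130, 30), 9, amp = 100, bg = 0) +
    disc_frame(160, 160, c(100, 100), 10, amp = 100, bg = 0) +
    disc_frame(160, 160, c(100, 117), 10, amp = 100, bg = 0)
  img <- gliovasc:::blur2d(img, 1.5)
  rois <- detect_somata(img, soma_diameter = 18)
  expect_equal(max(rois), 5)
  # the merged pair is split across its two true centres
  expect_true(rois[101, 101] != 0 && rois[101, 118] != 0)
  expect_true(rois[101, 101] != rois[101, 118])
})

test_that("dF/F is the fractional change about the baseline median", {
  expect_equal(compute_dff(rep(100, 50))$dff, rep(0, 50))
  x <- rep(100, 20); x[11] <- 125
  expect_equal(compute_dff(x, baseline_window = c(0, 9))$dff[11], 0.25)
  # percentile alternative
  d <- compute_dff(c(rep(10, 80), rep(30, 20)), f0_method = "percentile")
  expect_equal(d$baseline_f0, 10)
  expect_error(compute_dff(rep(0, 10)), "positive")
})

test_that("transient detection equals brute-force run enumeration", {
  set.seed(31)
  for (rep in 1:300) {
    nf <- sample(30:200, 1)
    ev <- NULL
    if (runif(1) < 0.7) {
      on <- sample(5:(nf - 10), 1)
      ev <- data.frame(onset = on, offset = min(nf - 1, on + sample(2:25, 1)),
                       amplitude = runif(1, 0.1, 1))
    }
    tr <- simulate_trace(nf, noise_sigma = 0.05, events = ev, decay_tau = 8,
                         seed = 5000 + rep)
    det <- detect_transients(tr$dff)
    or <- brute_force_transients(tr$dff)
    if (is.null(or)) {
      expect_equal(nrow(det), 0)
    } else {
      expect_true(nrow(det) == nrow(or) &&
                  all(cbind(det$onset_frame, det$offset_frame) == or))
    }
  }
})

test_that("the three-consecutive-frames rule vetoes short excursions", {
  # near-delta smoothing makes the suprathreshold run length explicit:
  # 2 frames above threshold is never an event, 3 frames is
  p_delta <- detection_params(smooth_sigma = 0.3)
  base <- simulate_trace(80, 0.02, seed = 3)$dff
  x2 <- base; x2[41:42] <- 1
  expect_equal(nrow(detect_transients(x2, p_delta)), 0)
  x3 <- base; x3[41:43] <- 1
  expect_equal(nrow(detect_transients(x3, p_delta)), 1)
  # at default smoothing a strong single-frame spike is spread too thin to
  # sustain three suprathreshold frames: vetoed
  xs <- simulate_trace(80, 0.05, seed = 4)$dff
  xs[41] <- 0.4  # 8 robust SDs for one frame
  expect_equal(nrow(detect_transients(xs)), 0)
  # a boxcar of 10 sigma produces exactly one event at the right place
  ev <- data.frame(onset = 40, offset = 50, amplitude = 10 * 0.05)
  tr <- simulate_trace(100, 0.05, ev, seed = 9)
  det2 <- detect_transients(tr$dff)
  expect_equal(nrow(det2), 1)
  expect_lt(abs(det2$onset_frame - 40), 2)
  expect_lt(abs(det2$offset_frame - 50), 2)
})

test_that("noiseless traces are flagged degenerate and use a zero threshold", {
  x <- numeric(60); x[30:35] <- 1
  det <- detect_transients(x)
  expect_true(attr(det, "degenerate"))
  expect_equal(nrow(det), 1)
})

test_that("detection is invariant under affine transforms of the raw trace", {
  ev <- data.frame(onset = c(30, 90), offset = c(42, 102), amplitude = 40)
  set.seed(41)
  raw <- 100 + simulate_trace(150, 2, ev, decay_tau = 6, seed = 11)$dff
  d1 <- detect_transients(compute_dff(raw, baseline_window = c(0, 25)))
  d2 <- detect_transients(compute_dff(3 * raw + 0,
                                      baseline_window = c(0, 25)))
  expect_equal(d1$onset_frame, d2$onset_frame)
  expect_equal(d1$offset_frame, d2$offset_frame)
})

test_that("raising the threshold shrinks the suprathreshold set (events nest)", {
  set.seed(43)
  for (rep in 1:20) {
    x <- simulate_trace(200, 0.05,
                        data.frame(onset = c(40, 120), offset = c(70, 150),
                                   amplitude = 0.4),
                        decay_tau = 10, seed = 600 + rep)$dff
    lo <- detect_transients(x, detection_params(threshold_k = 2))
    hi <- detect_transients(x, detection_params(threshold_k = 3.5))
    # every high-threshold event lies inside some low-threshold event
    for (i in seq_len(nrow(hi))) {
      expect_true(any(lo$onset_frame <= hi$onset_frame[i] &
                      lo$offset_frame >= hi$offset_frame[i]))
    }
    # total suprathreshold coverage shrinks
    expect_lte(sum(hi$offset_frame - hi$onset_frame + 1),
               sum(lo$offset_frame - lo$onset_frame + 1))
  }
})

test_that("active fractions follow the bin-overlap counting rule", {
  ev <- data.frame(roi_id = c(1, 2, 3), onset_frame = c(5, 12, 18),
                   offset_frame = c(8, 15, 22), peak_dff = 1, peak_frame = 6)
  af <- active_fraction(ev, roi_ids = 1:5, n_frames = 40, bin_width = 10,
                        stimulus_window = c(0, 39))
  expect_equal(af$responder_fraction, 0.6)  # 3 of 5 ROIs
  # an event spanning the bin boundary (frames 18-22) counts in both bins
  expect_equal(af$bins$fraction_active, c(0.2, 0.4, 0.2, 0))
  # no events at all
  af0 <- active_fraction(ev[0, ], roi_ids = 1:5, n_frames = 40)
  expect_true(all(af0$bins$fraction_active == 0))
  expect_error(active_fraction(ev, roi_ids = integer(), n_frames = 40),
               "empty")
})
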