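test_that("Chan-Vese recovers a noiseless disc and honours connectivity", {
  frame <- disc_frame(64, 64, c(31.5, 31.5), 10)
  ln <- line_scan(c(31.5, 5), c(31.5, 58))
  seg <- segment_lumen(frame, ln)
  expect_true(seg$valid)
  expect_lt(abs(sum(seg$mask) - pi * 100) / (pi * 100), 0.05)
  # oracle: on a binary-like disc the contour equals the thresholded disc
  thr <- frame > (20 + 200 / 2)
  expect_lt(sum(xor(seg$mask > 0, thr)) / sum(thr), 0.05)
  # all-background frame: invalid flag, no exception
  segb <- segment_lumen(matrix(20, 64, 64), ln)
  expect_false(segb$valid)
  # two discs: only the one the line crosses is kept
  fr2 <- disc_frame(64, 64, c(15, 15), 8) +
    disc_frame(64, 64, c(48, 48), 8) - 20
  ln2 <- line_scan(c(15, 2), c(15, 30))
  s2 <- segment_lumen(fr2, ln2)
  expect_equal(s2$mask[16, 16], 1)
  expect_equal(s2$mask[49, 49], 0)
  # diameter is invariant under global intensity scaling
  s3 <- segment_lumen(frame * 7.3, ln)
  expect_identical(s3$mask, seg$mask)
})

test_that("chord lengths match the analytic circle geometry", {
  frame <- disc_frame(64, 64, c(31.5, 31.5), 10)
  ln <- line_scan(c(31.5, 5), c(31.5, 58))
  mask <- segment_lumen(frame, ln)$mask
  d <- diameter_from_mask(mask, ln, pixel_size = 0.5)
  expect_lt(abs(d$px - 20), 0.5)           # diameter through the centre
  expect_equal(d$um, d$px * 0.5)           # unit conversion
  # chord offset 6 px from the centre: 2 * sqrt(10^2 - 6^2) = 16
  ln6 <- line_scan(c(31.5 - 6, 5), c(31.5 - 6, 58))
  mask6 <- segment_lumen(frame, ln6)$mask
  d6 <- diameter_from_mask(mask6, ln6)
  expect_lt(abs(d6$px - 16), 0.5)
  # empty intersection is invalid
  e <- diameter_from_mask(matrix(0, 64, 64), ln)
  expect_false(e$valid)
  # FWHM secondary estimator agrees on the clean disc
  f <- diameter_fwhm(frame, ln)
  expect_lt(abs(f$px - 20), 1)
})

test_that("diameter time series tracks flat and ramped dilation profiles", {
  p <- tiny_params(n_frames = 30, dilation_profile = rep(0, 30),
                   noise_sigma = 3, seed = 23)
  sim <- simulate_movie(p)
  ln <- line_scan(c(47.5, 20), c(47.5, 75))
  tr <- diameter_timeseries(sim$movie, ln, baseline_window = c(0, 14),
                            stimulus_window = c(15, 29))
  expect_true(all(tr$valid))
  expect_lt(sd(tr$diameter_px) / mean(tr$diameter_px), 0.02)
  # monotone ramp is recovered monotone after a 3-frame median filter
  ramp <- seq(0, 0.4, length.out = 30)
  p2 <- tiny_params(n_frames = 30, dilation_profile = ramp, noise_sigma = 3,
                    seed = 24)
  s2 <- simulate_movie(p2)
  t2 <- diameter_timeseries(s2$movie, ln, baseline_window = c(0, 4),
                            stimulus_window = c(5, 29))
  sm <- stats::runmed(t2$diameter_px, 3)
  expect_true(all(diff(sm) >= -1e-9))
})

test_that("response metrics reproduce closed-form pulse geometry", {
  # constant trace: peak 0, auc 0
  flat <- structure(
    data.frame(frame = 0:99, time = 0:99, diameter_px = 20,
               diameter_um = 10, valid = TRUE),
    class = c("diameter_trace", "data.frame"),
    baseline_window = c(0, 49), stimulus_window = c(50, 99))
  m0 <- response_metrics(flat)
  expect_equal(m0$peak_percent, 0)
  expect_equal(m0$auc, 0)
  # triangular pulse of height 0.2 lasting half the response window:
  # peak 20%, normalized auc = 0.5 * 0.5 * 0.2 = 0.05
  d <- rep(10, 201)
  d[76:126] <- 10 * (1 + 0.2 * (1 - abs(seq(-1, 1, length.out = 51))))
  tri <- structure(
    data.frame(frame = 0:200, time = 0:200, diameter_px = d,
               diameter_um = d, valid = TRUE),
    class = c("diameter_trace", "data.frame"),
    baseline_window = c(0, 49), stimulus_window = c(50, 150))
  m <- response_metrics(tri, response_window = c(50, 150), median_filter = 1)
  expect_equal(m$peak_percent, 20, tolerance = 1e-9)
  expect_equal(m$auc, 0.05, tolerance = 1e-3)
  # metrics are independent of the pixel-size calibration
  tri2 <- tri
  tri2$diameter_um <- d * 3
  m2 <- response_metrics(tri2, response_window = c(50, 150), median_filter = 1)
  expect_equal(m2$peak_percent, m$peak_percent)
  # degenerate baselines are rejected
  bad <- flat
  bad$diameter_px <- 0
  expect_error(response_metrics(bad), "baseline")
})

test_that("generator dilation peaks are recovered within 3 percentage points", {
  prof <- dilation_pulse(90, onset = 30, rise = 12, plateau = 15, fall = 25,
                         peak = 0.36)
  p <- tiny_params(height = 128, width = 128, n_frames = 90,
                   baseline_radius = 16, dilation_profile = prof,
                   noise_sigma = 5, seed = 25)
  sim <- simulate_movie(p)
  ln <- line_scan(c(63.5, 63.5 - 28), c(63.5, 63.5 + 28))
  tr <- diameter_timeseries(sim$movie, ln, baseline_window = c(0, 29),
                            stimulus_window = c(30, 89))
  m <- response_metrics(tr)
  expect_lt(abs(m$peak_percent - 36), 3)
  # auc matches the profile's normalized integral within 5 percent of peak
  auc_truth <- pracma::trapz(30:89, prof[31:90]) / (89 - 30)
  expect_lt(abs(m$auc - auc_truth), 0.05 * 0.36)
})
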