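ctr80 <- c(39.5, 39.5)

test_that("the ridge filter localizes an annulus and ignores flat input", {
  ann <- annulus_frame(80, 80, ctr80, function(a) 20, sigma = 1.5)
  ridge <- ridge_enhance(ann)
  pol <- to_polar(ridge, ctr80, 35)
  am <- apply(pol$intensity, 2, which.max)
  expect_true(all(abs(am - 20) <= 1))  # argmax within 1 px of centreline
  expect_true(all(ridge_enhance(matrix(5, 40, 40)) == 0))
  expect_true(all(ridge >= 0))
})

test_that("ridge response is stable under 90-degree rotation", {
  ann <- annulus_frame(80, 80, ctr80, function(a) 20 + 3 * sin(a))
  r1 <- ridge_enhance(ann)
  rot <- t(ann)[, seq_len(ncol(ann))][, rev(seq_len(ncol(ann)))]
  r2 <- ridge_enhance(rot)
  back <- t(r2[, rev(seq_len(ncol(r2)))])
  expect_lt(max(abs(back - r1)) / max(r1), 0.05)
})

test_that("polar resampling is faithful: symmetry, peaks, round trip", {
  rows <- matrix(0:79, 80, 80); cols <- t(rows)
  d <- sqrt((rows - 39.5)^2 + (cols - 39.5)^2)
  blob <- 50 * exp(-d^2 / (2 * 8^2))
  pol <- to_polar(blob, ctr80, 30)
  expect_equal(dim(pol$intensity), c(30, 360))
  # radially symmetric input: constant along the angle axis
  expect_lt(max(apply(pol$intensity, 1, sd)) / max(pol$intensity), 0.01)
  # annulus: its radius is the brightest polar row
  ann <- annulus_frame(80, 80, ctr80, function(a) 20, sigma = 1.5)
  pa <- to_polar(ann, ctr80, 35)
  expect_equal(unname(which.max(rowMeans(pa$intensity))), 20)
  # polar -> cartesian -> polar reproduces radial profiles within 2 percent
  back <- from_polar(pol, c(80, 80))
  sel <- d >= 2 & d <= 28
  expect_lt(max(abs(back[sel] - blob[sel])) / max(blob), 0.02)
  expect_error(to_polar(blob, c(200, 10), 30), "inside")
})

test_that("path tracing follows constant, sinusoidal and banded annuli", {
  # perfect circle
  ann <- annulus_frame(80, 80, ctr80, function(a) 20, sigma = 1.5)
  pol <- to_polar(ridge_enhance(ann), ctr80, 35)
  p <- trace_endfoot_path(pol)
  expect_true(p$feasible)
  expect_true(all(abs(p$radius - 20) <= 1))
  # sinusoidal deformation: RMS error < 1 px
  ann2 <- annulus_frame(80, 80, ctr80, function(a) 20 + 3 * sin(a))
  pol2 <- to_polar(ridge_enhance(ann2), ctr80, 35)
  p2 <- trace_endfoot_path(pol2)
  truth <- 20 + 3 * sin((0:359) * pi / 180)
  expect_lt(sqrt(mean((p2$radius - truth)^2)), 1)
  # two concentric annuli: the band constraint keeps the path on the inner
  ann3 <- ann + annulus_frame(80, 80, ctr80, function(a) 30, sigma = 1.5)
  pol3 <- to_polar(ridge_enhance(ann3), ctr80, 38)
  p3 <- trace_endfoot_path(pol3, prev_path = rep(20, 360), band = 4)
  expect_true(all(abs(p3$radius - 20) <= 2))
  # infeasible input carries the previous path forward, flagged
  flat <- to_polar(matrix(0, 80, 80), ctr80, 35)
  pf <- trace_endfoot_path(flat, prev_path = rep(20, 360), band = 2)
  expect_false(pf$feasible)
  expect_equal(pf$radius, rep(20, 360))
})

test_that("path tracking is equivariant to image rotation", {
  ann <- annulus_frame(80, 80, ctr80, function(a) 20 + 3 * sin(a))
  pol <- to_polar(ridge_enhance(ann), ctr80, 35)
  p <- trace_endfoot_path(pol)
  # rotate the image 90 degrees counter-clockwise
  rot <- t(ann)[rev(seq_len(nrow(ann))), ]
  polr <- to_polar(ridge_enhance(rot), ctr80, 35)
  pr <- trace_endfoot_path(polr)
  shifted <- c(p$radius[271:360], p$radius[1:270])  # angles advance by 90
  expect_true(mean(abs(pr$radius - shifted) <= 1) > 0.97)
})

test_that("the kymograph is quiet without events and lights up with one", {
  # static annulus, no events: |dff| below 3x the noise scale
  p <- tiny_params(height = 128, width = 128, n_frames = 50, n_somata = 2,
                   noise_sigma = 4, seed = 51)
  sim <- simulate_movie(p)
  ky <- build_kymograph(sim$movie$activity, p$vessel_center, r_max = 35,
                        baseline_window = c(0, 24))
  noise <- sd(ky$dff[, 1:25])
  expect_lt(quantile(abs(ky$dff), 0.95), 3 * noise)
  expect_equal(nrow(detect_kymo_events(ky)), 0)
  # scheduled endfoot event appears as a connected region at its location
  p2 <- tiny_params(height = 128, width = 128, n_frames = 60, n_somata = 2,
                    noise_sigma = 4, endfoot_event_rate = 2,
                    endfoot_event_amplitude = 0.3, seed = 52)
  s2 <- simulate_movie(p2)
  tr_ev <- s2$truth$endfoot_events
  expect_gt(nrow(tr_ev), 0)
  k2 <- build_kymograph(s2$movie$activity, p2$vessel_center, r_max = 35,
                        baseline_window = c(0, 9))
  ev <- detect_kymo_events(k2)
  m <- match_events(ev$frame_start, ev$frame_end, tr_ev$onset, tr_ev$offset)
  expect_gte(m$tp, 1)
})

test_that("a dilating vessel without events leaves the kymograph quiet", {
  prof <- dilation_pulse(60, onset = 20, rise = 10, plateau = 12, fall = 15,
                         peak = 0.36)
  p <- tiny_params(height = 128, width = 128, n_frames = 60, n_somata = 2,
                   baseline_radius = 14, dilation_profile = prof,
                   noise_sigma = 4, seed = 55)
  sim <- simulate_movie(p)
  ky <- build_kymograph(sim$movie$activity, p$vessel_center, r_max = 40,
                        baseline_window = c(0, 19))
  # the path tracks the moving annulus ...
  expect_lt(sqrt(mean((ky$radius - sim$truth$endfoot_radius)^2)), 1)
  # ... and the dF/F field stays below the 5 percent event threshold almost
  # everywhere (the band crossing static neuropil structure during a large
  # dilation leaves some residual baseline shift), with no spurious events
  expect_lt(quantile(abs(ky$dff), 0.95), 0.05)
  expect_equal(nrow(detect_kymo_events(ky)), 0)
})

test_that("kymograph events obey the amplitude and area rules", {
  k <- matrix(0, 360, 50)
  k[10:16, 10:19] <- 0.2    # 70 cells: accepted
  k[100:104, 30:39] <- 0.2  # 50 cells: rejected (area must exceed 64)
  ev <- detect_kymo_events(k)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$area, 70)
  # uniform 4 percent dF/F: below the 5 percent amplitude rule
  expect_equal(nrow(detect_kymo_events(matrix(0.04, 360, 50))), 0)
  # a component of exactly 64 cells is rejected ("larger than")
  k64 <- matrix(0, 360, 50)
  k64[20:27, 10:17] <- 0.2
  expect_equal(nrow(detect_kymo_events(k64)), 0)
})

test_that("components straddling the angular seam are counted once", {
  k <- matrix(0, 360, 30)
  k[351:360, 5:9] <- 0.2
  k[1:10, 5:9] <- 0.2  # wraps across 359/0: one 100-cell event
  ev <- detect_kymo_events(k)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$area, 100)
})

test_that("labelling matches the fixpoint-propagation oracle on random masks", {
  set.seed(61)
  for (rep in 1:25) {
    m <- matrix(runif(20 * 15) < 0.35, 20, 15)
    lab <- gliovasc:::label_periodic(m)
    orc <- flood_labels_oracle(m)
    expect_identical(component_signature(lab), component_signature(orc))
  }
})

test_that("event detection is monotone in its thresholds (nesting)", {
  set.seed(63)
  base <- matrix(rnorm(360 * 40, 0, 0.02), 360, 40)
  base[40:80, 10:25] <- base[40:80, 10:25] + 0.12
  base[200:215, 20:30] <- base[200:215, 20:30] + 0.07
  lo <- detect_kymo_events(base, min_amplitude = 0.05, min_area = 64)
  # raising min_area never adds events
  for (a in c(64, 100, 200, 400, 1000)) {
    n <- nrow(detect_kymo_events(base, min_amplitude = 0.05, min_area = a))
    expect_lte(n, nrow(lo))
    lo_a <- n
  }
  # raising min_amplitude: every surviving event nests inside a lower-
  # threshold component
  hi <- detect_kymo_events(base, min_amplitude = 0.08, min_area = 64)
  lab_lo <- attr(detect_kymo_events(base, min_amplitude = 0.05, min_area = 0),
                 "labels")
  lab_hi <- attr(hi, "labels")
  if (nrow(hi) > 0) {
    for (i in seq_len(nrow(hi))) {
      inside <- lab_lo[lab_hi == i]
      expect_true(all(inside > 0))
      expect_equal(length(unique(inside)), 1)
    }
  }
})

test_that("the maximal projection trace summarizes the kymograph", {
  expect_true(all(kymo_trace(matrix(0, 360, 20)) == 0))
  k <- matrix(0, 360, 60)
  k[120:150, 48:53] <- 0.3
  tr <- kymo_trace(k)
  expect_equal(max(tr), 0.3)
  expect_equal(unname(which.max(tr)), 48)  # frame 47, 0-based
  # max projection dominates the mean projection everywhere
  set.seed(65)
  k2 <- matrix(abs(rnorm(360 * 30, 0.02, 0.01)), 360, 30)
  expect_true(all(kymo_trace(k2) >= colMeans(k2)))
})
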