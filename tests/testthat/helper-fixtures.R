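# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive enumerations, independent of the package's vectorized paths.

# anti-aliased bright disc on a dark background
disc_frame <- function(H, W, center, radius, amp = 200, bg = 20) {
  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  d <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  bg + amp * pmin(pmax(radius + 0.5 - d, 0), 1)
}

# annulus with angle-dependent centreline radius (Gaussian cross-section)
annulus_frame <- function(H, W, center, radius_fun, sigma = 1.6, amp = 100) {
  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  dy <- rows - center[1]; dx <- cols - center[2]
  d <- sqrt(dy^2 + dx^2)
  ang <- atan2(-dy, dx)
  amp * exp(-(d - radius_fun(ang))^2 / (2 * sigma^2))
}

# small, fast generator settings for unit tests
tiny_params <- function(...) {
  defaults <- list(height = 96, width = 96, n_frames = 40, n_somata = 3,
                   soma_radius_range = c(8, 10), baseline_radius = 12,
                   drift_amplitude = 0, dilation_profile = rep(0, 40),
                   endfoot_event_rate = 0, seed = 1)
  args <- modifyList(defaults, list(...))
  if (length(args$dilation_profile) != args$n_frames)
    args$dilation_profile <- rep(0, args$n_frames)
  do.call(sim_params, args)
}

# brute-force transient enumeration: explicit scan over frames
brute_force_transients <- function(x, k = 2.5, minc = 3, sigma = 1,
                                   mad_to_sd = 1.4826, bw = NULL) {
  sm <- gliovasc::smooth_gauss(x, sigma)
  base <- if (is.null(bw)) x else x[(bw[1]:bw[2]) + 1]
  s <- mad_to_sd * median(abs(base - median(base)))
  thr <- if (s == 0) 0 else k * s
  above <- sm > thr
  out <- NULL
  i <- 1; n <- length(x)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      if (j - i + 1 >= minc) out <- rbind(out, c(i - 1, j - 1))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# fixpoint label propagation (8-connectivity, periodic rows): each cell takes
# the minimum label among itself and its neighbours until nothing changes
flood_labels_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    old <- lab
    for (r in 1:nr) for (c in 1:nc) {
      if (!mask[r, c]) next
      for (dr in -1:1) for (dc in -1:1) {
        rr <- ((r - 1 + dr) %% nr) + 1
        cc <- c + dc
        if (cc < 1 || cc > nc) next
        if (mask[rr, cc] && lab[rr, cc] < lab[r, c]) lab[r, c] <- lab[rr, cc]
      }
    }
    if (identical(old, lab)) break
  }
  lab
}

# canonical component partition as a sorted signature, for comparing labelings
component_signature <- function(lab) {
  ids <- setdiff(unique(as.vector(lab)), 0)
  sets <- lapply(ids, function(i) sort(which(lab == i)))
  sets[order(vapply(sets, min, numeric(1)))]
}

# interval-overlap matching of detected vs true event tables
match_events <- function(det_on, det_off, true_on, true_off) {
  matched_true <- logical(length(true_on))
  matched_det <- logical(length(det_on))
  for (i in seq_along(det_on)) {
    hit <- which(!matched_true & true_on <= det_off[i] & true_off >= det_on[i])
    if (length(hit)) {
      matched_true[hit[1]] <- TRUE
      matched_det[i] <- TRUE
    }
  }
  list(tp = sum(matched_det), fp = sum(!matched_det), fn = sum(!matched_true))
}
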