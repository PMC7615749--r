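#' Ridge enhancement of bright curvilinear structures
#'
#' Multi-scale Hessian-eigenvalue filter: at each scale the image is
#' Gaussian-smoothed, second derivatives are taken, and the response is the
#' scale-normalized magnitude of the negative principal eigenvalue (bright
#' ridges have a strongly negative second derivative across the ridge). The
#' per-pixel output is the maximum over scales; it is non-negative and
#' (up to discretization) rotation invariant.
#'
#' @param img numeric matrix (crop around the vessel).
#' @param scales Gaussian scales in px (default `c(1, 2, 4)`; match the
#'   endfoot thickness range).
#' @return non-negative matrix of the same shape.
#' @export
ridge_enhance <- function(img, scales = c(1, 2, 4)) {
  out <- matrix(0, nrow(img), ncol(img))
  if (max(img) == min(img)) return(out)
  for (s in scales) {
    sm <- as_matrix(EBImage::gblur(img, sigma = s))
    # central second differences and cross derivative
    hrr <- shift_mat(sm, 1, 0) + shift_mat(sm, -1, 0) - 2 * sm
    hcc <- shift_mat(sm, 0, 1) + shift_mat(sm, 0, -1) - 2 * sm
    hrc <- (shift_mat(sm, 1, 1) + shift_mat(sm, -1, -1) -
            shift_mat(sm, 1, -1) - shift_mat(sm, -1, 1)) / 4
    # smaller (more negative) Hessian eigenvalue
    tr2 <- (hrr + hcc) / 2
    dlt <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
    lam2 <- tr2 - dlt
    out <- pmax(out, s^2 * pmax(-lam2, 0))
  }
  out
}

#' Resample a frame to polar coordinates about the vessel centre
#'
#' Bilinear sampling on an `(r, phi)` grid with `r = 1..r_max` in 1-px steps
#' and `phi` in 360 one-degree bins (bin centre at the bin value). Angle 0
#' points along the +column axis and increases counter-clockwise.
#'
#' @param frame numeric matrix.
#' @param center `(row, col)` 0-based vessel centre.
#' @param r_max maximum radius, px.
#' @param fill value for samples outside the frame.
#' @return list of class `polar_frame`: `intensity` (`r_max x 360`), `center`,
#'   `r_max`.
#' @export
to_polar <- function(frame, center, r_max, fill = 0) {
  if (center[1] < 0 || center[1] > nrow(frame) - 1 ||
      center[2] < 0 || center[2] > ncol(frame) - 1)
    stop("center must lie inside the frame", call. = FALSE)
  phi <- (0:359) * pi / 180
  r <- seq_len(r_max)
  rr <- center[1] + 1 - outer(r, sin(phi))   # row axis points down
  cc <- center[2] + 1 + outer(r, cos(phi))
  v <- bilinear_sample(frame, as.vector(rr), as.vector(cc), fill = fill)
  structure(list(intensity = matrix(v, r_max, 360), center = center,
                 r_max = r_max), class = "polar_frame")
}

#' Back-project a polar image to cartesian coordinates
#'
#' Inverse of [to_polar()] (bilinear in `(r, phi)`, periodic in angle); used
#' to check resampling fidelity.
#'
#' @param polar a `polar_frame`.
#' @param dims `(H, W)` of the target frame.
#' @param fill value outside the sampled annulus (`r < 1` or `r > r_max`).
#' @return numeric matrix `H x W`.
#' @export
from_polar <- function(polar, dims, fill = 0) {
  H <- dims[1]; W <- dims[2]
  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  dy <- rows - polar$center[1]
  dx <- cols - polar$center[2]
  r <- sqrt(dy^2 + dx^2)
  a <- (atan2(-dy, dx) * 180 / pi) %% 360
  # periodic angle axis: pad one wrapped column
  P <- cbind(polar$intensity, polar$intensity[, 1])
  v <- bilinear_sample(P, as.vector(r), as.vector(a) + 1, fill = fill)
  out <- matrix(v, H, W)
  out[r < 1 | r > polar$r_max] <- fill
  out
}

#' Trace the endfoot circumference in a polar ridge map
#'
#' Nodes are the local maxima of the ridge response in each one-degree
#' column; edges connect nodes in adjacent columns with a radius jump of at
#' most `jump_limit` px, costed by `(max_ridge - node_value) +
#' lambda * |dr|`. The minimal-cost path from column 0 to column 359 is found
#' by dynamic programming over feasible start nodes, subject to the closure
#' constraint `|r_start - r_end| <= closure_tol` and a cap on the total path
#' length `sum(|dr|)`. When `prev_path` is given the search is restricted to
#' a band around it.
#'
#' @param polar_ridge a `polar_frame` of ridge responses (from
#'   [ridge_enhance()] + [to_polar()]).
#' @param prev_path optional numeric length-360 radius vector of the previous
#'   frame.
#' @param jump_limit max `|dr|` between adjacent columns, px.
#' @param lambda smoothness weight (ridge units per px).
#' @param closure_tol max `|r(0) - r(359)|`, px.
#' @param band half-width of the search band around `prev_path`, px.
#' @param length_cap cap on `sum(|dr|)`; default `4 * 360 * lambda`-free
#'   heuristic: `2 * r_max`.
#' @return list of class `endfoot_path`: `radius` (length 360), `cost`,
#'   `feasible` (FALSE when no admissible path exists; `radius` is then
#'   `prev_path` carried forward, or NA).
#' @export
trace_endfoot_path <- function(polar_ridge, prev_path = NULL, jump_limit = 2,
                               lambda = 0.5, closure_tol = 2, band = 5,
                               length_cap = NULL) {
  R <- polar_ridge$intensity
  r_max <- nrow(R)
  if (is.null(length_cap)) length_cap <- 2 * r_max
  if (max(R) <= 0) {
    # no ridge signal at all: nothing to trace
    return(structure(list(radius = prev_path %||% rep(NA_real_, 360),
                          cost = NA_real_, feasible = FALSE),
                     class = "endfoot_path"))
  }
  nodes <- vector("list", 360)
  for (j in 1:360) {
    col <- R[, j]
    loc <- which(diff(sign(diff(col))) < 0) + 1L
    if (!is.null(prev_path))
      loc <- loc[abs(loc - prev_path[j]) <= band]
    if (length(loc) == 0) {
      loc <- if (!is.null(prev_path)) {
        lo <- max(1L, floor(prev_path[j] - band))
        hi <- min(r_max, ceiling(prev_path[j] + band))
        lo - 1L + which.max(col[lo:hi])
      } else which.max(col)
    }
    nodes[[j]] <- loc
  }
  maxR <- max(R)
  node_cost <- lapply(1:360, function(j) maxR - R[nodes[[j]], j])
  best_cost <- Inf
  best_path <- NULL
  for (s in seq_along(nodes[[1]])) {
    r_start <- nodes[[1]][s]
    # DP state: cost to reach each node of column j
    cost <- rep(Inf, length(nodes[[1]]))
    cost[s] <- node_cost[[1]][s]
    back <- vector("list", 360)
    feasible <- TRUE
    for (j in 2:360) {
      rj <- nodes[[j]]; rp <- nodes[[j - 1]]
      cj <- rep(Inf, length(rj))
      bj <- rep(NA_integer_, length(rj))
      for (k in seq_along(rj)) {
        dr <- abs(rj[k] - rp)
        ok <- dr <= jump_limit & is.finite(cost)
        if (any(ok)) {
          cand <- cost + lambda * dr
          cand[!ok] <- Inf
          bj[k] <- which.min(cand)
          cj[k] <- cand[bj[k]] + node_cost[[j]][k]
        }
      }
      if (all(!is.finite(cj))) { feasible <- FALSE; break }
      cost <- cj
      back[[j]] <- bj
    }
    if (!feasible) next
    # closure: end node within closure_tol of the start radius (and a
    # feasible wrap jump)
    endo <- which(abs(nodes[[360]] - r_start) <= closure_tol &
                  is.finite(cost))
    if (length(endo) == 0) next
    e <- endo[which.min(cost[endo])]
    if (cost[e] >= best_cost) next
    path <- integer(360)
    path[360] <- e
    for (j in 360:2) path[j - 1] <- back[[j]][path[j]]
    radius <- vapply(1:360, function(j) nodes[[j]][path[j]], numeric(1))
    if (sum(abs(diff(radius))) > length_cap) next
    best_cost <- cost[e]
    best_path <- radius
  }
  if (is.null(best_path)) {
    return(structure(list(radius = prev_path %||% rep(NA_real_, 360),
                          cost = NA_real_, feasible = FALSE),
                     class = "endfoot_path"))
  }
  structure(list(radius = best_path, cost = best_cost, feasible = TRUE),
            class = "endfoot_path")
}

#' Track the endfoot over all frames and build the kymograph
#'
#' Per frame: ridge-enhance a crop around the vessel centre, resample to
#' polar coordinates, trace the endfoot path (band-constrained around the
#' previous frame's path), then sample the raw activity intensity in a radial
#' band around the path, giving one 360-degree column per frame. dF/F is
#' computed per angle against the baseline-window median.
#'
#' @param channel `H x W x T` activity array.
#' @param centers `T x 2` matrix of 0-based vessel centres (e.g. lumen
#'   centroids from [diameter_timeseries()]), or a single `(row, col)` centre.
#' @param r_max polar sampling radius, px.
#' @param baseline_window 0-based inclusive frame range for the per-angle
#'   baseline.
#' @param band_halfwidth radial averaging half-width, px (default 2).
#' @param scales ridge-filter scales.
#' @param ... passed to [trace_endfoot_path()].
#' @return list of class `kymograph`: `dff` (360 x T), `intensity` (360 x T),
#'   `radius` (360 x T tracked path), `baseline` (length 360), `valid`
#'   (length T), `centers`.
#' @export
build_kymograph <- function(channel, centers, r_max, baseline_window = NULL,
                            band_halfwidth = 2, scales = c(1, 2, 4), ...) {
  d <- dim(channel)
  T <- d[3]
  if (is.null(dim(centers)))
    centers <- matrix(rep(centers, each = T), T, 2)
  intensity <- matrix(NA_real_, 360, T)
  radius <- matrix(NA_real_, 360, T)
  valid <- logical(T)
  prev <- NULL
  for (t in seq_len(T)) {
    ctr <- centers[t, ]
    if (any(!is.finite(ctr))) { valid[t] <- FALSE; next }
    # crop around the centre for the ridge filter
    r0 <- max(1, floor(ctr[1] + 1 - r_max - 4))
    r1 <- min(d[1], ceiling(ctr[1] + 1 + r_max + 4))
    c0 <- max(1, floor(ctr[2] + 1 - r_max - 4))
    c1 <- min(d[2], ceiling(ctr[2] + 1 + r_max + 4))
    crop <- channel[r0:r1, c0:c1, t]
    ctr_c <- ctr - c(r0 - 1, c0 - 1)
    ridge <- ridge_enhance(crop, scales)
    pol_r <- to_polar(ridge, ctr_c, r_max)
    path <- trace_endfoot_path(pol_r, prev_path = prev, ...)
    radius[, t] <- path$radius
    valid[t] <- path$feasible
    if (path$feasible) prev <- path$radius
    if (all(is.finite(path$radius))) {
      pol_i <- to_polar(crop, ctr_c, r_max)
      for (a in 1:360) {
        lo <- max(1, floor(path$radius[a] - band_halfwidth))
        hi <- min(r_max, ceiling(path$radius[a] + band_halfwidth))
        intensity[a, t] <- mean(pol_i$intensity[lo:hi, a])
      }
    }
  }
  bw <- baseline_window %||% c(0, T - 1)
  bidx <- (bw[1]:bw[2]) + 1
  baseline <- apply(intensity[, bidx, drop = FALSE], 1, median, na.rm = TRUE)
  dff <- sweep(sweep(intensity, 1, baseline, "-"), 1, baseline, "/")
  structure(list(dff = dff, intensity = intensity, radius = radius,
                 baseline = baseline, valid = valid, centers = centers),
            class = "kymograph")
}

# Connected components of a logical matrix, 8-connectivity, rows periodic
# (row 1 adjacent to row n: the angle axis). BFS flood fill.
label_periodic <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx_all <- which(mask)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue
      queue <- integer(0)
      qr <- ((q - 1L) %% nr) + 1L
      qc <- ((q - 1L) %/% nr) + 1L
      for (o in seq_len(nrow(offs))) {
        rr <- ((qr - 1L + offs$dr[o]) %% nr) + 1L  # periodic rows
        cc <- qc + offs$dc[o]
        ok <- cc >= 1L & cc <= nc
        if (!any(ok)) next
        nb <- (cc[ok] - 1L) * nr + rr[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Detect Ca2+ events in an endfoot kymograph
#'
#' Thresholds the kymograph at `min_amplitude` dF/F and labels connected
#' components with 8-connectivity, the angle axis being periodic (degree 359
#' adjacent to degree 0); components whose area (frames x degrees cells)
#' exceeds `min_area` are events.
#'
#' @param kymo a `kymograph` from [build_kymograph()], or a 360 x T dF/F
#'   matrix.
#' @param min_amplitude dF/F threshold (default 0.05, i.e. 5 percent).
#' @param min_area strict lower area bound in cells (default 64; a 64-cell
#'   component is rejected).
#' @return data frame with one row per event: `event`, `area`, `peak_dff`,
#'   `angle_min`, `angle_max`, `frame_start`, `frame_end` (0-based);
#'   attribute `labels` holds the 360 x T component label matrix.
#' @export
detect_kymo_events <- function(kymo, min_amplitude = 0.05, min_area = 64) {
  dff <- if (inherits(kymo, "kymograph")) kymo$dff else kymo
  mask <- is.finite(dff) & dff > min_amplitude
  lab <- label_periodic(mask)
  keep <- which(tabulate(lab[lab > 0]) > min_area)
  out <- data.frame(event = integer(), area = integer(), peak_dff = numeric(),
                    angle_min = integer(), angle_max = integer(),
                    frame_start = integer(), frame_end = integer())
  relab <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) {
    sel <- lab == keep[i]
    relab[sel] <- i
    idx <- which(sel, arr.ind = TRUE)
    out <- rbind(out, data.frame(
      event = i, area = sum(sel), peak_dff = max(dff[sel]),
      angle_min = min(idx[, 1]) - 1L, angle_max = max(idx[, 1]) - 1L,
      frame_start = min(idx[, 2]) - 1L, frame_end = max(idx[, 2]) - 1L))
  }
  structure(out, labels = relab)
}

#' Maximum-projection Ca2+ trace of a kymograph
#'
#' `trace(t) = max over angles of dF/F(phi, t)` - the per-frame maximal
#' projection along the angle axis used to plot endfoot Ca2+ signal traces.
#'
#' @param kymo a `kymograph` or 360 x T dF/F matrix.
#' @return numeric vector of length T.
#' @export
kymo_trace <- function(kymo) {
  dff <- if (inherits(kymo, "kymograph")) kymo$dff else kymo
  apply(dff, 2, function(col) if (all(!is.finite(col))) NA_real_
        else max(col, na.rm = TRUE))
}
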