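#' Overlapping patch grid covering a frame
#'
#' Patch origins advance by `stride` px; the last patch in each direction is
#' anchored to the frame edge so the union of patches covers every pixel.
#'
#' @param height,width frame size, px.
#' @param patch_size square patch side, px (default 8).
#' @param stride origin spacing, px (default 4, i.e. 50 percent overlap);
#'   must not exceed `patch_size`.
#' @param group_size patches per side of the second-stage window (default 4,
#'   i.e. 4 x 4 blocks of patches).
#' @return list of class `patch_grid`: `origins` (n x 2 matrix, 0-based
#'   row/col), `patch_size`, `stride`, `group_size`, `group_id` (integer per
#'   patch).
#' @export
patch_grid <- function(height, width, patch_size = 8, stride = 4,
                       group_size = 4) {
  if (stride > patch_size)
    stop("stride must be <= patch_size (patches must overlap or tile)", call. = FALSE)
  if (patch_size > min(height, width))
    stop("patch_size exceeds frame size", call. = FALSE)
  axis_origins <- function(n) {
    o <- seq(0L, n - patch_size, by = stride)
    if (o[length(o)] != n - patch_size) o <- c(o, n - patch_size)
    o
  }
  ro <- axis_origins(height)
  co <- axis_origins(width)
  origins <- as.matrix(expand.grid(row = ro, col = co))
  gi <- findInterval(match(origins[, 1], ro) - 1, seq(0, length(ro), group_size))
  gj <- findInterval(match(origins[, 2], co) - 1, seq(0, length(co), group_size))
  structure(list(origins = origins, patch_size = patch_size, stride = stride,
                 group_size = group_size,
                 group_id = as.integer(interaction(gi, gj, drop = TRUE))),
            class = "patch_grid")
}

#' Serialize a spatial patch of a movie channel into a pixels x time matrix
#'
#' Row `i` of the result is the full time course of pixel `i` of the patch
#' (column-major order within the patch).
#'
#' @param channel `H x W x T` array.
#' @param origin `(row, col)` 0-based patch origin.
#' @param patch_size patch side, px.
#' @return matrix `(patch_size^2) x T`.
#' @export
patch_to_matrix <- function(channel, origin, patch_size) {
  d <- dim(channel)
  r <- origin[1] + 1; c <- origin[2] + 1
  if (r < 1 || c < 1 || r + patch_size - 1 > d[1] || c + patch_size - 1 > d[2])
    stop("patch out of bounds", call. = FALSE)
  block <- channel[r:(r + patch_size - 1), c:(c + patch_size - 1), , drop = FALSE]
  matrix(block, patch_size^2, d[3])
}

#' Restore a serialized patch matrix into a movie-shaped array
#'
#' Inverse of [patch_to_matrix()]; round-trips bit-exactly.
#'
#' @param mat `(patch_size^2) x T` matrix.
#' @param patch_size patch side, px.
#' @return `patch_size x patch_size x T` array.
#' @export
matrix_to_patch <- function(mat, patch_size) {
  array(mat, c(patch_size, patch_size, ncol(mat)))
}

#' Best low-rank approximation of a matrix (truncated SVD)
#'
#' Retains the leading `rank` singular triplets, the least-squares-optimal
#' approximation by the Eckart-Young theorem.
#'
#' @param mat numeric matrix.
#' @param rank number of components to keep (clamped to `min(dim(mat))` with
#'   a warning).
#' @return matrix of the same shape.
#' @export
truncated_svd_denoise <- function(mat, rank) {
  if (rank < 1) stop("rank must be >= 1", call. = FALSE)
  r <- min(rank, min(dim(mat)))
  if (r < rank) warning("rank clamped to min(dim(mat)) = ", r, call. = FALSE)
  s <- svd(mat, nu = r, nv = r)
  s$u %*% (s$d[seq_len(r)] * t(s$v))
}

#' Two-step truncated-SVD patch denoising of a movie channel
#'
#' Stage 1 approximates each serialized patch matrix (pixels x time) by a
#' truncated SVD of rank `rank1`. Stage 2 collects the retained temporal
#' singular vectors of all patches within each larger window (a
#' `group_size x group_size` block of patches), weighted by their singular
#' values, and approximates that collection by a second truncated SVD of rank
#' `rank2`; each patch's temporal components are then projected onto the
#' shared rank-`rank2` temporal basis and the patch is reconstructed by the
#' inverse transform. Estimates from overlapping patches are averaged.
#'
#' On noiseless input of global rank at most `min(rank1, rank2)` the pipeline
#' is the identity up to numerical tolerance, and the operator is
#' scale-equivariant and independent of patch enumeration order.
#'
#' @param channel `H x W x T` array.
#' @param grid a [patch_grid()] (default: 8 px patches, stride 4, 4 x 4 patch
#'   groups).
#' @param rank1 per-patch rank of the first truncation (default 4).
#' @param rank2 per-window rank of the second, temporal truncation
#'   (default 8).
#' @return denoised array of the same shape.
#' @export
two_step_denoise <- function(channel, grid = NULL, rank1 = 4, rank2 = 8) {
  d <- dim(channel)
  if (is.null(grid)) grid <- patch_grid(d[1], d[2])
  ps <- grid$patch_size
  T <- d[3]
  n_patch <- nrow(grid$origins)
  r1 <- min(rank1, ps^2, T)
  # stage 1: per-patch truncated SVD
  Us <- vector("list", n_patch)
  Cs <- vector("list", n_patch)  # temporal components, columns scaled by d
  for (i in seq_len(n_patch)) {
    M <- patch_to_matrix(channel, grid$origins[i, ], ps)
    s <- svd(M, nu = r1, nv = r1)
    Us[[i]] <- s$u
    Cs[[i]] <- s$v %*% diag(s$d[seq_len(r1)], r1)
  }
  # stage 2: shared temporal basis per larger window
  num <- array(0, d)
  den <- array(0, d[1:2])
  for (g in unique(grid$group_id)) {
    idx <- which(grid$group_id == g)
    G <- do.call(cbind, Cs[idx])           # T x (r1 * n_patches_in_group)
    r2 <- min(rank2, dim(G))
    Q <- svd(G, nu = r2, nv = 0)$u         # orthonormal temporal basis
    for (i in idx) {
      Cp <- Q %*% crossprod(Q, Cs[[i]])    # project onto shared basis
      est <- matrix_to_patch(Us[[i]] %*% t(Cp), ps)
      o <- grid$origins[i, ]
      rr <- (o[1] + 1):(o[1] + ps); cc <- (o[2] + 1):(o[2] + ps)
      num[rr, cc, ] <- num[rr, cc, ] + est
      den[rr, cc] <- den[rr, cc] + 1
    }
  }
  sweep(num, 1:2, den, "/")
}
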