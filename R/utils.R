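#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois runif median mad sd fft cor.test quantile
#' @importFrom utils write.csv read.csv
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stopifnot_finite <- function(x, name) {
  if (!all(is.finite(x))) stop(sprintf("`%s` must be finite", name), call. = FALSE)
  invisible(x)
}

#' Gaussian smoothing of a 1-D signal
#'
#' Convolves a trace with a normalized Gaussian kernel, renormalizing at the
#' edges so that a constant input maps to itself.
#'
#' @param x numeric vector.
#' @param sigma kernel standard deviation in samples; `0` returns `x`.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_gauss <- function(x, sigma = 1) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  n <- length(x)
  xp <- c(rep(NA_real_, r), x, rep(NA_real_, r))
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- xp[i:(i + 2 * r)]
    ok <- !is.na(w)
    out[i] <- sum(w[ok] * k[ok]) / sum(k[ok])
  }
  out
}

# Bilinear interpolation of `img` (matrix, 1-based coordinates) at fractional
# (r, c). Coordinates outside the support return `fill`.
bilinear_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  out <- rep(fill, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(ok)) return(out)
  r0k <- pmin(pmax(r0[ok], 1L), nr); c0k <- pmin(pmax(c0[ok], 1L), nc)
  r1k <- pmin(r0k + 1L, nr); c1k <- pmin(c0k + 1L, nc)
  frk <- fr[ok]; fck <- fc[ok]
  v00 <- img[cbind(r0k, c0k)]; v01 <- img[cbind(r0k, c1k)]
  v10 <- img[cbind(r1k, c0k)]; v11 <- img[cbind(r1k, c1k)]
  out[ok] <- v00 * (1 - frk) * (1 - fck) + v01 * (1 - frk) * fck +
    v10 * frk * (1 - fck) + v11 * frk * fck
  out
}

# Translate an image by (dy, dx) pixels (content moves down/right for positive
# shifts): out(r, c) = img(r - dy, c - dx), bilinear, `fill` outside.
translate_frame <- function(img, dy, dx, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  grid <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  v <- bilinear_sample(img, grid$r - dy, grid$c - dx, fill = fill)
  matrix(v, nr, nc)
}

# Shift a matrix by whole pixels with replicated edges (used by morphology).
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Maximal runs of TRUE in a logical vector: data.frame(start, end) 1-based.
true_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

as_matrix <- function(x) {
  # strips EBImage's Image class back to a plain matrix
  m <- as.array(x)
  dim(m) <- dim(m)[1:2]
  m
}
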