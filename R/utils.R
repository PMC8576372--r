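# Shared raster helpers: block binning, box filtering, integer-factor
# interpolation. All operate on plain numeric matrices.

#' Bin an intensity image to the sensor lattice
#'
#' Models the finite pixel aperture of a full-fill-factor sensor: each output
#' pixel is the arithmetic mean of its `L x L` input block, so the intensity
#' scale (and the image mean) is preserved exactly.
#'
#' @param intensity nonnegative numeric matrix whose dimensions are divisible
#'   by `L`.
#' @param L positive integer down-sampling factor.
#' @return numeric matrix of dimensions `dim(intensity) / L`.
#' @export
bin_to_sensor <- function(intensity, L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("bin_to_sensor: L must be a positive integer", call. = FALSE)
  if (L == 1L) return(intensity)
  d <- dim(intensity)
  if (is.null(d) || d[1] %% L != 0L || d[2] %% L != 0L)
    stop(sprintf("bin_to_sensor: dimensions %s not divisible by L = %d",
                 paste(d, collapse = "x"), L), call. = FALSE)
  nr <- d[1] %/% L
  nc <- d[2] %/% L
  # mean over each L x L block via a 4-d reshape
  a <- array(intensity, dim = c(L, nr, L, nc))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

# Reflect-pad a matrix by k pixels on every side (no edge duplication,
# "reflect" in the scipy sense of mode="mirror"? we use symmetric half-sample
# reflection: row k+1-i maps to row i).
reflect_pad <- function(x, k) {
  if (k == 0L) return(x)
  nr <- nrow(x); nc <- ncol(x)
  if (k > nr || k > nc)
    stop("reflect_pad: kernel radius exceeds image size", call. = FALSE)
  ri <- c(k:1, 1:nr, nr:(nr - k + 1L))
  ci <- c(k:1, 1:nc, nc:(nc - k + 1L))
  x[ri, ci, drop = FALSE]
}

#' Box (moving-average) filter
#'
#' `k x k` mean filter with symmetric reflect padding at the edges, so a
#' constant image is an exact fixed point.
#'
#' @param x numeric matrix.
#' @param k odd positive integer kernel size; `k = 1` is the identity.
#' @return filtered matrix of the same shape.
#' @export
box_filter <- function(x, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k %% 2L == 0L)
    stop("box_filter: kernel size must be an odd positive integer", call. = FALSE)
  if (k == 1L) return(x)
  r <- (k - 1L) %/% 2L
  p <- reflect_pad(x, r)
  # separable running sums: filter rows then columns
  cs <- apply(p, 2, function(col) {
    c0 <- cumsum(col)
    (c0[k:length(col)] - c(0, c0[seq_len(length(col) - k)])) / k
  })
  out <- t(apply(cs, 1, function(row) {
    c0 <- cumsum(row)
    (c0[k:length(row)] - c(0, c0[seq_len(length(row) - k)])) / k
  }))
  dimnames(out) <- NULL
  out
}

# 1-D interpolation weight matrix (n_out x n_in) for integer upsampling
# factor L. Output sample j (1-based) sits at input coordinate
# (j - 0.5) / L + 0.5, the pixel-centre-aligned convention that makes
# nearest-neighbour upsampling the exact inverse of block binning.
interp_weights_1d <- function(n_in, L, method) {
  n_out <- n_in * L
  pos <- (seq_len(n_out) - 0.5) / L + 0.5
  W <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    idx <- pmin(pmax(round(pos), 1L), n_in)
    W[cbind(seq_len(n_out), idx)] <- 1
    return(W)
  }
  if (method == "bilinear") {
    i0 <- floor(pos)
    frac <- pos - i0
    for (j in seq_len(n_out)) {
      ia <- min(max(i0[j], 1L), n_in)
      ib <- min(max(i0[j] + 1L, 1L), n_in)
      W[j, ia] <- W[j, ia] + (1 - frac[j])
      W[j, ib] <- W[j, ib] + frac[j]
    }
    return(W)
  }
  if (method == "bicubic") {
    # Catmull-Rom cubic kernel
    cub <- function(t) {
      t <- abs(t)
      ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
             ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
    }
    i0 <- floor(pos)
    for (j in seq_len(n_out)) {
      for (m in -1:2) {
        ii <- i0[j] + m
        w <- cub(pos[j] - ii)
        ic <- min(max(ii, 1L), n_in)    # clamp at the borders
        W[j, ic] <- W[j, ic] + w
      }
    }
    return(W)
  }
  stop("unknown interpolation method: ", method, call. = FALSE)
}

#' Up-sample an intensity image by an integer factor
#'
#' Separable interpolation to `L` times the input dimensions, with output
#' samples pixel-centre aligned so that `bin_to_sensor(upsample(x, L), L)`
#' is the exact identity for the `nearest` method.  Values are clamped at 0
#' (interpolation overshoot must not create negative intensities).
#'
#' @param intensity nonnegative numeric matrix.
#' @param L positive integer factor; `L = 1` returns the input unchanged.
#' @param method one of `"nearest"`, `"bilinear"`, `"bicubic"` (default).
#' @return numeric matrix of dimensions `dim(intensity) * L`.
#' @export
upsample_hologram <- function(intensity, L, method = c("bicubic", "bilinear", "nearest")) {
  method <- match.arg(method)
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("upsample_hologram: L must be a positive integer", call. = FALSE)
  if (L == 1L) return(intensity)
  Wr <- interp_weights_1d(nrow(intensity), L, method)
  Wc <- interp_weights_1d(ncol(intensity), L, method)
  out <- Wr %*% intensity %*% t(Wc)
  out[out < 0] <- 0
  out
}

# Bilinear point sampling of a matrix at fractional (row, col) positions.
sample_bilinear <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- pmin(pmax(floor(rows), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(cols), 1L), nc - 1L)
  fr <- pmin(pmax(rows - r0, 0), 1)
  fc <- pmin(pmax(cols - c0, 0), 1)
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}
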