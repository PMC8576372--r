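# RGB composition of per-band reconstructions and YUV-space chroma
# smoothing. Rainbow-like artifacts of coherent colour holography live in
# the chrominance planes; averaging U and V while keeping Y untouched
# removes them without blurring brightness detail.

YUV_WU <- 0.492   # BT.601 full-range chroma scale factors
YUV_WV <- 0.877
YUV_WR <- 0.299
YUV_WG <- 0.587
YUV_WB <- 0.114

#' Colour plane container
#'
#' Holds registered real-valued image planes: `R`, `G`, `B` in `[0, 1]`
#' and optionally `Y` (luminance, `[0, 1]`) plus signed chrominance `U`,
#' `V`.  All planes share one shape.
#'
#' @param R,G,B numeric matrices in `[0, 1]` (may be NULL if Y/U/V given).
#' @param Y,U,V optional numeric matrices.
#' @return an object of class `colour_planes`.
#' @export
colour_planes <- function(R = NULL, G = NULL, B = NULL,
                          Y = NULL, U = NULL, V = NULL) {
  planes <- Filter(Negate(is.null), list(R = R, G = G, B = B,
                                         Y = Y, U = U, V = V))
  if (length(planes) == 0L) stop("colour_planes: no planes supplied", call. = FALSE)
  d <- dim(planes[[1]])
  for (nm in names(planes)) {
    if (!is.matrix(planes[[nm]]) || !identical(dim(planes[[nm]]), d))
      stop("colour_planes: all planes must be matrices of one shape", call. = FALSE)
  }
  for (nm in intersect(c("R", "G", "B"), names(planes))) {
    p <- planes[[nm]]
    if (min(p) < -1e-9 || max(p) > 1 + 1e-9)
      stop(sprintf("colour_planes: plane %s out of [0, 1]", nm), call. = FALSE)
  }
  structure(c(planes, list(.dim = d)), class = "colour_planes")
}

#' @export
print.colour_planes <- function(x, ...) {
  nms <- intersect(c("R", "G", "B", "Y", "U", "V"), names(x))
  cat(sprintf("<colour_planes> %d x %d, planes: %s\n",
              x$.dim[1], x$.dim[2], paste(nms, collapse = ", ")))
  invisible(x)
}

# modal intensity: median of the most populated of 256 histogram bins
# (robust background estimate for background-dominated planes)
modal_value <- function(x) {
  if (diff(range(x)) == 0) return(x[1])
  h <- graphics::hist(x, breaks = 256, plot = FALSE)
  i <- which.max(h$counts)
  stats::median(x[x >= h$breaks[i] & x <= h$breaks[i + 1L]])
}

#' Compose per-band reconstructions into RGB planes
#'
#' Channel images are the squared magnitudes ("intensity images") of the
#' three object estimates, normalised so a blank background maps to 1.0 and
#' clipped to `[0, 1]`.  `background` normalisation divides by the modal
#' background intensity of each plane; `percentile` divides by the plane's
#' 99th percentile.
#'
#' @param O_R,O_G,O_B `object_estimate`s (or [complex_field()]s) on one grid.
#' @param normalization `"background"` (default) or `"percentile"`.
#' @param amplitude use amplitude instead of intensity (ablation flag).
#' @return a [colour_planes()] with R, G, B filled.
#' @export
compose_rgb <- function(O_R, O_G, O_B,
                        normalization = c("background", "percentile"),
                        amplitude = FALSE) {
  normalization <- match.arg(normalization)
  as_field <- function(o) if (inherits(o, "object_estimate")) o$field else o
  fields <- lapply(list(O_R, O_G, O_B), as_field)
  g <- fields[[1]]$grid
  if (!grids_equal(fields[[2]]$grid, g) || !grids_equal(fields[[3]]$grid, g))
    stop("compose_rgb: estimates must share one grid", call. = FALSE)
  planes <- lapply(fields, function(f) {
    img <- if (amplitude) Mod(f$values) else Mod(f$values)^2
    ref <- switch(normalization,
                  background = modal_value(img),
                  percentile = stats::quantile(img, 0.99, names = FALSE))
    if (ref <= 0) ref <- max(img, 1e-12)
    pmin(pmax(img / ref, 0), 1)
  })
  colour_planes(R = planes[[1]], G = planes[[2]], B = planes[[3]])
}

#' RGB to YUV (BT.601 full range)
#'
#' `Y = 0.299 R + 0.587 G + 0.114 B`, `U = 0.492 (B - Y)`,
#' `V = 0.877 (R - Y)`.
#'
#' @param planes a [colour_planes()] with R, G, B present.
#' @return the input with Y, U, V planes filled.
#' @export
rgb_to_yuv <- function(planes) {
  stopifnot(inherits(planes, "colour_planes"))
  if (is.null(planes$R) || is.null(planes$G) || is.null(planes$B))
    stop("rgb_to_yuv: R, G, B planes required", call. = FALSE)
  Y <- YUV_WR * planes$R + YUV_WG * planes$G + YUV_WB * planes$B
  colour_planes(R = planes$R, G = planes$G, B = planes$B,
                Y = Y, U = YUV_WU * (planes$B - Y), V = YUV_WV * (planes$R - Y))
}

#' YUV to RGB (exact inverse of [rgb_to_yuv()], clipped to `[0, 1]`)
#'
#' @param planes a [colour_planes()] with Y, U, V present.
#' @return a [colour_planes()] with R, G, B filled (and the Y, U, V kept).
#' @export
yuv_to_rgb <- function(planes) {
  stopifnot(inherits(planes, "colour_planes"))
  if (is.null(planes$Y) || is.null(planes$U) || is.null(planes$V))
    stop("yuv_to_rgb: Y, U, V planes required", call. = FALSE)
  R <- planes$Y + planes$V / YUV_WV
  B <- planes$Y + planes$U / YUV_WU
  G <- (planes$Y - YUV_WR * R - YUV_WB * B) / YUV_WG
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  colour_planes(R = clip01(R), G = clip01(G), B = clip01(B),
                Y = planes$Y, U = planes$U, V = planes$V)
}

#' Suppress rainbow artifacts by chroma smoothing
#'
#' Converts to YUV, mean-filters the U and V chrominance planes with a
#' `k x k` box kernel (reflect padding), keeps the luminance Y bit-identical,
#' and converts back to RGB.
#'
#' @param planes a [colour_planes()] with R, G, B.
#' @param chroma_filter_px odd kernel size (default 9).
#' @return enhanced [colour_planes()].
#' @export
enhance_colour <- function(planes, chroma_filter_px = 9L) {
  chroma_filter_px <- as.integer(chroma_filter_px)
  if (is.na(chroma_filter_px) || chroma_filter_px < 1L ||
      chroma_filter_px %% 2L == 0L)
    stop("enhance_colour: chroma_filter_px must be odd", call. = FALSE)
  yuv <- rgb_to_yuv(planes)
  yuv$U <- box_filter(yuv$U, chroma_filter_px)
  yuv$V <- box_filter(yuv$V, chroma_filter_px)
  yuv_to_rgb(yuv)
}

#' Single-band luminance-replacement baseline
#'
#' The comparison baseline in which colour comes from a low-resolution RGB
#' composite while brightness comes from one high-resolution band: the
#' low-resolution planes are converted to YUV, U and V are mean-filtered, Y
#' is replaced by the supplied single-band high-resolution image, and the
#' result is converted back to RGB.  Wavelength-selective absorption seen
#' only in the other bands is lost, which is what the full three-band
#' pipeline avoids.
#'
#' @param lowres_planes a [colour_planes()] with R, G, B.
#' @param hr_single_channel numeric matrix in `[0, 1]`, same shape.
#' @param chroma_filter_px odd kernel size (default 9).
#' @return [colour_planes()] of the baseline output.
#' @export
ablation_replace_y <- function(lowres_planes, hr_single_channel,
                               chroma_filter_px = 9L) {
  if (!identical(dim(hr_single_channel), lowres_planes$.dim))
    stop("ablation_replace_y: shape mismatch", call. = FALSE)
  yuv <- rgb_to_yuv(lowres_planes)
  yuv$U <- box_filter(yuv$U, as.integer(chroma_filter_px))
  yuv$V <- box_filter(yuv$V, as.integer(chroma_filter_px))
  yuv$Y <- hr_single_channel
  yuv_to_rgb(yuv)
}
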