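# Resolution, fidelity and colour-artifact metrics for acceptance testing.

#' Placement of a bar target in an image
#'
#' Records where a [bar_target_spec()] pattern sits in an image: the pattern
#' centre in fractional pixel coordinates (1-based, row/col) and the image
#' pixel pitch.  [make_bar_target()] centres the pattern on its grid, so the
#' default placement is the grid centre.
#'
#' @param spec a [bar_target_spec()].
#' @param grid [grid_spec()] of the image the target is located in.
#' @param center_row,center_col pattern centre (default: the lattice point
#'   nearest the grid centre, matching [make_bar_target()]'s snapping).
#' @return an object of class `bar_placement`.
#' @export
bar_placement <- function(spec, grid,
                          center_row = round((grid$height_px - 1) / 2) + 1,
                          center_col = round((grid$width_px - 1) / 2) + 1) {
  structure(list(spec = spec, pitch_um = grid$pitch_um,
                 center_row = center_row, center_col = center_col,
                 height_px = grid$height_px, width_px = grid$width_px),
            class = "bar_placement")
}

#' Michelson contrast of a three-bar element
#'
#' Extracts the mean profile across the bars (averaged along the central 60%
#' of the bar length to suppress noise), normalises it by the flank
#' (background) level, and samples it at the geometric bar centres (troughs)
#' and at the gap and flank centres (peaks).  Contrast is
#' `(I_max - I_min) / (I_max + I_min)` with `I_min` the mean of the bar-centre
#' values and `I_max` the mean of the gap/flank values, clipped to `[0, 1]`.
#' Division by the background level makes the statistic invariant to global
#' positive rescaling of the image.
#'
#' @param image numeric matrix (amplitude or intensity reconstruction).
#' @param placement a [bar_placement()] locating the pattern.
#' @return contrast in `[0, 1]`.
#' @export
michelson_contrast <- function(image, placement) {
  stopifnot(inherits(placement, "bar_placement"))
  spec <- placement$spec
  pitch <- placement$pitch_um
  period_px <- spec$line_width_um / spec$duty_cycle / pitch
  centres_px <- (seq_len(spec$n_bars) - (spec$n_bars + 1) / 2) * period_px
  gap_px <- (centres_px[-1] + centres_px[-spec$n_bars]) / 2
  flank_px <- c(min(centres_px) - period_px / 2, max(centres_px) + period_px / 2)
  ext <- bar_target_extent(spec)
  half_len_px <- 0.3 * ext["along"] / pitch   # central 60% of the bar length
  if (spec$orientation == "vertical") {
    c0 <- placement$center_col
    profile_at <- function(off) {
      rows <- seq(placement$center_row - half_len_px,
                  placement$center_row + half_len_px, length.out = 15)
      mean(sample_bilinear(image, rows, rep(c0 + off, length(rows))))
    }
    max_off <- placement$width_px - c0
    min_off <- 1 - c0
  } else {
    r0 <- placement$center_row
    profile_at <- function(off) {
      cols <- seq(placement$center_col - half_len_px,
                  placement$center_col + half_len_px, length.out = 15)
      mean(sample_bilinear(image, rep(r0 + off, length(cols)), cols))
    }
    max_off <- placement$height_px - r0
    min_off <- 1 - r0
  }
  all_off <- c(centres_px, gap_px, flank_px)
  if (any(all_off > max_off) || any(all_off < min_off))
    stop("michelson_contrast: placement extends outside the image", call. = FALSE)
  troughs <- vapply(centres_px, profile_at, numeric(1))
  peaks <- vapply(c(gap_px, flank_px), profile_at, numeric(1))
  bg <- mean(vapply(flank_px, profile_at, numeric(1)))
  if (bg > 0) { troughs <- troughs / bg; peaks <- peaks / bg }
  i_min <- mean(troughs); i_max <- mean(peaks)
  if (i_max + i_min <= 0) return(0)
  min(max((i_max - i_min) / (i_max + i_min), 0), 1)
}

#' Smallest resolved line width over a bar-width ladder
#'
#' Walks a ladder of three-bar elements from widest to finest and reports
#' the finest width whose Michelson contrast reaches the threshold in both
#' orientations; scanning stops at the first failure, following the USAF
#' reading convention that the resolution is the finest fully resolved
#' element.
#'
#' @param images named structure: for each ladder entry, a list with
#'   elements `vertical` and `horizontal`, each a list of `image` (matrix)
#'   and `placement` ([bar_placement()]).
#' @param widths_um descending numeric vector of line widths matching
#'   `images`.
#' @param threshold contrast threshold (default 0.15).
#' @return an object of class `resolution_report`: per-width contrasts, the
#'   threshold, and `smallest_resolved_um` (`NA` if nothing resolves).
#' @export
smallest_resolved_width <- function(images, widths_um, threshold = 0.15) {
  if (length(images) == 0L) stop("smallest_resolved_width: empty ladder", call. = FALSE)
  if (length(images) != length(widths_um))
    stop("smallest_resolved_width: ladder and widths differ in length", call. = FALSE)
  if (is.unsorted(rev(widths_um), strictly = TRUE))
    stop("smallest_resolved_width: widths must be strictly descending", call. = FALSE)
  contrasts <- data.frame(width_um = widths_um, vertical = NA_real_,
                          horizontal = NA_real_, resolved = NA)
  smallest <- NA_real_
  for (i in seq_along(widths_um)) {
    cv <- michelson_contrast(images[[i]]$vertical$image,
                             images[[i]]$vertical$placement)
    ch <- michelson_contrast(images[[i]]$horizontal$image,
                             images[[i]]$horizontal$placement)
    ok <- cv >= threshold && ch >= threshold
    contrasts$vertical[i] <- cv
    contrasts$horizontal[i] <- ch
    contrasts$resolved[i] <- ok
    if (!ok) break
    smallest <- widths_um[i]
  }
  structure(list(contrasts = contrasts, threshold = threshold,
                 smallest_resolved_um = smallest),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf("<resolution_report> threshold %.2f, smallest resolved: %s um\n",
              x$threshold,
              if (is.na(x$smallest_resolved_um)) "unresolved"
              else format(x$smallest_resolved_um)))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Amplitude-recovery fidelity
#'
#' Pearson correlation and normalised RMS error between the amplitude of an
#' estimate and the amplitude of the ground truth over an optional region.
#' `nrmse` is the RMS difference divided by the standard deviation of the
#' truth, so additive noise of known sigma gives `nrmse ~ sigma / sd(truth)`.
#'
#' @param estimate `object_estimate` or [complex_field()].
#' @param truth [complex_field()] on the same grid.
#' @param region optional logical matrix selecting pixels.
#' @return list with `pearson_r` and `nrmse`.
#' @export
recovery_error <- function(estimate, truth, region = NULL) {
  f <- if (inherits(estimate, "object_estimate")) estimate$field else estimate
  if (!grids_equal(f$grid, truth$grid))
    stop("recovery_error: grids differ", call. = FALSE)
  a <- Mod(f$values); b <- Mod(truth$values)
  if (!is.null(region)) { a <- a[region]; b <- b[region] }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("recovery_error: zero-variance input, correlation undefined", call. = FALSE)
  list(pearson_r = stats::cor(as.vector(a), as.vector(b)),
       nrmse = sqrt(mean((a - b)^2)) / stats::sd(as.vector(b)))
}

#' Background chroma artifact score
#'
#' Rainbow artifacts appear as spatial chroma fluctuation over regions that
#' should be achromatic; the score is `sqrt(var(U) + var(V))` over a
#' background mask.  Zero for achromatic or constant-chroma images.
#'
#' @param planes a [colour_planes()] with R, G, B.
#' @param background_mask logical matrix, at least one TRUE.
#' @return nonnegative scalar.
#' @export
chroma_artifact_score <- function(planes, background_mask) {
  if (!any(background_mask)) stop("chroma_artifact_score: empty mask", call. = FALSE)
  yuv <- rgb_to_yuv(planes)
  u <- yuv$U[background_mask]; v <- yuv$V[background_mask]
  if (length(u) < 2L) return(0)
  sqrt(stats::var(u) + stats::var(v))
}
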