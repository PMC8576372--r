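#' Build a wavelength-scanning illumination plan
#'
#' Inclusive arithmetic wavelength sequences per colour band.  The default
#' acquisition scans three bands of seven wavelengths each at a 6 nm step
#' (R 606-642, G 512-548, B 452-488 nm): 21 holograms in total.
#'
#' @param band_ranges named list mapping band (`"R"`, `"G"`, `"B"`) to a
#'   `c(min_nm, max_nm)` pair with `max >= min`.
#' @param step_nm positive wavelength increment in nm.
#' @return an object of class `wavelength_plan`: `$bands` is an ordered
#'   named list of strictly ascending wavelength vectors.
#' @examples
#' plan <- build_wavelength_plan()
#' n_wavelengths(plan)  # 21
#' @export
build_wavelength_plan <- function(band_ranges = list(R = c(606, 642),
                                                     G = c(512, 548),
                                                     B = c(452, 488)),
                                  step_nm = 6) {
  if (!is.finite(step_nm) || step_nm <= 0)
    stop("build_wavelength_plan: step_nm must be positive", call. = FALSE)
  bands <- lapply(band_ranges, function(rng) {
    if (length(rng) != 2L || !all(is.finite(rng)) || rng[2] < rng[1])
      stop("build_wavelength_plan: each range must be c(min_nm, max_nm) with max >= min",
           call. = FALSE)
    if (any(rng <= 0))
      stop("build_wavelength_plan: wavelengths must be positive", call. = FALSE)
    wl <- seq(rng[1], rng[2], by = step_nm)
    if (length(wl) == 1L && rng[2] > rng[1])
      warning("build_wavelength_plan: step larger than range; single-wavelength band",
              call. = FALSE)
    wl
  })
  structure(list(bands = bands), class = "wavelength_plan")
}

#' @export
print.wavelength_plan <- function(x, ...) {
  cat("<wavelength_plan>\n")
  for (b in names(x$bands))
    cat(sprintf("  %s: %s nm\n", b, paste(x$bands[[b]], collapse = ", ")))
  invisible(x)
}

#' Total number of wavelengths (holograms) in a plan
#' @param plan a `wavelength_plan`.
#' @return integer count over all bands.
#' @export
n_wavelengths <- function(plan) sum(lengths(plan$bands))

is_wavelength_plan <- function(x) inherits(x, "wavelength_plan")
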