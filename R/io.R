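# File I/O. No TIFF reader/writer is available in this R stack, so the
# on-disk formats are portable text/standard equivalents keeping the same
# run layout: holograms as 16-bit ASCII PGM (P2) with the intensity scale
# recorded in the YAML sidecar, float amplitude/phase planes as TSV, colour
# output as 8-bit PNG.

PGM_SCALE_DEFAULT <- 16384   # counts per unit intensity (headroom above 1.0)

#' Write a matrix as 16-bit ASCII PGM
#'
#' @param x nonnegative numeric matrix (intensity).
#' @param path output file path.
#' @param scale counts per unit intensity; values clip at 65535.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(x, path, scale = PGM_SCALE_DEFAULT) {
  counts <- round(pmin(pmax(x, 0) * scale, 65535))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(x), nrow(x)), "65535"), con)
  write(t(counts), file = con, ncolumns = ncol(x))
  invisible(path)
}

#' Read a 16-bit ASCII PGM written by [write_pgm()]
#'
#' @param path file path.
#' @param scale counts per unit intensity used at write time.
#' @return numeric matrix of intensities.
#' @export
read_pgm <- function(path, scale = PGM_SCALE_DEFAULT) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("read_pgm: not an ASCII PGM (P2) file: ", path, call. = FALSE)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("read_pgm: truncated file: ", path, call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / scale
}

write_plane_tsv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

read_plane_tsv <- function(path) {
  as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
}

#' Write a hologram stack to a run directory
#'
#' Layout: `<dir>/holograms/<band>_<wavelength>nm.pgm` plus a
#' `<dir>/holograms/sidecar.yaml` recording the acquisition parameters and
#' wavelength plan (units: nm for wavelengths, um for pitch and z2).
#'
#' @param stack a `hologram_stack`.
#' @param dir run directory (created if needed).
#' @return the hologram directory path, invisibly.
#' @export
write_hologram_stack <- function(stack, dir) {
  hdir <- file.path(dir, "holograms")
  dir.create(hdir, recursive = TRUE, showWarnings = FALSE)
  for (band in names(stack$bands))
    for (wl_name in names(stack$bands[[band]]))
      write_pgm(stack$bands[[band]][[wl_name]],
                file.path(hdir, sprintf("%s_%s.pgm", band, wl_name)))
  sidecar <- list(
    plan = lapply(stack$plan$bands, as.numeric),
    sensor = list(height_px = stack$sensor_grid$height_px,
                  width_px = stack$sensor_grid$width_px,
                  pitch_um = stack$sensor_grid$pitch_um),
    acquisition = list(upsample_factor_L = stack$acq$upsample_factor_L,
                       z2_um = stack$acq$z2_um,
                       noise_model = stack$acq$noise_model,
                       photon_budget = stack$acq$photon_budget,
                       rng_seed = stack$acq$rng_seed),
    intensity_scale = PGM_SCALE_DEFAULT)
  yaml::write_yaml(sidecar, file.path(hdir, "sidecar.yaml"))
  invisible(hdir)
}

#' Read a hologram stack from a run directory
#'
#' @param dir run directory containing `holograms/`.
#' @return a `hologram_stack`.
#' @export
read_hologram_stack <- function(dir) {
  hdir <- file.path(dir, "holograms")
  sc <- yaml::read_yaml(file.path(hdir, "sidecar.yaml"))
  grid <- grid_spec(sc$sensor$height_px, sc$sensor$width_px, sc$sensor$pitch_um)
  acq <- acquisition_spec(sensor_grid = grid,
                          upsample_factor_L = sc$acquisition$upsample_factor_L,
                          z2_um = sc$acquisition$z2_um,
                          noise_model = sc$acquisition$noise_model,
                          photon_budget = sc$acquisition$photon_budget,
                          rng_seed = sc$acquisition$rng_seed)
  plan <- structure(list(bands = lapply(sc$plan, as.numeric)),
                    class = "wavelength_plan")
  bands <- lapply(names(plan$bands), function(band) {
    holos <- lapply(plan$bands[[band]], function(wl) {
      f <- file.path(hdir, sprintf("%s_%s.pgm", band, format_nm(wl)))
      if (!file.exists(f))
        stop(sprintf("read_hologram_stack: missing hologram for band %s, %g nm (%s)",
                     band, wl, f), call. = FALSE)
      read_pgm(f, scale = sc$intensity_scale)
    })
    names(holos) <- format_nm(plan$bands[[band]])
    holos
  })
  names(bands) <- names(plan$bands)
  structure(list(bands = bands, sensor_grid = grid, plan = plan, acq = acq),
            class = "hologram_stack")
}

#' Write per-band amplitude and phase planes
#'
#' Layout: `<dir>/recon/<band>_amp.tsv`, `<dir>/recon/<band>_phase.tsv`
#' (float TSV) plus `<dir>/recon/residuals.json`.
#'
#' @param estimates named list of `object_estimate`s.
#' @param dir run directory.
#' @return the recon directory, invisibly.
#' @export
write_reconstruction <- function(estimates, dir) {
  rdir <- file.path(dir, "recon")
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  for (band in names(estimates)) {
    est <- estimates[[band]]
    write_plane_tsv(Mod(est$field$values),
                    file.path(rdir, sprintf("%s_amp.tsv", band)))
    write_plane_tsv(Arg(est$field$values),
                    file.path(rdir, sprintf("%s_phase.tsv", band)))
  }
  res <- lapply(estimates, function(e) e$residual_history)
  jsonlite::write_json(res, file.path(rdir, "residuals.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(rdir)
}

#' Read per-band reconstructions written by [write_reconstruction()]
#'
#' @param dir run directory.
#' @param pitch_um super-resolved pitch of the planes.
#' @param bands band names to read (default R, G, B).
#' @return named list of `object_estimate`s.
#' @export
read_reconstruction <- function(dir, pitch_um, bands = c("R", "G", "B")) {
  rdir <- file.path(dir, "recon")
  res <- jsonlite::read_json(file.path(rdir, "residuals.json"),
                             simplifyVector = TRUE)
  out <- lapply(bands, function(band) {
    fa <- file.path(rdir, sprintf("%s_amp.tsv", band))
    if (!file.exists(fa))
      stop("read_reconstruction: missing band ", band, call. = FALSE)
    amp <- read_plane_tsv(fa)
    ph <- read_plane_tsv(file.path(rdir, sprintf("%s_phase.tsv", band)))
    g <- grid_spec(nrow(amp), ncol(amp), pitch_um)
    object_estimate(complex_field(amp * exp(1i * ph), g), band,
                    as.numeric(res[[band]]))
  })
  names(out) <- bands
  out
}

#' Write colour planes as an 8-bit PNG
#'
#' @param planes a [colour_planes()] with R, G, B.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_colour_png <- function(planes, path) {
  arr <- array(0, dim = c(planes$.dim, 3L))
  arr[, , 1] <- pmin(pmax(planes$R, 0), 1)
  arr[, , 2] <- pmin(pmax(planes$G, 0), 1)
  arr[, , 3] <- pmin(pmax(planes$B, 0), 1)
  png::writePNG(arr, path)
  invisible(path)
}

#' Read an RGB PNG into colour planes
#'
#' @param path `.png` file path.
#' @return a [colour_planes()].
#' @export
read_colour_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L)
    return(colour_planes(R = arr, G = arr, B = arr))
  colour_planes(R = arr[, , 1], G = arr[, , 2], B = arr[, , 3])
}
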