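#' Hypercube: a calibrated reflectance cube with a wavelength axis
#'
#' A `Hypercube` is a 3-D array indexed (row, column, band) together with the
#' band-center wavelengths in nanometres and free-form acquisition metadata.
#' Reflectance is dimensionless, typically in \[0, ~1.2\]; values above 1 can
#' occur where a glossy seed coat out-reflects the white reference and are
#' kept (and flagged), not clipped.
#'
#' @param data numeric 3-D array, dimensions (rows, cols, bands), all finite.
#' @param wavelengths numeric vector of band centers in nm, strictly
#'   increasing, length equal to `dim(data)[3]`.
#' @param meta named list of free-form annotations.
#' @return An object of class `Hypercube`.
#' @export
hypercube <- function(data, wavelengths, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (row, column, band)")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("length(wavelengths) must equal the band count of `data`")
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be finite and strictly increasing")
  structure(list(data = data, wavelengths = wavelengths, meta = meta),
            class = "Hypercube")
}

#' @export
print.Hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Hypercube: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.Hypercube <- function(x) dim(x$data)

#' White/dark calibration reference frames
#'
#' References may be per-band vectors (length = bands), per-pixel matrices
#' replicated across bands, or full cubes matching the raw data. `white` must
#' exceed `dark` on every band used.
#'
#' @param white,dark numeric vector (per band) or array broadcastable to the
#'   cube they calibrate.
#' @return An object of class `CalibrationRefs`.
#' @export
calibration_refs <- function(white, dark) {
  structure(list(white = white, dark = dark), class = "CalibrationRefs")
}

# expand a reference (per-band vector or full cube) to cube dimensions
expand_ref <- function(ref, dims) {
  if (is.null(dim(ref))) {
    if (length(ref) != dims[3L])
      stop("reference band axis does not match the cube", call. = FALSE)
    aperm(array(rep(ref, each = dims[1L] * dims[2L]), dims), c(1, 2, 3))
  } else if (length(dim(ref)) == 3L) {
    if (!all(dim(ref) == dims))
      stop("reference band axis does not match the cube", call. = FALSE)
    ref
  } else stop("reference must be a per-band vector or a full cube",
              call. = FALSE)
}

#' Convert raw intensity to reflectance with white/dark references
#'
#' Standard flat-field calibration `R = (I - D) / (W - D)` applied per pixel
#' and band. Pixels/bands where `white == dark` are set to `NA` and counted in
#' `meta$n_invalid`. Values above 1 are retained (see [hypercube()]) and their
#' count recorded in `meta$n_above_one`.
#'
#' @param raw a [hypercube()] of raw intensities.
#' @param refs a [calibration_refs()] with matching band axis.
#' @return A calibrated `Hypercube`.
#' @export
calibrate_reflectance <- function(raw, refs) {
  stopifnot(inherits(raw, "Hypercube"), inherits(refs, "CalibrationRefs"))
  dims <- dim(raw$data)
  W <- expand_ref(refs$white, dims)
  D <- expand_ref(refs$dark, dims)
  den <- W - D
  bad <- den <= 0
  den[bad] <- NA_real_
  out <- (raw$data - D) / den
  meta <- raw$meta
  meta$calibrated <- TRUE
  meta$n_invalid <- sum(bad)
  meta$n_above_one <- sum(out > 1, na.rm = TRUE)
  hypercube(out, raw$wavelengths, meta)
}

#' Trim a cube to a closed wavelength interval
#'
#' Retains exactly the bands with `low_nm <= lambda <= high_nm` (closed
#' interval, so e.g. a band at exactly 1000 nm is kept). The defaults drop the
#' noisy spectrometer edges below 400 nm and above 1000 nm.
#'
#' @param cube a [hypercube()].
#' @param low_nm,high_nm interval bounds in nm.
#' @return A `Hypercube` with the retained bands, order preserved.
#' @export
trim_bands <- function(cube, low_nm = 400, high_nm = 1000) {
  stopifnot(inherits(cube, "Hypercube"))
  keep <- cube$wavelengths >= low_nm & cube$wavelengths <= high_nm
  if (!any(keep))
    stop(sprintf("no bands in [%g, %g] nm", low_nm, high_nm))
  if (all(keep)) return(cube)
  hypercube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
            cube$meta)
}

# ---- ENVI dialect -----------------------------------------------------------

parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  txt <- paste(txt, collapse = "\n")
  fields <- list()
  # `key = value` or `key = { multi, line, list }`
  pat <- "(?m)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("ENVI header: no fields found")
  starts <- m
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    key <- tolower(trimws(sub("=.*", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    if (startsWith(val, "{"))
      val <- trimws(strsplit(gsub("[{}]", "", val), ",")[[1]])
    fields[[key]] <- val
  }
  fields
}

#' Read an ENVI image + header pair
#'
#' Supports BSQ/BIL/BIP interleaves, data types 4 (float32) and 5 (float64),
#' both byte orders, and a `wavelength` list in the header. Wavelengths given
#' in micrometres (per the `wavelength units` field, or heuristically when all
#' values are < 50) are converted to nm.
#'
#' @param path path to the data file; the header is `<path>.hdr` or the path
#'   with its extension replaced by `.hdr`.
#' @param dialect only `"envi"` is supported.
#' @return A [hypercube()].
#' @export
read_cube <- function(path, dialect = "envi") {
  dialect <- match.arg(dialect, "envi")
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    hdr_path <- paste0(sub("\\.[^.]*$", "", path), ".hdr")
  if (!file.exists(path) || !file.exists(hdr_path))
    stop("ENVI pair not found: need both data file and .hdr")
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type")
  if (!all(need %in% names(h)))
    stop("ENVI header missing required fields: ",
         paste(setdiff(need, names(h)), collapse = ", "))
  samples <- as.integer(h[["samples"]])  # columns
  lines <- as.integer(h[["lines"]])      # rows
  bands <- as.integer(h[["bands"]])
  dtype <- as.integer(h[["data type"]])
  interleave <- tolower(if (is.null(h[["interleave"]])) "bsq"
                        else h[["interleave"]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype))
  endian <- if (!is.null(h[["byte order"]]) && h[["byte order"]] == "1")
    "big" else "little"
  n <- samples * lines * bands
  raw_vals <- readBin(path, "double", n = n, size = size, endian = endian)
  if (length(raw_vals) < n)
    stop("ENVI data file shorter than header declares")

  if (is.null(h[["wavelength"]]))
    stop("ENVI header declares no wavelength list")
  wl <- as.numeric(h[["wavelength"]])
  if (length(wl) != bands)
    stop(sprintf("ENVI header declares %d wavelengths for %d bands",
                 length(wl), bands))
  units <- tolower(if (is.null(h[["wavelength units"]])) ""
                   else h[["wavelength units"]])
  if (grepl("micro", units) || units %in% c("um") ||
      (units == "" && max(wl) < 50))
    wl <- wl * 1000  # micrometres -> nm

  a <- switch(interleave,
    bsq = aperm(array(raw_vals, c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(raw_vals, c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(raw_vals, c(bands, samples, lines)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave))
  hypercube(a, wl, meta = list(source = path, interleave = interleave))
}

#' Write a Hypercube as an ENVI image + header pair
#'
#' Minimal writer used for fixtures and pipeline artifacts: BSQ interleave,
#' float64, little endian, wavelengths in nm. Round-trips bit-exactly through
#' [read_cube()].
#'
#' @param cube a [hypercube()].
#' @param path data-file path; `<path>.hdr` is written alongside.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "Hypercube"))
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {", paste(format(cube$wavelengths, trim = TRUE),
                                   collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  # (row, col, band) -> BSQ on disk: sample fastest, then line, then band
  writeBin(as.vector(aperm(cube$data, c(2, 1, 3))), path, size = 8,
           endian = "little")
  invisible(path)
}

#' Export a wavelength vector as single-column CSV
#' @param cube a [hypercube()].
#' @param path output CSV path.
#' @export
write_wavelengths_csv <- function(cube, path) {
  write.csv(data.frame(wavelength_nm = cube$wavelengths), path,
            row.names = FALSE)
  invisible(path)
}
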