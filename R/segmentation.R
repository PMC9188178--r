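#' SeedMask: labeled seed regions on an image grid
#'
#' `labels` is a 2-D integer matrix: 0 = background, k in 1..n_seeds = one
#' seed. Labels are contiguous and ordered by the raster position (row, then
#' column) of each region's centroid, so that seeds laid out in a grid get
#' predictable identities.
#'
#' @param labels integer matrix of region labels.
#' @return An object of class `SeedMask`.
#' @export
seed_mask <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  u <- sort(unique(as.vector(labels)))
  u <- u[u > 0]
  if (length(u) && !identical(u, seq_along(u)))
    stop("seed labels must be contiguous 1..n_seeds")
  structure(list(labels = labels, n_seeds = length(u)), class = "SeedMask")
}

#' @export
print.SeedMask <- function(x, ...) {
  cat(sprintf("SeedMask: %d x %d, %d seeds\n", nrow(x$labels),
              ncol(x$labels), x$n_seeds))
  invisible(x)
}

#' Otsu's threshold on a numeric vector
#'
#' Histogram-based (256 bins) maximization of between-class variance.
#' Exported because segmentation and the RGB branch both use it.
#'
#' @param x numeric values (NA dropped).
#' @param n_bins histogram resolution.
#' @return The threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(n_bins, 1L + floor((x - r[1]) / diff(r) * n_bins)),
                n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  r[1] + k / n_bins * diff(r)
}

# order labels by raster position of region centroids, renumber contiguously
renumber_raster <- function(labels) {
  u <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (!length(u)) return(labels)
  cent <- t(vapply(u, function(k) {
    w <- which(labels == k, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2)))
  ord <- order(cent[, 1], cent[, 2])
  out <- labels
  for (i in seq_along(ord)) out[labels == u[ord[i]]] <- i
  out
}

#' Threshold segmentation of a hypercube into seed regions
#'
#' Reduces the cube to a single image (band average by default), thresholds
#' it (Otsu by default), labels connected foreground regions, drops regions
#' below `min_area`, and renumbers labels contiguously in raster order of
#' their centroids.
#'
#' @param cube a [hypercube()].
#' @param method `"otsu"` or `"fixed"` (requires `threshold`).
#' @param band_reduce `"mean"` over all bands or `"single-band"` (requires
#'   `band`, an index into the retained bands).
#' @param threshold fixed threshold (foreground strictly above).
#' @param band band index for `band_reduce = "single-band"`.
#' @param min_area minimum region size in pixels.
#' @param connectivity 4 or 8 (default) for region connectivity.
#' @return A [seed_mask()]; `n_seeds` can be 0 (with a warning).
#' @export
threshold_mask <- function(cube, method = c("otsu", "fixed"),
                           band_reduce = c("mean", "single-band"),
                           threshold = NULL, band = NULL, min_area = 50L,
                           connectivity = 8L) {
  stopifnot(inherits(cube, "Hypercube"))
  method <- match.arg(method)
  band_reduce <- match.arg(band_reduce)
  img <- switch(band_reduce,
    mean = apply(cube$data, c(1, 2), mean),
    `single-band` = {
      if (is.null(band)) stop("`band` required for single-band reduction")
      cube$data[, , band]
    })
  thr <- switch(method,
    otsu = otsu_threshold(as.vector(img)),
    fixed = {
      if (is.null(threshold)) stop("`threshold` required for method 'fixed'")
      threshold
    })
  fg <- img > thr
  fg[is.na(fg)] <- FALSE
  if (!any(fg)) {
    warning("no foreground pixels; returning empty mask")
    return(seed_mask(matrix(0L, nrow(img), ncol(img))))
  }
  lab <- cpp_label_components(fg, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_area)
  if (length(small)) lab[lab %in% small] <- 0L
  seed_mask(renumber_raster(lab))
}

#' SpectrumTable: one mean reflectance spectrum per seed, plus labels
#'
#' @param spectra numeric matrix, seeds x bands, all finite.
#' @param wavelengths band centers in nm (column order of `spectra`).
#' @param meta data.frame with one row per seed; columns `category`
#'   (`"target"`/`"non-target"`), `variety`, `lot`, `surface` (`"germ"`,
#'   `"non-germ"` or `"unknown"`). Missing columns are filled with
#'   `"unknown"`.
#' @return An object of class `SpectrumTable`.
#' @export
spectrum_table <- function(spectra, wavelengths, meta = NULL) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavelengths))
    stop("spectrum length must equal the band count")
  if (any(!is.finite(spectra))) stop("spectra must be finite")
  n <- nrow(spectra)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))
  if (nrow(meta) != n) stop("meta rows must match seed count")
  for (col in c("category", "variety", "lot", "surface"))
    if (is.null(meta[[col]])) meta[[col]] <- rep("unknown", n)
  colnames(spectra) <- sprintf("%.1f", wavelengths)
  structure(list(spectra = spectra, wavelengths = as.numeric(wavelengths),
                 meta = meta), class = "SpectrumTable")
}

#' @export
print.SpectrumTable <- function(x, ...) {
  cat(sprintf("SpectrumTable: %d seeds x %d bands (%.1f-%.1f nm)\n",
              nrow(x$spectra), ncol(x$spectra), min(x$wavelengths),
              max(x$wavelengths)))
  if (nrow(x$spectra))
    print(table(category = x$meta$category))
  invisible(x)
}

#' Number of seeds in a SpectrumTable
#' @param x a [spectrum_table()].
#' @param ... unused.
#' @export
nseeds <- function(x, ...) UseMethod("nseeds")

#' @export
nseeds.SpectrumTable <- function(x, ...) nrow(x$spectra)

#' Row-subset a SpectrumTable
#' @param x a [spectrum_table()].
#' @param i row index.
#' @param ... unused.
#' @export
subset_rows <- function(x, i, ...) UseMethod("subset_rows")

#' @export
subset_rows.SpectrumTable <- function(x, i, ...) {
  spectrum_table(x$spectra[i, , drop = FALSE], x$wavelengths,
                 x$meta[i, , drop = FALSE])
}

#' Concatenate SpectrumTables sharing a wavelength grid
#' @param ... [spectrum_table()] objects.
#' @return A combined `SpectrumTable`.
#' @export
bind_spectra <- function(...) {
  xs <- list(...)
  wl <- xs[[1]]$wavelengths
  for (x in xs)
    if (!isTRUE(all.equal(x$wavelengths, wl)))
      stop("wavelength grids differ")
  spectrum_table(do.call(rbind, lapply(xs, `[[`, "spectra")), wl,
                 do.call(rbind, lapply(xs, `[[`, "meta")))
}

#' Extract one mean spectrum per seed
#'
#' `spectrum[b]` for seed k is the arithmetic mean of the cube over the
#' pixels labeled k at band b; background (label 0) never contributes. Rows
#' are ordered by ascending label.
#'
#' @param cube a [hypercube()].
#' @param mask a [seed_mask()] with the cube's spatial shape.
#' @param labels_meta optional data.frame of per-seed annotations (one row
#'   per seed, in label order).
#' @return A [spectrum_table()].
#' @export
extract_mean_spectra <- function(cube, mask, labels_meta = NULL) {
  stopifnot(inherits(cube, "Hypercube"), inherits(mask, "SeedMask"))
  if (!all(dim(mask$labels) == dim(cube$data)[1:2]))
    stop("mask shape does not match cube spatial shape")
  if (!is.null(labels_meta) && nrow(labels_meta) != mask$n_seeds)
    stop(sprintf("annotation rows (%d) != n_seeds (%d)", nrow(labels_meta),
                 mask$n_seeds))
  nb <- dim(cube$data)[3L]
  lab <- as.vector(mask$labels)
  keep <- lab > 0
  flat <- matrix(cube$data, ncol = nb)  # pixels x bands
  sums <- rowsum(flat[keep, , drop = FALSE], lab[keep])
  counts <- tabulate(lab[keep], mask$n_seeds)
  spectra <- sums / counts
  rownames(spectra) <- NULL
  spectrum_table(spectra, cube$wavelengths, labels_meta)
}

#' Write/read a SpectrumTable as CSV
#'
#' One row per seed: wavelength-named reflectance columns (e.g. `wl_400.0`)
#' followed by the label columns.
#'
#' @param x a [spectrum_table()].
#' @param path CSV path.
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "SpectrumTable"))
  df <- as.data.frame(x$spectra)
  names(df) <- paste0("wl_", sprintf("%.1f", x$wavelengths))
  write.csv(cbind(df, x$meta), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wl_cols <- grep("^wl_", names(df))
  if (!length(wl_cols)) stop("no wl_* columns in ", path)
  wl <- as.numeric(sub("^wl_", "", names(df)[wl_cols]))
  spectrum_table(as.matrix(df[wl_cols]), wl, df[-wl_cols])
}

#' Export a SeedMask as a plain-text label image (PGM)
#' @param mask a [seed_mask()].
#' @param path output path (plain PGM, P2).
#' @export
write_mask_pgm <- function(mask, path) {
  stopifnot(inherits(mask, "SeedMask"))
  m <- mask$labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(max(1L, max(m)))),
             con)
  write(t(m), con, ncolumns = ncol(m))
  invisible(path)
}
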