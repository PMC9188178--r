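#' The 54-feature registry for RGB seed scans
#'
#' Names of the fixed per-seed feature set: 14 shape, 24 color and 16 texture
#' features. The commercial tool the field uses does not publish its feature
#' list; this registry is a documented stand-in with the same group structure
#' and cardinality (shape/color/texture, 54 total).
#'
#' @return Named list with `shape`, `color`, `texture` character vectors (14,
#'   24 and 16 names; 54 in total).
#' @export
feature_registry <- function() {
  shape <- c("area", "perimeter", "major_axis", "minor_axis", "aspect_ratio",
             "eccentricity", "circularity", "solidity", "extent",
             "convex_area", "equiv_diameter", "orientation", "bbox_width",
             "bbox_height")
  color <- as.vector(t(outer(c("R", "G", "B", "H", "S", "V"),
                             c("mean", "std", "min", "max"), paste,
                             sep = "_")))
  texture <- as.vector(t(outer(c("glcm_contrast", "glcm_correlation",
                                 "glcm_energy", "glcm_homogeneity"),
                               c("0", "45", "90", "135"), paste, sep = "_")))
  list(shape = shape, color = color, texture = texture)
}

feature_names <- function() unlist(feature_registry(), use.names = FALSE)

#' Read an RGB image from a PNG file
#'
#' Returns an (rows x cols x 3) array in \[0, 1\]. TIFF input is not
#' supported in this environment; convert to PNG first or pass arrays
#' directly to [extract_seed_features()].
#'
#' @param path PNG path.
#' @return Numeric array (rows, cols, 3).
#' @export
read_rgb <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG requires the 'png' package")
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

# -- shape helpers ------------------------------------------------------------

# Cauchy-Crofton perimeter: pi/4 * (horizontal + vertical boundary
# transitions), minus the constant +pi digitization bias of convex blobs.
# Near-exact for discs/ellipses (seed-like shapes); biased low for
# rectilinear shapes, a documented limitation.
region_perimeter <- function(ind) {
  pad <- matrix(0, nrow(ind) + 2, ncol(ind) + 2)
  pad[2:(nrow(ind) + 1), 2:(ncol(ind) + 1)] <- ind
  n_h <- sum(pad[, -1] != pad[, -ncol(pad)])
  n_v <- sum(pad[-1, ] != pad[-nrow(pad), ])
  max(pi / 4 * (n_h + n_v) - pi, 2)
}

# area of the convex hull of pixel centers (+0.5 px dilation not attempted)
convex_hull_area <- function(rc) {
  if (nrow(rc) < 3) return(nrow(rc))
  h <- chull(rc)
  xy <- rc[h, , drop = FALSE]
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

shape_features <- function(ind) {
  rc <- which(ind > 0, arr.ind = TRUE)
  area <- nrow(rc)
  per <- region_perimeter(ind)
  mu <- colMeans(rc)
  xc <- rc[, 1] - mu[1]; yc <- rc[, 2] - mu[2]
  # second central moments with the 1/12 px^2 correction of a unit square
  uxx <- mean(xc^2) + 1 / 12
  uyy <- mean(yc^2) + 1 / 12
  uxy <- mean(xc * yc)
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major <- 4 * sqrt((uxx + uyy + common) / 2)
  minor <- 4 * sqrt(pmax(uxx + uyy - common, 0) / 2)
  ecc <- if (major > 0) sqrt(pmax(1 - (minor / major)^2, 0)) else 0
  orient <- 0.5 * atan2(2 * uxy, uxx - uyy)
  bb_h <- diff(range(rc[, 1])) + 1  # rows
  bb_w <- diff(range(rc[, 2])) + 1  # columns
  conv <- max(convex_hull_area(rc), area)
  c(area = area,
    perimeter = per,
    major_axis = major,
    minor_axis = minor,
    aspect_ratio = if (minor > 0) major / minor else NA_real_,
    eccentricity = ecc,
    circularity = 4 * pi * area / per^2,
    solidity = area / conv,
    extent = area / (bb_w * bb_h),
    convex_area = conv,
    equiv_diameter = sqrt(4 * area / pi),
    orientation = orient,
    bbox_width = bb_w,
    bbox_height = bb_h)
}

# -- color helpers ------------------------------------------------------------

color_features <- function(image, idx) {
  chans <- lapply(1:3, function(k) as.vector(image[, , k])[idx])
  hsv <- rgb2hsv(rbind(chans[[1]], chans[[2]], chans[[3]]), maxColorValue = 1)
  all6 <- c(chans, list(hsv[1, ], hsv[2, ], hsv[3, ]))
  names(all6) <- c("R", "G", "B", "H", "S", "V")
  out <- unlist(lapply(names(all6), function(nm) {
    v <- all6[[nm]]
    s <- c(mean(v), sd(v), min(v), max(v))
    names(s) <- paste(nm, c("mean", "std", "min", "max"), sep = "_")
    s
  }))
  out[is.na(out)] <- 0  # sd of a single pixel
  out
}

# -- texture helpers ----------------------------------------------------------

# GLCM over pixel pairs that are both inside the region; symmetric,
# normalized; `gray` is an integer matrix in 1..levels, 0 outside the region
glcm_stats <- function(gray, levels, dr, dc) {
  nr <- nrow(gray); nc <- ncol(gray)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- gray[r1, c1, drop = FALSE]
  b <- gray[r1 + dr, c1 + dc, drop = FALSE]
  ok <- a > 0 & b > 0
  if (!any(ok))
    return(c(contrast = 0, correlation = 1, energy = 1, homogeneity = 1))
  ai <- a[ok]; bi <- b[ok]
  P <- matrix(0, levels, levels)
  tab <- table(factor(ai, levels = 1:levels), factor(bi, levels = 1:levels))
  P <- unclass(tab) + t(unclass(tab))  # symmetric
  P <- P / sum(P)
  i <- row(P); j <- col(P)
  contrast <- sum(P * (i - j)^2)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + (i - j)^2))
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  s_i <- sqrt(sum((i - mu_i)^2 * P)); s_j <- sqrt(sum((j - mu_j)^2 * P))
  correlation <- if (s_i > 0 && s_j > 0)
    sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j) else 1
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity)
}

texture_features <- function(image, ind, levels = 32L) {
  # ITU-R 601 luma, quantized to `levels` gray levels over [0, 1]
  luma <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  gray <- matrix(0L, nrow(ind), ncol(ind))
  gray[ind > 0] <- pmin(levels, 1L + as.integer(floor(luma[ind > 0] * levels)))
  # orientations 0, 45, 90, 135 degrees at distance 1 (image convention:
  # 0 = along a row, 90 = along a column)
  offs <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
               `135` = c(-1L, -1L))
  out <- numeric(0)
  for (ang in names(offs)) {
    s <- glcm_stats(gray, levels, offs[[ang]][1], offs[[ang]][2])
    names(s) <- paste0("glcm_", names(s), "_", ang)
    out <- c(out, s)
  }
  out
}

#' Extract the 54 shape/color/texture features for every seed
#'
#' Features follow [feature_registry()]: 14 shape features from the binary
#' region (moments-based axes, sub-pixel contour perimeter, convex hull), 24
#' color features (mean/std/min/max of R, G, B, H, S, V over seed pixels) and
#' 16 texture features (gray-level co-occurrence contrast, correlation,
#' energy and homogeneity at orientations 0/45/90/135 degrees, distance 1 px,
#' on a 32-level ITU-R 601 gray conversion). Seeds touching the image border
#' are flagged in the `border` column but their features are still computed
#' on the visible region.
#'
#' @param image numeric array (rows, cols, 3) in \[0, 1\], or a PNG path.
#' @param mask a [seed_mask()] aligned to the image.
#' @param meta optional per-seed annotation data.frame (category, variety,
#'   lot, surface), one row per seed.
#' @return A `FeatureTable`: data.frame with 54 feature columns, a `border`
#'   flag, and the annotation columns.
#' @export
extract_seed_features <- function(image, mask, meta = NULL) {
  if (is.character(image)) image <- read_rgb(image)
  stopifnot(inherits(mask, "SeedMask"), length(dim(image)) == 3L)
  if (!all(dim(mask$labels) == dim(image)[1:2]))
    stop("mask not aligned to image")
  n <- mask$n_seeds
  if (!is.null(meta) && nrow(meta) != n)
    stop("annotation rows must equal n_seeds")
  rows <- vector("list", n)
  border <- logical(n)
  for (k in seq_len(n)) {
    ind <- (mask$labels == k) * 1
    idx <- which(as.vector(ind) > 0)
    rc <- which(ind > 0, arr.ind = TRUE)
    border[k] <- any(rc[, 1] %in% c(1, nrow(ind))) ||
      any(rc[, 2] %in% c(1, ncol(ind)))
    rows[[k]] <- c(shape_features(ind), color_features(image, idx),
                   texture_features(image, ind))
  }
  ft <- as.data.frame(do.call(rbind, rows))
  ft <- ft[feature_names()]  # registry order (rows are grouped by angle)
  ft$border <- border
  if (is.null(meta))
    meta <- data.frame(category = rep("unknown", n), variety = "unknown",
                       lot = "unknown", surface = "unknown")
  ft <- cbind(ft, meta)
  class(ft) <- c("FeatureTable", "data.frame")
  ft
}

#' Construct a FeatureTable from a plain data.frame
#'
#' Validates that all 54 registry features are present and finite.
#'
#' @param df data.frame containing the 54 feature columns plus annotations.
#' @return A `FeatureTable`.
#' @export
feature_table <- function(df) {
  missing_cols <- setdiff(feature_names(), names(df))
  if (length(missing_cols))
    stop("missing feature columns: ", paste(head(missing_cols, 5),
                                            collapse = ", "))
  if (any(!is.finite(as.matrix(df[feature_names()]))))
    stop("feature values must be finite")
  for (col in c("category", "variety", "lot", "surface"))
    if (is.null(df[[col]])) df[[col]] <- "unknown"
  class(df) <- c("FeatureTable", "data.frame")
  df
}

#' Feature matrix / labels accessors
#' @param x a `FeatureTable`.
#' @return `feature_matrix`: numeric matrix (seeds x 54);
#' @export
feature_matrix <- function(x) as.matrix(as.data.frame(x)[feature_names()])

#' Per-feature distribution overlap between the two categories
#'
#' For each of the 54 features, estimates a kernel density per category on a
#' shared grid and reports the overlap coefficient: the integral of the
#' pointwise minimum of the two densities, in \[0, 1\] (1 = identical
#' distributions, 0 = disjoint supports). This quantifies how confounded
#' each feature is between target and non-target seeds.
#'
#' @param table a `FeatureTable` containing both categories.
#' @param n_grid density grid resolution.
#' @return data.frame with `feature`, `group` and `overlap` columns, sorted
#'   by ascending overlap.
#' @export
feature_overlap_report <- function(table, n_grid = 512L) {
  df <- as.data.frame(table)
  cats <- unique(df$category)
  if (length(cats) < 2)
    stop("feature_overlap_report needs both categories present")
  reg <- feature_registry()
  grp <- rep(names(reg), lengths(reg))
  out <- data.frame(feature = feature_names(), group = grp,
                    overlap = NA_real_)
  a <- df$category == cats[1]
  for (i in seq_len(nrow(out))) {
    v1 <- df[[out$feature[i]]][a]
    v2 <- df[[out$feature[i]]][!a]
    out$overlap[i] <- density_overlap(v1, v2, n_grid)
  }
  out[order(out$overlap), ]
}

# overlap coefficient of two samples via KDE on a common grid
density_overlap <- function(v1, v2, n_grid = 512L) {
  if (sd(v1) == 0 && sd(v2) == 0)
    return(if (isTRUE(all.equal(mean(v1), mean(v2)))) 1 else 0)
  lo <- min(v1, v2); hi <- max(v1, v2)
  pad <- 0.2 * (hi - lo) + 1e-12
  bw1 <- tryCatch(stats::bw.nrd0(v1), error = function(e) 1e-6)
  bw2 <- tryCatch(stats::bw.nrd0(v2), error = function(e) 1e-6)
  d1 <- density(v1, bw = max(bw1, 1e-9), from = lo - pad, to = hi + pad,
                n = n_grid)
  d2 <- density(v2, bw = max(bw2, 1e-9), from = lo - pad, to = hi + pad,
                n = n_grid)
  dx <- d1$x[2] - d1$x[1]
  min(1, sum(pmin(d1$y, d2$y)) * dx)
}

#' Write a FeatureTable (or overlap report) as CSV
#' @param x data.frame-like object.
#' @param path CSV path.
#' @export
write_feature_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) feature_table(read.csv(path))
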