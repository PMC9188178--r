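#' VarietySpec: generative parameters for one variety's reflectance
#'
#' A variety's mean spectrum on 400-1000 nm is a smooth logistic ramp rising
#' toward the NIR (reflectance capped below 0.8) minus Gaussian absorption
#' features at the regions where seed chemistry differentiates varieties:
#' protein-linked absorption at 400-500 nm, starch/oil-linked absorption at
#' 500-750 nm, and the ~980 nm water/carbohydrate band (second overtone of
#' O-H stretching). Variability has two scales: a flat between-lot shift
#' (`lot_sigma`, drawn once per lot) and smooth within-lot seed-to-seed
#' noise (`seed_sigma`, spectrally correlated with ~20 nm bandwidth).
#'
#' @param baseline list(lo, hi, center, width) of the logistic ramp
#'   `lo + (hi - lo) / (1 + exp(-(lambda - center)/width))`.
#' @param bands data.frame with columns `center` (nm), `depth` (reflectance
#'   units), `width` (nm, Gaussian sigma) and `name`.
#' @param lot_sigma,seed_sigma,scatter_sigma noise scales in reflectance
#'   units: flat between-lot shift, smooth within-lot spectral noise, and
#'   flat per-seed scattering offset (the dominant seed-to-seed spread in
#'   raw reflectance plots, caused by coat gloss/geometry rather than
#'   chemistry).
#' @param d divergence of this variety's band depths from the target's
#'   (Euclidean distance in depth space); 0 for the target itself.
#' @param name variety label.
#' @return A `VarietySpec`.
#' @export
variety_spec <- function(baseline = list(lo = 0.15, hi = 0.65, center = 720,
                                         width = 120),
                         bands = data.frame(
                           center = c(450, 650, 980),
                           depth = c(0.08, 0.06, 0.10),
                           width = c(30, 60, 25),
                           name = c("protein", "starch_oil", "water")),
                         lot_sigma = 0.01, seed_sigma = 0.008,
                         scatter_sigma = 0.02, d = 0,
                         name = "target") {
  structure(list(baseline = baseline, bands = bands, lot_sigma = lot_sigma,
                 seed_sigma = seed_sigma, scatter_sigma = scatter_sigma,
                 d = d, name = name),
            class = "VarietySpec")
}

#' Analytic mean spectrum of a VarietySpec
#' @param spec a [variety_spec()].
#' @param grid wavelengths in nm.
#' @return Numeric vector of reflectance values.
#' @export
mean_spectrum <- function(spec, grid) {
  b <- spec$baseline
  r <- b$lo + (b$hi - b$lo) / (1 + exp(-(grid - b$center) / b$width))
  for (i in seq_len(nrow(spec$bands)))
    r <- r - spec$bands$depth[i] *
      exp(-(grid - spec$bands$center[i])^2 / (2 * spec$bands$width[i]^2))
  r
}

#' Derive a non-target VarietySpec at divergence d from a target
#'
#' Perturbs the target's band depths by `d * u`, where `u` is a seeded
#' random unit direction in depth space. The map is linear in `d`: for a
#' fixed seed, doubling `d` exactly doubles the Euclidean distance between
#' the two mean spectra. (The mapping from genetic distance, e.g. differing
#' SSR loci, to `d` is a modeling convenience, not a biological claim.)
#'
#' @param target a [variety_spec()].
#' @param d divergence scalar (>= 0).
#' @param seed RNG seed fixing the perturbation direction.
#' @param name label for the derived variety.
#' @return A `VarietySpec` with perturbed depths and `d` recorded.
#' @export
make_variety_spec <- function(target, d, seed = 1L, name = NULL) {
  stopifnot(inherits(target, "VarietySpec"), d >= 0)
  out <- target
  if (d > 0) {
    set.seed(seed)
    u <- rnorm(nrow(target$bands))
    u <- u / sqrt(sum(u^2))
    out$bands$depth <- target$bands$depth + d * u
  }
  out$d <- d
  out$name <- name %||% paste0(target$name, "_d", format(d))
  out
}

# spectrally-correlated noise: kernel-smoothed white noise, unit marginal sd
smooth_noise <- function(n, grid, bandwidth = 20) {
  W <- matrix(rnorm(n * length(grid)), n)
  Kern <- exp(-outer(grid, grid, `-`)^2 / (2 * bandwidth^2))
  Kern <- Kern / sqrt(rowSums(Kern^2))  # rows scaled to unit L2 norm
  W %*% t(Kern)
}

#' Simulate per-seed mean spectra for one variety
#'
#' `spectrum = mean_spectrum - surface offset + lot shift + per-seed
#' scattering offset + smooth seed noise`, then clipped (with a warning)
#' into (0, 0.8) — measured seed reflectance stays below 0.8. The lot shift
#' is flat across wavelength, drawn once per lot at scale `lot_sigma`; the
#' scattering offset is flat per seed at scale `scatter_sigma` (coat
#' gloss/geometry — the dominant within-lot spread); the spectral residual
#' is smooth (bandwidth ~20 nm) at marginal scale `seed_sigma`.
#' Germ-surface rows sit `germ_offset` lower than non-germ rows (the embryo
#' absorbs slightly more).
#'
#' @param spec a [variety_spec()].
#' @param n_lots,seeds_per_lot design of this variety's sample.
#' @param grid wavelengths in nm, within \[400, 1000\].
#' @param seed RNG seed.
#' @param category `"target"` or `"non-target"`.
#' @param surface `"germ"`, `"non-germ"`, `"unknown"`, or both (each seed
#'   then contributes one row per surface).
#' @param germ_offset flat reflectance decrease on the germ surface.
#' @return A [spectrum_table()] labeled with variety/lot/surface.
#' @export
simulate_spectra <- function(spec, n_lots = 1L, seeds_per_lot = 35L,
                             grid = seq(400, 1000, by = 4), seed = 1L,
                             category = "non-target", surface = "unknown",
                             germ_offset = 0.02) {
  stopifnot(inherits(spec, "VarietySpec"), min(grid) >= 400,
            max(grid) <= 1000, n_lots >= 1, seeds_per_lot >= 1)
  set.seed(seed)
  mu <- mean_spectrum(spec, grid)
  n <- n_lots * seeds_per_lot * length(surface)
  lot_shift <- rnorm(n_lots, 0, spec$lot_sigma)
  rows <- matrix(rep(mu, each = n), n)
  lot_id <- rep(rep(seq_len(n_lots), each = seeds_per_lot), length(surface))
  surf <- rep(surface, each = n_lots * seeds_per_lot)
  rows <- rows + lot_shift[lot_id]
  if ((spec$scatter_sigma %||% 0) > 0)
    rows <- rows + rnorm(n, 0, spec$scatter_sigma)
  if (spec$seed_sigma > 0)
    rows <- rows + spec$seed_sigma * smooth_noise(n, grid)
  rows <- rows - germ_offset * (surf == "germ")
  if (any(rows <= 0) || any(rows >= 0.8)) {
    warning("simulated reflectance clipped into (0, 0.8)")
    rows <- pmin(pmax(rows, 1e-6), 0.8 - 1e-6)
  }
  meta <- data.frame(category = category, variety = spec$name,
                     lot = paste0(spec$name, "_lot", lot_id),
                     surface = surf)
  spectrum_table(rows, grid, meta)
}

#' ScenarioConfig: a full two-category study design
#'
#' Defaults mirror the reference design: a target variety with 9 seed lots
#' of 35 seeds, against 9 genetically similar non-target varieties of 35
#' seeds each (divergences mapped linearly from 2-10 differing SSR loci out
#' of 40), plus an optional external verification panel (2 held-out target
#' lots and 10 common-hybrid varieties, 35 seeds each).
#'
#' @param n_target_lots,seeds_per_lot target design.
#' @param nontarget_divergence divergence per non-target variety; the
#'   default maps loci counts (2,3,5,5,7,8,8,8,10) at `divergence_per_locus`.
#' @param divergence_per_locus linear loci-to-divergence scale.
#' @param n_external_target_lots,external_divergence external panel: held-out
#'   target lots and divergences of the external varieties (NULL disables
#'   the panel).
#' @param surfaces surfaces generated per seed (one row per surface).
#' @param lot_sigma,seed_sigma,scatter_sigma noise scales handed to every
#'   variety (see [variety_spec()]).
#' @param target a [variety_spec()] for the target variety.
#' @return A `ScenarioConfig`.
#' @export
scenario_config <- function(n_target_lots = 9L, seeds_per_lot = 35L,
                            nontarget_divergence =
                              c(2, 3, 5, 5, 7, 8, 8, 8, 10) *
                              divergence_per_locus,
                            divergence_per_locus = 0.016,
                            n_external_target_lots = 0L,
                            external_divergence = NULL,
                            surfaces = "unknown",
                            lot_sigma = 0.01, seed_sigma = 0.008,
                            scatter_sigma = 0.02,
                            target = variety_spec(lot_sigma = lot_sigma,
                                                  seed_sigma = seed_sigma,
                                                  scatter_sigma =
                                                    scatter_sigma)) {
  stopifnot(seeds_per_lot >= 1, n_target_lots >= 1,
            all(nontarget_divergence >= 0))
  target$lot_sigma <- lot_sigma
  target$seed_sigma <- seed_sigma
  target$scatter_sigma <- scatter_sigma
  structure(list(n_target_lots = n_target_lots,
                 seeds_per_lot = seeds_per_lot,
                 nontarget_divergence = nontarget_divergence,
                 n_external_target_lots = n_external_target_lots,
                 external_divergence = external_divergence,
                 surfaces = surfaces, target = target),
            class = "ScenarioConfig")
}

#' Simulate a full scenario: training table and optional external panel
#'
#' @param cfg a [scenario_config()].
#' @param seed RNG seed; everything (specs, lots, noise) derives from it.
#' @param grid wavelength grid in nm.
#' @return list with `train` (a [spectrum_table()] holding both categories)
#'   and `external` (a `SpectrumTable` of held-out lots/varieties, or NULL).
#' @export
simulate_scenario <- function(cfg, seed = 1L,
                              grid = seq(400, 1000, by = 4)) {
  stopifnot(inherits(cfg, "ScenarioConfig"))
  tgt <- cfg$target
  parts <- list(simulate_spectra(tgt, cfg$n_target_lots, cfg$seeds_per_lot,
                                 grid, seed = seed, category = "target",
                                 surface = cfg$surfaces))
  nd <- cfg$nontarget_divergence
  for (i in seq_along(nd)) {
    sp <- make_variety_spec(tgt, nd[i], seed = seed * 1000L + i,
                            name = paste0("sim_nt_", i))
    parts[[length(parts) + 1L]] <-
      simulate_spectra(sp, 1L, cfg$seeds_per_lot, grid,
                       seed = seed * 100L + i, category = "non-target",
                       surface = cfg$surfaces)
  }
  train <- do.call(bind_spectra, parts)

  external <- NULL
  n_ext <- length(cfg$external_divergence %||% numeric(0))
  if (cfg$n_external_target_lots > 0 || n_ext > 0) {
    ext <- list()
    if (cfg$n_external_target_lots > 0) {
      et <- simulate_spectra(tgt, cfg$n_external_target_lots,
                             cfg$seeds_per_lot, grid,
                             seed = seed + 7777L, category = "target",
                             surface = cfg$surfaces)
      et$meta$variety <- "target_external"
      ext[[1]] <- et
    }
    for (i in seq_len(n_ext)) {
      sp <- make_variety_spec(tgt, cfg$external_divergence[i],
                              seed = seed * 1000L + 500L + i,
                              name = paste0("sim_ext_", i))
      ext[[length(ext) + 1L]] <-
        simulate_spectra(sp, 1L, cfg$seeds_per_lot, grid,
                         seed = seed * 100L + 50L + i,
                         category = "non-target", surface = cfg$surfaces)
    }
    external <- do.call(bind_spectra, ext)
  }
  list(train = train, external = external)
}

#' Simulate a hypercube with known per-seed spectra and ground-truth mask
#'
#' Lays ellipse-footprint seeds on a regular grid over a flat background,
#' fills each footprint with one simulated per-seed spectrum (optionally
#' plus iid pixel noise), and returns the cube together with the
#' ground-truth mask and spectrum table — the oracle for segmentation and
#' extraction tests. Footprints never touch (grid placement is checked;
#' overlap is an error).
#'
#' @param specs a `VarietySpec` or list of them, recycled over seeds.
#' @param n_seeds number of seeds to place.
#' @param image_size c(rows, cols).
#' @param background flat background reflectance (default 0.05).
#' @param seed_rx,seed_ry ellipse semi-axes in px.
#' @param pixel_sigma iid per-pixel noise sd (0 = noise-free).
#' @param seed RNG seed.
#' @param grid wavelength grid in nm.
#' @return list(cube, mask, table): [hypercube()], [seed_mask()],
#'   [spectrum_table()]; table row k corresponds to mask label k.
#' @export
simulate_hypercube <- function(specs, n_seeds = 4L,
                               image_size = c(60, 60), background = 0.05,
                               seed_rx = 5, seed_ry = 4, pixel_sigma = 0,
                               seed = 1L, grid = seq(400, 1000, by = 50)) {
  if (inherits(specs, "VarietySpec")) specs <- list(specs)
  nr <- image_size[1]; nc <- image_size[2]
  # grid layout with >= 2 px clearance between footprints
  pitch_r <- 2 * seed_ry + 4
  pitch_c <- 2 * seed_rx + 4
  per_row <- floor((nc - 2) / pitch_c)
  n_rows <- floor((nr - 2) / pitch_r)
  if (per_row < 1 || n_rows * per_row < n_seeds)
    stop("seed footprints do not fit the image without overlap")
  centers <- cbind(
    r = 1 + pitch_r * (ceiling(seq_len(n_seeds) / per_row) - 0.5),
    c = 1 + pitch_c * (((seq_len(n_seeds) - 1) %% per_row) + 0.5))

  nb <- length(grid)
  cube <- array(background, c(nr, nc, nb))
  labels <- matrix(0L, nr, nc)
  spectra <- matrix(NA_real_, n_seeds, nb)
  meta <- NULL
  rr <- row(labels); cc <- col(labels)
  for (k in seq_len(n_seeds)) {
    sp <- specs[[(k - 1) %% length(specs) + 1]]
    st <- simulate_spectra(sp, 1L, 1L, grid, seed = seed * 100L + k,
                           category = if (sp$d == 0) "target" else
                             "non-target")
    spectra[k, ] <- st$spectra[1, ]
    meta <- rbind(meta, st$meta)
    inside <- ((rr - centers[k, 1]) / seed_ry)^2 +
      ((cc - centers[k, 2]) / seed_rx)^2 <= 1
    if (any(labels[inside] != 0)) stop("seed footprints overlap")
    labels[inside] <- k
    for (b in seq_len(nb)) {
      plane <- cube[, , b]
      plane[inside] <- spectra[k, b]
      cube[, , b] <- plane
    }
  }
  if (pixel_sigma > 0) {
    set.seed(seed + 999L)
    cube <- cube + array(rnorm(length(cube), 0, pixel_sigma), dim(cube))
  }
  list(cube = hypercube(cube, grid, meta = list(simulated = TRUE)),
       mask = seed_mask(labels),
       table = spectrum_table(spectra, grid, meta))
}

#' Simulate a 54-feature table with controlled between-category shifts
#'
#' Draws both categories from independent-normal feature distributions with
#' unit variance; the target category's means are shifted by `effect`
#' (named vector over registry features, or a single number recycled).
#' A zero effect reproduces the heavily overlapping feature distributions
#' seen in real scans of near-identical varieties.
#'
#' @param n_per_class seeds per category.
#' @param effect per-feature mean shift; names must be registry feature
#'   names (unnamed scalar/vector recycled over all 54).
#' @param seed RNG seed.
#' @return A `FeatureTable` with `2 * n_per_class` rows.
#' @export
simulate_feature_table <- function(n_per_class = 300L, effect = 0,
                                   seed = 1L) {
  nms <- feature_names()
  shift <- rep(0, length(nms))
  names(shift) <- nms
  if (is.null(names(effect))) {
    shift[] <- rep_len(effect, length(nms))
  } else {
    bad <- setdiff(names(effect), nms)
    if (length(bad)) stop("unknown features in effect: ",
                          paste(bad, collapse = ", "))
    shift[names(effect)] <- effect
  }
  set.seed(seed)
  x0 <- matrix(rnorm(n_per_class * length(nms)), n_per_class)
  x1 <- matrix(rnorm(n_per_class * length(nms)), n_per_class,
               byrow = FALSE) + matrix(shift, n_per_class, length(nms),
                                       byrow = TRUE)
  df <- as.data.frame(rbind(x1, x0))
  names(df) <- nms
  df$category <- rep(c("target", "non-target"), each = n_per_class)
  df$variety <- rep(c("sim_target", "sim_nontarget"), each = n_per_class)
  df$lot <- "sim_lot"
  df$surface <- "unknown"
  feature_table(df)
}

#' Write/read a ScenarioConfig as JSON
#' @param cfg a [scenario_config()].
#' @param path JSON path.
#' @export
write_scenario_json <- function(cfg, path) {
  x <- unclass(cfg)
  x$target <- unclass(x$target)
  x$target$bands <- as.list(x$target$bands)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tgt <- variety_spec(baseline = as.list(x$target$baseline),
                      bands = as.data.frame(x$target$bands),
                      lot_sigma = x$target$lot_sigma,
                      seed_sigma = x$target$seed_sigma,
                      scatter_sigma = x$target$scatter_sigma %||% 0,
                      d = x$target$d, name = x$target$name)
  scenario_config(n_target_lots = x$n_target_lots,
                  seeds_per_lot = x$seeds_per_lot,
                  nontarget_divergence = x$nontarget_divergence,
                  n_external_target_lots = x$n_external_target_lots %||% 0L,
                  external_divergence = x$external_divergence,
                  surfaces = x$surfaces,
                  lot_sigma = x$target$lot_sigma,
                  seed_sigma = x$target$seed_sigma,
                  scatter_sigma = x$target$scatter_sigma %||% 0,
                  target = tgt)
}
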