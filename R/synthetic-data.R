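#' Synthetic seed-spectra generator configuration
#'
#' Defines the statistical conditions under which synthetic maize-seed
#' reflectance spectra and hyperspectral scenes are generated. The defaults
#' mirror the acquisition design of the study system: 20 varieties, 150 seeds
#' per variety (3000 samples), 320 bands spanning 380-1018 nm.
#'
#' The class-mean template is a logistic rise centred at 650 nm (width 60 nm)
#' from a visible-range baseline of 0.1 to a near-infrared plateau of 0.65,
#' reproducing the canonical maize-seed reflectance shape: low reflectance
#' over 380-550 nm, a rapid rise over 550-750 nm and a plateau over
#' 750-900 nm. Class identity is carried by Gaussian bumps confined to the
#' discriminative windows 600-750 nm and 900-1018 nm.
#'
#' @param n_classes number of varieties (default 20).
#' @param seeds_per_class seeds per variety (default 150).
#' @param n_bands spectral bands (default 320).
#' @param wavelength_min_nm,wavelength_max_nm grid limits (default 380, 1018).
#' @param class_separation non-negative scalar scaling the class-specific
#'   bump amplitudes; 0 removes all inter-class structure.
#' @param noise_sd per-band i.i.d. Gaussian noise standard deviation.
#' @param seed_curve_amplitude amplitude scale of the smooth per-seed random
#'   curve emulating within-variety biological variability; 0 disables it.
#' @param mode `"bumps"` gives each class independently drawn bumps in the
#'   two discriminative windows; `"long_range"` builds classes from a grid of
#'   shared visible-range and NIR bump centres so that no single window
#'   identifies a class -- only the *pair* of bumps does, planting a
#'   long-range spectral dependency.
#' @param rng_seed integer seed making all generated output reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_classes = 20, seeds_per_class = 150, n_bands = 320,
                         wavelength_min_nm = 380, wavelength_max_nm = 1018,
                         class_separation = 1.4, noise_sd = 0.01,
                         seed_curve_amplitude = 0.02,
                         mode = c("bumps", "long_range"), rng_seed = 1L) {
  cfg <- list(
    n_classes = check_count(n_classes, "n_classes"),
    seeds_per_class = check_count(seeds_per_class, "seeds_per_class"),
    n_bands = check_count(n_bands, "n_bands", min = 2),
    wavelength_min_nm = as.numeric(wavelength_min_nm),
    wavelength_max_nm = as.numeric(wavelength_max_nm),
    class_separation = check_nonneg(class_separation, "class_separation"),
    noise_sd = check_nonneg(noise_sd, "noise_sd"),
    seed_curve_amplitude = check_nonneg(seed_curve_amplitude, "seed_curve_amplitude"),
    mode = match.arg(mode),
    rng_seed = as.integer(rng_seed))
  if (cfg$wavelength_min_nm >= cfg$wavelength_max_nm)
    abort("wavelength_min_nm must be < wavelength_max_nm",
          class = "spectraseed_config_error")
  structure(cfg, class = "synth_config")
}

synth_wavelengths <- function(cfg) {
  seq(cfg$wavelength_min_nm, cfg$wavelength_max_nm, length.out = cfg$n_bands)
}

# logistic VIS->NIR template shared by all classes
synth_template <- function(wl) 0.1 + 0.55 * stats::plogis((wl - 650) / 60)

# Class-mean curves: template plus class bumps. Drawn under the config RNG so
# the same config always yields the same class structure.
synth_class_means <- function(cfg) {
  wl <- synth_wavelengths(cfg)
  base <- synth_template(wl)
  gauss <- function(centre, sigma) exp(-0.5 * ((wl - centre) / sigma)^2)
  means <- matrix(rep(base, cfg$n_classes), nrow = cfg$n_classes, byrow = TRUE)
  with_seed(cfg$rng_seed, {
    if (cfg$mode == "bumps") {
      for (k in seq_len(cfg$n_classes)) {
        c1 <- runif(1, 600, 750); c2 <- runif(1, 900, 1018)
        s1 <- runif(1, 15, 30);   s2 <- runif(1, 15, 30)
        a1 <- sample(c(-1, 1), 1) * runif(1, 0.04, 0.09) * cfg$class_separation
        a2 <- sample(c(-1, 1), 1) * runif(1, 0.04, 0.09) * cfg$class_separation
        means[k, ] <- means[k, ] + a1 * gauss(c1, s1) + a2 * gauss(c2, s2)
      }
    } else {
      # long-range mode: classes are (visible centre, NIR centre) pairs from
      # small shared pools, so each window alone is ambiguous
      n_vis <- min(5L, cfg$n_classes)
      n_nir <- ceiling(cfg$n_classes / n_vis)
      vis <- seq(615, 735, length.out = n_vis)
      nir <- seq(910, 1000, length.out = n_nir)
      amp <- 0.06 * cfg$class_separation
      for (k in seq_len(cfg$n_classes)) {
        i <- (k - 1) %% n_vis + 1
        j <- (k - 1) %/% n_vis + 1
        means[k, ] <- means[k, ] + amp * gauss(vis[i], 20) + amp * gauss(nir[j], 20)
      }
    }
  })
  means
}

# smooth low-amplitude random curve over `n_knots` knots (cubic spline)
synth_seed_curve <- function(wl, amplitude, n_knots = 8) {
  if (amplitude <= 0) return(rep(0, length(wl)))
  knots_x <- seq(min(wl), max(wl), length.out = n_knots)
  knots_y <- rnorm(n_knots) * amplitude * runif(1, 0.5, 1.5)
  stats::splinefun(knots_x, knots_y, method = "natural")(wl)
}

#' Generate a labelled synthetic spectra set
#'
#' Draws `n_classes * seeds_per_class` reflectance spectra on an evenly
#' spaced wavelength grid. Each spectrum is its class-mean curve plus a
#' smooth low-amplitude per-seed random curve plus i.i.d. per-band Gaussian
#' noise, clipped to `[0, 1]`. Bit-identical for a fixed `rng_seed`.
#'
#' @param cfg a [synth_config()].
#' @return A [spectra_tbl()] with `n_classes * seeds_per_class` rows.
#' @export
#' @examples
#' sp <- generate_spectra(synth_config(n_classes = 3, seeds_per_class = 5,
#'                                     n_bands = 50))
#' dim(spectra_matrix(sp))
generate_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  wl <- synth_wavelengths(cfg)
  means <- synth_class_means(cfg)
  n <- cfg$n_classes * cfg$seeds_per_class
  x <- matrix(0, n, cfg$n_bands)
  labels <- rep(seq_len(cfg$n_classes) - 1L, each = cfg$seeds_per_class)
  with_seed(cfg$rng_seed + 1L, {
    for (i in seq_len(n)) {
      x[i, ] <- means[labels[i] + 1L, ] +
        synth_seed_curve(wl, cfg$seed_curve_amplitude) +
        rnorm(cfg$n_bands, sd = cfg$noise_sd)
    }
  })
  x <- pmin(pmax(x, 0), 1)
  spectra_tbl(x, wl, labels = labels,
              sample_ids = sprintf("seed_%02d_%04d", labels, seq_len(n)))
}

#' Acquisition plan implied by a generator configuration
#'
#' Mirrors the imaging protocol: each scene images `seeds_per_scene` seeds of
#' one variety, so each variety needs
#' `ceiling(seeds_per_class / seeds_per_scene)` acquisitions.
#'
#' @param cfg a [synth_config()].
#' @param seeds_per_scene seeds imaged per acquisition (default 30).
#' @return Tibble with one row per acquisition (`scene_id`, `class`, `n_seeds`).
#' @export
acquisition_plan <- function(cfg, seeds_per_scene = 30) {
  stopifnot(inherits(cfg, "synth_config"))
  per_class <- ceiling(cfg$seeds_per_class / seeds_per_scene)
  counts <- rep(seeds_per_scene, per_class)
  counts[per_class] <- cfg$seeds_per_class - seeds_per_scene * (per_class - 1)
  tidyr::expand_grid(class = seq_len(cfg$n_classes) - 1L,
                     acquisition = seq_len(per_class)) |>
    dplyr::mutate(scene_id = dplyr::row_number(),
                  n_seeds = counts[.data$acquisition]) |>
    dplyr::select("scene_id", "class", "acquisition", "n_seeds")
}

#' Generate a synthetic raw-DN hyperspectral scene
#'
#' Places elliptical seed blobs on a dark background. Blob interiors carry
#' spectra drawn from the configured class structure, encoded back to raw
#' digital numbers as `raw = dark + reflectance * (white - dark)` on a
#' 12-bit-like scale (dark around 100 DN, white around 3500 DN) with small
#' Gaussian sensor noise on all three rasters, so that black/white
#' calibration has to do real work to recover the planted reflectance.
#'
#' Blobs are laid out on a cell grid with a safety margin, which guarantees
#' pairwise disjoint masks by construction.
#'
#' @param cfg a [synth_config()].
#' @param grid_rows,grid_cols scene size in pixels.
#' @param n_seeds number of seed blobs.
#' @param classes integer class per blob (`0`-based); defaults to cycling
#'   through all classes.
#' @param seed RNG seed for the scene (defaults to `cfg$rng_seed`).
#' @return A `synthetic_scene` list: `cube` (raw [hyper_cube()]), `white` and
#'   `dark` reference frames (matrices), `masks` (list of logical matrices),
#'   `labels`, and a `blobs` tibble of ground-truth geometry.
#' @export
generate_cube <- function(cfg, grid_rows, grid_cols, n_seeds = 30,
                          classes = NULL, seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "synth_config"))
  grid_rows <- check_count(grid_rows, "grid_rows")
  grid_cols <- check_count(grid_cols, "grid_cols")
  n_seeds <- check_count(n_seeds, "n_seeds")
  if (is.null(classes)) classes <- (seq_len(n_seeds) - 1L) %% cfg$n_classes
  classes <- rep_len(as.integer(classes), n_seeds)
  # cell grid sized to the scene aspect ratio
  nc_cells <- max(1L, ceiling(sqrt(n_seeds * grid_cols / grid_rows)))
  nr_cells <- ceiling(n_seeds / nc_cells)
  cell_h <- grid_rows %/% nr_cells
  cell_w <- grid_cols %/% nc_cells
  if (cell_h < 8 || cell_w < 8)
    abort("scene too small for the requested number of seeds",
          class = "spectraseed_config_error")
  wl <- synth_wavelengths(cfg)
  means <- synth_class_means(cfg)
  B <- cfg$n_bands

  with_seed(seed, {
    white <- matrix(3500 + rnorm(grid_rows * grid_cols, sd = 10), grid_rows)
    dark <- matrix(100 + rnorm(grid_rows * grid_cols, sd = 3), grid_rows)
    refl <- array(0.01, c(grid_rows, grid_cols, B))  # near-dark background
    masks <- vector("list", n_seeds)
    blob_rows <- integer(0)
    blobs <- vector("list", n_seeds)
    for (s in seq_len(n_seeds)) {
      ci <- (s - 1L) %/% nc_cells
      cj <- (s - 1L) %% nc_cells
      r0 <- ci * cell_h; c0 <- cj * cell_w
      ry <- floor(cell_h * runif(1, 0.22, 0.34))
      rx <- floor(cell_w * runif(1, 0.22, 0.34))
      cy <- r0 + cell_h / 2 + runif(1, -0.08, 0.08) * cell_h
      cx <- c0 + cell_w / 2 + runif(1, -0.08, 0.08) * cell_w
      rr <- seq_len(grid_rows); cc <- seq_len(grid_cols)
      mask <- outer(((rr - cy) / ry)^2, rep(1, grid_cols)) +
        outer(rep(1, grid_rows), ((cc - cx) / rx)^2) <= 1
      base <- means[classes[s] + 1L, ] +
        synth_seed_curve(wl, cfg$seed_curve_amplitude)
      idx <- which(mask)
      for (b in seq_len(B)) {
        plane <- refl[, , b]
        plane[idx] <- pmin(pmax(base[b] + rnorm(length(idx), sd = cfg$noise_sd), 0), 1)
        refl[, , b] <- plane
      }
      masks[[s]] <- mask
      blobs[[s]] <- tibble::tibble(
        seed_id = sprintf("blob_%03d", s), label = classes[s],
        row_start = min(rr[rowSums(mask) > 0]) - 1L,
        row_end = max(rr[rowSums(mask) > 0]),
        col_start = min(cc[colSums(mask) > 0]) - 1L,
        col_end = max(cc[colSums(mask) > 0]))
    }
    raw <- array(0, c(grid_rows, grid_cols, B))
    span <- white - dark
    for (b in seq_len(B))
      raw[, , b] <- dark + refl[, , b] * span +
        rnorm(grid_rows * grid_cols, sd = 2)
    structure(list(
      cube = hyper_cube(raw, wl, kind = "raw"),
      white = white, dark = dark,
      masks = masks, labels = classes,
      blobs = dplyr::bind_rows(blobs)), class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("# Synthetic scene: %d x %d px, %d bands, %d seed blobs (%d classes)\n",
              dim(x$cube$data)[1], dim(x$cube$data)[2], dim(x$cube$data)[3],
              length(x$masks), length(unique(x$labels))))
  invisible(x)
}
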