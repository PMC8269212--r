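#' Wavenumber axis specification
#'
#' The default axis, 400-3,200 cm^-1 at 1 cm^-1, covers the fingerprint
#' region, all three carotenoid resonance bands, the silent region used for
#' noise estimation, and the C-D / C-H stretching regions.
#'
#' @param start_cm1,stop_cm1 axis bounds (cm^-1), `start < stop`.
#' @param step_cm1 increment (cm^-1), positive.
#' @return a `spectrum_axis` object; `axis_points()` materializes it.
#' @export
spectrum_axis <- function(start_cm1 = 400, stop_cm1 = 3200, step_cm1 = 1) {
  if (!(start_cm1 < stop_cm1)) stop("axis requires start < stop")
  if (step_cm1 <= 0) stop("axis step must be positive")
  structure(list(start_cm1 = start_cm1, stop_cm1 = stop_cm1,
                 step_cm1 = step_cm1), class = "spectrum_axis")
}

#' @rdname spectrum_axis
#' @param axis a `spectrum_axis`.
#' @export
axis_points <- function(axis) {
  stopifnot(inherits(axis, "spectrum_axis"))
  seq(axis$start_cm1, axis$stop_cm1, by = axis$step_cm1)
}

#' Gaussian band model
#'
#' A single Raman band modeled as a Gaussian with closed-form area
#' `amplitude * width * sqrt(2*pi)`, which gives analytic ground truth for
#' the CDR statistic of synthetic spectra.
#'
#' @param center_cm1 band center (cm^-1).
#' @param width_cm1 Gaussian sigma (cm^-1), positive.
#' @param amplitude peak intensity (a.u.), non-negative.
#' @param name optional label used in error messages.
#' @return a `band_model` object.
#' @export
band_model <- function(center_cm1, width_cm1, amplitude, name = NULL) {
  if (width_cm1 <= 0) stop("band width must be positive")
  if (amplitude < 0) stop("band amplitude must be non-negative")
  structure(list(center_cm1 = center_cm1, width_cm1 = width_cm1,
                 amplitude = amplitude,
                 name = if (is.null(name))
                   sprintf("band@%g", center_cm1) else name),
            class = "band_model")
}

#' @rdname band_model
#' @param band a `band_model`.
#' @return `band_model_area()`: the analytic area `amplitude * sigma * sqrt(2 pi)`.
#' @export
band_model_area <- function(band) {
  stopifnot(inherits(band, "band_model"))
  band$amplitude * band$width_cm1 * sqrt(2 * pi)
}

band_center_in <- function(band, window) {
  band$center_cm1 >= window$lo_cm1 && band$center_cm1 <= window$hi_cm1
}

#' Analytic CDR of a set of band models
#'
#' Ratio of the analytic area of bands centered in the C-D window to the
#' summed analytic areas of bands centered in the C-D and C-H windows.
#' Returns 0 when no C-D band is present.
#'
#' @param bands list of [band_model()] objects.
#' @return fraction in `[0, 1]`.
#' @export
analytic_cdr <- function(bands) {
  ws <- band_windows()
  cd <- sum(vapply(bands, function(b)
    if (band_center_in(b, ws$CD)) band_model_area(b) else 0, 0))
  ch <- sum(vapply(bands, function(b)
    if (band_center_in(b, ws$CH)) band_model_area(b) else 0, 0))
  if (cd + ch == 0) stop("no band centered in the C-D or C-H window")
  cd / (cd + ch)
}

#' Generate one synthetic single-cell Raman spectrum
#'
#' Builds `sum(Gaussian bands) + polynomial baseline (+ optional broad
#' fluorescence hump) + i.i.d. Gaussian noise` on the given axis, together
#' with the ground truth attached for parameter-recovery tests. The true
#' CDR is computed analytically from the band models before noise.
#'
#' @param axis a [spectrum_axis()].
#' @param bands list of [band_model()] objects; every center must lie
#'   within the axis by at least 4 sigma.
#' @param baseline_params numeric polynomial coefficients, lowest order
#'   first, evaluated on a `[0, 1]`-rescaled axis (so magnitudes are
#'   comparable across axes).
#' @param fluor_hump optional `c(center, sigma, amplitude)` broad Gaussian
#'   added to the baseline.
#' @param noise_sd standard deviation of additive Gaussian noise (a.u.).
#' @param seed integer seed; fully determines the output.
#' @param cell_id identifier stored in the spectrum.
#' @return list with `spectrum` (a raw [raman_spectrum()]) and `truth`
#'   (list: `true_cdr`, `carotenoid_present`, `species_label`,
#'   `baseline_params`, `noise_sd`, `seed`).
#' @export
make_spectrum <- function(axis = spectrum_axis(), bands, baseline_params = 0,
                          fluor_hump = NULL, noise_sd = 0, seed = 1L,
                          cell_id = NA_character_,
                          species_label = NA_character_) {
  stopifnot(inherits(axis, "spectrum_axis"))
  w <- axis_points(axis)
  for (b in bands) {
    lo <- b$center_cm1 - 4 * b$width_cm1
    hi <- b$center_cm1 + 4 * b$width_cm1
    if (lo < axis$start_cm1 || hi > axis$stop_cm1)
      stop(sprintf("band '%s' (center %g, sigma %g) extends outside the axis",
                   b$name, b$center_cm1, b$width_cm1))
  }
  y <- numeric(length(w))
  for (b in bands)
    y <- y + b$amplitude * exp(-0.5 * ((w - b$center_cm1) / b$width_cm1)^2)
  u <- (w - axis$start_cm1) / (axis$stop_cm1 - axis$start_cm1)
  base <- rep(0, length(w))
  for (i in seq_along(baseline_params))
    base <- base + baseline_params[i] * u^(i - 1L)
  if (!is.null(fluor_hump))
    base <- base + fluor_hump[3L] *
      exp(-0.5 * ((w - fluor_hump[1L]) / fluor_hump[2L])^2)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    noise <- stats::rnorm(length(w), 0, noise_sd)
  } else noise <- 0
  ws <- band_windows()
  has_cd <- any(vapply(bands, band_center_in, TRUE, window = ws$CD))
  carot <- any(vapply(bands, band_center_in, TRUE, window = ws$CAROT_V3))
  cdr <- if (has_cd ||
             any(vapply(bands, band_center_in, TRUE, window = ws$CH)))
    analytic_cdr(bands) else NA_real_
  list(
    spectrum = raman_spectrum(w, y + base + noise, state = "raw",
                              cell_id = cell_id),
    truth = list(true_cdr = cdr, carotenoid_present = carot,
                 species_label = species_label,
                 baseline_params = baseline_params, noise_sd = noise_sd,
                 seed = as.integer(seed)))
}

#' Mock-community specification
#'
#' Describes a defined mixture of species with per-species metabolic
#' phenotype flags. The default reproduces the benchmark four-species
#' community (*E. coli*, *H. pylori*, *S. elongatus*, *S. cerevisiae*,
#' 1:1:1:1) in which only *Ec* is heavy-water labeled and only *Se*
#' contains carotenoids.
#'
#' @param species data.frame with columns `label`, `proportion`,
#'   `d2o_labeled`, `carotenoid_producer`.
#' @param n_cells number of cells to generate (>= 1).
#' @return a `mock_community_spec` object.
#' @export
mock_community_spec <- function(species = default_mock_species(),
                                n_cells = 20L) {
  stopifnot(is.data.frame(species))
  need <- c("label", "proportion", "d2o_labeled", "carotenoid_producer")
  if (!all(need %in% names(species)))
    stop("species table needs columns ", paste(need, collapse = ", "))
  if (nrow(species) == 0L) stop("empty community specification")
  if (abs(sum(species$proportion) - 1) > 1e-8)
    stop("species proportions must sum to 1")
  if (n_cells < 1L) stop("n_cells must be >= 1")
  structure(list(species = species, n_cells = as.integer(n_cells)),
            class = "mock_community_spec")
}

#' @rdname mock_community_spec
#' @export
default_mock_species <- function() {
  data.frame(
    label = c("Ec", "Hp", "Se", "Sc"),
    proportion = rep(0.25, 4),
    d2o_labeled = c(TRUE, FALSE, FALSE, FALSE),
    carotenoid_producer = c(FALSE, FALSE, TRUE, FALSE))
}

#' Largest-remainder apportionment of cells to species
#'
#' Deterministic rounding of `proportion * n` to integers that sum exactly
#' to `n`: floor everything, then hand the remaining units to the largest
#' fractional remainders (ties broken by input order).
#'
#' @param proportions non-negative weights summing to 1.
#' @param n total count.
#' @return integer vector summing to `n`.
#' @export
largest_remainder <- function(proportions, n) {
  raw <- proportions * n
  base <- floor(raw)
  rem <- raw - base
  left <- as.integer(round(n - sum(base)))
  if (left > 0L) {
    give <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Per-species spectral templates for the synthetic mock community
#'
#' Every cell carries a C-H band (2,930 cm^-1, sigma 60). Heavy-water
#' labeled species additionally carry a C-D band (2,157 cm^-1, sigma 40);
#' carotenoid producers carry the three resonance bands (v1 1,008 / v2
#' 1,158 / v3 1,521 cm^-1). Amplitudes are in arbitrary units; with the
#' default noise sd of 0.05 the C-D band sits at a signal-to-noise ratio
#' of about 20 and the C-H band at about 60.
#'
#' @param ch_amp,cd_amp,carot_amp amplitudes (a.u.) of the C-H band, the
#'   C-D band of labeled cells, and the v3 carotenoid band (v2 and v1 are
#'   scaled to 0.5 and 0.3 of v3).
#' @return function `(d2o_labeled, carotenoid_producer) -> list of bands`.
#' @export
mock_band_templates <- function(ch_amp = 3, cd_amp = 1, carot_amp = 5) {
  function(d2o_labeled, carotenoid_producer) {
    bands <- list(band_model(2930, 60, ch_amp, "CH"))
    if (d2o_labeled)
      bands <- c(bands, list(band_model(2157, 40, cd_amp, "CD")))
    if (carotenoid_producer)
      bands <- c(bands, list(
        band_model(1521, 10, carot_amp, "CAROT_V3"),
        band_model(1158, 6, 0.5 * carot_amp, "CAROT_V2"),
        band_model(1008, 5, 0.3 * carot_amp, "CAROT_V1")))
    bands
  }
}

#' Generate a synthetic mock community of single-cell spectra
#'
#' Cells are apportioned to species by largest-remainder rounding of the
#' community proportions, then each cell's spectrum is generated from its
#' species template on a fluorescence baseline with noise.
#'
#' @param spec a [mock_community_spec()].
#' @param templates template function from [mock_band_templates()].
#' @param axis a [spectrum_axis()].
#' @param baseline_params,fluor_hump,noise_sd baseline and noise settings
#'   shared by all cells (defaults: gently sloping polynomial baseline, a
#'   broad fluorescence hump, noise sd 0.05 a.u.).
#' @param seed integer seed; cell seeds are derived deterministically.
#' @return list of per-cell lists `(cell_id, species, spectrum, truth)`.
#' @export
make_mock_community <- function(spec = mock_community_spec(),
                                templates = mock_band_templates(),
                                axis = spectrum_axis(),
                                baseline_params = c(2, -0.5),
                                fluor_hump = c(1300, 500, 1),
                                noise_sd = 0.05,
                                seed = 1L) {
  stopifnot(inherits(spec, "mock_community_spec"))
  counts <- largest_remainder(spec$species$proportion, spec$n_cells)
  out <- vector("list", spec$n_cells)
  k <- 0L
  for (i in seq_len(nrow(spec$species))) {
    row <- spec$species[i, ]
    bands <- templates(row$d2o_labeled, row$carotenoid_producer)
    for (j in seq_len(counts[i])) {
      k <- k + 1L
      cell_id <- sprintf("%s_%03d", row$label, j)
      cell_seed <- (as.integer(seed) * 10007L + k * 389L) %% 2147483647L
      ms <- make_spectrum(axis, bands, baseline_params = baseline_params,
                          fluor_hump = fluor_hump, noise_sd = noise_sd,
                          seed = cell_seed, cell_id = cell_id,
                          species_label = row$label)
      ms$truth$d2o_labeled <- row$d2o_labeled
      ms$truth$carotenoid_producer <- row$carotenoid_producer
      out[[k]] <- list(cell_id = cell_id, species = row$label,
                       spectrum = ms$spectrum, truth = ms$truth)
    }
  }
  out
}
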