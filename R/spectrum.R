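#' Single-cell Raman spectrum
#'
#' Container for one cell's Raman trace: a strictly increasing wavenumber
#' axis (cm^-1), one intensity per axis point (arbitrary units), and a
#' processing state that tracks the preprocessing pipeline. States advance
#' only forward through `raw -> dark_subtracted -> baseline_corrected ->
#' ch_normalized`.
#'
#' @param wavenumber numeric vector of wavenumbers (cm^-1), strictly
#'   increasing.
#' @param intensity numeric vector of intensities (a.u.), same length.
#' @param state processing state, one of [spectrum_states()].
#' @param cell_id optional identifier carried through to phenotype tables.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity, state = "raw",
                           cell_id = NA_character_) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity must have the same length")
  if (length(wavenumber) < 2L)
    stop("a spectrum needs at least two axis points")
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be strictly increasing")
  if (anyNA(intensity)) stop("intensity contains NA")
  state <- match.arg(state, spectrum_states())
  structure(
    list(wavenumber = wavenumber, intensity = intensity,
         state = state, cell_id = as.character(cell_id)),
    class = "raman_spectrum")
}

#' Processing states of a Raman spectrum, in pipeline order
#' @return character vector of the four states.
#' @export
spectrum_states <- function() {
  c("raw", "dark_subtracted", "baseline_corrected", "ch_normalized")
}

state_rank <- function(s) match(s, spectrum_states())

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(
    "raman_spectrum%s: %d points, %.0f-%.0f cm-1, state '%s'\n",
    if (is.na(x$cell_id)) "" else paste0(" [", x$cell_id, "]"),
    length(x$wavenumber), min(x$wavenumber), max(x$wavenumber), x$state))
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...) {
  graphics::plot(x$wavenumber, x$intensity, type = "l",
                 xlab = expression(paste("wavenumber (", cm^-1, ")")),
                 ylab = "intensity (a.u.)", ...)
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(wavenumber_cm1 = x$wavenumber, intensity = x$intensity)
}

#' Named wavenumber window
#'
#' @param name window label.
#' @param lo_cm1,hi_cm1 window bounds in cm^-1, `lo_cm1 < hi_cm1`.
#' @return A `band_window` object.
#' @export
band_window <- function(name, lo_cm1, hi_cm1) {
  if (!(lo_cm1 < hi_cm1)) stop("band window requires lo < hi")
  structure(list(name = name, lo_cm1 = lo_cm1, hi_cm1 = hi_cm1),
            class = "band_window")
}

#' Canonical band windows
#'
#' The five wavenumber intervals the analysis relies on: the C-D stretching
#' region populated after deuterium incorporation from heavy water
#' (2,040-2,300 cm^-1, peaked near 2,157 cm^-1), the C-H stretching region
#' (2,800-3,100 cm^-1) used for normalization and as the CDR denominator,
#' and the three carotenoid resonance bands (v1 CH3 rocking 1,000-1,020;
#' v2 C-C stretch 1,150-1,170; v3 C=C stretch 1,500-1,550 cm^-1).
#'
#' @return named list of [band_window()] objects: `CD`, `CH`, `CAROT_V1`,
#'   `CAROT_V2`, `CAROT_V3`.
#' @export
band_windows <- function() {
  list(
    CD       = band_window("CD", 2040, 2300),
    CH       = band_window("CH", 2800, 3100),
    CAROT_V1 = band_window("CAROT_V1", 1000, 1020),
    CAROT_V2 = band_window("CAROT_V2", 1150, 1170),
    CAROT_V3 = band_window("CAROT_V3", 1500, 1550))
}

#' Integrate intensity over a wavenumber window
#'
#' Trapezoidal integral of the intensity trace over `[lo, hi]`, on the
#' native axis (no resampling). With `clip_negative = TRUE` (default),
#' negative intensities are treated as zero before integration so that
#' residual noise around zero after baseline removal cannot produce
#' negative band areas.
#'
#' @param spectrum a [raman_spectrum()].
#' @param window a [band_window()], or a name from [band_windows()].
#' @param clip_negative clip negative intensities to zero first?
#' @return area in a.u. * cm^-1.
#' @export
band_area <- function(spectrum, window, clip_negative = TRUE) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  window <- resolve_window(window)
  w <- spectrum$wavenumber
  if (window$hi_cm1 < w[1L] || window$lo_cm1 > w[length(w)])
    stop(sprintf("window '%s' [%g, %g] lies outside the spectrum axis",
                 window$name, window$lo_cm1, window$hi_cm1))
  sel <- which(w >= window$lo_cm1 & w <= window$hi_cm1)
  if (length(sel) < 2L)
    stop(sprintf("window '%s' covers fewer than two axis points",
                 window$name))
  y <- spectrum$intensity[sel]
  if (clip_negative) y <- pmax(y, 0)
  x <- w[sel]
  sum(diff(x) * (y[-1L] + y[-length(y)])) / 2
}

resolve_window <- function(window) {
  if (is.character(window)) {
    ws <- band_windows()
    if (!window %in% names(ws))
      stop(sprintf("unknown band window '%s'", window))
    return(ws[[window]])
  }
  stopifnot(inherits(window, "band_window"))
  window
}

#' Subtract a dark (background) trace
#'
#' Pointwise subtraction of a dark/background acquisition from a raw
#' spectrum; the first preprocessing step.
#'
#' @param spectrum a raw [raman_spectrum()].
#' @param dark a [raman_spectrum()] on the identical axis.
#' @return the dark-subtracted spectrum (state `dark_subtracted`).
#' @export
subtract_dark <- function(spectrum, dark) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(dark, "raman_spectrum"))
  if (spectrum$state != "raw")
    stop(sprintf("subtract_dark expects a raw spectrum, got state '%s'",
                 spectrum$state))
  same <- spectrum$wavenumber == dark$wavenumber
  if (length(spectrum$wavenumber) != length(dark$wavenumber) || !all(same)) {
    first <- if (length(spectrum$wavenumber) != length(dark$wavenumber))
      "different axis lengths"
    else sprintf("first differing wavenumber %g vs %g",
                 spectrum$wavenumber[which(!same)[1L]],
                 dark$wavenumber[which(!same)[1L]])
    stop("spectrum and dark trace axes differ: ", first)
  }
  raman_spectrum(spectrum$wavenumber, spectrum$intensity - dark$intensity,
                 state = "dark_subtracted", cell_id = spectrum$cell_id)
}

#' Asymmetric-least-squares baseline correction
#'
#' Estimates a smooth fluorescence baseline by asymmetric least squares
#' (second-difference penalty with smoothness `lambda`; points above the
#' current baseline down-weighted to `p`, points below to `1 - p`) and
#' subtracts it. This is the standard open formulation of the baseline
#' removal that commercial spectrometer software performs.
#'
#' The penalty acts on index second differences, so the appropriate
#' `lambda` grows with the fourth power of the axis density; the default
#' of 1e8 keeps the estimate stiff enough on a 1 cm^-1 grid to pass under
#' the 300-cm^-1-wide C-H stretching envelope instead of climbing into it,
#' while still following fluorescence humps a few hundred cm^-1 across.
#' Because the asymmetric fit hugs the lower envelope of the noise, the
#' corrected trace is re-zeroed by subtracting its median over a
#' biologically silent window (default 1,800-1,900 cm^-1); the offset is
#' folded into the returned baseline so `corrected = input - baseline`
#' holds exactly. Set `rezero_window = NULL` to disable.
#'
#' @param spectrum a [raman_spectrum()] in state `raw` or `dark_subtracted`.
#' @param lambda smoothness penalty (default 1e8 for a 1 cm^-1 axis).
#' @param p asymmetry weight in (0, 1) (default 0.01).
#' @param n_iter number of reweighting iterations (default 10).
#' @param rezero_window [band_window()] used to re-zero the corrected
#'   trace; skipped when it does not overlap the axis.
#' @return list with `corrected` and `baseline` spectra; `corrected` has
#'   state `baseline_corrected`.
#' @export
correct_baseline <- function(spectrum, lambda = 1e8, p = 0.01, n_iter = 10L,
                             rezero_window = band_window("SILENT", 1800, 1900)) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (!spectrum$state %in% c("raw", "dark_subtracted"))
    stop(sprintf("correct_baseline expects state raw/dark_subtracted, got '%s'",
                 spectrum$state))
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (!(p > 0 && p < 1)) stop("asymmetry p must lie in (0, 1)")
  if (lambda <= 0) stop("lambda must be positive")
  y <- spectrum$intensity
  z <- als_baseline(y, lambda = lambda, p = p, n_iter = n_iter)
  if (!is.null(rezero_window)) {
    sel <- spectrum$wavenumber >= rezero_window$lo_cm1 &
      spectrum$wavenumber <= rezero_window$hi_cm1
    if (sum(sel) >= 3L) z <- z + stats::median(y[sel] - z[sel])
  }
  list(
    corrected = raman_spectrum(spectrum$wavenumber, y - z,
                               state = "baseline_corrected",
                               cell_id = spectrum$cell_id),
    baseline = raman_spectrum(spectrum$wavenumber, z,
                              state = spectrum$state,
                              cell_id = spectrum$cell_id))
}

als_baseline <- function(y, lambda, p, n_iter) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2L, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (i in seq_len(n_iter)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Normalize a spectrum to unit C-H band area
#'
#' Divides all intensities by the C-H window area so that
#' `band_area(result, "CH") == 1`. Requires a baseline-corrected spectrum
#' and a positive C-H area; a non-positive C-H area signals a dead pixel
#' row or an empty trap.
#'
#' @param spectrum a baseline-corrected [raman_spectrum()].
#' @return the normalized spectrum (state `ch_normalized`).
#' @export
normalize_ch <- function(spectrum) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (spectrum$state == "ch_normalized") return(spectrum)
  if (spectrum$state != "baseline_corrected")
    stop(sprintf(
      "normalize_ch expects a baseline_corrected spectrum, got '%s'",
      spectrum$state))
  a <- band_area(spectrum, "CH", clip_negative = TRUE)
  if (a <= 0) stop("no C-H signal: C-H band area is not positive")
  raman_spectrum(spectrum$wavenumber, spectrum$intensity / a,
                 state = "ch_normalized", cell_id = spectrum$cell_id)
}

#' Savitzky-Golay smoothing (optional)
#'
#' Off by default in the preprocessing pipeline; provided for noisy traces.
#' Preserves the processing state.
#'
#' @param spectrum a [raman_spectrum()].
#' @param window odd filter length (default 9 points).
#' @param order polynomial order (default 3).
#' @return the smoothed spectrum.
#' @export
smooth_spectrum <- function(spectrum, window = 9L, order = 3L) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  sm <- signal::sgolayfilt(spectrum$intensity, p = order, n = window)
  raman_spectrum(spectrum$wavenumber, sm, state = spectrum$state,
                 cell_id = spectrum$cell_id)
}

#' Run the full preprocessing pipeline on one spectrum
#'
#' Dark subtraction (when a dark trace is supplied), baseline correction,
#' and C-H area normalization, in that order.
#'
#' @inheritParams correct_baseline
#' @param dark optional dark trace.
#' @return the `ch_normalized` spectrum.
#' @export
preprocess_spectrum <- function(spectrum, dark = NULL, lambda = 1e8,
                                p = 0.01, n_iter = 10L) {
  if (!is.null(dark)) spectrum <- subtract_dark(spectrum, dark)
  if (spectrum$state == "raw")
    spectrum$state <- "dark_subtracted"   # no dark trace available
  bc <- correct_baseline(spectrum, lambda = lambda, p = p, n_iter = n_iter)
  normalize_ch(bc$corrected)
}

#' Write / read the two-column spectrum TSV dialect
#'
#' Spectra are exchanged as TSV with header
#' `wavenumber_cm1<TAB>intensity`; the processing state (and any synthetic
#' ground truth) lives in a JSON sidecar `<path>.json`.
#'
#' @param spectrum a [raman_spectrum()].
#' @param path TSV path.
#' @param truth optional list written into the sidecar under `truth`.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path, truth = NULL) {
  utils::write.table(as.data.frame(spectrum), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  side <- list(cell_id = spectrum$cell_id, processing_state = spectrum$state)
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("wavenumber_cm1", "intensity")
  if (!all(need %in% names(df)))
    stop(sprintf("malformed spectrum TSV '%s': expected columns %s (line 1)",
                 path, paste(need, collapse = ", ")))
  state <- "raw"; cell_id <- NA_character_; truth <- NULL
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$processing_state)) state <- side$processing_state
    if (!is.null(side$cell_id)) cell_id <- side$cell_id
    truth <- side$truth
  }
  sp <- raman_spectrum(df$wavenumber_cm1, df$intensity, state = state,
                       cell_id = cell_id)
  attr(sp, "truth") <- truth
  sp
}
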