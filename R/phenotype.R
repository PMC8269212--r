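#' C-D ratio (CDR) of a preprocessed spectrum
#'
#' CDR = area(C-D) / (area(C-D) + area(C-H)) with the C-D window at
#' 2,040-2,300 cm^-1 and the C-H window at 2,800-3,100 cm^-1. The ratio is
#' the deuterium-incorporation proxy used to flag metabolically active
#' cells after heavy-water labeling. Because the numerator and denominator
#' scale together, the statistic is invariant to C-H normalization and may
#' be computed on either a `baseline_corrected` or a `ch_normalized`
#' spectrum.
#'
#' @param spectrum a [raman_spectrum()] in state `baseline_corrected` or
#'   `ch_normalized`.
#' @param clip_negative passed to [band_area()].
#' @return fraction in `[0, 1]`.
#' @export
compute_cdr <- function(spectrum, clip_negative = TRUE) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (state_rank(spectrum$state) < state_rank("baseline_corrected"))
    stop(sprintf("compute_cdr needs a baseline-corrected spectrum, got '%s'",
                 spectrum$state))
  cd <- band_area(spectrum, "CD", clip_negative = clip_negative)
  ch <- band_area(spectrum, "CH", clip_negative = clip_negative)
  if (cd + ch == 0) stop("empty spectrum: zero area in both C-D and C-H windows")
  cd / (cd + ch)
}

#' Detect carotenoid resonance bands
#'
#' Estimates the noise floor as the standard deviation of intensities in a
#' biologically silent region (default 1,800-1,900 cm^-1), computes the
#' signal-to-noise ratio of each carotenoid window as its maximum intensity
#' over the noise sd, and calls a cell carotenoid-positive when the v3
#' (C=C stretch) band clears the threshold AND at least one of v1/v2 does.
#' v3 anchors the call because it is the strongest resonance band.
#'
#' @param spectrum a [raman_spectrum()], at least baseline-corrected.
#' @param noise_sd_estimate noise sd (a.u.); estimated from
#'   `noise_window` when `NULL`.
#' @param snr_threshold_k SNR threshold (default 5).
#' @param noise_window window used for noise estimation.
#' @return list with `positive` (logical) and `snr` (named vector over
#'   `CAROT_V1`, `CAROT_V2`, `CAROT_V3`).
#' @export
detect_carotenoid <- function(spectrum, noise_sd_estimate = NULL,
                              snr_threshold_k = 5,
                              noise_window = band_window("SILENT", 1800, 1900)) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (state_rank(spectrum$state) < state_rank("baseline_corrected"))
    stop(sprintf("detect_carotenoid needs a baseline-corrected spectrum, got '%s'",
                 spectrum$state))
  if (is.null(noise_sd_estimate)) {
    sel <- spectrum$wavenumber >= noise_window$lo_cm1 &
      spectrum$wavenumber <= noise_window$hi_cm1
    if (sum(sel) < 3L) stop("noise window covers too few axis points")
    noise_sd_estimate <- stats::sd(spectrum$intensity[sel])
  }
  if (noise_sd_estimate <= 0) stop("noise sd estimate must be positive")
  ws <- band_windows()[c("CAROT_V1", "CAROT_V2", "CAROT_V3")]
  snr <- vapply(ws, function(win) {
    sel <- spectrum$wavenumber >= win$lo_cm1 & spectrum$wavenumber <= win$hi_cm1
    max(spectrum$intensity[sel]) / noise_sd_estimate
  }, 0)
  positive <- snr[["CAROT_V3"]] >= snr_threshold_k &&
    (snr[["CAROT_V1"]] >= snr_threshold_k ||
       snr[["CAROT_V2"]] >= snr_threshold_k)
  list(positive = positive, snr = snr)
}

#' Joint metabolic phenotype of one cell
#'
#' Combines the CDR call (CDR at or above `cdr_threshold` means C-D
#' positive, i.e. metabolically active) with the carotenoid call into the
#' four-way joint class `CD+CAR+`, `CD-CAR+`, `CD+CAR-`, `CD-CAR-`.
#' Deterministic and, because CDR is a ratio of band areas and the SNR a
#' ratio of intensities, invariant to overall intensity scaling.
#'
#' Carotenoid resonance can swamp the C-D reading in practice (instruments
#' photobleach the pigment before reading C-D); the CDR of a
#' carotenoid-positive cell is therefore additionally flagged
#' `cdr_post_quench` = FALSE in the output to mark it as read without
#' quenching.
#'
#' @param spectrum a preprocessed [raman_spectrum()].
#' @param cdr_threshold CDR positivity cutoff (see
#'   [calibrate_cdr_threshold()]).
#' @param snr_threshold_k,noise_sd_estimate passed to [detect_carotenoid()].
#' @return a `cell_phenotype` object (also a one-row data.frame via
#'   [as.data.frame()]): `cell_id`, `cdr`, `cd_positive`,
#'   `carotenoid_positive`, per-band SNRs, `joint_class`, `sort_target`.
#' @export
classify_cell <- function(spectrum, cdr_threshold = 0.05,
                          snr_threshold_k = 5, noise_sd_estimate = NULL) {
  cdr <- compute_cdr(spectrum)
  car <- detect_carotenoid(spectrum, noise_sd_estimate = noise_sd_estimate,
                           snr_threshold_k = snr_threshold_k)
  cd_pos <- cdr >= cdr_threshold
  joint <- paste0(if (cd_pos) "CD+" else "CD-",
                  if (car$positive) "CAR+" else "CAR-")
  structure(
    list(cell_id = spectrum$cell_id, cdr = cdr, cd_positive = cd_pos,
         carotenoid_positive = car$positive, snr = car$snr,
         joint_class = joint, cdr_post_quench = !car$positive,
         sort_target = NA),
    class = "cell_phenotype")
}

#' @export
print.cell_phenotype <- function(x, ...) {
  cat(sprintf("cell_phenotype [%s]: CDR %.4f, %s (v3 SNR %.1f)\n",
              x$cell_id, x$cdr, x$joint_class, x$snr[["CAROT_V3"]]))
  invisible(x)
}

#' @export
as.data.frame.cell_phenotype <- function(x, ...) {
  data.frame(cell_id = x$cell_id, cdr = x$cdr, cd_positive = x$cd_positive,
             carotenoid_positive = x$carotenoid_positive,
             v1_snr = x$snr[["CAROT_V1"]], v2_snr = x$snr[["CAROT_V2"]],
             v3_snr = x$snr[["CAROT_V3"]], joint_class = x$joint_class,
             sort_target = x$sort_target)
}

#' Sorting decision for a phenotyped cell
#'
#' @param phenotype a `cell_phenotype` from [classify_cell()].
#' @param criterion `"cd_band"` (sort metabolically active cells),
#'   `"carotenoid"` (sort pigment producers), or
#'   `"morphology_passthrough"` (shape-based sorting happens upstream of
#'   the spectrum, so every cell passes).
#' @return logical: sort this cell?
#' @export
sort_decision <- function(phenotype,
                          criterion = c("cd_band", "carotenoid",
                                        "morphology_passthrough")) {
  stopifnot(inherits(phenotype, "cell_phenotype"))
  criterion <- match.arg(criterion)
  switch(criterion,
         cd_band = phenotype$cd_positive,
         carotenoid = phenotype$carotenoid_positive,
         morphology_passthrough = TRUE)
}

#' Calibrate the CDR positivity threshold from unlabeled controls
#'
#' The CDR of unlabeled cells is not exactly zero (noise and clipping leave
#' a small positive floor), so the cutoff separating labeled from unlabeled
#' cells is calibrated on a control population. The default rule is the
#' standard mean + 3 sd of control CDRs; alternatives are the control
#' maximum or a fixed value.
#'
#' @param control_cdrs CDR values from unlabeled control cells (>= 20).
#' @param rule `"mean_plus_sd"`, `"max"`, or `"fixed"`.
#' @param sd_multiplier multiplier for `mean_plus_sd` (default 3).
#' @param fixed_value threshold used when `rule = "fixed"`.
#' @return the threshold (fraction).
#' @export
calibrate_cdr_threshold <- function(control_cdrs,
                                    rule = c("mean_plus_sd", "max", "fixed"),
                                    sd_multiplier = 3, fixed_value = NULL) {
  rule <- match.arg(rule)
  if (rule == "fixed") {
    if (is.null(fixed_value)) stop("rule 'fixed' needs fixed_value")
    return(fixed_value)
  }
  if (length(control_cdrs) < 20L)
    stop("need at least 20 control CDR values to calibrate a threshold")
  switch(rule,
         mean_plus_sd = mean(control_cdrs) +
           sd_multiplier * stats::sd(control_cdrs),
         max = max(control_cdrs))
}

#' Summarize a heavy-water labeling time course
#'
#' Per-timepoint mean/median/sd of single-cell CDR values, a plateau flag,
#' and (when replicates are supplied) the Pearson correlation between
#' replicate mean-CDR profiles. The consortium is considered to have
#' plateaued when the last inter-timepoint increase in mean CDR is below
#' 10% of the total rise from the first to the last timepoint.
#'
#' @param data data.frame with columns `time_h`, `cdr`, and optionally
#'   `replicate`. When replicates are present they must share the same
#'   time grid.
#' @return list with `summary` (data.frame: `time_h`, `n`, `mean_cdr`,
#'   `median_cdr`, `sd_cdr`), `plateau` (logical), and
#'   `replicate_correlation` (matrix or `NULL`).
#' @export
summarize_timecourse <- function(data) {
  stopifnot(is.data.frame(data), all(c("time_h", "cdr") %in% names(data)))
  times <- sort(unique(data$time_h))
  if (length(times) < 2L) stop("need at least two time points")
  counts <- table(data$time_h)
  if (any(counts < 2L)) stop("each time point needs at least two cells")
  summ <- do.call(rbind, lapply(times, function(t) {
    v <- data$cdr[data$time_h == t]
    data.frame(time_h = t, n = length(v), mean_cdr = mean(v),
               median_cdr = stats::median(v), sd_cdr = stats::sd(v))
  }))
  m <- summ$mean_cdr
  total_rise <- m[length(m)] - m[1L]
  last_inc <- m[length(m)] - m[length(m) - 1L]
  plateau <- last_inc < 0.1 * max(total_rise, .Machine$double.eps)
  rep_cor <- NULL
  if ("replicate" %in% names(data)) {
    reps <- sort(unique(data$replicate))
    if (length(reps) > 1L) {
      grids <- lapply(reps, function(r)
        sort(unique(data$time_h[data$replicate == r])))
      if (!all(vapply(grids, identical, TRUE, grids[[1L]])))
        stop("replicates must share the same time grid")
      prof <- vapply(reps, function(r)
        vapply(grids[[1L]], function(t)
          mean(data$cdr[data$replicate == r & data$time_h == t]), 0),
        numeric(length(grids[[1L]])))
      colnames(prof) <- as.character(reps)
      rep_cor <- stats::cor(prof)
    }
  }
  list(summary = summ, plateau = plateau, replicate_correlation = rep_cor)
}

#' Phenotype a list of cells and assemble the sorting table
#'
#' Preprocesses every spectrum, classifies it, applies the sorting
#' criterion, and returns the per-cell phenotype table.
#'
#' @param cells list of per-cell lists with `spectrum` (the output of
#'   [make_mock_community()] works directly) or a list of spectra.
#' @param cdr_threshold,snr_threshold_k classification parameters.
#' @param criterion sorting criterion, see [sort_decision()].
#' @param lambda,p,n_iter baseline-correction parameters.
#' @return data.frame, one row per cell, with the columns of
#'   [as.data.frame.cell_phenotype()].
#' @export
phenotype_cells <- function(cells, cdr_threshold = 0.05, snr_threshold_k = 5,
                            criterion = "cd_band",
                            lambda = 1e8, p = 0.01, n_iter = 10L) {
  rows <- lapply(cells, function(cell) {
    sp <- if (inherits(cell, "raman_spectrum")) cell else cell$spectrum
    pre <- preprocess_spectrum(sp, lambda = lambda, p = p, n_iter = n_iter)
    ph <- classify_cell(pre, cdr_threshold = cdr_threshold,
                        snr_threshold_k = snr_threshold_k)
    ph$sort_target <- sort_decision(ph, criterion)
    as.data.frame(ph)
  })
  do.call(rbind, rows)
}
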