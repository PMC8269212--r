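#' Simulate sorting + amplification outcomes for a batch of cells
#'
#' Emulates the bookkeeping of a sorted batch: each sorted cell undergoes
#' whole-genome amplification with success probability `p_mda_success`;
#' amplification-negative cells yield no sequencing record but stay in the
#' success-rate denominator. Each successful cell gets a row of per-reference
#' read-mapping percentages: its own species receives the bulk, a small
#' contaminating percentage (default uniform on 0-1.5%, mirroring observed
#' cross-mapping that is mostly under 0.5% and at most about 1.3%) goes to
#' one non-self reference, and the remainder is unassigned
#' (`hit_no_genomes_pct`, modeling nonspecific amplification). Percentages
#' are rounded to 2 decimals and sum to 100 within rounding.
#'
#' @param cells list of per-cell lists with `cell_id` and `species` (the
#'   output of [make_mock_community()] works directly).
#' @param references reference labels; defaults to the species present.
#' @param p_mda_success probability a sorted cell amplifies, in `[0, 1]`.
#' @param hit_no_meanlog,hit_no_sdlog log-normal parameters of the
#'   unassigned-read percentage (capped at 95).
#' @param contam_max upper bound of the uniform contaminating percentage.
#' @param completeness_shape1,completeness_shape2 Beta parameters of the
#'   genome completeness draw (scaled to percent).
#' @param experiment_id experiment label stamped on every record.
#' @param seed integer seed.
#' @return list with `records` (data.frame of sequencing outcomes, one row
#'   per amplification-positive cell) and `n_sorted` (batch denominator).
#' @export
simulate_batch <- function(cells,
                           references = NULL,
                           p_mda_success = 0.43,
                           hit_no_meanlog = 2, hit_no_sdlog = 1,
                           contam_max = 1.5,
                           completeness_shape1 = 2,
                           completeness_shape2 = 1,
                           experiment_id = "sim-1",
                           seed = 1L) {
  if (p_mda_success < 0 || p_mda_success > 1)
    stop("p_mda_success must lie in [0, 1]")
  if (contam_max < 0) stop("contam_max must be non-negative")
  species <- vapply(cells, function(c) c$species, "")
  if (is.null(references)) references <- sort(unique(species))
  set.seed(as.integer(seed))
  rows <- list()
  for (i in seq_along(cells)) {
    ok <- stats::runif(1) < p_mda_success
    if (!ok) next
    own <- species[i]
    hit_no <- min(95, stats::rlnorm(1, hit_no_meanlog, hit_no_sdlog))
    contam <- if (contam_max > 0) stats::runif(1, 0, contam_max) else 0
    mapped <- stats::setNames(numeric(length(references)), references)
    others <- setdiff(references, own)
    if (length(others) > 0L && contam > 0) {
      tgt <- if (length(others) == 1L) others else sample(others, 1L)
      mapped[tgt] <- round(contam, 2)
    }
    mapped[own] <- round(100 - hit_no - sum(mapped), 2)
    hit_no <- round(100 - sum(mapped), 2)
    completeness <- round(
      100 * stats::rbeta(1, completeness_shape1, completeness_shape2), 2)
    names(mapped) <- paste0("mapped_pct_", references)
    rows[[length(rows) + 1L]] <- data.frame(
      experiment_id = experiment_id,
      sample_id = cells[[i]]$cell_id,
      species = own,
      t(mapped),
      hit_no_genomes_pct = hit_no,
      taxonomy_bin = own,
      completeness_pct = completeness,
      consistent_with_sort = TRUE,
      is_negative_control = FALSE,
      check.names = FALSE)
  }
  records <- if (length(rows)) do.call(rbind, rows) else NULL
  list(records = records, n_sorted = length(cells),
       references = references)
}

#' Write a batch record table as TSV
#'
#' Mapping percentages appear as one `mapped_pct_<reference>` column per
#' reference, followed by the unassigned percentage and assembly columns;
#' the result is readable by [read_cell_records()].
#'
#' @param batch the list returned by [simulate_batch()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_batch_tsv <- function(batch, path) {
  if (is.null(batch$records)) stop("batch has no records to write")
  utils::write.table(batch$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
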