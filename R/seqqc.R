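#' Half-up rounding
#'
#' Table statistics are printed with half-up rounding (so 36.295 -> 36.30),
#' unlike base R's round-half-even. A small guard absorbs binary floating
#' point representation error of decimal inputs.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  f <- 10^digits
  sign(x) * floor(round(abs(x) * f, 6) + 0.5) / f
}

#' Mean of percentages, printed-table style
#'
#' Arithmetic mean with half-up rounding, the aggregation used for the
#' per-species average mapping-rate and completeness columns of the
#' benchmark tables.
#'
#' @param values percentages in `[0, 100]`.
#' @param decimals decimal places (default 2, matching the tables).
#' @return the rounded mean.
#' @export
mean_pct <- function(values, decimals = 2L) {
  if (length(values) == 0L) stop("mean_pct: empty input")
  if (any(values < 0 | values > 100))
    stop("mean_pct: values must lie in [0, 100]")
  round_half_up(mean(values), decimals)
}

#' Sorting success rate
#'
#' `100 * n_positive / n_sorted`, half-up rounded: the fraction of sorted
#' cells that yielded a validated amplification product.
#'
#' @param n_positive number of successful cells, `0 <= n_positive <=
#'   n_sorted`.
#' @param n_sorted number of sorted cells (> 0), including failures.
#' @param decimals decimal places.
#' @return percentage.
#' @export
success_rate <- function(n_positive, n_sorted, decimals = 2L) {
  if (n_sorted <= 0) stop("success_rate: n_sorted must be positive")
  if (n_positive < 0 || n_positive > n_sorted)
    stop("success_rate: need 0 <= n_positive <= n_sorted")
  round_half_up(100 * n_positive / n_sorted, decimals)
}

#' Read a per-cell sequencing record table
#'
#' Expects a tidy TSV with one row per sorted cell (or negative control):
#' `experiment_id`, `sample_id`, `species` (the sorted target; empty for
#' controls), one `mapped_pct_<reference>` column per reference genome,
#' `hit_no_genomes_pct`, `taxonomy_bin`, `completeness_pct`,
#' `contaminant_pct_bound`, `consistent_with_sort`, `is_negative_control`.
#'
#' For simulated records the per-reference percentages plus the unassigned
#' percentage sum to 100 within rounding; published benchmark tables carry
#' transcription and rounding anomalies of several percent, so the row-sum
#' check can be relaxed.
#'
#' @param path TSV path.
#' @param sum_check what to do when a cell row's percentages sum outside
#'   `[99, 101]`: `"error"` (default), `"warn"`, or `"none"`.
#' @return data.frame of records.
#' @export
read_cell_records <- function(path, sum_check = c("error", "warn", "none")) {
  sum_check <- match.arg(sum_check)
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("NA", ""), comment.char = "#")
  need <- c("experiment_id", "sample_id", "hit_no_genomes_pct",
            "is_negative_control")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("record table is missing column(s): ", paste(miss, collapse = ", "))
  df$is_negative_control <- as.logical(df$is_negative_control)
  pct <- grep("^mapped_pct_", names(df), value = TRUE)
  if (length(pct) == 0L) stop("record table has no mapped_pct_* columns")
  sums <- rowSums(df[pct], na.rm = TRUE) + df$hit_no_genomes_pct
  # negative controls (empty droplets) map to nothing in particular and
  # are exempt from the row-sum invariant
  bad <- which((sums < 99 | sums > 101) & !df$is_negative_control)
  if (length(bad) && sum_check != "none") {
    msg <- sprintf("row %d: mapping percentages sum to %.2f, outside [99, 101]",
                   bad[1L], sums[bad[1L]])
    if (sum_check == "error") stop(msg) else warning(msg)
  }
  df
}

#' Own-species mapping percentage of each record
#'
#' @param records record data.frame (see [read_cell_records()]).
#' @return numeric vector; `NA` for negative controls.
#' @export
own_species_mapping <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    sp <- records$species[i]
    if (is.na(sp) || isTRUE(records$is_negative_control[i])) return(NA_real_)
    col <- paste0("mapped_pct_", sp)
    if (!col %in% names(records))
      stop(sprintf("no mapped_pct_ column for species '%s'", sp))
    records[[col]][i]
  }, 0)
}

#' Batch-level summary of sorting and sequencing outcomes
#'
#' Aggregates per-cell records into the derived statistics of the
#' benchmark tables: per experiment and species, the mean own-species
#' mapping percentage and mean genome completeness (via [mean_pct()]);
#' per experiment, the success rate (records divided by cells sorted);
#' and the global minimum / maximum of the species-average mapping rates.
#' Negative controls are excluded from every mean and from success-rate
#' numerators.
#'
#' @param records record data.frame (see [read_cell_records()]).
#' @param sorted_counts named vector or data.frame (`experiment_id`,
#'   `n_sorted`) giving the number of cells sorted per experiment.
#' @param decimals rounding for the table statistics.
#' @return a `batch_summary` object: list with `species_stats`
#'   (experiment x species means), `success` (per-experiment success
#'   rates), `mapping_avg_range` (min/max of species averages), and
#'   `n_records`.
#' @export
batch_summary <- function(records, sorted_counts, decimals = 2L) {
  if (is.data.frame(sorted_counts))
    sorted_counts <- stats::setNames(sorted_counts$n_sorted,
                                     sorted_counts$experiment_id)
  cells <- records[!records$is_negative_control, , drop = FALSE]
  unknown <- setdiff(unique(cells$experiment_id), names(sorted_counts))
  if (length(unknown))
    stop("records reference unknown experiment(s): ",
         paste(unknown, collapse = ", "))
  cells$own_mapping <- own_species_mapping(cells)
  groups <- unique(cells[c("experiment_id", "species")])
  species_stats <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- cells[cells$experiment_id == groups$experiment_id[i] &
                 cells$species == groups$species[i], , drop = FALSE]
    data.frame(
      experiment_id = groups$experiment_id[i], species = groups$species[i],
      n_cells = nrow(g),
      avg_mapping_pct = mean_pct(g$own_mapping, decimals),
      avg_completeness_pct =
        if (all(is.na(g$completeness_pct))) NA_real_
        else mean_pct(g$completeness_pct[!is.na(g$completeness_pct)],
                      decimals))
  }))
  success <- do.call(rbind, lapply(names(sorted_counts), function(e) {
    n_pos <- sum(cells$experiment_id == e)
    data.frame(experiment_id = e, n_positive = n_pos,
               n_sorted = sorted_counts[[e]],
               success_rate_pct = success_rate(n_pos, sorted_counts[[e]],
                                               decimals))
  }))
  structure(
    list(species_stats = species_stats, success = success,
         mapping_avg_range = range(species_stats$avg_mapping_pct),
         n_records = nrow(cells)),
    class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf("batch_summary: %d records, species-average mapping %.2f-%.2f%%\n",
              x$n_records, x$mapping_avg_range[1L], x$mapping_avg_range[2L]))
  print(x$species_stats, row.names = FALSE)
  print(x$success, row.names = FALSE)
  invisible(x)
}

#' Identity of a cell from its top contig bin
#'
#' Assigns the cell to the taxon whose contig bin carries the largest
#' total contig length; ties are broken alphabetically with a warning.
#'
#' @param annotations data.frame with columns `contig_id`, `length`,
#'   `genus`.
#' @return list with `genus` and `weight` (fraction of total contig
#'   length in the top bin).
#' @export
top_bin_taxonomy <- function(annotations) {
  stopifnot(is.data.frame(annotations), nrow(annotations) > 0L,
            all(c("length", "genus") %in% names(annotations)))
  totals <- tapply(annotations$length, annotations$genus, sum)
  totals <- totals[order(names(totals))]
  top <- which(totals == max(totals))
  if (length(top) > 1L)
    warning("tie between contig bins; broken alphabetically")
  list(genus = names(totals)[top[1L]],
       weight = unname(totals[top[1L]] / sum(totals)))
}
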