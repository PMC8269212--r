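#' Bundled mock-community benchmark records
#'
#' The per-cell sequencing outcome table of the four-species
#' mock-community sorting benchmark shipped with the package (see
#' `inst/extdata/mock_benchmark_records.tsv`): nine experiments in three
#' series — morphology-sorted (`A-1`..`A-3`, 20 cells sorted each),
#' C-D-band-sorted (`B-1`..`B-3`, 11 each) and carotenoid-band-sorted
#' (`C-1`..`C-3`, 11 each) — with one row per amplification-positive
#' cell or negative control.
#'
#' @return data.frame of records (see [read_cell_records()]).
#' @export
mock_benchmark_records <- function() {
  # printed tables carry per-row rounding anomalies of a few percent,
  # so the row-sum invariant is not enforced on this fixture
  read_cell_records(system.file("extdata", "mock_benchmark_records.tsv",
                                package = "ramansort", mustWork = TRUE),
                    sum_check = "none")
}

#' Cells sorted per benchmark experiment
#'
#' @return data.frame `experiment_id`, `n_sorted` for the nine bundled
#'   benchmark experiments.
#' @export
mock_sorted_counts <- function() {
  data.frame(
    experiment_id = c("A-1", "A-2", "A-3", "B-1", "B-2", "B-3",
                      "C-1", "C-2", "C-3"),
    n_sorted = c(20L, 20L, 20L, 11L, 11L, 11L, 11L, 11L, 11L))
}

#' Bundled soil single-cell assembly records
#'
#' Marker-gene completeness, recovered genome size and GC of single-cell
#' amplified genomes sorted from a soil cell extract, by sorting
#' criterion (`cd_peak` or `carotenoid`).
#'
#' @return data.frame with columns `sample_id`, `group`, `genus`,
#'   `completeness_pct`, `genome_kbp`, `gc_pct`.
#' @export
soil_sag_records <- function() {
  utils::read.delim(system.file("extdata", "soil_sag_records.tsv",
                                package = "ramansort", mustWork = TRUE),
                    comment.char = "#")
}

#' Pathway-gene annotations of the soil carotenoid-producer assemblies
#'
#' Presence of carotenoid-biosynthesis genes in the seven
#' carotenoid-sorted single-cell assemblies, as reported by homology
#' annotation of their contigs: the three most complete assemblies
#' (CRG1, CRG2, CRG4) reconstruct the MEP module (CRG4 lacking `ispA`);
#' in the beta-carotene module only CRG2 carries `crtB` while CRG1
#' carries `crtI` and `lcyB`; in the astaxanthin module CRG1 carries both
#' `crtW` and `crtZ`, CRG2 and CRG4 carry `crtZ` only.
#'
#' @return named list: sample id -> character vector of gene labels.
#' @export
soil_pathway_annotations <- function() {
  mep_full <- pathway_modules()$MEP
  list(
    CRG1 = c(mep_full, "crtE", "crtI", "lcyB", "crtW", "crtZ"),
    CRG2 = c(mep_full, "crtE", "crtB", "crtZ"),
    CRG4 = c(setdiff(mep_full, "ispA"), "crtZ"),
    CRG5 = c("dxs", "idi"),
    CRG6 = c("dxr", "ispE"),
    CRG7 = c("dxs", "ispG", "crtE"),
    CRG11 = c("ispH"))
}
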