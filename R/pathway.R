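#' Bundled carotenoid-biosynthesis pathway modules
#'
#' Fixed step lists for the three modules of microbial carotenoid
#' biosynthesis used to score single-cell assemblies:
#'
#' * `MEP` — methyl-D-erythritol-4-phosphate route to isopentenyl
#'   pyrophosphate, plus the prenyl chain elongation step (`dxs`, `dxr`,
#'   `ispD`, `ispE`, `ispF`, `ispG`, `ispH`, `idi`, `ispA`).
#' * `beta_carotene` — GGPP synthase through lycopene cyclization
#'   (`crtE`, `crtB`, `crtI`, `lcyB`).
#' * `astaxanthin` — the two-step conversion of beta-carotene
#'   (`crtW` beta-carotene ketolase, `crtZ` beta-carotene hydroxylase).
#'
#' @return named list of character vectors (ordered step labels).
#' @export
pathway_modules <- function() {
  list(
    MEP = c("dxs", "dxr", "ispD", "ispE", "ispF", "ispG", "ispH",
            "idi", "ispA"),
    beta_carotene = c("crtE", "crtB", "crtI", "lcyB"),
    astaxanthin = c("crtW", "crtZ"))
}

#' Pathway-module step coverage of annotated gene sets
#'
#' Fraction of a module's steps present among the gene labels of one
#' sample, or — in union mode, when a list of samples is supplied — among
#' the merged labels of all samples (collective coverage).
#'
#' @param gene_labels character vector of gene labels for one sample, or
#'   a list of such vectors for union-mode collective coverage.
#' @param module module name, one of `names(pathway_modules())`.
#' @return list with `coverage` (fraction in `[0, 1]`), `present` and
#'   `missing` step vectors.
#' @export
pathway_step_coverage <- function(gene_labels, module) {
  mods <- pathway_modules()
  if (!module %in% names(mods))
    stop(sprintf("unknown pathway module '%s'; available: %s", module,
                 paste(names(mods), collapse = ", ")))
  steps <- mods[[module]]
  if (is.list(gene_labels)) gene_labels <- unique(unlist(gene_labels))
  present <- intersect(steps, gene_labels)
  list(coverage = length(present) / length(steps),
       present = present, missing = setdiff(steps, present))
}
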