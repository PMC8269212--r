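#' Run configuration
#'
#' A flat, YAML-serializable list of every tunable the pipeline commands
#' use: axis bounds, baseline parameters, thresholds, rounding, seed and
#' community size. `save_config()` / `load_config()` round-trip it, and
#' every command logs the resolved configuration to stderr.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return a `run_config` object.
#' @export
run_config <- function(...) {
  cfg <- list(
    axis_start_cm1 = 400, axis_stop_cm1 = 3200, axis_step_cm1 = 1,
    baseline_lambda = 1e8, baseline_p = 0.01, baseline_iter = 10L,
    cdr_threshold = 0.05, snr_threshold_k = 5,
    sort_criterion = "cd_band",
    n_cells = 20L, noise_sd = 0.05,
    p_mda_success = 0.43,
    qc_decimals = 2L,
    record_sum_check = "error",
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$n_cells < 1L) stop("n_cells must be >= 1")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

log_config <- function(config, cmd) {
  hash <- substr(tools::md5sum(
    files = {
      tf <- tempfile(); save_config(config, tf); tf
    }), 1, 8)
  message(sprintf("[%s] ramansort %s, config hash %s, seed %d", cmd,
                  as.character(utils::packageVersion("ramansort")),
                  hash, config$seed))
}

#' Simulate a full study: spectra, contigs and an outcome table
#'
#' Generates the default mock community on the configured axis, writes
#' per-cell spectrum TSVs with ground-truth JSON sidecars, a synthetic
#' contig FASTA per species, the simulated sorting outcome table, and a
#' manifest listing every output with its checksum. Deterministic per
#' seed: rerunning with the same configuration reproduces identical
#' files.
#'
#' @param config a [run_config()].
#' @param out_dir writable output directory (created if missing).
#' @return path of the manifest file, invisibly.
#' @export
cmd_simulate <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  log_config(config, "simulate")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
    stop("output directory is not writable: ", out_dir)
  axis <- spectrum_axis(config$axis_start_cm1, config$axis_stop_cm1,
                        config$axis_step_cm1)
  cells <- make_mock_community(
    mock_community_spec(n_cells = config$n_cells), axis = axis,
    noise_sd = config$noise_sd, seed = config$seed)
  files <- character(0)
  spec_dir <- file.path(out_dir, "spectra")
  dir.create(spec_dir, showWarnings = FALSE)
  for (cell in cells) {
    f <- file.path(spec_dir, paste0(cell$cell_id, ".tsv"))
    write_spectrum_tsv(cell$spectrum, f, truth = cell$truth)
    files <- c(files, f, paste0(f, ".json"))
  }
  gcs <- c(Ec = 0.50, Hp = 0.39, Se = 0.55, Sc = 0.38)
  for (sp in names(gcs)) {
    g <- synthetic_genome(sp, 60000L, gcs[[sp]],
                          seed = config$seed + match(sp, names(gcs)))
    contigs <- make_contigs(g, 20L, lengths = 2500L,
                            seed = config$seed + 100L)
    f <- file.path(out_dir, paste0("contigs_", sp, ".fasta"))
    write_contigs_fasta(contigs, f)
    files <- c(files, f)
  }
  batch <- simulate_batch(cells, p_mda_success = config$p_mda_success,
                          experiment_id = "sim-1", seed = config$seed)
  if (!is.null(batch$records)) {
    f <- file.path(out_dir, "batch_records.tsv")
    write_batch_tsv(batch, f)
    files <- c(files, f)
  }
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  mf <- file.path(out_dir, "MANIFEST.tsv")
  utils::write.table(manifest, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mf)
}

#' Phenotype a directory of spectrum TSVs
#'
#' Reads every `*.tsv` spectrum in a directory, runs the preprocessing
#' pipeline and classification, and writes the phenotype table. When
#' ground-truth sidecars are present, a truth-versus-call confusion
#' matrix over the joint classes is written alongside.
#'
#' @param spectra_dir directory of spectrum TSVs (the `spectra/` output
#'   of [cmd_simulate()]).
#' @param config a [run_config()].
#' @param out_tsv output phenotype TSV path.
#' @return the phenotype data.frame, invisibly.
#' @export
cmd_phenotype <- function(spectra_dir, config = run_config(), out_tsv) {
  stopifnot(inherits(config, "run_config"))
  log_config(config, "phenotype")
  paths <- list.files(spectra_dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(paths) == 0L)
    stop("no spectrum TSV files in ", spectra_dir)
  specs <- lapply(paths, read_spectrum_tsv)
  tab <- phenotype_cells(specs,
                         cdr_threshold = config$cdr_threshold,
                         snr_threshold_k = config$snr_threshold_k,
                         criterion = config$sort_criterion,
                         lambda = config$baseline_lambda,
                         p = config$baseline_p,
                         n_iter = config$baseline_iter)
  utils::write.table(tab, out_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truths <- lapply(specs, attr, "truth")
  if (all(!vapply(truths, is.null, TRUE))) {
    true_class <- vapply(truths, function(tr) paste0(
      if (isTRUE(tr$d2o_labeled)) "CD+" else "CD-",
      if (isTRUE(tr$carotenoid_producer)) "CAR+" else "CAR-"), "")
    cm <- table(truth = true_class, call = tab$joint_class)
    utils::write.table(as.data.frame(cm),
                       sub("\\.tsv$", "_confusion.tsv", out_tsv),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tab)
}

#' Summarize a sequencing record table
#'
#' Runs [batch_summary()] on a record TSV and writes the species-level
#' statistics as TSV plus the whole summary as JSON.
#'
#' @param records_tsv record table path (see [read_cell_records()]).
#' @param sorted_counts data.frame `experiment_id`, `n_sorted`.
#' @param config a [run_config()].
#' @param out_prefix output path prefix; writes `<prefix>_species.tsv`
#'   and `<prefix>_summary.json`.
#' @return the `batch_summary`, invisibly.
#' @export
cmd_qc <- function(records_tsv, sorted_counts, config = run_config(),
                   out_prefix) {
  stopifnot(inherits(config, "run_config"))
  log_config(config, "qc")
  records <- read_cell_records(records_tsv,
                               sum_check = config$record_sum_check)
  bs <- batch_summary(records, sorted_counts,
                      decimals = config$qc_decimals)
  utils::write.table(bs$species_stats, paste0(out_prefix, "_species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(species_stats = bs$species_stats, success = bs$success,
         mapping_avg_range = bs$mapping_avg_range,
         n_records = bs$n_records),
    paste0(out_prefix, "_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(bs)
}
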