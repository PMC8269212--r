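#' Genome completeness as the fraction of reference bases covered
#'
#' Mock-benchmark completeness definition: the percentage of reference
#' positions covered by at least one contig alignment (a base counts as
#' aligned if any contig aligns over it; overlapping alignments are
#' unioned). Alignment uses a simplified exact-anchor scheme intended for
#' synthetic data: every contig (both strands) is scanned for exact
#' k-mer anchors in the reference, each anchor is extended without gaps
#' while bases match, and the covered intervals are unioned.
#'
#' @param contigs a `Biostrings::DNAStringSet` (or character vector).
#' @param reference a `Biostrings::DNAString` (or single string).
#' @param anchor_k anchor length (default 31); must not exceed the
#'   shortest contig.
#' @param anchor_stride distance between anchor start positions along a
#'   contig (default `anchor_k`, i.e. non-overlapping anchors).
#' @param decimals rounding of the reported percentage.
#' @return completeness percentage of the reference.
#' @export
completeness_by_aligned_bases <- function(contigs, reference, anchor_k = 31L,
                                          anchor_stride = anchor_k,
                                          decimals = 2L) {
  if (is.character(reference)) reference <- Biostrings::DNAString(reference)
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  if (length(reference) == 0L) stop("empty reference")
  if (length(contigs) == 0L) stop("no contigs")
  if (min(Biostrings::width(contigs)) < anchor_k)
    stop(sprintf("anchor_k = %d exceeds the shortest contig (%d bp)",
                 anchor_k, min(Biostrings::width(contigs))))
  ref_chars <- strsplit(as.character(reference), "")[[1L]]
  cover <- list()
  for (i in seq_along(contigs)) {
    for (strand_seq in list(contigs[[i]],
                            Biostrings::reverseComplement(contigs[[i]]))) {
      cov <- anchor_extend(strand_seq, reference, ref_chars,
                           anchor_k, anchor_stride)
      if (length(cov)) cover[[length(cover) + 1L]] <- cov
    }
  }
  if (length(cover) == 0L) return(round_half_up(0, decimals))
  all_iv <- IRanges::reduce(do.call(c, cover))
  round_half_up(100 * sum(IRanges::width(all_iv)) / length(reference),
                decimals)
}

# Exact k-mer anchoring plus ungapped extension of one contig strand
# against the reference; returns covered reference intervals.
anchor_extend <- function(contig, reference, ref_chars, k, stride) {
  clen <- length(contig)
  con_chars <- strsplit(as.character(contig), "")[[1L]]
  starts <- unique(c(seq(1L, clen - k + 1L, by = stride), clen - k + 1L))
  hits <- list()
  seen <- character(0)
  for (s in starts) {
    anchor <- Biostrings::subseq(contig, s, s + k - 1L)
    m <- Biostrings::matchPattern(anchor, reference)
    for (p in IRanges::start(m)) {
      # extend left
      ci <- s; ri <- p
      while (ci > 1L && ri > 1L && con_chars[ci - 1L] == ref_chars[ri - 1L]) {
        ci <- ci - 1L; ri <- ri - 1L
      }
      # extend right
      cj <- s + k - 1L; rj <- p + k - 1L
      while (cj < clen && rj < length(ref_chars) &&
             con_chars[cj + 1L] == ref_chars[rj + 1L]) {
        cj <- cj + 1L; rj <- rj + 1L
      }
      key <- paste(ri, rj)
      if (!key %in% seen) {
        seen <- c(seen, key)
        hits[[length(hits) + 1L]] <- IRanges::IRanges(ri, rj)
      }
    }
  }
  if (length(hits)) IRanges::reduce(do.call(c, hits)) else IRanges::IRanges()
}

#' Windowed GC content along a sequence
#'
#' Tiles (default) or slides a fixed-width window along the sequence and
#' reports per-window GC percentage, `100 * (G + C) / (A + C + G + T)`.
#' `N` (and any other ambiguity code, treated as `N`) is excluded from
#' both numerator and denominator; all-ambiguous windows are skipped with
#' a message. The trailing partial window is dropped.
#'
#' @param sequence a `Biostrings::DNAString` or single character string.
#' @param window window width in bp (default 200).
#' @param step step between window starts (default `window`, i.e. tiling).
#' @return numeric vector of per-window GC percentages.
#' @export
gc_windows <- function(sequence, window = 200L, step = window) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  n <- length(sequence)
  if (n < window) stop("sequence shorter than one window")
  starts <- seq(1L, n - window + 1L, by = step)
  v <- Biostrings::Views(sequence, start = starts, width = window)
  counts <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"),
                                        OR = 0)
  valid <- rowSums(counts)
  gc <- unname(100 * (counts[, "G"] + counts[, "C"]) / valid)
  skipped <- valid == 0
  if (any(skipped))
    message(sprintf("gc_windows: skipped %d all-ambiguous window(s)",
                    sum(skipped)))
  gc[!skipped]
}

#' Moments of the pooled window-GC distribution of a contig set
#'
#' Pools [gc_windows()] over every contig long enough to hold one window
#' and reports mean, sd, skewness and excess kurtosis, plus the matched
#' normal parameters for a density overlay (the visual normality check
#' applied to single-cell assemblies).
#'
#' @param contigs a `Biostrings::DNAStringSet` or character vector.
#' @param window,step window parameters for [gc_windows()].
#' @param min_windows minimum pooled window count (default 30).
#' @return list: `gc` (pooled window GC values), `mean`, `sd`,
#'   `skewness`, `excess_kurtosis`, `normal_overlay` (list `mean`, `sd`),
#'   `n_windows`.
#' @export
gc_profile <- function(contigs, window = 200L, step = window,
                       min_windows = 30L) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  keep <- Biostrings::width(contigs) >= window
  vals <- unlist(lapply(which(keep), function(i)
    gc_windows(contigs[[i]], window = window, step = step)))
  if (length(vals) < min_windows)
    stop(sprintf("only %d windows; need at least %d", length(vals),
                 min_windows))
  m <- mean(vals); s <- stats::sd(vals)
  list(gc = vals, mean = m, sd = s,
       skewness = unname(e1071::skewness(vals, type = 2)),
       excess_kurtosis = unname(e1071::kurtosis(vals, type = 2)),
       normal_overlay = list(mean = m, sd = s),
       n_windows = length(vals))
}

#' Canonical tetranucleotide (k-mer) signature of contigs
#'
#' Counts k-mers merged with their reverse complements (contig strand is
#' arbitrary, so a k-mer and its reverse complement are the same feature;
#' at k = 4 this yields 136 canonical features), row-normalized to sum 1.
#' Contigs at or below `min_len` are dropped first; windows containing
#' non-ACGT letters are skipped by the counter.
#'
#' @param contigs a `Biostrings::DNAStringSet` or character vector.
#' @param k k-mer size (default 4).
#' @param min_len length filter: only contigs strictly longer are kept
#'   (default 1,500 bp, the contig filter used for embedding).
#' @param canonical merge reverse complements? (default TRUE)
#' @return numeric matrix, contigs x k-mer features, rows summing to 1.
#' @export
kmer_features <- function(contigs, k = 4L, min_len = 1500L,
                          canonical = TRUE) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  keep <- Biostrings::width(contigs) > min_len
  if (!any(keep))
    stop(sprintf("no contig longer than %d bp", min_len))
  contigs <- contigs[keep]
  counts <- Biostrings::oligonucleotideFrequency(contigs, width = k)
  if (canonical) {
    kmers <- colnames(counts)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(kmers)))
    canon <- ifelse(kmers <= rc, kmers, rc)
    counts <- t(rowsum(t(counts), group = canon))
  }
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("contig with no countable k-mers")
  feats <- counts / tot
  rownames(feats) <- names(contigs)
  feats
}

#' 2-D embedding of contig k-mer signatures
#'
#' Projects the k-mer feature table to two dimensions for visual binning
#' of contigs by genome of origin. The default is t-SNE (the standard
#' choice for contig-signature maps); `method = "pca"` gives the first
#' two principal components. Deterministic given `seed`.
#'
#' @param features matrix from [kmer_features()].
#' @param perplexity t-SNE perplexity; requires
#'   `nrow(features) - 1 >= 3 * perplexity`.
#' @param seed integer seed.
#' @param method `"tsne"` or `"pca"`.
#' @return data.frame `contig_id`, `x`, `y`.
#' @export
embed_features <- function(features, perplexity = 30, seed = 1L,
                           method = c("tsne", "pca")) {
  method <- match.arg(method)
  n <- nrow(features)
  if (method == "tsne") {
    if (n - 1 < 3 * perplexity)
      stop(sprintf("too few rows (%d) for perplexity %g: need > %g",
                   n, perplexity, 3 * perplexity + 1))
    set.seed(as.integer(seed))
    fit <- Rtsne::Rtsne(features, perplexity = perplexity, dims = 2L,
                        check_duplicates = FALSE, pca = TRUE,
                        verbose = FALSE)
    xy <- fit$Y
  } else {
    if (n < 3L) stop("too few rows for an embedding")
    xy <- stats::prcomp(features, center = TRUE, scale. = FALSE)$x[, 1:2]
  }
  data.frame(contig_id = rownames(features) %||% as.character(seq_len(n)),
             x = xy[, 1L], y = xy[, 2L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write embedding coordinates as TSV
#'
#' @param embedding data.frame from [embed_features()].
#' @param labels optional per-contig labels (e.g. genome of origin).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding_tsv <- function(embedding, path, labels = NULL) {
  if (!is.null(labels)) embedding$label <- labels
  utils::write.table(embedding, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
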