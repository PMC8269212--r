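#' Synthetic genome model
#'
#' An order-0 (i.i.d. base) composition model with a target GC fraction,
#' used to manufacture contig sets whose GC and tetranucleotide signatures
#' behave like genomes of the stated composition.
#'
#' @param label genome label.
#' @param length_bp genome length in bp.
#' @param gc_fraction target GC fraction in `[0, 1]`.
#' @param seed integer seed; fully determines the sequence.
#' @return a `synthetic_genome` object with the realized sequence
#'   (a `Biostrings::DNAString`).
#' @export
synthetic_genome <- function(label, length_bp, gc_fraction, seed = 1L) {
  if (length_bp < 1) stop("genome length must be positive")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must lie in [0, 1]")
  set.seed(as.integer(seed))
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- sample(names(p), length_bp, replace = TRUE, prob = p)
  structure(list(label = label, length_bp = as.integer(length_bp),
                 gc_fraction = gc_fraction, seed = as.integer(seed),
                 sequence = Biostrings::DNAString(paste(bases, collapse = ""))),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome '%s': %d bp, target GC %.2f\n",
              x$label, x$length_bp, x$gc_fraction))
  invisible(x)
}

#' Slice contigs out of a synthetic genome
#'
#' Draws contigs as substrings of the genome at random start positions,
#' mimicking an assembly of that genome. Deterministic given the seed.
#'
#' @param genome a [synthetic_genome()].
#' @param n_contigs number of contigs.
#' @param lengths contig lengths (recycled); all must be positive and no
#'   longer than the genome.
#' @param seed integer seed.
#' @return a named `Biostrings::DNAStringSet` (`<label>_c001`, ...).
#' @export
make_contigs <- function(genome, n_contigs, lengths, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (n_contigs < 1) stop("n_contigs must be >= 1")
  lengths <- as.integer(rep_len(lengths, n_contigs))
  if (any(lengths < 1)) stop("contig lengths must be positive")
  if (any(lengths > genome$length_bp))
    stop("contig length exceeds genome length")
  set.seed(as.integer(seed))
  starts <- vapply(lengths, function(L)
    sample.int(genome$length_bp - L + 1L, 1L), 1L)
  seqs <- Biostrings::DNAStringSet(
    mapply(function(s, L) as.character(
      Biostrings::subseq(genome$sequence, s, s + L - 1L)),
      starts, lengths))
  names(seqs) <- sprintf("%s_c%03d", genome$label, seq_len(n_contigs))
  attr(seqs, "starts") <- starts
  seqs
}

#' Write contigs as wrapped FASTA
#'
#' @param contigs a `Biostrings::DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  Biostrings::writeXStringSet(contigs, path, width = 60L)
  invisible(path)
}

#' @rdname write_contigs_fasta
#' @export
read_contigs_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
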