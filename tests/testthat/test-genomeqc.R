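test_that("aligned-base completeness handles exact tilings and halves", {
  ref <- synthetic_genome("r", 20000, 0.5, seed = 1)$sequence
  tiling <- Biostrings::DNAStringSet(vapply(seq(1, 20000, by = 2000),
    function(s) as.character(Biostrings::subseq(ref, s, s + 1999)), ""))
  expect_equal(completeness_by_aligned_bases(tiling, ref), 100.00)
  half <- Biostrings::DNAStringSet(as.character(
    Biostrings::subseq(ref, 1, 10000)))
  expect_equal(completeness_by_aligned_bases(half, ref), 50.00)
})

test_that("aligned-base completeness equals the boolean-array oracle", {
  ref <- synthetic_genome("r", 50000, 0.45, seed = 2)$sequence
  # random non-overlapping fragments covering ~40%
  set.seed(37)
  starts <- seq(1, 48000, by = 5000)
  lens <- sample(1500:2500, length(starts), TRUE)
  frag <- Biostrings::DNAStringSet(vapply(seq_along(starts), function(i)
    as.character(Biostrings::subseq(ref, starts[i],
                                    starts[i] + lens[i] - 1)), ""))
  mask <- logical(50000)
  for (i in seq_along(starts)) mask[starts[i]:(starts[i] + lens[i] - 1)] <- TRUE
  expect_equal(completeness_by_aligned_bases(frag, ref),
               round_half_up(100 * mean(mask), 2))
})

test_that("aligned-base completeness sees reverse-complemented contigs", {
  ref <- synthetic_genome("r", 10000, 0.5, seed = 3)$sequence
  rc <- Biostrings::reverseComplement(Biostrings::subseq(ref, 2001, 4000))
  expect_equal(completeness_by_aligned_bases(
    Biostrings::DNAStringSet(as.character(rc)), ref), 20.00)
})

test_that("aligned-base completeness validates the anchor length", {
  ref <- synthetic_genome("r", 5000, 0.5, seed = 4)$sequence
  short <- Biostrings::DNAStringSet("ACGTACGTACGT")
  expect_error(completeness_by_aligned_bases(short, ref), "anchor_k")
})

test_that("windowed GC matches hand-countable sequences", {
  expect_equal(gc_windows(strrep("ATGC", 100)), rep(50, 2))
  expect_equal(gc_windows(strrep("G", 600)), rep(100, 3))
  # trailing partial window dropped
  expect_length(gc_windows(strrep("A", 450)), 2)
  expect_error(gc_windows("ACGT"), "shorter")
})

test_that("windowed GC equals the naive counting oracle", {
  g <- synthetic_genome("g", 10000, 0.62, seed = 5)
  s <- as.character(g$sequence)
  got <- gc_windows(s)
  expect_equal(got, gc_windows_oracle(s))
  expect_lt(abs(mean(got) - 62), 2)
  # sliding mode
  expect_equal(gc_windows(s, step = 100), gc_windows_oracle(s, step = 100))
})

test_that("ambiguity codes are excluded from GC numerator and denominator", {
  s <- paste0(strrep("G", 100), strrep("N", 50), strrep("A", 50))
  expect_equal(gc_windows(s), 100 * 100 / 150)
  expect_message(out <- gc_windows(paste0(strrep("N", 200), strrep("GA", 100))),
                 "skipped")
  expect_equal(out, 50)
})

test_that("tiling window GC averages back to whole-sequence GC", {
  g <- synthetic_genome("g", 8000, 0.44, seed = 6)
  s <- as.character(g$sequence)
  whole <- 100 * Biostrings::letterFrequency(g$sequence, "GC",
                                             as.prob = TRUE)[[1]]
  expect_equal(mean(gc_windows(s, window = 200)), whole, tolerance = 1e-12)
})

test_that("GC profile of order-0 contigs is near normal", {
  ct <- make_contigs(synthetic_genome("g", 200000, 0.5, seed = 7),
                     200, 2500, seed = 8)
  gp <- gc_profile(ct)
  expect_gte(gp$n_windows, 2000)
  expect_lt(abs(gp$skewness), 0.2)
  expect_lt(abs(gp$excess_kurtosis), 0.3)
  expect_equal(gp$normal_overlay$mean, gp$mean)
})

test_that("a two-genome mixture inflates the GC spread", {
  lo <- make_contigs(synthetic_genome("lo", 60000, 0.30, seed = 9),
                     40, 2000, seed = 10)
  hi <- make_contigs(synthetic_genome("hi", 60000, 0.62, seed = 11),
                     40, 2000, seed = 12)
  single <- gc_profile(lo)
  mix <- gc_profile(c(lo, hi))
  expect_gt(mix$sd, 2 * single$sd)
  expect_error(gc_profile(Biostrings::DNAStringSet(strrep("ACGT", 100))),
               "windows")
})

test_that("GC profile of a constant-composition sequence has zero spread", {
  gp <- gc_profile(Biostrings::DNAStringSet(strrep("GC", 5000)))
  expect_equal(gp$sd, 0)
})

test_that("k-mer features live on the simplex with canonical merging", {
  polyA <- Biostrings::DNAStringSet(strrep("A", 1603))
  f <- kmer_features(polyA)
  expect_equal(ncol(f), 136)
  expect_equal(unname(f[1, "AAAA"]), 1)
  expect_equal(sum(f[1, ] != 0), 1)
  ct <- make_contigs(synthetic_genome("g", 50000, 0.5, seed = 13),
                     20, 2000, seed = 14)
  ff <- kmer_features(ct)
  expect_equal(unname(rowSums(ff)), rep(1, 20), tolerance = 1e-9)
})

test_that("k-mer features are invariant under reverse complement", {
  ct <- make_contigs(synthetic_genome("g", 30000, 0.55, seed = 15),
                     5, 2000, seed = 16)
  rc <- Biostrings::DNAStringSet(vapply(as.character(ct), revcomp_chr, ""))
  f1 <- kmer_features(ct)
  f2 <- kmer_features(rc)
  expect_equal(unname(f1), unname(f2))
})

test_that("k-mer featurization enforces the length filter", {
  short <- Biostrings::DNAStringSet(strrep("ACGT", 100))
  expect_error(kmer_features(short), "1500")
  mixed <- Biostrings::DNAStringSet(c(strrep("ACGT", 100),
                                      strrep("ACGT", 500)))
  expect_equal(nrow(kmer_features(mixed)), 1)
})

test_that("embedding separates genomes and is seed-deterministic", {
  ct <- do.call(c, lapply(seq_along(c(0.30, 0.45, 0.62)), function(i)
    make_contigs(synthetic_genome(paste0("g", i), 80000,
                                  c(0.30, 0.45, 0.62)[i], seed = i),
                 60, 2000, seed = 20 + i)))
  f <- kmer_features(ct)
  e1 <- embed_features(f, perplexity = 15, seed = 5)
  e2 <- embed_features(f, perplexity = 15, seed = 5)
  expect_equal(e1, e2)
  sil <- cluster::silhouette(rep(1:3, each = 60),
                             dist(e1[, c("x", "y")]))
  expect_gt(mean(sil[, 3]), 0.5)
  expect_error(embed_features(f[1:10, ], perplexity = 15), "perplexity")
})

test_that("duplicate feature rows embed to nearby points", {
  ct <- make_contigs(synthetic_genome("g", 50000, 0.5, seed = 17),
                     30, 2000, seed = 18)
  f <- kmer_features(ct)
  fdup <- rbind(f, f[1, , drop = FALSE])
  # exact with the linear embedding
  ep <- embed_features(fdup, method = "pca")
  expect_equal(unlist(ep[31, c("x", "y")]), unlist(ep[1, c("x", "y")]),
               ignore_attr = TRUE)
})
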