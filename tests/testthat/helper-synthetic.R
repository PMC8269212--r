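# shared fixtures and independent oracles, built in code at test time

# trapezoid oracle, written independently of band_area
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

# default study conditions: full axis, mock templates, noise sd 0.05
test_axis <- spectrum_axis()

quiet_cell <- function(bands, seed = 1, noise_sd = 0.05,
                       baseline = c(2, -0.5), hump = c(1300, 500, 1)) {
  make_spectrum(test_axis, bands, baseline_params = baseline,
                fluor_hump = hump, noise_sd = noise_sd, seed = seed)
}

# a baseline-free spectrum pre-marked as corrected, for tests that probe
# the statistics rather than the baseline estimator
corrected_spectrum <- function(bands, noise_sd = 0, seed = 1) {
  ms <- make_spectrum(test_axis, bands, baseline_params = 0,
                      noise_sd = noise_sd, seed = seed)
  sp <- ms$spectrum
  sp$state <- "baseline_corrected"
  list(spectrum = sp, truth = ms$truth)
}

# minimal cell list for batch simulation (no spectra needed)
stub_cells <- function(n, species = c("Ec", "Hp", "Se", "Sc")) {
  sp <- rep_len(species, n)
  lapply(seq_len(n), function(i)
    list(cell_id = sprintf("cell%03d", i), species = sp[i]))
}

# independent largest-remainder enumeration
largest_remainder_oracle <- function(p, n) {
  raw <- p * n
  k <- floor(raw)
  left <- n - sum(k)
  ord <- order(raw - k, decreasing = TRUE)
  for (i in seq_len(left)) k[ord[i]] <- k[ord[i]] + 1
  as.integer(k)
}

# naive per-window GC counter
gc_windows_oracle <- function(seq_chr, window = 200, step = window) {
  chars <- strsplit(seq_chr, "")[[1]]
  starts <- seq(1, length(chars) - window + 1, by = step)
  out <- numeric(0)
  for (s in starts) {
    win <- chars[s:(s + window - 1)]
    acgt <- sum(win %in% c("A", "C", "G", "T"))
    if (acgt == 0) next
    out <- c(out, 100 * sum(win %in% c("G", "C")) / acgt)
  }
  out
}

# explicit reverse complement for k-mer canonicalization checks
revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}
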