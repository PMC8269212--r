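---
title: "Methods: single-cell Raman phenotyping and single-cell genome QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell Raman phenotyping and single-cell genome QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramansort)
```

## The measurement model

A single-cell Raman spectrum (SCRS) is a trace of scattered-light
intensity against Raman shift (wavenumber, cm^-1^). Two metabolic
phenotypes are read from it:

* **Heavy-water labeling.** Cells incubated with D~2~O incorporate
  deuterium into biomass through NADPH-mediated H/D exchange; C--D bonds
  scatter in a band red-shifted from the C--H stretching region. The
  package quantifies incorporation with the C-D ratio
  $$\mathrm{CDR} = \frac{A_{\mathrm{CD}}}{A_{\mathrm{CD}} + A_{\mathrm{CH}}},$$
  where $A_{\mathrm{CD}}$ is the band area over 2,040--2,300 cm^-1^
  (peak near 2,157 cm^-1^) and $A_{\mathrm{CH}}$ the area over
  2,800--3,100 cm^-1^. CDR is a fraction in [0, 1] and is invariant both
  to C--H normalization and to overall intensity scaling, because
  numerator and denominator scale together.

* **Carotenoid content.** Carotenoids give three strong resonance bands:
  *v*~1~ (CH~3~ rocking, 1,000--1,020 cm^-1^), *v*~2~ (C--C stretch,
  1,150--1,170 cm^-1^) and *v*~3~ (C=C stretch, 1,500--1,550 cm^-1^).

The two boolean calls combine into the four-way joint class
(`CD+CAR+`, `CD-CAR+`, `CD+CAR-`, `CD-CAR-`) that drives the sorting
decision (`cd_band`, `carotenoid`, or `morphology_passthrough`).

## Preprocessing pipeline

Spectra move through four states, strictly forward:
`raw -> dark_subtracted -> baseline_corrected -> ch_normalized`.

1. **Dark subtraction** is an exact pointwise difference on identical
   axes.
2. **Baseline correction** is asymmetric least squares (ALS): minimize
   $\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2$ with
   weights $w_i = p$ above the current baseline and $1 - p$ below,
   iterated to a fixed point. Defaults: $p = 0.01$, 10 iterations,
   $\lambda = 10^8$.
3. **C--H normalization** divides the trace by its C--H window area, so
   `band_area(x, "CH") == 1` afterwards; a non-positive C--H area is an
   error (dead pixel row or empty trap).

### Why $\lambda = 10^8$

The ALS penalty acts on *index* second differences, so the smoothness
that a given $\lambda$ buys scales with the fourth power of points per
cm^-1^. On the default 1 cm^-1^ axis, the baseline must stay stiff
across the C--H envelope, which is ~300 cm^-1^ wide; weaker penalties
(10^5^--10^6^) visibly climb into that band and can swallow most of its
area, biasing CDR upward by ~0.1. $\lambda = 10^8$ preserves bands up
to a few hundred cm^-1^ wide while still following fluorescence humps of
the several-hundred-cm^-1^ scale; at $10^9$ the estimate becomes too
stiff to track realistic fluorescence. Users working on coarser axes
should scale $\lambda$ accordingly.

### Re-zeroing on the silent region

With $p = 0.01$ the asymmetric fit tracks the *lower envelope* of the
noise, leaving residuals biased high by roughly two noise standard
deviations. Combined with negative clipping during integration (below),
this would manufacture C-D area in unlabeled cells. `correct_baseline()`
therefore subtracts the median residual over a biologically silent
window (default 1,800--1,900 cm^-1^) and folds the offset into the
returned baseline, so `corrected = input - baseline` holds exactly.
The window is configurable and the step can be disabled.

### Integration and clipping

Band areas are trapezoidal integrals on the native axis — no
resampling, for bit-reproducibility. Negative intensities are clipped to
zero before integration by default: after baseline removal, noise
oscillates around zero, and allowing negative area into the CDR
numerator would make the statistic noise-sign-dependent. Clipping
leaves a small positive floor (about $\sigma/\sqrt{2\pi}$ per point) in
signal-free windows, which is exactly why the CDR positivity threshold
is calibrated rather than set to zero.

Savitzky--Golay smoothing (window 9, order 3) is available but off by
default; the preprocessing contract does not include smoothing.

## Detection rules and thresholds

* **CDR threshold.** No fixed cutoff is hard-coded as "the" labeled
  threshold. `calibrate_cdr_threshold()` implements the standard
  stable-isotope-probing practice of mean + 3 sd over an unlabeled
  control population (>= 20 cells), with `max` and `fixed` alternatives.
  The package default of 0.05 sits several control-floor standard
  deviations above the clipping floor (~0.01) at the default noise
  level and far below labeled values (~0.18 under default templates).
* **Carotenoid rule.** The three resonance windows give per-band SNR =
  (max intensity in window) / (noise sd from the silent region). A cell
  is carotenoid-positive when *v*~3~ — the strongest resonance band —
  clears the threshold (default k = 5) AND at least one of *v*~1~ /
  *v*~2~ does. Requiring a corroborating band suppresses single-window
  noise spikes.
* **Carotenoid/CDR interaction.** Instruments photobleach carotenoids
  before reading C-D, because the resonance signal can swamp the weaker
  C-D band. Computationally the CDR is still evaluated on every
  baseline-corrected spectrum; carotenoid-positive cells carry
  `cdr_post_quench = FALSE` to flag that their CDR was read without
  quenching.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study
conditions under which every recovery claim is made.

* **Bands are Gaussian** with closed-form area
  $a \sigma \sqrt{2\pi}$, so the true CDR of any synthetic cell is
  known analytically before noise is added. Real Raman lines are
  Voigt-like and can be asymmetric; line-shape mismatch is not part of
  what the tests probe.
* **Baselines** are degree-<= 5 polynomials (on a [0, 1]-rescaled axis)
  plus an optional broad fluorescence Gaussian; defaults: a gently
  sloping polynomial with a 500 cm^-1^-wide hump of amplitude 1/3 of
  the C--H peak, which stresses the corrector on both scales.
* **Default community** mirrors the benchmark design: four species in a
  1:1:1:1 ratio, one heavy-water-labeled (*Ec*), one carotenoid
  producer (*Se*). Cells are apportioned by largest-remainder rounding
  (deterministic, sums exactly; 126 cells over four equal species gives
  32/32/31/31).
* **Noise** is i.i.d. Gaussian, default sd 0.05 a.u. against a C-D
  amplitude of 1 (SNR ~ 20) and C--H amplitude of 3 (SNR ~ 60). The
  instrument's real SNR is not published; these values were chosen once
  as representative of confocal single-cell acquisitions and place the
  benchmark in the regime where the pipeline should work, not where it
  trivially saturates. Spectral cosmic-ray spikes, detector etaloning
  and wavenumber miscalibration are *not* simulated, so passing tests
  bound only noise-and-baseline behavior, not those artifacts.
* **Genomes** are order-0 (i.i.d. base) sequences at a target GC;
  contigs are substrings at random positions. Real genomes have
  codon structure, repeats and skew; order-0 composition suffices for
  GC-window and tetranucleotide-signature behavior but overstates
  within-genome homogeneity, so embedding separations on synthetic data
  are upper bounds on real-data separability at equal GC contrast.
* **Sequencing outcomes** model post-pipeline summaries only (no reads,
  no chimera structure): amplification success is Bernoulli, the
  unassigned-read percentage log-normal, and cross-species
  contamination uniform on 0--1.5%, mirroring observed cross-mapping
  that is mostly below 0.5% and maximally ~1.3%. Rows are rounded to
  two decimals with the unassigned column absorbing the rounding
  residue, so percentages sum to 100 within 0.05.

## Sequencing-QC statistics

* **Table statistics** use half-up rounding at two decimals (one or
  zero where the benchmark prints them so); base R's `round()`
  half-even rule would disagree with printed values such as 36.295
  -> 36.30. Published table rows themselves carry per-row anomalies of
  several percent in their mapping-percentage sums, so
  `read_cell_records()` lets the row-sum invariant be enforced
  (`error`), reported (`warn`) or skipped (`none`, used for the
  bundled transcription).
* **Success rate** divides validated cells by all sorted cells. Two
  numerators circulate in practice — amplification-positive cells and
  16S-validated cells — and they differ; both are supported by passing
  the corresponding count, neither is canonized.
* **Aligned-base completeness** (the mock-benchmark definition: percent
  of reference bases under at least one contig alignment) uses an
  exact k-mer anchor (default k = 31, both strands) with ungapped
  extension and interval union. This simplified aligner is valid for
  synthetic, near-exact-substring data only; marker-gene completeness
  estimation for real assemblies is out of scope.
* **GC windows** default to 200 bp tiling (step = window). Tiling gives
  independent windows, which the moment-based normality summaries
  assume; true sliding is available via `step`. `N` and all other
  ambiguity codes are excluded from numerator and denominator;
  all-ambiguous windows are skipped.
* **Tetranucleotide signatures** merge each 4-mer with its reverse
  complement (136 canonical features) because contig strand is
  arbitrary; rows are normalized to the simplex. Contigs must exceed
  1,500 bp, the conventional floor below which 4-mer profiles are too
  noisy to bin. The 2-D map is t-SNE by default (deterministic given a
  seed) with a PCA alternative.
* **Pathway coverage** scores fixed step lists for the MEP,
  beta-carotene and astaxanthin modules (bundled as static definitions;
  no database queries), per sample or as the union over samples.

## Problem sizes and determinism

The test suite and the acceptance script regenerate all synthetic
inputs at run time: 200 cells for CDR recovery, a 60-cell four-species
community for joint classification, three 150-kb genomes yielding 300
contigs of 2 kb for the embedding, and reference genomes of 20--60 kb
for completeness oracles. These sizes keep the full suite under a
minute while leaving every stochastic margin wide (recovery and
accuracy near 100% against 95%/98% requirements, silhouette ~0.8
against 0.5). Every random draw is seed-derived; identical seeds give
bit-identical spectra, sequences and embeddings on the same platform.

## Known limitations

* ALS parameters are tuned to the default axis; other spectrometer
  grids need $\lambda$ rescaled by (points per cm^-1^)^4^.
* The exact-anchor aligner has no mismatch or gap model; divergent
  contigs under-cover.
* Carotenoid band positions are fixed windows; unusual pigments with
  shifted resonance bands would be missed.
* The time-course plateau flag compares the last inter-timepoint rise
  to 10% of the total rise; near that boundary the flag is sensitive to
  sampling noise in the per-timepoint means.
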