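# ramansort

Single-cell Raman phenotyping, sorting decisions, and quality control of
single-cell amplified genomes — for microbiologists who sort
metabolically active or pigment-producing cells out of complex
communities (soil, mock consortia) by their Raman spectra and then
sequence them one cell at a time.

## What it computes

The central statistic is the **C-D ratio** of a single-cell Raman
spectrum, the deuterium-incorporation proxy used to flag metabolically
active cells after heavy-water (D₂O) labeling:

```
CDR = A_CD / (A_CD + A_CH)
```

with `A_CD` the band area over 2,040–2,300 cm⁻¹ (C–D stretch, peaked
near 2,157 cm⁻¹) and `A_CH` the area over 2,800–3,100 cm⁻¹ (C–H
stretch). Around it the package provides:

* **Spectral preprocessing** with the states
  `raw → dark_subtracted → baseline_corrected → ch_normalized`:
  dark-trace subtraction, asymmetric-least-squares baseline correction,
  and normalization to unit C–H band area.
* **Phenotyping**: CDR, carotenoid detection from the three resonance
  bands (*v*₁ 1,000–1,020, *v*₂ 1,150–1,170, *v*₃ 1,500–1,550 cm⁻¹,
  SNR rule anchored on *v*₃), the four-way joint class, sorting
  decisions, CDR-threshold calibration from unlabeled controls, and
  D₂O time-course summaries with a plateau flag.
* **Sequencing QC** for sorted cells: per-species mapping-rate and
  completeness averages, success rates, aligned-base genome
  completeness (exact-anchor aligner for synthetic benchmarks),
  200-bp GC-window profiles with normality moments, canonical
  tetranucleotide contig signatures with a 2-D t-SNE map, top-bin
  taxonomy, and carotenoid-pathway (MEP / β-carotene / astaxanthin)
  step coverage.
* **Synthetic data with ground truth**: Gaussian-band spectra on
  fluorescence baselines (analytic CDR truth), mock communities with
  species-linked phenotypes, order-0 genomes/contigs with target GC,
  and stochastic sorting/amplification outcome tables.
* **Bundled benchmark tables** from a four-species mock community
  (*E. coli*, *H. pylori*, *S. elongatus*, *S. cerevisiae*, 1:1:1:1)
  sorted by morphology, C-D band, or carotenoid bands, plus soil
  single-cell assembly records.

## Worked example

Simulate a 12-cell mock community (3 cells per species; only *Ec* is
D₂O-labeled, only *Se* contains carotenoids), run the full pipeline,
and decide which cells to sort by the C-D criterion:

```r
library(ramansort)
cells <- make_mock_community(mock_community_spec(n_cells = 12), seed = 42)
phenotype_cells(cells, criterion = "cd_band")
#>    cell_id     cdr cd_positive carotenoid_positive joint_class sort_target
#> 1   Ec_001 0.18266        TRUE               FALSE     CD+CAR-        TRUE
#> 2   Ec_002 0.18076        TRUE               FALSE     CD+CAR-        TRUE
#> 3   Ec_003 0.18378        TRUE               FALSE     CD+CAR-        TRUE
#> 4   Hp_001 0.01050       FALSE               FALSE     CD-CAR-       FALSE
#> 7   Se_001 0.01433       FALSE                TRUE     CD-CAR+       FALSE
#> 10  Sc_001 0.00783       FALSE               FALSE     CD-CAR-       FALSE
#> ...
```

The three labeled cells come back with CDR ≈ 0.18 (their analytic truth
is 0.1818) and are the only sort targets; unlabeled cells sit at the
noise floor around 0.01, and the carotenoid producers are flagged
`CAR+`.

Summarizing the bundled benchmark records reproduces the derived table
statistics:

```r
bs <- batch_summary(mock_benchmark_records(), mock_sorted_counts())
bs$species_stats[13, ]
#>  experiment_id species n_cells avg_mapping_pct avg_completeness_pct
#>            B-1      Ec       4           65.00                36.30
bs$mapping_avg_range
#> [1] 52.79 98.83
success_rate(26, 60, 1)   # morphology-sorted series, 26 of 60 cells
#> [1] 43.3
```

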