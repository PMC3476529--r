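# dcmap

Cross-species transcriptome mapping of dendritic cell and monocyte
subsets by directional connectivity scoring.

## The problem

Human and mouse mononuclear phagocyte subsets are sorted by surface
markers that do not correspond across species, and expression profiles of
the "same" subset differ with the tissue it came from. `dcmap` aligns
subsets on transcriptome evidence alone: it removes genes that track
tissue of origin, condenses each subset into a rank-based gene signature,
and scores signatures against reference profiles with a directional
enrichment statistic, so that a human subset can be matched to its mouse
counterpart (and mismatches show up as negative, inverse scores). It is
aimed at immunologists and computational biologists doing comparative
profiling of sorted cell populations on array-style (log-intensity) data.

## The method

For one subset against all others, every gene is ranked by the
signal-to-noise ratio

    SNR(g) = (mu_target - mu_rest) / (sigma_target + sigma_rest),

with each sigma floored at `max(0.2*|mu|, 0.2)`; the top and bottom 150
genes form the up and down halves of the signature. Genes differentially
expressed between tissues (pooled Welch t across matched subsets,
Benjamini–Hochberg at 0.05) are removed first. A reference profile is
ranked best-to-worst and each signature half is scored with the signed
Kolmogorov–Smirnov running sum: with set size `t`, universe `n`, and
`V(j)` the j-th smallest set rank,

    a = max_j( j/t - V(j)/n ),   b = max_j( V(j)/n - (j-1)/t ),
    ks = a  if a > b  else  -b.

The connectivity score is `ks_up - ks_down` when the two halves disagree
in sign and 0 otherwise, positive for proximal and negative for inverse
profiles; scores are scaled jointly into [-1, 1] per run. Significance
comes from `B = 1000` random signatures of matched sizes
(`p = (1 + #{|null| >= |obs|}) / (B + 1)`). Human signatures are
translated to mouse gene space through an ortholog table (strict 1:1
policy by default), and subset relationships are visualized by
average-linkage clustering of 1 − Pearson correlation distances. A
synthetic two-species cohort generator with planted lineage homology,
tissue effects, donor offsets and noise makes the whole chain testable
against ground truth.

## Worked example

Simulate the default two-species cohort, run the cross-species arm, and
inspect how the pooled human cd141-lineage signature scores against the
mouse subsets:

```r
library(dcmap)
cfg <- analysis_config(design = default_cohort_design(),
                       seed = 17, permutations = 1000)
res <- run_cross_species(cfg, "cross_run")
res$enrichment$cd141_like_query
#> EnrichmentResult: query 'cd141_like_query' vs 28 profiles in 5 subsets (B = 1000)
#>             query   subset n_profiles mean_scaled    median_p
#>  cd141_like_query   CD8_DC          4   0.9531129 0.000999001
#>  cd141_like_query CD103_DC          8   0.9158411 0.000999001
#>  cd141_like_query   CD4_DC          4  -0.4259642 0.000999001
#>  cd141_like_query CD11b_DC          8  -0.4963250 0.000999001
#>  cd141_like_query monocyte          4  -0.9495393 0.000999001
```

Reading the table: the human cd141-lineage signature is most enriched in
the mouse CD8+ and CD103+ DC profiles (mean scaled scores 0.95 and 0.92 —
the planted cross-presenting homologs), is inversely related to mouse
monocytes (-0.95), and every per-sample score is significant at the
permutation minimum p = 1/1001. The run directory also receives the
pooled and ortholog-mapped signatures (GMT), the per-sample score table
(TSV), and a log with configuration echo and checksums; rerunning the
same configuration reproduces the files byte for byte.

The within-species arm (`run_within_species()`) produces the tissue-gene
list, per-subset signatures, the subset dendrogram (Newick), and the
connectivity table of the cd141-like query against all human subsets.

## Layout

- `R/` — generator, I/O, signatures, enrichment, orthology, clustering,
  pipeline
- `tests/testthat/` — unit, property, and end-to-end recovery tests
- `vignettes/cross-species-connectivity.Rmd` — the methods vignette:
  model, parameters, numerical choices, limitations
- `scripts/acceptance.R` — headline-number recomputation (above)
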