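# deepsage

Digital gene-expression analysis for deepSuperSAGE tag libraries in R.

SuperSAGE profiles a transcriptome by sequencing 26 bp tags anchored at the
3'-most NlaIII site (`CATG`) of each transcript; deep sequencing of ditags
(two tags ligated tail-to-tail) yields tens of thousands of tag observations
per library. `deepsage` implements the full desk-scale workflow around that
assay for studies comparing organs and stress conditions — e.g. roots and
nodules of a legume before and after salt treatment:

- **Tag extraction** — parse ditag reads (FASTA/FASTQ), recover both anchored
  26 bp tags (`tag1` from position 1, `tag2` as the reverse complement of the
  last 26 bases), count UniTags per library, and apply organ-wise singleton
  and low-complexity filters.
- **Expression profiles** — normalization to copies × 100,000⁻¹, abundance
  classes (<10, 10–100, (100,500], >500), fold change and the natural-log
  ratio `R_ln` (so `R_ln > 1` is the classical "at least 2.7-fold" mark), and
  Venn decompositions of regulated tag sets at 3-, 8- and 20-fold thresholds.
- **Significance** — the exact Audic–Claverie test for digital profiles.
  Conditional on count `x` in a library of size `N1`, the count `y` in a
  library of size `N2` follows
  `p(y|x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1))` with `r = N2/N1` — a negative
  binomial with size `x+1` and success probability `N1/(N1+N2)`. The
  two-sided p doubles the smaller of `P(Y ≤ y)` and its complement, the one
  doubling convention that is exactly symmetric under swapping the libraries.
- **SAAT families** — SNP-associated alternative tags clustered by ungapped
  positional identity (≥ 23 of 26 matching bases, i.e. homology over more
  than 22 bp) with single linkage; per-family representatives, called SNP
  positions, similar-hit histograms, and within-family expression divergence.
  External aligner output (BLAST outfmt 6) can replace the built-in metric.
- **EST-bridged annotation** — anchored ≤1-mismatch matching of tags onto an
  EST collection (mismatches never inside the `CATG` anchor), a ≥25/26
  matched-bases retention gate (surrogate for `E < 1e-5`; imported hits can
  gate on printed e-values), tiered taxonomic annotation transfer
  (e.g. Cicer/Fabaceae → Arabidopsis → rice/maize, e-value ≤ 1e-50 per tier,
  anonymous and weak-similarity entries excluded), GO linking, and
  UniTags-per-EST multiplicity reports.
- **GSR enrichment** — gene score resampling over-representation of GO and
  custom pathway categories: per-gene scores are `|R_ln|`, a category's
  observed aggregate is the mean member score, and the p-value compares it
  against `B` random same-size draws from the scored universe
  (`p = (1 + #{null ≥ observed}) / (B + 1)`), with no hit/no-hit cutoff.
  GO-slim summaries of the top-regulated tags are included.
- **Synthetic data** — a ground-truthed generator emulating the two-organ ×
  two-condition design: heavy-tailed abundances calibrated so ~90% of
  transcripts sit below 10 copies × 100,000⁻¹ and <1% above 500, planted SAAT
  families, spiked differential expression with `|R_ln| ∈ [1.0, 4.3]`, a
  spiked enriched category, ESTs, tier tables and GO maps — so every stage of
  the pipeline is testable against known truth. A mismatch-probe designer
  (complemented bases at positions 7, 13, 20) supports microarray
  cross-validation layouts.

Everything is tibble-in/tibble-out and pipe-friendly, with `tidy()`,
`glance()`, `autoplot()` and `plot_*()` methods for the main result types.

## Worked example

Simulate a study, extract and count tags, filter, and test for differential
expression:

```r
library(deepsage)
library(dplyr)

cfg <- sim_config(n_transcripts = 2000, depths = c(root = 40000, nodule = 30000))
sim <- simulate_transcriptome(cfg, seed = 7)
lib <- simulate_libraries(sim, seed = 8)

tags <- bind_rows(lapply(names(lib$reads), function(l)
  tibble(library = l, tag = extract_ditag_tags(lib$reads[[l]])$tag)))
counts <- count_tags(tags, lib$libraries[, c("id", "organ", "condition")]) |>
  filter_singletons() |>
  filter_low_complexity()
tag_libraries(counts)
#>   id             organ  condition total_tags
#> 1 root_control   root   control        19921
#> 2 root_nacl      root   NaCl           19920
#> 3 nodule_control nodule control        14924
#> 4 nodule_nacl    nodule NaCl           14927

dge <- differential_table(counts, "root_control", "root_nacl")
glance(dge)
#>   control      treatment n_tags n_up_2.7fold n_down_2.7fold min_p pseudocount
#> 1 root_control root_nacl    259           46             65     0           1

arrange(tidy(dge), p_value) |>
  select(unitag_id, count_control, count_treatment, fold_change, r_ln, p_value) |>
  head(3)
#>   unitag_id count_control count_treatment fold_change   r_ln   p_value
#> 1 STCa-10             275            3018      11.0    2.40  0
#> 2 STCa-39              19            1082      57.0    4.04  1.62e-291
#> 3 STCa-1            15936           12351       0.775 -0.255 4.88e-101
```

`STCa-10` rose from 275 to 3018 counts at comparable depth — an 11-fold
induction (`R_ln = 2.40`) the Audic–Claverie test calls at vanishing p;
`STCa-1` shows how even a modest 0.78-fold shift is highly significant for an
abundant tag. SAAT clustering on the same matrix:

```r
fam <- build_saat_families(counts)
glance(fam)
#>   n_tags n_families n_singletons largest_family min_identity
#> 1    289        283          277              2           23
hit_histogram(fam)
#>   similar_hits   n   pct
#> 1 0            277 95.8
#> 2 1             12  4.15
#> 3 2              0  0
#> 4 >=3            0  0
```

Twelve of the observed UniTags pair into 6 two-member isoform families (the
planted low-abundance isoforms are mostly below the sampling floor at this
depth). Downstream, `match_tags_to_ests()` → `retain_matches()` →
`transfer_annotation()` → `link_go()` carries tags to protein and GO
annotation, `aggregate_scores()` + `gsr()` runs the enrichment analysis, and
`autoplot(dge)`, `plot_abundance_classes()`, `plot_hit_histogram()` and
`autoplot(gsr_result)` draw the standard figures.

A command-line interface with subcommands `extract`, `dge`, `saat`,
`annotate`, `enrich` and `simulate` is installed at
`system.file("cli", "deepsage.R", package = "deepsage")`.

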