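---
title: "Methods: digital expression profiling with deepsage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital expression profiling with deepsage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepsage)
library(dplyr)
```

`deepsage` analyses deepSuperSAGE digital expression data: libraries of
26 bp transcript tags anchored at the 3'-most NlaIII site (`CATG`) of each
mRNA, sequenced as tail-to-tail ditags. This vignette documents the models
and procedures behind each stage, the tunable parameters and their defaults,
the numerical conventions, and the known limitations — in particular what the
synthetic benchmarks do and do not demonstrate about real data.

## Ditag extraction

A ditag read carries two tags: `tag1` is the first 26 bases in read sense,
`tag2` the reverse complement of the last 26 bases. Valid tags are exactly
26 bp, uppercase `ACGT`, and start with `CATG`; because `CATG` is its own
reverse complement, a read must both start and end with the anchor. Accepted
read lengths default to 50–54 bp, covering the cut-length variation of the
tagging enzyme (EcoP15I) around the nominal 52 bp ditag; tags shorter than
26 bases after trimming are rejected, never padded.

Reads are never half-lost silently: a read yielding at least one tag is
*accepted*, and the missing end (e.g. a read with no terminal anchor)
is tallied per tag in the extraction report under `no_end_anchor`. A read
yielding no tag is *rejected* under its first failing reason
(`no_start_anchor`, `no_end_anchor`, `bad_length`, `ambiguous_base`), so that
`reads_seen = reads_accepted + sum(rejections)` holds exactly. IUPAC
ambiguity codes are tolerated in a read but reject the affected tag;
characters outside the IUPAC alphabet reject the whole read.

Tags are strand-specific and never canonicalized by reverse complement: SAGE
tags derive from the transcript's sense strand, so a tag and its reverse
complement are different observations. UniTag ids (`STCa-1`, `STCa-2`, ...)
are assigned in first-seen order and persist through every downstream table.

### Filters

*Singletons.* A UniTag whose summed count across all libraries of one organ
equals 1 is removed from that organ (counts zeroed; rows that become
all-zero are dropped). The rule is organ-wise because organ-level UniTag
totals are the quantity SAGE studies conventionally report; a tag that is a
singleton in one organ but replicated in the other survives where it is
supported. Library sizes (`total_tags`, the `N` of the significance test)
are recomputed after every filter.

*Low complexity.* The assay's anchor makes positions 1–4 uninformative, so
complexity is assessed on positions 5–26: a tag is dropped when one base
occupies ≥ 80% of the 22 variable positions, or when a 1–2 nt motif tandem
repeat spans ≥ 18 consecutive variable positions. Both thresholds are
arguments; the defaults are deliberately conservative so that ordinary
AT-rich plant 3' ends survive while homopolymer and dinucleotide artifacts
do not.

## Normalization and abundance classes

Counts are scaled to copies × 100,000⁻¹ (`count × 1e5 / total_tags`), the
customary SAGE unit; per library the normalized column sums to 100,000 up to
floating-point rounding, and values are only rounded for display. Abundance
classes follow the conventional labels `<10`, `10–100`, `(100,500]`, `>500`,
binned as `[0,10)`, `[10,100]`, `(100,500]`, `(500,∞)` over tags with nonzero
counts — a complete partition whose boundaries match the printed class names.
Because such classes are conventionally reported at organ level,
`pool_by_organ()` sums a matrix's libraries within organs first.

## Fold change, R(ln), and the pseudocount

For a tag with counts `x` (control) and `y` (treatment) in libraries of sizes
`N_c`, `N_t`:

\[
\mathrm{fold} = \frac{(y + pc)/N_t}{(x + pc)/N_c}, \qquad
R_{\ln} = \ln(\mathrm{fold}).
\]

The pseudocount (default 1) is added to *both* counts and *only when one of
them is zero*: observed nonzero ratios are reported exactly as measured,
while zeros yield finite folds instead of infinities. `R_ln` is the natural
logarithm — forced by the field's equivalence "at least 2.7-fold ⇔
R(ln) > 1.0" (e ≈ 2.718) — with up-regulation positive. Fold thresholds
(3, 8, 20) are applied on the linear scale with `≥`.

## The Audic–Claverie test

Under the null of equal relative abundance, conditional on `x`, the count `y`
follows

\[
p(y \mid x) = \frac{r^y \, (x+y)!}{x!\, y!\, (1+r)^{x+y+1}}, \quad r = N_2/N_1,
\]

which is a negative binomial with size `x + 1` and success probability
`N1/(N1+N2)`. The implementation evaluates tails through `stats::pnbinom`
(log-gamma/incomplete-beta path), numerically stable for counts far beyond
10⁵, rather than summing terms.

**Two-sided convention.** We report `p = min(1, 2·min(F(y), 1 − F(y)))` with
`F(y) = P(Y ≤ y | x)`. The alternative convention `2·min(P(Y≤y), P(Y≥y))`
(point mass counted in both tails) is *not* symmetric under swapping the
libraries, because the conditional's size parameter is `x + 1`: e.g. it gives
0.082 for `(x,y) = (12,3)` with `N = (80000, 60000)` but 0.119 for the
swapped call. The complement convention is exactly symmetric — the identity
`P(Y ≤ y | x; N_1, N_2) = 1 − P(Y ≤ x | y; N_2, N_1)` holds because both
tails reduce to tails of the same Binomial(x+y+1, N₁/(N₁+N₂)) — and a test
that answers differently depending on which library is named first would be
incoherent for a two-library comparison. Both conventions agree on the
standard worked examples (`p(0,0) = 1`, `p(5,0) = 2·(1/2)⁶ = 0.03125` at
equal sizes).

The doubled-tail test on a discrete distribution is conservative: on null
multinomial simulations at depth 100,000 per library, tags with expected
count ≥ 20 reach p < 0.05 at a rate of roughly 0.04–0.05 (the test suite
asserts the band [0.02, 0.07]). Raw p-values are reported, as is customary
for these profiles; a Benjamini–Hochberg column is available via
`differential_table(..., adjust = TRUE)`.

## SAAT families

SNP-associated alternative tags — near-identical UniTags interpreted as
transcript isoforms or allelic variants — are detected by ungapped positional
identity on the anchor-aligned 26-mers. Tags are linked at ≥ 23 identical
positions ("homology over more than 22 bases"); families are the
single-linkage connected components, computed via an igraph component search
over edges found by one-hot matrix products (chunked to bound memory). A
fixed-length Hamming metric is the appropriate similarity for anchor-aligned
tags of constant length; *indel* isoforms are outside its reach by
construction, and gapped alternatives can be injected through
`import_similarity_pairs()` (BLAST outfmt 6; a hit is a link when
`length × pident/100 ≥ 23` equivalent matched bases; self-hits dropped, links
symmetrized).

The family representative is the member with the highest summed copies ×
100,000⁻¹ across libraries, ties broken by lexicographically smallest
sequence (a deterministic choice that also fixes the partition's reported
order under input permutation). SNP positions are called per member against
the representative and always lie in 5–26, since the anchor is invariant.
`family_profile()` reports each member's summed abundance, the
representative's share, and — given a DGE table — whether members are
regulated in discordant directions.

## EST-bridged annotation

Tags are located on an EST collection by an anchored dictionary scan
(Biostrings `PDict` with the `CATG` anchor as trusted band): every occurrence
on either strand with at most 1 mismatch is reported, mismatches never fall
inside the anchor, and `matched_bases = 26 − mismatches`. Offsets are 0-based
on the EST forward strand for both strands. The retention gate keeps matches
with ≥ 25 of 26 matched bases — a deliberate surrogate for the conventional
`E < 1e-5` BLAST cutoff of a 26-mer against a ~44k EST collection, chosen so
the test path needs no external binary; imported tabular hits can be gated on
their printed e-values directly (`retain_matches(..., max_evalue = 1e-5)`),
and alignment-specific settings such as gap costs then live with the external
aligner.

Annotation transfers through tier tables in taxonomic priority order
(e.g. Cicer/Fabaceae → Arabidopsis → rice/maize). An EST takes the first tier
whose entry passes: not anonymous, not flagged weak-similarity, e-value at or
below the tier gate (default 1e-50, per tier configurable). Priority beats
magnitude — a passing higher-tier hit wins over a stronger lower-tier one —
and ESTs passing no tier are reported as `anonymous` (candidate novel
transcripts). The transfer is deterministic and order-independent given fixed
tables (within a tier, the lowest e-value per EST is taken). GO terms attach
per accession as deduplicated sets; multiplicity reports tabulate UniTags per
EST in the classes 1, 2, 3, 4, 5, >5.

## Gene score resampling

GSR asks whether a category's genes carry unusually large expression changes
*without* declaring a hit threshold. Per-accession scores default to the
maximum `|R_ln|` over the accession's tags (both directions count, matching
how organ- and stress-responses are reported in both senses; `mean_abs` and
the choice of score scale are arguments). A category's observed aggregate is
the mean score of its members present in the scored universe; the null is
`B = 10,000` draws (configurable) of equally many accessions without
replacement; and

\[
p = \frac{1 + \#\{\text{null aggregates} \ge \text{observed}\}}{B + 1},
\]

never exactly zero and deterministic given the seed (`withr::with_seed`
isolates the RNG). Categories with analyzed size outside `[5, 100]` are
skipped with a notice; both bounds are arguments since the appropriate range
depends on the annotation's granularity. Custom pathway categories
(e.g. an SOS-pathway or ROS-scavenger set) are added with
`add_custom_category()` and analyzed identically, only flagged. Raw p-values
are reported; BH correction can be applied downstream. GO DAG propagation is
intentionally out of scope — categories are taken as given, as
resampling-based over-representation tools conventionally do.

`goslim_top_summary()` counts distinct accessions per slim term among the
`top_n` tags ranked by fold change; ties at the cut are broken by smaller
p-value, then UniTag id, so the summary is reproducible.

## The synthetic study generator

The generator emulates the structure of a two-organ (root, nodule) ×
two-condition (control, 25 mM NaCl) deepSuperSAGE experiment, with defaults
fixed as the package's study conditions:

- **Pool size** 20,000 transcripts, matching the ~21,000-UniTag scale of a
  deep two-organ study; library depths 86,919 (root) and 57,281 (nodule)
  tag observations, split between conditions.
- **Abundances** are lognormal weights. The log-scale sd is solved
  analytically from the class targets — ~90% of true abundances below 10
  copies × 100,000⁻¹ and at most 1% above 500 — via
  `P(ln w < ln(n/10^4) + σ²/2) = 0.9`, taking the heavy-tailed root
  (σ ≈ 1.79 at n = 20,000; ≈ 3.02 at n = 5,000). The targets hold for the
  *generated* abundance vector at any n ≥ 5,000; the classes observed among
  *detected* tags in a finite library sit lower (≈ 77–82% below 10), because
  detection conditions on at least one sampled copy.
- **SAAT families**: similar-hit class fractions 79/15/4/2% for 0/1/2/3+
  similar tags (the unnamed residual of the 70/15/4/2 convention is assigned
  to singletons). Two-member families carry 1–3 SNPs per isoform; larger
  families one SNP per isoform at distinct positions, keeping all members
  within the linkage threshold of each other. Isoform weights are 1–10% of
  their parent's, so the parent is the representative. Substitutions are
  resampled if they would create a second `CATG`.
- **ESTs**: each tag is embedded in its own synthetic EST as
  `prefix + tag + tail`, the tail drawn G-free so the embedded anchor is
  provably the 3'-most NlaIII site with 22 bases downstream; isoform ESTs
  duplicate the parent's flanks. Tier tables give each non-anonymous parent
  a passing entry in one tier (probabilities 0.5/0.3/0.2; ~10% anonymous),
  and categories are drawn over the parent accession universe.
- **Differential expression**: 200 tags with `|R_ln| ~ U(1.0, 4.3)` and
  random sign; one spiked category of 20 accessions whose tags are always
  differentially expressed with an extra +1.0 score shift. Truly-null
  simulations set both `n_de_tags = 0` and `spike_size = 0`.
- **Ditags** pair observations uniformly at random (`tag1 + revcomp(tag2)`,
  52 bp); the real protocol's pairing carries no counting information. An odd
  depth draws one completing observation, and the recorded truth is always
  the multiset actually embedded, so extraction and counting must round-trip
  exactly — and the test suite asserts that they do, at depth 10⁵.

**What the truth means for R(ln).** Multinomial sampling realizes *relative*
abundances, so scaling the DE tags' weights shifts every tag's realized
log-ratio by the compositional constant `ln(Σw_ctrl / Σw_trt)`. The
generator's effective truth therefore includes that offset; recovery checks
compare estimates against it, which is what the generating process actually
embeds (the same compositional ambiguity affects real digital profiles).

**No sequencing-error model** is applied by default: the assay's proprietary
basecalling and error handling are not modelled, and the recovery benchmarks
are statements about sampling noise, not about robustness to miscalls. This
is the main respect in which passing tests do not certify behaviour on real
reads; the extraction filters and the ≤1-mismatch EST matcher are where
errors would surface.

## Benchmark problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
statistical assertions have adequate resolution: the Audic–Claverie oracle
grid spans x, y ∈ [0, 50] at size ratios {0.5, 1, 2} (7,803 cases; the
brute-force reference is direct pmf summation via the exact term recurrence,
which on this grid is accurate to ~1e-13); the null type-I band pools ~4,000
tag tests across five replicate library pairs at depth 100,000; R(ln)
recovery uses 2,000-transcript pools at 100,000 tags per library, where ≥ 100
DE measurements have expected counts ≥ 50 in both libraries (the estimator's
binomial sd is then ≤ 0.15, so the ±0.3 band captures ≥ 90%); SAAT recovery
clusters a 5,000–20,000-tag pool; spiked-category power uses ten replicate
1,500-transcript studies at B = 2,000 resamples.

## Known limitations

- Exact per-library UniTag totals of any particular published study are not
  reproducible from first principles: proprietary tag-sorting software and
  read-level quality rules are unspecified, so only the procedure — not the
  dataset — is re-implemented.
- The built-in similarity and matching metrics are ungapped; indel isoforms
  require imported aligner output.
- The fold-change pseudocount convention of legacy software is unknowable
  from printed tables; ours (both counts, only on zeros, default 1) is
  documented and configurable.
- GSR is implemented with mean aggregation and best-score-per-gene replicate
  handling; precision–recall style aggregates of other implementations are
  out of scope.
- Database-version-dependent annotation counts are not targets; the
  annotation stage is validated on planted truth instead.
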