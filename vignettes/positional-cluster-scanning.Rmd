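---
title: "Positional cluster scanning: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional cluster scanning: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffscan)
```

## The question the scan answers

In many fungal genomes, functionally related genes -- carbohydrate-active
enzymes (CAZymes), secondary-metabolite synthases -- sit in discrete
physical clusters rather than being scattered along the chromosomes. When a
regulator is perturbed and a few hundred genes change expression, a natural
question is whether the responding genes are *positionally clustered*: do
they sit closer together along the gene order of the scaffolds than uniform
random placement would put them?

`scaffscan` answers this with a spacing-threshold scanning statistic on
*gene-ordinal* coordinates. Every gene gets a 0-based rank (its ordinal) in
the coordinate-sorted gene list of its scaffold; all distances are
differences of ordinals, not base pairs. Working in gene-count space makes
the statistic insensitive to intergenic-distance variation and matches how
cluster density is usually quoted ("one affected gene at every third
locus").

## The scan statistic

Let $N$ be the number of genes in the genome and $k$ the number of *hits*
(e.g. significantly downregulated genes). Under uniform placement the
expected ordinal spacing between consecutive hits is

$$\bar{d} = N / k,$$

and the cluster criterion uses the threshold $\tau = \bar{d} / c$ with
divisor $c = 3$ by default: two consecutive hits on the same scaffold are
chained when their gap is at most $\tau$, i.e. at least threefold closer
than expected. At the scale the defaults encode ($N = 9143$, $k = 769$)
this gives $\bar{d} \approx 11.9$ and $\tau \approx 3.96$; with integer
ordinal gaps the criterion admits gaps of 1--3 genes.

A *candidate cluster* is a maximal run of hits whose internal gaps all
satisfy the criterion. Candidates become calls when

* they contain at least `min_hits` hits (default 3), and
* their local hit density, `n_hits / span_genes` over the ordinal span from
  first to last hit, is at least `min_enrichment`-fold (default 3) the
  genome-wide density $k / N$.

`min_hits = 3` exists because any two adjacent hits trivially exceed
threefold enrichment; the enrichment filter alone would call every chance
pair. Both knobs are exposed in `scan_params()`.

Two deliberately configurable ambiguities:

* **Gap metric.** "Distance in genes" can mean the ordinal difference
  (adjacent genes have distance 1) or the number of intervening genes
  (adjacent genes have distance 0). The default is the ordinal difference;
  `gap_metric = "intervening"` switches to the other reading, which shifts
  every gap down by one and makes the criterion slightly more permissive.
* **Boundary strictness.** Gaps are compared with `<=` by default
  (`strict = FALSE`); $\tau$ is real-valued, so with $c = 3$ this is only
  observable when $\bar d / 3$ is an integer.

Cluster boundaries are the first and last *hit*; spans are never extended
into the flanking non-hit genes.

## Significance: a permutation null

The scan always calls *something* on real-sized inputs: with $k/N \approx
0.084$ and $\tau \approx 4$, uniformly placed hits produce chance runs of
three nearby hits at an appreciable rate. The package therefore attaches a
permutation test (`permutation_test()`): `n_permutations` times (default
1000), $k$ loci are drawn uniformly without replacement from the genome --
preserving the scaffold structure, since drawn loci keep their scaffold and
ordinal -- and rescanned with identical parameters. The reported
upper-tail p-value for the observed cluster count uses add-one smoothing,

$$p = \frac{1 + \#\{b : n^{(b)}_{\text{clusters}} \ge n^{\text{obs}}_{\text{clusters}}\}}{B + 1},$$

so it is never 0 and is valid at any $B$. A per-scaffold stratified draw
(`stratified = TRUE`) is available when hits are unevenly spread over
scaffolds for reasons unrelated to local clustering (e.g. scaffold-level
assembly artefacts); it conditions on the observed per-scaffold hit counts.

An older convention for this kind of claim was a correlation-based
randomness argument; it is statistically opaque (it does not state what is
correlated with what), so the package does not implement it and uses the
permutation null as its only significance machinery.

The calibration experiment in the test suite draws 200 independent uniform
hit sets at the default scale and checks that the fraction of datasets with
$p \le 0.05$ stays near the nominal level (accepting 0.02--0.09: the
discreteness of cluster counts and the add-one smoothing make the test
slightly conservative).

## Upstream: selecting the hit genes

The DE stage reproduces a standard two-condition microarray selection
chain, in this order:

1. **Quantile normalization** (`quantile_normalize()`), delegated to
   `limma::normalizeQuantiles(ties = TRUE)`: every column is forced onto
   the row-means-of-sorted-columns reference; ties are mapped by
   average-rank interpolation, so tied values stay tied. For a tie spanning
   two ranks this equals the mean of the two reference values; for longer
   ties it is the midpoint reference value. The operation is idempotent,
   and on tie-free data all column sorted-value vectors coincide exactly.
2. **Replicate-CV filter** (`cv_filter()`): a gene passes when
   `sd/mean` of its linear-scale replicates is at most `cv_threshold`
   (default 0.20) in *every* condition, with the sample ($n-1$) SD. The
   threshold is interpreted as a coefficient of variation because an
   absolute "SD > 20%" is meaningless on arbitrary intensity units. Genes
   with a zero or undefined replicate mean fail with a flagged reason
   rather than raising an error.
3. **Fold change and test** (`fold_and_test()`): fold change is the ratio
   of linear-scale condition means, folded to `>= 1` with a `direction`
   label. The default per-gene test is limma's moderated t on log2
   intensities. With the two biological replicates per condition that the
   defaults model, an unmoderated Welch t has 2 degrees of freedom and
   essentially no power at FDR-corrected thresholds, whereas variance
   moderation borrows strength across the thousands of genes on the array;
   this is the standard practice for small-replicate microarrays. Welch's
   t remains available as `test = "welch"` for designs with many
   replicates.
4. **BH FDR** (`bh_adjust()`): the Benjamini--Hochberg step-up adjustment,
   delegated to `stats::p.adjust(method = "BH")` and verified in the test
   suite against a brute-force implementation of the step-up definition.
5. **Selection** (`select_regulated()`): `fold >= 2`, `q <= 0.05`,
   matching direction (default `"down"`), and optionally the CV flag.

A practical interaction worth knowing: at the default replicate noise
(`noise_sd = 0.25` on log2, i.e. a true linear CV of about 0.17), the CV
filter at 0.20 sits *inside* the noise distribution -- with two replicates
the sample CV exceeds 0.20 for roughly a quarter of all genes per
condition, regulated or not. The filter is therefore a data-quality device
for real arrays (where high CV flags bad probes), not a power-preserving
one; benchmark experiments that measure recall of planted effects disable
it (`cv_threshold = Inf`) and rely on the fold and FDR thresholds.

## The synthetic-data generator

`simulate_genome()` and `simulate_expression()` generate the study
conditions every test runs under. Defaults: 9143 genes on 40 scaffolds
(sizes proportional to `40:1`, a simple decreasing series standing in for
an assembly's scaffold-size distribution), 769 regulated genes of which 20
planted clusters of 6--10 hits (consecutive planted hits at ordinal gaps
of at most 2) absorb about 160, the rest placed uniformly outside the
planted spans; two biological replicates per condition; baseline log2
intensities `Normal(10, 2)`; replicate noise `Normal(0, 0.25)` on log2;
regulated genes shifted by `log2fc = -2` (fourfold down) in the treatment.

Choices that need a word of justification:

* **Gaussian log2 noise** is the standard microarray error model; 0.25 is
  a typical between-biological-replicate spread.
* **Baseline spread matters.** If every gene had the same baseline, the
  downregulated 8% of genes would occupy the lower tail of the treatment
  intensity distribution and quantile normalization would shrink the
  planted effect by roughly half. A baseline SD of 2 log2 units (typical
  intensities spanning ~2^6--2^14, as on real arrays) scatters regulated
  genes across the distribution, which is exactly the regime in which
  quantile normalization is safe.
* **Planted-cluster separation.** Planted spans are kept at least the
  expected spacing ($\lceil N/k \rceil$ ordinals) apart, so under the
  default $\tau = \bar d/3$ two planted clusters cannot chain into one and
  the ground truth is well defined.
* **Split between clustered and dispersed hits** is not a quantity the
  method prescribes; it is a free parameter (`n_planted_clusters`,
  `cluster_size_range`) with defaults of 20 clusters of 6--10 hits.
* **Category labels**: per-gene Bernoulli draws (default
  `CAZyme` at probability 320/9143), with the probability multiplied by
  `category_cluster_enrichment = 5` inside planted spans -- emulating the
  roughly fivefold CAZyme density of clustered genome regions. Because the
  genome-wide average includes the enriched spans, the measured density
  ratio of the planted regions lands somewhat below the nominal
  multiplier.
* **One RNG stream per stage, documented draw order.** The genome stage
  consumes its stream in the order: bp layout, cluster sizes, cluster
  placements, within-cluster gaps, dispersed hits, category labels; the
  expression stage (seeded at `seed + 1`) draws baselines then noise. A
  seed therefore reproduces every output bit for bit.

What the generator does *not* emulate: probe-level effects (the matrix is
gene-level by construction), dye or batch effects, correlated noise,
intensity-dependent variance, sequence content. Passing tests on this
generator show that the pipeline's logic is correct under its stated model,
not that real arrays satisfy that model.

## The recovery experiment

The planted-cluster benchmark simulates the default genome and scans the
true regulated set with `min_hits = 6` -- the smallest planted cluster
size, i.e. the scan is asked for the planted cluster class. This is a
deliberate choice: at `min_hits = 3`, uniformly dispersed hits alone
produce dozens of chance three-hit runs at this scale (the permutation
null quantifies exactly this), so counting them as "false" clusters would
measure the null behaviour of the statistic, not the scanner's
correctness. Recovery is scored as the fraction of planted ordinal spans
at least 90%-covered by a called cluster; a call is "unplanted" when it
overlaps no planted span at all. Span agreement is scored as coverage of
the planted span (not Jaccard) because a dispersed hit that happens to sit
within $\tau$ of a planted boundary legitimately extends the called run.

## Gene-list overlap

`directional_overlap()` reports the intersection of two gene lists as a
percentage of each list plus a hypergeometric upper-tail p-value
(`P(X >= overlap)` drawing `|A|` from a universe with `|B|` marked;
`stats::phyper`). The universe defaults to the genome gene count in the
pipeline. `reciprocal_overlap()` computes the two anti-correlated
components (up in A and down in B; down in A and up in B) separately and
summed, for comparisons of signed responses. The percentages are pure
arithmetic; the p-value is an addition beyond the percentage-only
convention, since a percentage without a null is uninterpretable.

## Numerical and interface conventions

* Ordinals are 0-based and contiguous per scaffold; bp coordinates are
  1-based inclusive internally; BED files are read and written 0-based
  half-open; GFF3 ties are broken by `(start, end, gene_id)`.
* Strand is carried through IO but ignored by the scan (gene-count
  distances are strand-blind).
* Category labels are case-sensitive exact strings.
* `expected_spacing()` returns the unrounded ratio; display rounding is
  one decimal by convention, and the threshold's customary printed form
  truncates (11.9 / 3 prints as 3.9).
* The pipeline fans one global seed out by fixed offsets (genome `seed`,
  expression `seed + 1`, permutations `seed + 2`) so stages can be rerun
  in isolation with unchanged results.
* Problem sizes in the test suite: oracle equivalence on 500 random
  scaffolds of up to 200 genes; permutation calibration on 200 datasets of
  199 permutations each at the default 9143-gene scale; DE recovery on
  2000 genes with 200 planted effects. These sizes make the whole suite
  run in about a minute while keeping every check at, or above, the scale
  at which the corresponding behaviour stabilizes.

## Known limitations

* The scan works purely in gene-ordinal space; a cluster criterion in
  base pairs (or one weighting intergenic distances) is out of scope.
* Cluster calls depend on the hit list being a meaningful set; the
  permutation test conditions on its size, not on how it was selected.
* The permutation p-value targets a single statistic (the cluster count);
  enrichment in cluster *strength* at equal counts is not tested.
* Only two-condition designs are supported upstream; multi-factor designs
  would need a different DE stage behind the same interface.
* The moderated test assumes shared variance structure across genes; with
  many replicates and strongly heteroskedastic data, `test = "welch"` may
  be preferable.
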