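---
title: "Recurrent CNV regions and candidate gene prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent CNV regions and candidate gene prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrecur)
```

## The analytical problem

Patients with congenital malformations — the motivating application is
orofacial clefts (OFC), i.e. cleft lip and/or palate — often carry large
genomic deletions or duplications (copy-number variants, CNVs) spanning tens
of genes. A single patient's CNV rarely identifies the causative gene, but a
cohort does: genomic segments deleted or duplicated in *several unrelated
patients with the same phenotype* are unlikely to recur by chance and are
enriched for dosage-sensitive genes. `cnvrecur` implements that reasoning as
a pipeline:

1. **Segmentation.** All CNVs of one type (deletions or duplications) are
   partitioned into maximal segments of constant coverage depth; a segment
   covered by $d$ CNVs is an *overlap region* of depth $d$.
2. **Permutation test.** Observed recurrence is compared to a null obtained
   by randomly relocating the same intervals over the placeable genome.
3. **Prioritization.** Genes in shared regions are filtered by recurrence,
   regional gene count and embryonic palate expression.
4. **Panel enrichment.** The candidate set is tested for enrichment of a
   literature-curated disease-gene panel (hypergeometric test).
5. **Variability scoring.** Candidate loci are checked against a population
   structural-variant catalog via windowed density z-scores, to verify they
   are not simply hypervariable regions of the genome.
6. **Phenotype mapping.** Co-occurring patient phenotypes are summarized at
   the top level of a phenotype ontology, and penetrance is contrasted
   against background carriers.

All internal coordinates are 0-based half-open. Tables exported from
genome-browser style resources (1-based inclusive) are converted once, at
read time (`coordinate_dialect = "ucsc_1_inclusive"`); no downstream code
re-checks dialects. Because the convention of a given supplementary export
is not always documented, the flag makes both readings available when
reproducing published coordinate-dependent numbers.

## Segmentation and the overlap statistic

`coverage_segments()` partitions the union of intervals at every interval
endpoint (the `disjoin` semantics of Bioconductor's ranges infrastructure)
and annotates each segment with the number of covering intervals. Two
conventions deserve note:

* **Depth counts intervals, not distinct patients.** This mirrors the
  behaviour of coverage-based BED tooling on which this style of analysis is
  built; patient multiplicity is resolved only in the contributor sets
  (`collapse_contributors()`), where a patient with two tandem CNVs over a
  segment appears once. In cohorts with essentially one CNV per patient the
  distinction is immaterial.
* **Maximality.** Adjacent output segments always differ in depth or in
  contributing interval set, so pairwise-disjoint input intervals are
  returned unchanged with depth 1, and conservation holds exactly:
  $\sum_\text{segments} d \times \ell = \sum_\text{intervals} \ell$.

The statistic summarized per interval list is the *mean overlap*: the
arithmetic mean of depth over all regions, singletons included. Depth-1
regions are part of the accounting (they are tabulated alongside shared
regions in the per-depth summary) even though only depth ≥ 2 regions feed
gene retrieval.

## The genome-shuffling null

`shuffle_intervals()` relocates each interval, preserving its length, to a
start position drawn uniformly over every legal position genome-wide — legal
meaning the interval lies within a chromosome and intersects no excluded
interval (assembly gaps, alternative haplotypes, random contigs).
Chromosomes are thus chosen with probability proportional to their legal
space, placements are mutually independent, and shuffled intervals may
overlap one another. Rather than rejection sampling, the legal start space
is enumerated per interval length and sampled exactly; an interval longer
than every gap-free stretch raises an error naming its length.

`randomization_test()` repeats shuffle → segment → mean overlap $R$ times
(1000 by default), yielding permutation means $\mu_i$. With
$\bar\mu = \text{mean}(\mu_i)$ and $\sigma = \text{sd}(\mu_i)$ (sample SD),

$$z_i = (\mu_i - \bar\mu)/\sigma,$$

and the observed list's $z_\text{real}$ uses the same formula with the
null's $\bar\mu$ and $\sigma$. By construction the permutation z-scores have
mean 0 and SD 1 (asserted to 1e-9 in the tests). The permutation z-scores
are generally *not* normal — Shapiro–Wilk is computed and reported — so
significance is the empirical p-value: the fraction of permutations with
$z_i \ge z_\text{real}$. When no permutation reaches the observed score the
conservative bound $1/R$ is reported with an explicit `p_is_upper_bound`
flag (at $R = 1000$, "p ≤ 0.001").

**Sparse regimes.** When intervals are few relative to the genome, most
permutations produce no overlaps at all and the null distribution of
$\mu_i$ is nearly discrete at 1; $z_\text{real}$ then jumps in units of
$1/\sigma$ and can exceed 3 for unremarkable cohorts. This is precisely why
the pipeline's inferential quantity is the empirical p, which remains
calibrated (we observe null empirical p ≈ 0.3–0.5 in such cases); the z is
a descriptive effect size. Per-permutation sub-seeds are derived
deterministically from one user seed, so runs are reproducible.

## Prioritization

Three criteria, each a named threshold in `prioritization_config()`:

| parameter | default | meaning |
|---|---|---|
| `min_patients` | 2 | distinct patients whose CNVs of the type overlap the gene |
| `max_genes_per_region` | 5 | maximum gene count of a supporting shared region |
| `nrpk_cutoff` | recomputed | minimum expression (nRPK) at any stage |

*Recurrence* is counted over distinct patients, not raw CNVs, consistent
with excluding genes altered in only one patient. *Regional gene count* is
evaluated on shared overlap regions (depth ≥ 2 segments): a gene passes if
**any** supporting shared region containing it has at most
`max_genes_per_region` genes (the `"all"` alternative is available via
`region_rule`). Genes are assigned to regions by any-overlap (≥ 1 bp), the
same rule genome-browser region queries use; full containment is available
as `mode = "contained"` in `genes_in_interval()`. *Expression* uses nRPK —
normalized counts divided by transcript length in kb — with gene-level
values aggregated across transcripts and stages by maximum, the permissive
reading of a "≥ cutoff at any stage" test. The default cutoff is the mean
nRPK over all expressed records (nRPK > 0), pooled across stages rather
than averaged per gene first; pooling weights every measurement equally and
is the simpler convention to reproduce. A fixed cutoff (e.g. the reference
analysis's 59.00) can be pinned via `nrpk_cutoff`.

Per-criterion pass flags are retained for every gene in the universe so that
filter attrition (universe → recurrent → small-region → expressed) is
reportable and monotone, and relaxing any threshold can only add candidates
(a property the tests assert).

## Panel enrichment

With $N$ universe genes (all genes retrieved from CNVs of one type before
prioritization), $K$ panel genes among them, $n$ candidates and $k$ panel
genes among candidates, fold enrichment is $(k/n)/(K/N)$ and significance
comes from the hypergeometric distribution. Two upper tails are reported:
`p_value` $= P(X \ge k)$, the conventional enrichment p-value, and
`p_value_published` $= P(X > k)$ — the strictly-exceeding tail produced by
`phyper(k, K, N-K, n, lower.tail = FALSE)`. The reference analysis's printed
p-values follow the latter convention, so that is what report twins print;
both are exposed and both are validated against exhaustive enumeration of
all $\binom{N}{n}$ draws for $N \le 12$ in the tests. Symbol matching is
case-insensitive with an explicit alias table (e.g. WHSC2/NELFA,
MAPK3/ERK1); fuzzy matching is deliberately avoided.

## Genomic variability

The genome is tiled into fixed windows (1 Mb default; the last window of a
chromosome keeps its remainder, flagged by its shorter width) and windows
overlapping any excluded interval are removed. Variant counts $c_i$ per
retained window come from any-overlap counting of a population
structural-variant catalog. Because counts are heavy-tailed, the score is
computed on logs:

$$\mu = \frac{\sum_i \log_{10} c_i}{n}, \qquad
  \sigma = \sqrt{\frac{\sum_i (\log_{10} c_i - \mu)^2}{n-1}}, \qquad
  z_i = \frac{\log_{10} c_i - \mu}{\sigma}.$$

Zero-count windows are dropped before standardization ($\log 0$ is
undefined) with a logged count; $\sigma$ uses the $n-1$ denominator. A
region or gene spanning several windows is scored by averaging the *raw*
counts of the windows it overlaps, then standardizing the log of that mean
with the genome-wide $\mu, \sigma$; a query overlapping no retained window
(telomeric candidates) is reported "not assessable" (`NA`). Gene burden
counts catalog losses/gains over the gene span (genic) and over any exon
(exonic; an intronic variant is genic only). Hypervariable-region flags are
quantile-based (default 0.999) because no universal numeric z cutoff
exists; the choice only labels windows and affects no other statistic.

## Phenotype mapping

The ontology loader accepts an OBO subset (`id`, `name`, `is_a`) or a
child–parent TSV; the root is auto-detected as the unique parentless term
and its direct children are the top-level categories. Mapping returns *all*
top-level ancestors of a term (faithful DAG semantics under multiple
inheritance); unknown term ids are recorded as unmapped rather than fatal,
so mapping failures surface here and not at cohort-read time. The
patient-by-category matrix excludes the selection phenotype's category by
default in the pipeline (every patient would carry it by construction); a
config key re-includes it. Penetrance contrasts distinct affected carriers
against background carriers per gene.

## The synthetic-data generator

`generate_all()` writes every input the pipeline consumes, with known
ground truth. It emulates:

* a multi-chromosome genome (5 × 100 Mb by default) with interior assembly
  gaps (2% of each chromosome) and one telomeric gap;
* a cohort (60 patients, one CNV each) containing planted recurrent loci —
  by default a deletion core stacked 8 deep, a duplication core 5 deep, and
  a gene-rich deletion core 2 deep — each carrier CNV extending the core by
  an independent uniform jitter (≤ 100 kb per side), over a uniform
  background of log-normal CNVs (median 150 kb, truncated to 1 kb–2 Mb,
  the size range typical of database cohorts);
* gene models with 1–8 exons; planted candidate loci hold few genes (≤ 5)
  of which exactly one is highly expressed, the gene-rich decoy locus holds
  7 highly expressed genes (fails only the gene-count criterion), one
  singleton locus holds a highly expressed gene carried by a single patient
  (fails only recurrence), and low-expression decoys inside candidate loci
  fail only the expression criterion — so every filter boundary is probed;
* log-normal expression with a configurable zero fraction, planted
  candidates at 3× the provisional cutoff and low decoys at 5% of it;
* a variant catalog that is Poisson per Mb window (rate 5/Mb) with a few
  windows elevated 15-fold (planted hotspots);
* a two-level mini-ontology whose top level includes the OFC category and
  whose leaf terms annotate the patients;
* a gene panel containing the planted candidates, and a background-carrier
  table giving the planted deletion candidate the highest
  affected-to-background ratio.

The generator does **not** mimic real cohorts' chromosome-specific CNV
rates, recurrent breakpoint architecture (segmental duplications), linkage
between CNV type and phenotype severity, or realistic expression
correlation across stages. Green tests on planted bundles therefore
demonstrate that the machinery detects the statistical structure it is
designed for — they do not certify performance on any particular real
dataset, whose reproduction additionally requires the original cohort
table, annotation, expression table and variant catalog as inputs.

## Numerical choices and degenerate inputs

* Exact legal-space sampling replaces rejection sampling in the shuffle;
  the distribution is identical and unplaceable intervals fail fast.
* `randomization_test()` errors on $\sigma = 0$ (degenerate null) with the
  advice to increase $R$ or the genome; `window_zscores()` errors when all
  counts are identical or fewer than two windows carry variants.
* Shapiro–Wilk is restricted to $3 \le n \le 5000$ (the implementation's
  supported range); constant vectors are an error rather than p ≈ 0.
* The empirical p is floored at $1/R$ and flagged as an upper bound.
* Mean-overlap computation inside the permutation loop uses an
  endpoint-sweep depth-run routine that provably agrees with the
  segmentation (asserted on random instances); the full segmentation is
  used everywhere results are reported.
* Ties in candidate tables are broken by patient count then symbol;
  per-depth summaries are sorted by depth.

## Problem sizes in the test suite

The suite validates against brute-force oracles on small instances
(per-base depth arrays on 10 kb toy chromosomes, exhaustive hypergeometric
enumeration at $N \le 12$, recursive DAG closures), runs the full pipeline
on default-size synthetic bundles, checks shuffle uniformity with a
χ² goodness-of-fit test at α = 0.01 on ~6,000 placements, and calibrates
the null with 100 replicate cohorts at $R = 100$ permutations each on a
compact three-chromosome genome where the overlap statistic is approximately
continuous. These sizes were chosen to exercise every code path with
comfortably stable statistics while keeping the default run fast.

## Known limitations

* No liftover: all inputs must share one genome build.
* No strand-aware logic; CNVs, windows and catalog variants are unstranded.
* The analytic null for overlap counts is out of scope by design — the
  null is purely simulation-based.
* Gene-level expression aggregation by maximum is permissive; cohorts with
  dominant short isoforms may prefer a length-weighted aggregate (not
  implemented).
* Enrichment assumes the panel and annotation use reconcilable symbol
  namespaces; only the explicit alias table bridges them.
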