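# cnvrecur

Candidate-gene discovery from recurrent copy-number variants (CNVs) in
patient cohorts.

When many unrelated patients who share a phenotype — the motivating
application is orofacial clefts — carry overlapping genomic deletions or
duplications, the shared segments point at dosage-sensitive candidate
genes. `cnvrecur` implements that analysis end to end, for geneticists
working from database-style CNV cohorts (patient id, CNV type,
chrom:start–end, phenotype terms):

* **Overlap segmentation** — partitions each CNV type's intervals into
  maximal constant-depth *overlap regions* with their contributing
  patients, and summarizes region counts and mean lengths per depth.
* **Permutation test** — shuffles the same intervals uniformly over the
  gap-free genome *R* times; with permutation mean overlaps
  $\mu_i$, $z_i = (\mu_i - \bar\mu)/\sigma$, the observed list's
  $z_\text{real}$ uses the same formula, and significance is the empirical
  p-value $\#\{z_i \ge z_\text{real}\}/R$ (reported as ≤ 1/R when no
  permutation reaches it; Shapiro–Wilk non-normality of the $z_i$ is
  checked and reported).
* **Prioritization** — genes in shared regions filtered by recurrence
  (≥ 2 distinct patients), regional gene count (≤ 5 genes in a supporting
  shared region) and embryonic palate expression (nRPK — normalized counts
  per kb of transcript — above a cutoff recomputed as the mean over
  expressed genes, or pinned).
* **Panel enrichment** — fold enrichment $(k/n)/(K/N)$ of a curated
  disease-gene panel among candidates, with hypergeometric upper-tail
  p-values (both $P(X \ge k)$ and the strictly-exceeding tail that
  published tables of this analysis style print).
* **Genomic variability** — 1 Mb windowed z-scores of
  $\log_{10}$ population variant counts from a DGV-style catalog
  ($n-1$ SD; gap windows removed; zero-count windows dropped), region/gene
  scoring and genic-vs-exonic burden.
* **Phenotype mapping** — patient terms mapped to all top-level categories
  of an HPO-style ontology (OBO subset or edge TSV), plus a penetrance
  contrast against non-affected background carriers.
* **Synthetic data** — a generator that emulates every input with planted
  ground truth (recurrent loci, candidate genes, filter-boundary decoys,
  catalog hotspots), so the full pipeline is testable offline.

## Worked example

A synthetic cohort with a deletion locus planted at depth 8 (eight carriers
with jittered breakpoints) over a uniform CNV background:

```r
library(cnvrecur)

b <- generate_all(synthetic_spec(), "bundle/", seed = 42)
genome <- read_genome(b$paths$chrom_sizes, b$paths$exclusions, "synthetic")
cohort <- read_cnv_cohort(b$paths$cohort, genome)
del    <- cohort$cnvs[cohort$cnvs$cnv_type == "deletion", ]

summarize_overlaps(coverage_segments(del, genome))
#> 41 overlap regions (14 shared by >= 2 CNVs), mean overlap 2.220
#>  depth n_regions mean_length
#>      1        27    123052.7
#>      2         3    161624.3
#>  ...
#>      8         1    537366.0
```

The planted locus surfaces as the single depth-8 region (537 kb: the 480 kb
core plus carrier jitter). Is that much overlap expected by chance?

```r
randomization_test(del, genome, R = 1000, rng_seed = 1)
#> permutation test: R = 1000, mu_bar = 1.0174, sigma = 0.0222
#>   observed mean overlap 2.2195, z_real = 54.20,
#>   empirical p <= 0.001 (Shapiro-Wilk p = 8.26e-37)
```

No permutation approaches the observed mean overlap, so the empirical p is
the conservative 1/R bound. Prioritization then reduces 16 deleted genes to
one candidate — the planted gene — with the attrition of each filter logged:

```r
ann  <- read_annotation(b$paths$annotation)
expr <- compute_nrpk(read_expression(b$paths$expression))
prio <- prioritize(cohort$cnvs, ann, expr, "deletion")
head(prio[, c("gene", "n_patients", "min_region_gene_count", "max_nrpk", "candidate")], 4)
#>       gene n_patients min_region_gene_count  max_nrpk candidate
#> 1 CANDDEL1          8                     3 83.484583      TRUE
#> 2   LOW1_2          8                     3  1.391458     FALSE
#> 3   LOW1_3          8                     3  1.391458     FALSE
#> 4  RICH3_1          2                     7 83.484804     FALSE
attr(prio, "attrition")
#>         universe after_recurrence     after_region       candidates
#>               16               10                3                1
```

`LOW1_2/3` fail only expression, `RICH3_1` only the gene-count criterion —
the generator plants one decoy per filter boundary. Enrichment of the
bundled gene panel among candidates:

```r
pan <- read_gene_panel(b$paths$panel)
pi  <- panel_intersection(prio$gene[prio$candidate], pan, prio$gene)
fold_enrichment(pi$N, pi$K, pi$n, pi$k)
#> panel enrichment: 1/1 candidates vs 1/16 universe -> fold 16.00, P(X >= k) = 0.0625
```

`run_pipeline("bundle/pipeline.yaml")` runs all stages (including window
z-scores, gene burden, the phenotype matrix and penetrance) and writes the
report tables under the configured output directory. A thin CLI wrapper
with `synth`, `run` and `randomize` subcommands is installed at
`inst/scripts/cnvrecur`.

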