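# latcohort

Analysis toolkit for cohort studies of **laterality congenital heart disease
(CHD)** — heterotaxy, situs inversus and the transposition spectrum — in which
probands carry candidate variants in a left-right patterning gene. The package
implements, as tested reusable functions, the computational stages such a
study needs:

* **Ontology-based quantitative phenotypic similarity.** Probands annotated
  with phenotype-ontology terms are compared with a symmetric Lin score.
  Term information content is `IC(t) = -ln(n_t / N)` over the cohort's
  ancestor-closed annotation sets; term-term similarity is
  `Lin(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2))` (MICA = most-informative
  common ancestor); set-set similarity is the symmetric best-match average
  `sym(a, b) = ½ [ mean_{x∈a} max_{y∈b} Lin(x, y) + mean_{y∈b} max_{x∈a} Lin(x, y) ]`.
* **Cluster-number selection and clustering.** Distances `d = 1 - s`, a gap
  statistic curve for k = 1..15 (reference data sampled uniformly in the
  bounding box of a classical-MDS embedding), Ward ("ward.D2") hierarchical
  agglomerative clustering, cluster cuts, per-cluster phenotype frequencies,
  similarity heatmaps and Newick dendrogram export.
* **Rare-variant prioritisation and inheritance.** Population-frequency
  (max MAF < 0.01%) and CADD-phred (> 15) filtering over a gene panel with a
  rescue list and per-record decision logs; trio inheritance labelling
  (maternal / paternal / de novo / unknown); compound-heterozygote
  trans/cis phasing from allele-separating clone reads; cohort-yield tables
  by lesion category.
* **Case-control allele enrichment.** Allele-based 2×2 tables (het = 1,
  hom = 2 variant alleles), odds ratios with Wald 95% intervals
  (Haldane-Anscombe corrected when a cell is zero), exact two-sided Fisher
  tests, and expected-carrier calculations `2 n q`.
* **Structural-variant characterisation.** RPKM normalisation, a
  cohort-median-ratio read-depth deletion screen, deletion sizes from
  printed coordinates, exact breakpoint-junction resolution with
  microhomology / inserted-sequence detection, and classification of
  directly oriented Alu-Alu mediated rearrangements (AAMR).
* **Synthetic data.** Seeded generators for every input — phenotype cohorts
  drawn from lesion archetypes, case-control genotype cohorts with trios and
  clone sets, negative-binomial read-count matrices with embedded deletions,
  and junction sequences with engineered microhomology — each with a ground
  truth bundle, so the whole pipeline is testable without patient data.

All user-facing functions take data frames first and return tibbles, so
stages chain with the pipe; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

The packaged fixtures reproduce the headline numbers of a 321-proband
laterality cohort in which 33 probands carry candidate variants (four of
them biallelic).

```r
library(latcohort)

g <- mini_ontology()
fit <- phenocluster(proband_annotations(), g, exclude = exclusion_terms(),
                    k = 5, B = 100, seed = 1)
glance(fit)
#> # A tibble: 1 × 4
#>   n_probands     k mean_similarity gap_at_k
#>        <int> <int>           <dbl>    <dbl>
#> 1         33     5           0.608     1.32

cocluster_count(fit$assignment, biallelic_probands())
#> [1] 4
```

All four biallelic probands land in a single cluster: their shared
heterotaxy / right atrial isomerism / asplenia phenotype is the most
internally consistent block of the cohort.

```r
enrich(c(rep("het", 8), rep("hom", 2)), n_cases = 111,
       control_ac = 76, control_an = 34592)
#> OR = 26.0 (95% CI 13.9-48.4), Fisher p = 4.5e-13
```

Ten carriers (two homozygous) among 111 probands — 12 of 222 alleles —
against a population frequency of 76/34,592 give a 26-fold allele-level
enrichment, while chance alone would supply under half a variant allele:

```r
expected_variant_alleles(76 / 34592, 111)
#> [1] 0.4877428
```

Per-lesion diagnostic yield:

```r
cohort_yield_table(cohort_lesion_rows(laterality_cohort()))
#> # A tibble: 11 × 5
#>    lesion                          total carriers percent proportion
#>    <chr>                           <int>    <int>   <dbl>      <dbl>
#>  1 (all)                             321       21     6.5     0.0654
#>  2 Any L-looping                      66        9    13.6     0.136
#>  3 CCTGA                              26        4    15.4     0.154
#>  ...
```

Carrier frequency is highest in congenitally corrected transposition
(15.4%) and L-looping lesions (13.6%), and zero in DORV with malposed
great arteries — the pattern expected if the gene acts through left-right
patterning.

## Notes

The per-proband annotation fixture is a synthetic reconstruction from
summary-level lesion and segmental-anatomy information; see the methods
vignette (`vignettes/laterality-phenotype-analysis.Rmd`) for the modelling
assumptions, parameter choices and known limitations.
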