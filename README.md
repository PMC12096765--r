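# prsdual

Polygenic risk scoring over dense and sparse genotype representations, with
a concordance-evaluation battery for comparing the two paths.

## The problem

A polygenic risk score (PRS) for an individual *i* is the weighted sum of
effect-allele dosages over the variants of a published score:

```
PRS_i = Σ_j  d_ij · w_j
```

where `w_j` is the per-allele weight of variant *j* (from a scoring file in
the PGS Catalog dialect) and `d_ij ∈ {0, 1, 2}` counts how many of sample
*i*'s two alleles at that site equal the score's *effect allele* — which may
be the genomic REF or an ALT allele, so each weight row must be matched
against the site's alleles before counting.

Biobank-scale cohorts increasingly distribute genotypes in a *sparse*,
reference-block representation: only non-reference calls are stored, and
homozygous-reference stretches are encoded as per-sample interval blocks.
Scoring such a store requires interval queries at the score's loci and a
policy for calls absent from the store — conventionally, *assume homozygous
reference*. That assumption is cheap but not free: it silently converts
genuinely missing calls into hom-ref dosages, which can shift scores
relative to a dense pipeline that excludes missing calls. `prsdual`
implements both paths over the same scoring engine so the discrepancy can
be measured rather than guessed:

* **dense path** — explicit sample × variant genotype matrix read from VCF;
  missing calls are excluded by default;
* **sparse path** — variant entries + reference blocks, densified at the
  weight-table loci by interval query; absent calls imputed hom-ref by
  default, optionally pre-filtered to QC-passed variants via an annotation
  table.

Agreement between two score vectors is quantified the way method-comparison
studies do: Lin's concordance correlation coefficient
`ρ_c = 2ρσₓσᵧ / (σₓ² + σᵧ² + (μₓ − μᵧ)²)`, the rank-based (Mann–Whitney)
AUC against a binary outcome, the per-SD odds ratio from a univariate
logistic fit with Wald 95% CI, and the supremum distance between empirical
CDFs. A seeded cohort simulator with known allele frequencies, weights,
missingness and disease model makes every stage testable without any
controlled-access data.

## Worked example

```r
library(prsdual)

# a 200-sample, 300-variant cohort with 5% missing calls and a real
# per-SD effect (OR 1.8, prevalence 10%)
sim <- simulate_cohort(cohort_sim_config(
  n_samples = 200, n_variants = 300, missing_rate = 0.05,
  effect_orientation = "random", seed = 11))

dense_scores  <- score_dense(sim$dense, sim$weights)            # policy: exclude
sparse_scores <- score_sparse(sparsify(sim$dense), sim$weights) # policy: hom_ref

compare_score_sets(dense_scores, sparse_scores, sim$phenotype)
```

```
<score_comparison> 200 joined samples
  CCC 0.852730 | ECDF sup-distance 0.070000
  -- score set A --
<association_report> 18 cases / 182 controls
  OR  1.5981 [0.9581, 2.6656] (per SD of score, Wald 95% CI)
  AUC 0.6316
  -- score set B --
<association_report> 18 cases / 182 controls
  OR  2.0106 [1.1721, 3.4491] (per SD of score, Wald 95% CI)
  AUC 0.7048
```

The CCC below 1 is exactly the footprint of the hom-ref assumption on the
5% missing calls: both paths see the same genotypes everywhere else, and
with `missing_rate = 0` the comparison prints `CCC 1.000000`, distance
`0.000000`, identical association reports. The per-sample difference
between the two paths equals, sample by sample, the enumerable sum of
`hom-ref dosage × weight` over that sample's missing weight variants.

The same workflows are available from a shell via the thin wrapper in
`inst/cli/`:

```sh
prsdual simulate --out-dir cohort/ --n-samples 200 --n-variants 300 --seed 11
prsdual score-dense  --vcf cohort/cohort.vcf --weights cohort/weights.txt --out dense.tsv
prsdual score-sparse --sparse cohort/cohort.sparse.tsv --weights cohort/weights.txt \
                     --annotation cohort/annotation.tsv --out sparse.tsv
prsdual compare --a dense.tsv --b sparse.tsv --phenotype cohort/phenotype.tsv \
                --out report --plot
```

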