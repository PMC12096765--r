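---
title: "Dual-path polygenic risk scoring: model, policies, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-path polygenic risk scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsdual)
```

## The scoring model

A polygenic risk score is additive over independent scoring variants: for
sample $i$, $\mathrm{PRS}_i = \sum_j d_{ij} w_j$, where $w_j$ is the
published per-effect-allele weight (dimensionless score units, typically of
magnitude $10^{-3}$–$10^{-1}$) and $d_{ij} \in \{0,1,2\}$ is the diploid
count of the effect allele. Three matching outcomes are possible for a
weight row at a genotyped site:

* the effect allele equals the site's REF (`REF_EFFECT`, dosage counts
  reference alleles),
* it equals the $k$-th ALT (`ALT_EFFECT`, dosage counts that alternate
  allele),
* it matches nothing, or the weight row's *other* allele matches neither
  REF nor any ALT (`UNMATCHED`). Unmatched rows are skipped and tallied,
  never an error: published scoring files routinely contain a handful of
  rows that do not correspond to the cohort's site representation.

Multiallelic sites are kept as single records with ordered ALTs and the
dosage counts one specific allele index; no re-normalization or splitting
is attempted, which avoids the ambiguity of re-keying weights against split
records.

## Two genotype representations, one engine

The **dense** store is a samples × variants matrix of explicit unphased
calls, each a pair of allele indices (`NA` = missing), ingested from VCF.
The **sparse** store keeps, per sample, only non-reference calls plus
half-open homozygous-reference blocks `[start, end)`; positions covered by
neither are *missing in storage*. Densification at a locus applies the
precedence *entry > covering block (hom-ref) > missing*, and batch queries
are defined to agree exactly with locus-by-locus queries.

Both paths feed the same scoring core; the only behavioural difference is
the missing-call policy:

* `exclude` (dense default): a missing call contributes nothing and is not
  counted in that sample's `n_variants_found`, so found-counts vary by
  sample;
* `hom_ref` (sparse default): a missing call is treated as `(0,0)` —
  dosage 2 for a REF-effect variant, 0 for an ALT-effect one — and
  found-counts are constant across samples.

These defaults mirror how the two representations are scored in practice:
explicit matrices make missingness visible and excludable, while sparse
reference-block stores are scored under the hom-ref assumption. Both are
flags, so either policy can be forced on either path. The package treats
the hom-ref interpretation as a *scoring-time policy*, not a storage
property: converting dense → sparse preserves the distinction between
observed hom-ref (block) and no-data (uncovered), so no information is
destroyed before the policy is applied. The per-sample difference between
`score_sparse(hom_ref)` and `score_dense(exclude)` on the same underlying
data is therefore exactly $\sum_{j \in \text{missing}} h_j w_j$ with
$h_j \in \{0, 2\}$ the hom-ref dosage — an enumerable quantity the test
suite and the acceptance script verify directly.

### Allele orientation at loci the sparse store has never seen

A site that is hom-ref (or missing) in *every* sample leaves no variant
entry, so its REF/ALT context is unrecoverable from the sparse store alone.
When scoring such a locus the engine orients from the weight row itself:
`other_allele` is taken as REF and the effect allele as ALT, so a
block-covered sample receives dosage 0 there. This is the convention
dosage-from-weights tools use when no site key is available, and it is
exact whenever the scoring file's effect allele is the non-reference allele
— the overwhelmingly common case. A weight row whose effect allele is the
genomic REF *and* whose locus carries no non-reference call anywhere in
the cohort would be under-counted by 2 per sample; at realistic frequencies
such loci are vanishingly rare (a locus must be non-segregating in the
entire cohort), and the limitation is confined to the sparse path.

## The statistics battery

Agreement between two score vectors uses Lin's concordance correlation
coefficient
$\rho_c = 2\rho\sigma_x\sigma_y / (\sigma_x^2 + \sigma_y^2 + (\mu_x-\mu_y)^2)$
with moments computed with denominator $n$ (Lin's original definition; the
$n$ vs $n-1$ choice is fixed and covered by a unit test because at small
$n$ it is visible). $\rho_c$ penalizes location and scale shifts on top of
scatter, so $|\rho_c| \le |\rho|$ always, with equality only under equal
means and variances. Distributional shift is summarized by the supremum
distance between the two empirical CDFs over the pooled sample points (the
two-sample Kolmogorov–Smirnov statistic, reported as a descriptive
distance, not a test).

Predictive performance against a binary outcome uses the rank-based
(Mann–Whitney) AUC with midranks for ties, and a univariate logistic fit.
The PRS is z-scored before fitting by default, so the odds ratio is per
standard deviation of score — the field's reporting convention, and the
scale on which simulation truth is defined here; a flag disables it for
scores already on a meaningful scale. The CI is Wald,
$\exp(\hat\beta \pm 1.96\,\mathrm{SE})$: profile-likelihood intervals buy
little at cohort sizes and cost a dependency on the fit path. Complete or
quasi-complete separation and non-convergence raise errors rather than
returning inflated estimates. No multiple-testing correction is applied:
each score is evaluated on its own.

## The synthetic cohort

`simulate_cohort()` draws independent Hardy–Weinberg variants: allele
frequency $p_j \sim U(\text{maf}_{lo}, \text{maf}_{hi})$ (defaults
0.01–0.49), genotypes $\mathrm{Bin}(2, p_j)$, weights
$N(0, \sigma_w^2)$ with $\sigma_w = 0.1$, per-call missingness at a
configurable rate, and outcome
$\mathrm{Bern}(\mathrm{logit}^{-1}(\alpha + \beta z_i))$ where $z_i$ is
the z-scored complete-data PRS, $\beta$ the per-SD log OR (default
$\log 1.8$) and $\alpha = \mathrm{logit}(\text{prevalence})$ (default
0.1). Effect alleles are assigned to ALT by default; the
`effect_orientation = "random"` flag flips half the rows to REF-effect to
exercise both matching branches and to make the exclude-vs-hom-ref
discrepancy non-trivial (ALT-effect rows contribute dosage 0 either way, so
an all-ALT score shows no discrepancy at all). One seed feeds six named
sub-streams (positions/frequencies, genotypes, weights, phenotype,
missingness, QC flags), so each component is independently reproducible.

What the simulator deliberately omits: linkage disequilibrium, population
structure, relatedness, realistic site-frequency spectra, genotyping error
correlated with frequency. None of these affect the correctness of scoring
arithmetic, interval queries, or the estimators under test, which is what
the synthetic cohorts exist to establish; passing tests therefore certify
the *engine*, not the epidemiological validity of any particular published
score on real data.

## Problem sizes and numerical tolerances

The heavier checks run at 500 samples × 2,000 variants (path equivalence
and policy discrepancy), 20,000 samples × 100 variants for odds-ratio
recovery, and 50 replicates of 20,000 × 50 for CI coverage — sizes chosen
so the full battery completes in well under a minute each on one core while
leaving binomial standard errors small enough for the stated tolerances.
Path equivalence on complete data is exact (the two paths execute the same
summation over identical term order), and is asserted at $10^{-9}$ with a
CCC of 1 to $10^{-12}$. The policy-discrepancy identity is asserted at
$10^{-10}$ absolute rather than literal equality: the sparse sum interleaves
extra hom-ref terms, and the floating-point accumulation bound
$n\,\varepsilon \max|s_k| \approx 2\times10^{-12}$ at 2,000 terms makes
bit-identity the wrong contract. Weight round-trips use `%.17g` so
read-after-write is bit-exact; exported score TSVs use fixed 6-decimal
formatting, so file-level conservation checks carry a rounding allowance of
$5\times10^{-7}$ per summand.

## Weight-file dialect decisions

Harmonized coordinates (`hm_chr`/`hm_pos`) win over author-reported ones
when both are present, since the harmonized columns are the ones on the
cohort's build; the build declared in metadata (preferring `#HmPOS_build=`)
is checked against the caller's expectation with a warning, not an error —
a mismatch is frequently intentional during exploration. Rows with
unparseable weights or positions are dropped and counted, and duplicates of
a `(chrom, pos, effect, other)` key keep the first occurrence with a
warning: deterministic and auditable, and the row-count identity
`surviving + dropped = raw` is asserted per file. Chromosome names are
normalized to the `chr`-prefixed convention. Annotation-table lookups try
both allele orientations (`other`→REF/`effect`→ALT and the swap) because
annotation resources do not guarantee which orientation a scoring file
used; rows lacking an `other_allele` cannot form a complete key and are
conservatively removed by the QC filter. Strand flipping, palindromic-SNP
resolution and cross-build liftover are out of scope and documented as
such.

## Known limitations

* No phased-genotype semantics, ploidy ≠ 2, genotype likelihoods or dosage
  probabilities — calls are hard diploid calls.
* The sparse-path orientation fallback described above.
* Reference-block `min_quality` is carried through the format but never
  consulted by scoring.
* The ECDF overlay plot is a diagnostic, not a test statistic.
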