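---
title: "Statistical methods of the lfqpipe label-free proteomics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods of the lfqpipe label-free proteomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqpipe)
```

## Scope and data model

`lfqpipe` implements the downstream data-handling stages of a label-free
shotgun-proteomics discovery experiment on tissue samples: it starts from
MaxQuant-style peptide and protein-group quantification tables (per-sample
intensities, per-sample MS/MS spectral counts, decoy and uniqueness
annotations) and a study design that classifies each LC-MS/MS run as a
technical-replicate control (`WTL-CTRL`, whole tissue lysate), a
biological-replicate control (`LCM-CTRL`, laser-capture-microdissected
material from one source), or an `EXPERIMENTAL` sample carrying a
biological group label (for instance ER+ / ER- breast tumors).

The central convention, applied at read time and never revisited, is that a
zero or blank intensity cell means *not observed*: the value becomes
missing, and all observed intensities are strictly positive. This matters
because shotgun proteomics missingness is heavily intensity-dependent --
low-abundance peptides drop below the detection limit -- so zeros are
censoring events, not measurements.

## Preprocessing

Peptide intensities are log2-transformed and then median-centered per
sample: the median of each sample's *observed* log2 values is subtracted,
so each sample's observed median becomes exactly 0. Median centering on the
log scale is robust to the heavy right tail of intensity distributions and
removes per-run loading and instrument-response differences. Centering is
idempotent and leaves missing cells untouched.

Peptides enter differential testing only if (a) they are unique to one
protein group, (b) they are not reversed-sequence (decoy) hits, and (c)
they are observed in at least `ceiling(min_obs_fraction * n)` of the
reference samples. The default fraction is 0.5, which for a 9-sample
experimental cohort gives the 5-of-9 rule; 0.3 is the documented
alternative for large cohorts (n > 60). The reference set for rule (c) is
the experimental cohort by default (controls do not count toward the
threshold), configurable through `filter_criteria()`. The threshold is
implemented as a ceiling of the fraction so that both the "50 %" reading
and the "at least 5 of 9" reading hold simultaneously.

The package applies transform, then centering, then filtering. The
ordering of centering versus filtering is not forced by the method --
median centering over a large peptide population is insensitive to
dropping a minority of rows -- and the two stages are exposed as separate
functions so either order can be composed.

## Protein quantification (LFQ rollup)

When a protein-level LFQ table is supplied (the normal case for MaxQuant
output) it is used as-is. For peptide-only input and for synthetic data
the package reconstructs protein abundances with a pairwise-ratio scheme,
`rollup_protein_table()`:

* For one protein, every pair of samples (a, b) gets an edge carrying the
  *median* log2 ratio of the peptides observed in both, provided at least
  `min_shared` peptides are shared (default 1; the small replicate sets
  this pipeline targets make a higher minimum needlessly destructive).
  Medians of ratios are robust to single aberrant peptides. Antisymmetry
  r[a,b] = -r[b,a] holds exactly because each unordered pair is evaluated
  once.
* Within each connected component of the resulting ratio graph, per-sample
  protein values minimize the sum of squared edge residuals
  (x_a - x_b - r[a,b])^2. This is a graph-Laplacian least-squares system
  solved with the mean-zero gauge; the free constant per component is then
  anchored so the mean of the solved values equals the mean of the
  observed per-sample median peptide log2 intensities, keeping the output
  on the absolute intensity scale. Samples with no quantifiable evidence
  stay missing; isolated samples are anchored at their own median.
* Only razor-or-unique peptides contribute. Shared peptides are assigned,
  razor-style, to the first protein group in their assignment list (the
  leading group in the MaxQuant dialect); protein-level spectral counts
  are the sums of member-peptide counts.

The scheme deliberately omits MaxQuant's delayed normalization (per-run
normalization factors are assumed already absorbed by upstream processing)
and its minimum-ratio-count default of 2.

## Differential expression: two complementary branches

### Branch 1 -- abundance differences

Proteins expressed in most samples of both groups but at different levels
are found by a peptide-level model followed by a protein-level
confirmation:

1. **Robust peptide-level ANOVA** (`fit_me_anova`). For one protein, the
   observed log2 cells of its top peptides are modeled as
   `intercept + group + peptide + error` and fitted by iteratively
   reweighted least squares with Huber weights (tuning constant 1.345, at
   most 50 iterations, coefficient tolerance 1e-8). The peptide fixed
   effect absorbs ionization-efficiency offsets; per-sample shifts are
   assumed removed by the upstream median centering; with one measurement
   per sample-peptide cell a sample-level random effect is not separable
   from the residual, so the model is a fixed-effects robust regression.
   The group effect is tested with a Wald t on `n_obs - rank` residual
   degrees of freedom. Peptides whose missingness pattern makes columns
   collinear are dropped by pivoted least squares; if the group contrast
   itself is inestimable (all observations in one group), the protein gets
   a missing p and is left for branch 2.
2. **Top-10 peptide selection.** At most 10 peptides per protein enter the
   fit, ranked by the median of their observed log2 intensities -- a
   robust operationalization of "most abundant" under missingness -- with
   lexicographic tie-breaking for determinism. Restricting to abundant
   peptides focuses the fit on well-measured ions; no additional
   abundance weights are applied beyond this cut.
3. **Benjamini-Hochberg adjustment** (`bh_adjust`): the classic step-up
   rule with missing p-values excluded from the family size. Proteins with
   adjusted p < 0.05 form the pre-selection.
4. **t-test refinement with permutation FDR.** Pre-selected proteins are
   re-tested on their protein-level log2 abundances with a two-sided
   Welch t (unequal variances -- the design is unbalanced and no variance
   homogeneity is assumed). The q value is a SAM-style permutation FDR:
   group labels are permuted, and for each protein
   `q = mean_perm #{|t_perm| >= |t|} / #{|t_obs| >= |t|}`, made monotone
   non-increasing in |t| by a running minimum and capped at 1. For a
   5-vs-4 design all `choose(9,5) - 1 = 125` non-identity label splits
   are enumerated, so the refinement is fully deterministic; larger
   designs fall back to `n_perm` sampled splits (default 250) under the
   run seed. The refined set requires t-test p < 0.05 and q <= 0.05.

Group effects and mean differences are always reported as *second group
minus first*, with the two experimental group labels taken in sorted
order, so that relabeling the groups exactly negates every signed
statistic.

### Branch 2 -- presence/absence differences

Proteins detected (mainly) in one group produce invalid abundance tests
-- there is nothing to compare -- yet are among the most interesting
markers. Branch 2 finds them from spectral counts:

1. **Fisher exact test** (`fisher_presence`). For each forward protein the
   2x2 table `[[SpC_A, SpC_B], [Tot_A - SpC_A, Tot_B - SpC_B]]` compares
   the protein's summed MS/MS counts per group against the remaining
   library totals. The two-sided p is computed by full hypergeometric
   enumeration over the fixed margins (summing all tables whose
   probability does not exceed the observed one, with the conventional
   1e-7 relative tolerance). An alternative table construction -- counting
   detected/undetected samples per group -- is available via
   `mode = "detection"`. Proteins with zero counts in both groups are
   flagged invalid with p = 1.
2. **Downshifted-normal imputation** (`impute_downshifted_normal`). To
   confirm hits at the abundance level despite one-group absence, missing
   log2 abundances are drawn per sample from
   `Normal(mean_s - 1.8 * sd_s, (0.3 * sd_s)^2)`, the standard model for
   values censored at the detection limit: imputed values sit in the lower
   tail of each sample's observed distribution. Width 0.3 and downshift
   1.8 are the established defaults of this imputation family; both are
   exposed in `imputation_spec()`. Draws are made in a fixed row-major
   order under a mandatory seed, so runs are exactly reproducible, and
   observed cells are never modified. The whole matrix is completed once;
   the subsequent permutation test permutes labels over the completed
   matrix rather than re-imputing per permutation (re-imputation would mix
   imputation variance into the permutation null and is far costlier).
3. **t-test + permutation FDR** on the imputed abundances of the
   Fisher-significant proteins, with the same machinery and cutoffs as
   branch 1. The consolidated set requires all three criteria.

`branch_overlap()` reports the intersection of the two branches'
significant sets and, per shared protein, whether the abundance direction
(sign of the Welch mean difference) agrees with the group carrying the
spectral-count excess.

## Hierarchical clustering

Differentially expressed proteins are clustered bidirectionally
(`cluster_bidirectional`): rows are median-centered per protein, then both
proteins and samples are clustered by complete linkage on Euclidean
distances. Two conventions make results well-defined on incomplete
matrices and exactly reproducible:

* **Missing-value rescaling.** The squared distance over jointly observed
  positions is scaled by `K / |O|` (full vector length over shared
  positions), so vectors with different missingness remain comparable; a
  pair with no shared positions is an error.
* **Deterministic tie-breaking.** Among equally distant cluster pairs the
  one with the smallest older node index (then smallest younger) merges
  first; the leaf ordering puts the subtree containing the lowest original
  index on the left. Any valid dendrogram would be equally defensible
  biologically; fixing one makes outputs byte-stable.

Clustering operates on log2 abundances (consistent with the centering
step). The 2-cut purity of the sample tree -- the average majority-group
fraction across the two clusters -- is reported as a separation score.
Output is written in Cluster 3.0 format (`.cdt`/`.gtr`/`.atr`), loadable
in TreeView, plus plain merge-list TSVs.

## Replicate QC battery

`qc_report()` computes, per sample class: identification counts (features
with observed intensity, total and unique-only) with mean, sd and CV%;
pairwise Pearson correlations of log2 abundances over pairwise-complete
positions (pairs with fewer than 3 shared observations are excluded with a
warning); reproducibility tiers -- a feature observed in fraction f of a
class's samples is *low* (f <= 1/3), *medium*, or *high* (f >= 2/3)
reproducibility, boundaries chosen so the integer bands <=33 % / 34-66 % /
>=67 % are reproduced exactly for the cohort sizes 12, 5 and 9; and
per-feature CV% on the *linear* (non-log) scale for features observed at
least twice in the class, the conventional scale for reporting replicate
CVs. Protein identification sets of the two control classes are compared
with a shared/exclusive overlap. "Identified in a sample" is
operationalized throughout as a non-missing intensity in that sample's
column -- the only reading computable from quantification tables alone.
Correlations default to log2 scale; the linear alternative can be had by
passing an uncentered linear matrix, since the functions are scale-agnostic.

## Synthetic data generator

Because the statistical pipeline is the product, the package ships a
generator (`generate_dataset`) whose output exercises every stage with
known truth. On the log2 scale a peptide intensity is

    baseline_p + offset_q + effect_p * 1[group 2] + shift_s + noise

with protein baselines Normal(25, 2) (typical Orbitrap log2 intensities
span roughly 20-30), peptide ionization offsets Normal(0, 1.5), per-sample
shifts Normal(0, 0.2), residual noise sd 0.4 (a realistic replicate CV of
~30 % on the linear scale), 1 + Poisson(6) peptides per protein, and DE
effects of magnitude 1 (2-fold) with random sign for a `frac_de` fraction
of proteins. Detection is missing-not-at-random: a cell is observed with
probability `plogis((log2 intensity - 21) / 1)`, monotone in intensity, so
low-abundance peptides are preferentially censored (~90 % overall
detection at the defaults). Observed cells receive spectral counts
`max(1, Poisson(2 * 2^((intensity - 25)/4)))`, coupling counts to
intensity. Decoy entries (1 %) and two-group shared peptides (5 %) are
appended so that the filtering rules have something to remove. The default
experimental design is two groups of 5 and 4; technical (WTL, half
residual noise) and biological (LCM) replicate controls of a single
source can be added for QC studies. The protein table is produced by the
package's own rollup.

The generator emulates the *statistical* structure the pipeline assumes --
log-additive effects, MNAR detection, intensity-coupled counts. It does
not emulate retention-time structure, interference/co-elution, shared-
peptide intensity mixing, or between-protein correlation; passing recovery
tests on synthetic data therefore validates the inferential machinery, not
instrument-level behavior on real spectra.

## Validation strategy and problem sizes

The test suite validates each exact component against an independent
oracle: the Fisher p against exhaustive hypergeometric enumeration over
all 2x2 tables with margins up to 30 (max |difference| < 1e-12); complete
linkage against a from-scratch merge oracle that recomputes all cluster
distances directly, on random and tie-heavy inputs up to n = 6; BH
adjustment against the reference step-up implementation on 1000 random
vectors; the non-robust ANOVA limit against the closed-form pooled t-test
and explicit normal equations; Welch tests against `stats::t.test`.
Error control and recovery are checked by simulation at the study scale:
20 seeds of 500 effect-free proteins must average at most 2 false
discoveries per branch; 20 seeds with 10 % true 2-fold effects must give
branch-1 power of at least 0.8 at empirical FDR at most 0.10; and an MNAR
scenario in which down-regulated proteins vanish from one group must show
branch 2 recovering at least 80 % of those proteins while branch 1, which
needs observations in both groups, recovers under 20 % -- the quantitative
statement of why the two branches are complementary. These problem sizes
keep the full suite to a few minutes while leaving binomial noise well
below the asserted margins.

## Known limitations

* The ANOVA branch handles exactly two experimental groups; multi-group
  contrasts are an extension point, not implemented.
* No empirical-Bayes variance moderation is applied; with 5-vs-4 samples
  the permutation FDR provides the resampling-based error control
  instead.
* The rollup's min-shared-peptides default of 1 favors coverage over
  conservatism; sparsely observed proteins can differ systematically from
  an upstream LFQ that requires two shared peptides.
* Imputation assumes left-censoring; values missing for other reasons
  (e.g. misidentification) are downshifted regardless.
* The Fisher table construction treats summed spectral counts as
  independent draws, ignoring within-peptide count correlation; the
  `detection` mode is the conservative alternative.
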