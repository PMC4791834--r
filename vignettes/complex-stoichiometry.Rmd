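---
title: "Detecting stoichiometric variation of protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stoichiometric variation of protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichiovar)
library(dplyr)
```

## The problem

Most members of a protein complex are co-regulated: when a cell needs more of
the complex, all subunits rise together. Compositional (stoichiometric)
variation is the interesting exception — a subunit whose abundance deviates
from its complex's common trend in some cell type or state, producing distinct
complex variants. Detecting it from shotgun proteomics data requires removing
the dominant whole-complex abundance signal first; otherwise a change in
complex abundance makes *every* member look differentially expressed.

`stoichiovar` implements that removal and the downstream analyses: variable
member/complex calling with a decoy null, paralog-switch detection,
transcriptional classification, co-expression summaries and compositional
signature classification. This vignette documents the model, the parameters
that matter, the numerical choices, and what the synthetic benchmark does and
does not demonstrate.

## Model and procedure

Input is a proteins × samples matrix of log2 abundances (or log2 ratios
between consecutive states, in which case "conditions" are transitions) with a
design table `(sample_id, condition, replicate)`, plus complex definitions.

**Preprocessing.** Sample profiles are median-centered. Proteins can be
filtered to those quantified in at least `min_reps` replicates of every
condition, and replicates whose nearest neighbour (highest Pearson
correlation over shared proteins) belongs to a different condition can be
flagged for inspection — flagged, not auto-excluded, because outlier exclusion
deserves human eyes.

**Complex resource.** Definitions from several sources are merged by ranking
(manually curated < COMPLEAT-style < CORUM-style < user), complexes with
fewer than `min_members = 5` members are dropped, and a single greedy pass
keeps each highest-ranked complex while removing every lower-ranked complex
that shares at least `overlap_threshold = 0.5` of **its own** members with a
kept complex. The denominator is deliberately the candidate's member count:
that removes near-subsets of a representative, the conservative reading of
"shares half its members". After (source, size) ranking, ties break
lexicographically on the complex id so the output ordering is deterministic.
Complexes are finally restricted to quantified proteins and must retain at
least five of them — below that, the "rest of the complex" reference in the
normalization is too noisy to be meaningful.

**Complex-wise normalization.** With per-condition means $\bar y_{pc}$, each
protein is first expressed relative to its trimmed mean across conditions
($\lfloor 0.2\,C\rfloor$ trimmed from each tail; the plain mean when nothing
is trimmed). Trimming is applied to condition means, not to individual
replicates, so unequal replicate counts cannot bias the reference, and an
effect confined to one or two conditions does not drag its own baseline.
Then, per complex and sample, the mean relative abundance of the *other*
present members is subtracted. For a complex of $n$ fully observed members
this equals $c_p = (n r_p - \sum_q r_q)/(n-1)$, so the corrected values of a
complex sum to zero in every sample and any constant added to all members of
a complex cancels exactly — the algebraic content of "removing overall
complex abundance". Members missing in a sample are excluded from that
sample's reference mean; a complex with fewer than two present members in a
sample yields missing output rather than a fake zero. Proteins in several
complexes get the average of their per-complex corrections.

**Testing and calling.** For each protein a one-way model on conditions is
fitted over its present samples; the contrast for condition $c$ is the
condition mean minus the *unweighted* mean of the other condition means
(robust to unequal replicate counts; testing against pooled remaining samples
would weight conditions by replicate number). Standard errors use the
residual variance pooled over all of the protein's samples, so a
single-replicate condition still receives a valid test. Variances are then
moderated with the usual hierarchical model: residual variances are assumed
scaled-inverse-chi-square around a prior $(d_0, s_0^2)$ estimated by
moment-matching of log variances (the digamma/trigamma equations, solved by
Newton inversion of the trigamma function). The posterior variance
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ gives a t statistic on
$d_0 + d$ degrees of freedom. Two degenerate regimes are handled explicitly:
$d_0 = 0$ reproduces the ordinary t exactly, and near-identical variances
drive $d_0 \to \infty$ (pooled-variance t). Proteins with zero residual
degrees of freedom are excluded from the hyperparameter fit but still
moderated, receiving the prior variance. With fewer than 10 usable proteins
the moderation falls back to ordinary t.

p-values are BH-adjusted **within each condition** (not globally — each
condition is its own family of member tests). A member is *variable* when its
adjusted p falls below `member_alpha = 0.05` in at least one condition; a
complex is *variable* when at least `complex_threshold = 0.20` of its
quantified members are variable, with the boundary included and the
denominator being the quantified (restricted) membership, not the annotated
size.

**Decoy benchmark.** Decoy resources reassign proteins to complexes at random
while preserving the pool of member occurrences and every complex size
(within-complex duplicates are repaired by random position swaps, which keeps
the multiset exact and terminates for every feasible input). Run over nested,
increasing condition subsets, real complexes should show saturating variable
counts while decoys track the null: in a decoy, the shared abundance term of
a real complex no longer cancels, so power against genuinely planted (or
real) member deviations collapses into the noise floor.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `overlap_threshold` | 0.5 | fraction of candidate's members | half-overlap merging rule |
| `min_members` | 5 | proteins | below this the "rest of complex" reference is unstable |
| `trim_fraction` | 0.2 | fraction per tail of condition means | robust location; degrades to plain mean for few conditions |
| `member_alpha` | 0.05 | adjusted p | conventional per-condition FDR level |
| `complex_threshold` | 0.20 | fraction of quantified members | guards against single-member noise promoting a complex |
| `fc_floor` | 0.5 | log2 | minimum mRNA change for a transcriptional call |
| `mirna_alpha` | 0.01 | adjusted p | stricter level for miRNA regulation evidence |

## Paralogs, transcripts, signatures

A paralog pair is *co-regulated* at a condition when both members are
significant there; it is a *switch* when their fold changes have opposite
signs (a zero fold change never supports a switch claim). Each co-significant
condition is classified independently, and the per-pair roll-up labels a pair
a switch if any condition is — matching how one would count distinct switch
events. Pair tables are an input; inferring paralogy is out of scope.

For transcriptional classification, one probe set per gene is kept (highest
variance, ties lexicographic), and each variable (protein, condition) call is
classed `transcriptional_true` (same-sign mRNA change, $|log_2 fc| >$ floor,
adjusted p < 0.05), `transcriptional_trend` (same but non-significant), or
`not_transcriptional`. Calls without a gene mapping or without mRNA data at
that condition are `unclassifiable` rather than forced into a class — a
missing measurement is not evidence of absence of transcriptional regulation.
A call is miRNA-linked when a significantly regulated miRNA targeting the
gene moves opposite to the mRNA at the same condition.

For cohort classification, proteins need ≥ 2 unique peptides and presence in
≥ 4 samples of each group, then log2 and quantile normalization. A sample is
assigned by the nearer group centroid (Euclidean distance over the chosen
features) under leave-one-out; distance ties count as errors, the
conservative choice. `feature_sampling_eval()` draws 100 feature sets per
size (4–28 in steps of 4) from the signature pool and from all quantified
proteins — signature members included in the random pool, since the
comparison is against "any features", with a flag to exclude them — and
compares the two accuracy distributions per size with a Wilcoxon rank-sum
test. Accuracy is averaged per feature set (not pooled over predictions),
and the reported uncertainty is the standard error over the 100 sets.

Rank-sum tests enumerate the exact null distribution (midranks, so ties are
handled exactly) whenever the two groups total at most 12 observations, and
use the tie-corrected normal approximation with continuity correction above
that. Fisher overlap tests report the exact two-sided hypergeometric p, the
*sample* odds ratio, and the Jaccard overlap.

## The synthetic generator

`generate_resource()` draws complex sizes uniformly (default 5–30) and
assigns a fraction of proteins (default 0.1) to two complexes.
`generate_proteome()` builds each log2 entry as
baseline + shared per-(complex, sample) term + planted member effect + noise.
Defaults encode the study conditions the package is benchmarked under:
22 % of members variable, effect size 1 (log2), noise SD 0.25, three
replicates. The shared-term SD defaults to 1.0 — comfortably above the noise
so that within-complex correlation is strong, as observed for real complex
members, and so that the decoy benchmark is informative: decoys inherit this
un-cancelled variance and lose power, which is exactly the contrast the
benchmark measures. Effects are planted on individual members, never on whole
complexes, so complex-wise normalization must *recover* them; that is the
core recovery contract the tests check. Paralog generation places pairs in a
shared complex with opposite-sign (switch fraction, default 0.7) or same-sign
effects at a shared condition, plus an equal number of no-effect null pairs
for false-call estimation. Transcript/miRNA tables are noiseless-threshold
inputs (values clearly on the intended side of every threshold; planted
fractions 0.38 transcriptional, 0.06 trend, 0.45 miRNA-linked, echoing the
proportions reported for reprogramming time courses), so classification
recovery is exact by construction and tests the plumbing, not the thresholds.
The cohort generator plants 53 signature proteins at a log2 shift of 1.5 ×
noise SD between 7 and 14 samples.

What the generator does **not** emulate: intensity-dependent missingness
(missingness is completely at random, default rate 0), peptide-level
variation and shared peptides, correlated noise between conditions, batch
effects, and heavy-tailed abundance errors. Passing recovery tests therefore
demonstrates correctness of the computations under the stated model, not
robustness to every real-data pathology.

## Numerical choices and degenerate inputs

* Trigamma inversion by Newton iteration from the asymptotic start
  $y_0 = 0.5 + 1/x$; non-positive moment estimates map to $d_0 = \infty$.
* Quantile normalization preserves the missingness pattern; present values
  are ranked among present values and interpolated at proportional rank.
* `filter_redundant` and the decoy generator are deterministic given their
  inputs (and seed); all generators restore the caller's RNG state.
* Outlier-replicate flags break correlation ties in favour of the
  same-condition neighbour, so degenerate identical-profile designs produce
  no flags; single-replicate conditions are never flagged.
* Empty resources after size filtering are returned empty, not as errors;
  an empty paralog set is an error (the enrichment table is undefined).

## Problem sizes used by the test-suite benchmarks

The packaged benchmarks run at 100 complexes (sizes 5–30, ~1500 members)
× 16 conditions × 3 replicates for calling calibration (25 null + 25 planted
simulations) and for the decoy benchmark (20 decoy seeds over condition
subsets of 4, 8, 12, 16); 25 seeds of a 20-complex design for paralog
recovery; a 2000-protein, 7 + 14-sample cohort with 100 feature sets per
size for the signature analysis. These sizes give stable estimates of the
recovery rates while keeping a full run of the suite in the minutes range on
a laptop.

## Known limitations

* The contrast "condition vs mean of other conditions" spreads a strong
  single-condition effect slightly into the other contrasts of the same
  protein (by $-e/(C-1)$), and a planted member shifts its co-members'
  corrected values by $-e/(n-1)$; with many conditions and typical complex
  sizes both leakages stay well below detection thresholds, but they are
  visible in very small designs.
* Per-condition BH control means the member-level "variable in ≥ 1
  condition" rate grows with the number of conditions; the decoy benchmark
  is the intended guard against over-reading that union.
* Complexes are treated as flat member sets; sub-complex structure and
  mutually exclusive modules are only visible indirectly (e.g. as paralog
  switches).
* With only two conditions the trimmed mean degenerates to the plain mean
  and relative abundances of a two-condition design are anti-symmetric by
  construction; interpretation there should lean on the fold changes, not on
  the stable/variable dichotomy.
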