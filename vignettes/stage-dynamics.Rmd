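---
title: "Stage-wise neurogenomic dynamics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise neurogenomic dynamics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stagedyn` analyzes brain gene expression measured over an ordered series of
behavioural stages — the motivating system is paternal care in stickleback
fish, where males pass through nesting, egg care and three phases of hatching,
each sampled against a reproductively mature control group matched for
circadian time. Three biological hypotheses structure the analysis: each
stage may recruit its own transcriptional program (*unique* genes), a
program may persist for a while after its triggering stage (*carryover*),
or programs may accumulate so that each stage's genes are added to the
previously acquired state and retained to the end (*additivity*). The
package turns each hypothesis into an explicit, testable set definition over
per-stage differential expression tables, and adds two companion analyses:
a cross-species comparison at the orthogroup level and a transcriptional
regulatory network (TRN) built from mutual information and prediction error.

This vignette records the statistical models, the tunable parameters and the
design decisions behind each component, including the choices made where the
design was genuinely open.

## Differential expression per stage

Counts are filtered by detectability (at least 0.5 counts per million in at
least five samples, both bounds inclusive) and normalized by trimmed mean of
M-values (TMM; delegated to edgeR's implementation, with the default 30%/5%
trims on M and A values). Each experimental stage is contrasted against the
control group sharing its circadian batch; with the five-stage design the
first three stages share one control group sampled at the same clock time.
Regions are analyzed fully independently.

The test is a per-gene negative-binomial likelihood-ratio test. For a gene
with counts $y_{ij}$ and effective library sizes $N_j$ (library size times
TMM factor), each group has mean $\mu_{ij} = m_g N_j$ on the cpm scale, with
variance $\mu + \phi\mu^2$. Group means are fitted by Newton iteration on
the log scale, and the equal-means null is tested against $\chi^2_1$.
Dispersion $\phi$ is estimated per gene by maximizing a Cox–Reid adjusted
profile likelihood on a 16-point log-spaced grid (plug-in group means,
quadratic interpolation around the grid argmax), and is shrunk toward the
local trend by adding `prior_df / residual df` (default 10/8) times the
neighbor-averaged likelihood over genes ordered by average log-cpm — a
weighted-likelihood empirical-Bayes scheme in the spirit of the tagwise
dispersion estimators used by count-based DE packages, but self-contained.
This deliberately does not reproduce any specific package's dispersion
machinery; downstream analyses depend only on the per-contrast table of
(log2 fold change, p, empirical FDR).

Reported fold changes moderate each group mean with a 0.5-cpm prior so
empty groups stay finite; all-zero genes get p = 1 and fold change 0.

## Empirical FDR by label permutation

P-values are converted to an empirical FDR using a pooled permutation null:
group labels are permuted within the contrast's sample block (circadian
pairing is preserved by construction, since a contrast lives inside one
batch), the full test — *including dispersion re-estimation* — is re-run,
and for each observed threshold $t$

$$\widehat{FDR}(t) = \frac{\text{mean}_b\,\#\{p^{null}_b \le t\}}{\max(1, \#\{p^{obs} \le t\})},$$

clipped to $[0,1]$ and made monotone by step-up over the observed p-value
ordering (ties broken by p, then |log2 FC| descending, then gene id).
Re-estimating dispersion inside each permutation matters: holding
dispersions fixed lets genes with genuine effects flood the pooled null
with small p-values (a permuted split still separates their means), which
destroys power; re-estimation absorbs the effect into the permuted
dispersion, as a full re-analysis would.

When the group sizes admit fewer distinct label assignments than `n_perm`
(the default 500), all distinct splits are enumerated, *excluding* the
observed assignment and its label-swapped mirror, and the effective count is
recorded (n = 5 vs 5 gives 250 informative splits). The exclusion is
deliberate: with the observed labeling inside the null, every gene's own
p-value is part of its null tail, the estimator acquires a floor of about
1/126, and a perfectly separated gene can never reach an FDR below it. With
the exclusion, a gene whose observed p is never matched by any permutation
attains an empirical FDR of exactly 0.

## Set algebra over the stage series

*Unique genes.* A gene is unique to a focal stage if its empirical FDR is
below 0.01 there while staying **at or above** a relaxed threshold at every
other stage. The relaxation guards against false negatives — a gene that
barely misses significance elsewhere is not credibly unique. The schedule
{0.05, 0.10, 0.20} is swept and retained in the result; the terminal (most
relaxed, hence strictest for exclusion) value 0.20 defines the reported
sets. The schedule itself is a package choice: only the principle of
relaxation, not its exact values, is fixed by the analysis design.

*Pairwise overlap.* Stage-pair DEG overlaps are tested by the upper-tail
hypergeometric distribution over the region's post-filter universe,
BH-adjusted across the 10 pairs.

*Added shared genes.* For each focal stage, members must be (1) significant
at the focal stage, (2) not significant at any preceding stage, (3)
significant at one or more later stages — not necessarily the immediate
successor — where only stage pairs passing the overlap pre-screen
(hypergeometric FDR < 0.05) may contribute, and (4) not already claimed by
an earlier focal stage's set. The final stage yields an empty set by
definition. Direction vectors record the fold-change sign at the focal
stage and at every later significant stage, regardless of the pre-screen,
since direction is a property of the gene, not of the pair test.

*Concordance.* A member significant in $k$ stages is concordant when all
$k$ signs agree; under an independent equiprobable-signs null each direction
has probability $(1/2)^k$ per gene. Observed counts of
(concordant-up, concordant-down, discordant) are compared with their summed
expectations by a chi-square over the three categories, df = 2. The null's
independence assumption is a modelling choice — it reproduces the
three-category test structure and makes the expectation analytic. Both
per-focal-set and pooled statistics are reported, since a single pooled
statistic and per-set statistics answer slightly different questions and
the choice between them is otherwise arbitrary.

*Directional persistence.* Whether an added-shared set remains up- (or
down-) regulated in a later contrast is tested by a self-contained sign-flip
set test: the observed mean signed z of the set is compared with a null
formed by random sign assignment of the members' z magnitudes, one-sided in
the stated direction, with $p \ge 1/(n_{rot}+1)$. This replaces rotation
set testing with a simpler exchangeability argument on the signed
group-mean differences; it tests the same Up/Down hypotheses without
importing another package's internals.

## Cross-species orthogroup overlap

Gene-level overlap tests are inappropriate across species because
orthogroups carry several genes per species, only some differentially
expressed. The package therefore compares gene sets at the orthogroup
level: the observed statistic $t^\*$ counts orthogroups hit by both
species' sets, and the null redraws both sets ($n_1$, $n_2$ genes, **with
replacement**, duplicates counting once) from each species' universe $M$
times, giving

$$\hat p = \frac{1 + \sum_{i=1}^{M} I(t_i \ge t^\*)}{1 + M}.$$

Sampling with replacement follows the stated procedure even though real
gene sets are without-replacement draws; a without-replacement mode is
available behind a flag for sensitivity analysis. The default universe is
the map-covered gene set of each species (the universe definition is
surfaced as an argument because it is genuinely underdetermined — whole
genome and measured transcriptome are both defensible). $p$ is bounded
below by $1/(1+M)$ and equals 1 exactly when $t^\* = 0$.

## TRN inference

Expression profiles are standardized log2-cpm (mean 0, s.d. 1 per gene).
Candidate regulators of a target are transcription factors sharing
significant mutual information with it: MI is the plug-in estimator on
equal-frequency (rank) bins — hence invariant to monotone transforms — with
$B = \lceil\sqrt{n/5}\rceil$ bins by default, and significance uses the
G-statistic identity $2 n \cdot MI \sim \chi^2_{(B-1)^2}$ with the Williams
correction $q = 1 + (B+1)^2/(6n)$ for equal margins. The extreme threshold
$P < 10^{-6}$ is evaluated analytically because $10^6$ permutations per
pair is impractical; the analytic null is cross-checked against permutation
at attainable significance levels in the test suite, and the Williams
correction is what brings the permutation and analytic nulls into
agreement at the sample sizes used here.

Each target's sparse linear model is built by forward selection over its
MI-significant TFs with a BIC stop (at most 5 regulators), on the
standardized scale; edges are kept only if the final model's RMSD is below
0.33, i.e. the prediction error is under one-third of the target's standard
deviation. The original algorithm this emulates used least-angle
regression; forward selection with an information-criterion stop is an
approximation chosen for transparency, since only the MI and RMSD criteria
are fixed by the analysis design.

TF enrichment in an experiment's pooled DEG set is the upper-tail
hypergeometric test, Bonferroni-corrected across TFs. A TF is "regulated in
opposite directions" between two experiments only when it is significantly
up in some condition of one and significantly down in some condition of the
other — opposite signs without significance on both sides do not count.

## The synthetic-data generator

`simulate_counts()` emulates the study design: five ordered stages (nest,
eggs, early/mid/late hatching), circadian batches (first three stages share
the 9 a.m. control group), n = 5 per group, two brain regions analyzed
independently. Counts are negative binomial with variance $\mu + \phi\mu^2$,
$\phi = 0.1$ by default, and log-normal baseline means (median 50 counts,
log-sd 1.2) — conventional values for bulk brain RNA-seq at this depth; the
source study does not publish effect-size or dispersion distributions, so
these are explicit package defaults rather than estimates. The planted
effect is $|\log_2 FC| = 2$ with random sign, applied to the experimental
group of the gene's active stages only: unique genes are active in exactly
one stage, carryover genes from a random onset through a contiguous later
(non-final) stage, additive genes from their onset through the final stage.
Planting is restricted to genes with baseline mean at least 20 counts so
that the planted truth is identifiable at the design's sample sizes —
effects planted on barely detected genes would measure the count depth, not
the pipeline.

TF structure is planted on the standardized log-cpm scale (where the TRN
operates): a target's profile is its TF's profile times a random sign plus
Gaussian noise of s.d. `edge_noise_sd`, renormalized to unit variance, and
target counts are regenerated from the rewritten profiles. With noise 0 a
target is an exact linear function of its TF. The orthogroup generator
emulates the density of the real two-species map (3790 orthogroups covering
roughly 4.8k genes per species, member counts skewed toward one-to-one)
embedded in transcriptome-scale universes of 18,000 genes per species —
map coverage of only part of the transcriptome is what keeps a set of a
few hundred genes within a few dozen orthogroups, and hence keeps the
chance orthogroup overlap small. It plants 14 signal orthogroups
guaranteed to be hit by both species' gene sets of sizes 356 and 838 — the
reported sizes for the diencephalon/hypothalamus comparison — yielding an
observed overlap around 20 against a null mean near 5.

One master seed drives everything; regions and generators use
deterministically derived substreams, so equal seeds give bit-identical
outputs. What the generator does **not** emulate: circadian rhythmicity
beyond batch structure, correlated co-expression modules beyond the planted
TF edges, outlier samples, GC/length biases, and compositional distortions
larger than what TMM removes. Passing the recovery tests therefore shows
the estimators are correct and well calibrated under the stated model, not
that real data meet that model.

## Numerical choices and degenerate inputs

- Newton fits for NB means run on the log scale with steps clamped to ±5;
  all-zero genes short-circuit to mean 0, p = 1, fold change 0.
- The dispersion grid spans $[10^{-4}, 10]$ with quadratic interpolation in
  log-dispersion around the grid maximum.
- Ranking ties in the FDR step-up break by (p, |lfc| descending, gene id),
  making outputs order-independent and reproducible.
- Equal-frequency binning uses first-occurrence rank ties, so MI is
  deterministic on tied data.
- Monte Carlo overlap iterations are processed in blocks whose size adapts
  to the orthogroup count, bounding memory at a few million incidence cells.
- Empty added-shared sets (e.g. the final stage) propagate as empty data
  frames; concordance on an empty collection raises an error rather than
  returning NaN.

## Problem sizes used in the checks

The packaged tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes while keeping every Monte Carlo
comparison statistically meaningful: 2,000 genes for planted-recovery runs
(10,000 for the null-calibration run), the full 250-split enumeration per
contrast for empirical FDR, M = 2000 with 500 repetitions for the
uniformity check of the overlap test (on a 4,000-orthogroup map, sized so
the discreteness of the overlap statistic stays well below the tested KS
distance), and M = 100,000 for the single paper-scale overlap test. The
brute-force oracles (exhaustive hypergeometric enumeration up to universe
12, rule evaluation on 1,000 random significance grids) are exact.

## Known limitations

- The NB test's dispersion shrinkage and the LRT reference are asymptotic;
  at n = 5 vs 5 the raw p-values are near-uniform but not exact, which is
  precisely why the empirical permutation FDR, not the raw p, drives all
  downstream set definitions.
- The pooled permutation FDR estimates a tail-area FDR; it is not a
  per-gene local FDR, and with heavy contamination (many strong effects)
  it is conservative.
- The concordance null assumes independent signs across stages; positively
  autocorrelated expression would make the null conservative in the other
  direction.
- The analytic MI null is a corrected large-sample approximation; at the
  extreme threshold ($10^{-6}$) its accuracy is extrapolated from agreement
  at attainable levels.
- Accession-scale results from the motivating study depend on its exact DE
  machinery and full data; this package's substitutes reproduce the logic
  and calibration, not byte-identical gene lists.
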