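---
title: "Modelling cis-regulation of expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cis-regulation of expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisreg)
```

## The problem

A gene's expression level in a cell line panel is often partly
determined by nearby DNA variants (cis-regulation). Given (i) a dense
panel of variants around the gene, coded additively (0/1/2 copies of
the alternate allele), and (ii) expression measurements from one or
more microarray studies, each with its own probes and noise, we want
to answer three linked questions:

1. Which probes measure the same underlying transcript signal, and how
   should several probes (or several studies) be summarized into one
   representative signal?
2. Which small set of variants best explains that signal, and do the
   best models found in different studies agree once formally compared?
3. How do predefined haplotypes of the region relate to expression,
   and how strongly do the selected models correlate with those
   haplotypes?

`cisreg` implements this workflow end to end, together with a
synthetic-data generator that produces genotypes and expression with
known ground truth so every stage can be tested without external data.

## Expression preprocessing and representative signals

Each probe is standardized to mean 0 and sample standard deviation 1
(z-scores). Standardization removes platform scale differences and is a
prerequisite for comparing or averaging probes across studies; all
downstream effect sizes are therefore on the standardized expression
scale. Probes annotated as targeting introns are removed first:
intronic signal tracks unspliced RNA rather than mature transcript
abundance.

Probe coherence is measured by the matrix of squared Pearson
correlations (r²). A representative probe group is found greedily: seed
with the most correlated pair, then repeatedly add the probe with the
highest mean r² against the current group. A candidate enters only if
(a) its own mean r² with the current members reaches `min_mean_r2`
(default 0.5) and (b) the group's mean pairwise r² stays at or above
the same threshold. Condition (a) matters: a tight group of eight
probes with pairwise r² near 0.8 could otherwise absorb one or two
unrelated probes while its *group mean* drifted down to the threshold;
requiring cohesion of the entering probe keeps outlier probes
(alternative first exons, rare splice variants) out. The threshold
default of 0.5 is deliberately below the cross-study correlations
(r² ≥ 0.56) that motivate treating signals as "the same", and is
configurable. Ties are broken by lexicographic probe id, which makes
the selection invariant to probe order.

The representative signal is the arithmetic mean of the standardized
members (a composite), re-standardized. For a study without an internal
group, the pipeline supports two declared alternatives: pick the probe
most correlated with a reference study's composite (requires shared
samples), or pick a named probe (when the choice is made on annotation
grounds, e.g. a probe shared between platforms). Classical (Torgerson)
MDS on the distance d = sqrt(1 − r²) provides display coordinates;
this is a display approximation (a nonparametric MDS would preserve
only rank order) and nothing downstream consumes the coordinates.

## Genotypes, LD and pruning

Genotypes are additive dosages in {0, 1, 2}. LD between two variants is
the squared Pearson correlation of their dosage vectors (genotypic r²,
computed on samples non-missing at both variants). This dialect needs
no phasing and directly measures the collinearity that harms a
regression design, which is the reason for pruning in the first place.

Pruning scans pairs in genomic position order: while any retained pair
has r² at or above the threshold (default 0.90), the member with the
lower minor allele frequency is removed (ties keep the smaller
position), and the removal is logged as (removed, kept proxy, r²).
Declared functional variants are never removed — their high-LD partners
are removed instead — because later stages must be able to fit models
restricted to exactly those variants. The keep-rule is a declared
convention: the data do not determine which member of a near-duplicate
pair is "the" variant, so the rule simply has to be deterministic and
reportable.

## The regression engine

All models are ordinary least squares with an intercept, solved by QR
decomposition (the normal equations are never formed explicitly; exact
collinearity is detected from the QR rank and reported with the names
of the dependent columns). Each fit records per-term two-sided t tests,
the model F test against the intercept-only model, adjusted
r² = 1 − (1 − r²)(n − 1)/(n − p − 1), the residual sum of squares, and
the Gaussian profile log-likelihood (with sigma-hat² = RSS/n). Missing
data are handled per fit by complete-case analysis, and the sample set
is stored in the fit so model comparisons can insist on identical
samples.

Nested models are compared by the likelihood-ratio test: the statistic
2(ll_large − ll_small) = n·log(RSS_small/RSS_large) referred to a
chi-square with one degree of freedom per added variant. A chi-square
reference is the default; an F-change calibration is available behind
a flag (at the sample sizes involved the two agree closely; the
chi-square form is the conventional reading of "likelihood ratio test"
for linear models without a stated small-sample correction).

Non-nested models A and B over the same response are compared by the
Davidson-MacKinnon J-test: fit B, add its fitted values as a proxy
regressor to A's design, and t-test the proxy coefficient; then
symmetrically for the other direction. A significant proxy in direction
A means A fails to capture signal that B carries. The two directions
answer different questions, are both reported, and are never combined.
If the rival's fitted values are linearly dependent on the base design
(the models span the same space), the comparison is degenerate and is
reported as such rather than forced.

No multiple-testing correction is applied anywhere; every P value is
reported raw, and the tables say so implicitly by reporting P values
rather than adjusted quantities. Comparison verdicts use the
conventional star scale (n.s., then *, **, ***, **** below 0.05, 0.01,
0.001, 0.0001).

## Forward-entry model selection

Candidate variants (the pruned panel) enter one at a time: step 1 takes
the variant with the smallest univariate P (for univariate OLS this is
identical to the largest absolute correlation, so the two readings of
"most associated" coincide); each later step takes the candidate with
the smallest nested-LRT improvement P against the current model.
Selection stops when the best available improvement no longer beats
`alpha_entry`, or when an entry pushes any term's P to `alpha_stay` or
above — in that case the offending entry is rolled back and selection
stops. A continue-without-that-candidate mode exists behind a flag for
exploration, but the stop-on-loss rule is the default semantics.
Both levels default to 0.05; entry ties are broken by the larger
absolute t of the entering term, then by genomic position.

Fixed compositions travel between datasets by plain refitting (no
reselection). The cross-check grid refits every best-model composition
on every dataset and compares it with that dataset's own best model:
LRT if one composition nests the other, J-test otherwise. A travelling
composition that *contains* the proper best model cannot be inferior in
the nested direction and is reported n.s. with an explanatory note.
Models restricted to declared functional variants (all size-1 and
size-2 subsets of the functional panel) are fitted and compared to the
proper best model the same way, ranked by model P.

## Haplotypes

Haplotype frequencies at a small tag panel (at most 12 tags, since
compatible haplotype pairs are enumerated per sample) are estimated by
EM under Hardy-Weinberg equilibrium: the E step distributes each
multilocus genotype over its compatible ordered haplotype pairs with
weights 2·f_a·f_b (f_a² for homozygous pairs), the M step re-estimates
frequencies from expected counts. Initial frequencies are uniform over
the haplotypes compatible with the sample; convergence is declared when
the log-likelihood increase falls below 1e-8 (hard cap of 10,000
iterations, non-convergence is an error reporting the final delta); the
log-likelihood is checked to be non-decreasing at every iteration.
Coalescent-informed phasing (recombination priors, approximate
likelihoods) is out of scope: at tag-panel scale the plain EM maximum
likelihood estimate is deterministic and can be verified against
brute-force likelihood maximization, which the test suite does.

Each sample gets its most probable haplotype pair (with posterior
probability) and posterior-expected per-haplotype dosages (which sum to
2 per sample). Association analyses default to hard counts from the
most probable diplotype — matching the 0/1/2 coding convention for
absent/heterozygous/homozygous — with expected dosages available and
labelled. Estimated haplotypes are named by descending frequency
(`hap01`, ...); when a predefined haplotype table is supplied, matching
allele vectors are relabelled to its names, which also keeps labels
comparable across genotype collections.

Haplotype-expression association is univariate OLS of the standardized
signal on one haplotype's dosage, reported as the coefficient per copy
with a t-based 95% confidence interval (n − 2 degrees of freedom).
Joint regression on all haplotype dosages is deliberately not offered:
dosages sum to 2, so the joint design is rank-deficient with an
intercept, and the engine refuses it with an explanatory error.
Single-variant associations are oriented to the minor allele in the
analysed samples, with the orientation recorded. For display, per-
dataset coefficient panels can be rescaled by the maximum absolute
coefficient (confidence bounds scale identically, so zero-crossing
status — hence significance — is unchanged); the scaled values are
display-only.

The correlation between a fitted cis-regulatory model and a haplotype
is the squared Pearson correlation between the model's fitted values
and the haplotype's dosage: a compound-signal version of "does this
model's prediction ride on that haplotype".

## The synthetic-data generator

The generator draws two haplotypes per sample from a frequency-weighted
pool (Hardy-Weinberg random mating, no inbreeding, no recombination or
mutation — the pool is the population) and adds expression as

latent = sum(beta_v · dosage_v) + Normal(0, sigma_bio);
probe_j = latent + Normal(0, sigma_probe_j)

directly on the scale that will be standardized anyway. Helper
functions invert the variance identities: `effect_for_h2` sizes an
effect so genotype explains a target fraction h² of latent variance
(h² = beta²·Var(d)/(beta²·Var(d) + sigma²)); `probe_sd_for_pair_r2`
inverts the attenuation identity r²_pair = (VarL/(VarL + sigma_p²))²
for probes sharing a latent signal.

### The four-study fixture

`make_four_study_fixture()` is the package's reference scenario,
emulating the structure of a multi-study cis-regulation analysis of one
gene in lymphoblastoid cell lines:

* **Samples.** One collection of 60 cell lines measured by three
  studies (which use 57, 60 and 58 of them — same lines, partially
  overlapping availability), plus an independent collection of 181
  lines for the fourth study. The three same-collection studies share
  genotypes and differ in measurement noise; each study's biological/
  technical noise draw is independent.
* **Variants.** A 24-variant cis block built from four distinct
  haplotype-incidence patterns; all other variants are perfect-LD
  duplicates, so pruning at r² ≥ 0.90 collapses 24 → 4 (a scaled-down
  analogue of a dense local panel collapsing to its effectively
  independent variants). Eight variants (the first two of each
  pattern) form the haplotype tag panel; the 6 haplotypes H1-H6 are
  mutually distinguishable at those tags.
* **Effects.** Every retained pattern is causal: −1.05, +1.05, −1.30
  and +1.45 per copy. This is a deliberate design decision: with no
  truly null candidates in the pruned panel, forward selection in the
  best-powered study tends to select the entire panel, and the other
  studies select subsets of it — which is exactly the condition under
  which the cross-check pattern "the low-noise study's composition is
  never significantly inferior elsewhere" is structurally expected
  rather than accidental. The +1.45 pattern is carried only by
  haplotype H6, making H6 the simulated risk haplotype (positively
  associated with expression everywhere); the signed effects were
  balanced so the frequency-weighted mean haplotype effect is near
  zero, which makes H3 — the haplotype carrying no minor alleles —
  effectively decoupled from the fitted models (model-haplotype
  r² ≈ 0.01 in the high-precision study).
* **Noise.** Per-study noise is solved analytically so the
  genotype-explained variance of the representative signal is 0.31,
  0.80, 0.55 and 0.28 — spanning the range reported in multi-study
  cis-regulation work — and the 8 signal probes of the first study get
  probe noise solved for an expected pairwise r² of 0.79. The first
  study also carries 5 uncorrelated exonic probes and 4 intron-
  targeting probes (removed by the annotation filter: 17 → 13), the
  second a signal probe plus an unrelated probe, the fourth a signal
  probe plus two unrelated probes.

What the fixture does *not* emulate: genotyping error and
imputation uncertainty, non-Gaussian expression noise, population
structure, recombination within the block, and batch structure beyond
a single per-study noise level. Passing fixture tests therefore
demonstrates the *machinery* (selection, comparison, phasing,
association) under the generative model it assumes, not robustness to
real-data violations of that model.

Because the fixture uses the study sample sizes (57-181), its
qualitative patterns are properties of a random draw, not certainties:
across random seeds roughly nine in ten draws exhibit all of them
simultaneously (the rare exceptions are draws where the best-powered
study misses one weak effect that another study then picks up). The
test suite pins the fixture seed; the acceptance script recomputes the
patterns at whatever seed it is given and reports the counts it
observes.

## Numerical and design choices

* QR-based solving throughout; rank deficiency is an error naming the
  dependent columns, never a silent drop.
* The LRT uses the Gaussian profile likelihood and a chi-square
  reference (F-change available); no small-sample correction.
* EM convergence at log-likelihood delta < 1e-8, cap 10,000
  iterations; haplotypes below a frequency floor (default 0.05) are
  skipped by the association stage.
* Pruning keep-rule: higher MAF wins, ties keep the smaller position;
  functional variants are exempt.
* Tie-breaks elsewhere: probe-group ties lexicographic; entry ties by
  larger |t|, then position. These make every stage deterministic
  given the input.
* Composites refuse silently mismatched sample sets; the intersection
  is only used when explicitly allowed, and dropped samples are
  listed.
* Thresholds (LD 0.90, alpha 0.05, group r² 0.5, stars) are
  configurable; defaults follow the conventions stated above.

## Problem sizes used by the tests

The test suite and acceptance script run entirely on generated data at
desk scale, chosen to make Monte-Carlo error small relative to each
tolerance: 100 random instances for the OLS oracle, 50 panels of 15
variants at n = 200 for selection-vs-exhaustive agreement, 2,000
replicates for test size and confidence-interval coverage, 500 for
J-test power, n = 10,000 for heritability recovery, n = 200 for
phasing recovery, and the fixture's own 57/60/58/181 for the
cross-study patterns.

## Known limitations

* Genotypic (unphased) r² is used for pruning; haplotypic D-based r²
  can differ near rare alleles.
* EM phasing assumes Hardy-Weinberg proportions and a modest tag
  count; it does not model genotype error or relatedness.
* Forward entry is a greedy path and can differ from exhaustive best-
  subset search (measured agreement ~95% under the tested conditions);
  the exhaustive search exists in the tests as an oracle only.
* Classical MDS coordinates are a display convenience, not an
  inferential object.
* The generator's Gaussian, standardized-scale model is the analysis
  model; it cannot reveal robustness failures to distributional
  violations.
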