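---
title: "Resolving 5mC and 5hmC from paired BS/TAB arrays: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving 5mC and 5hmC from paired BS/TAB arrays: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabhmc)
```

## The measurement problem

Conventional bisulfite (BS) conversion cannot distinguish
5-methylcytosine (5mC) from 5-hydroxymethylcytosine (5hmC): both survive
conversion and read as "modified". TET-assisted bisulfite (TAB) chemistry
glucosylates 5hmC so that it alone is protected, while 5mC is oxidized and
converted. Splitting each DNA sample into two fractions and hybridizing
both to a methylation array therefore yields two beta values per CpG per
tissue sample:

* BS channel: $\beta_{BS} \approx p_{5mC} + p_{5hmC}$
* TAB channel: $\beta_{TAB} \approx p_{5hmC}$

`tabhmc` turns paired tumor/adjacent BS/TAB array data into per-CpG
(5mC, 5hmC) estimates, differential-5hmC calls between tissues, and
enrichment summaries over genomic annotations and gene sets.

## Per-channel preprocessing

Each channel is processed separately end to end, and the two are merged
only at the estimation step.

**Detection-p filter.** A probe is low-quality when its detection p
exceeds $10^{-6}$ in strictly more than 5% of that channel's samples.
Failures from the two channels are pooled and the union is removed from
both, so both channels keep one shared probe universe. Both thresholds
are configuration fields (`detection_p_threshold`,
`detection_sample_fraction`).

**Background correction.** An observed intensity is modelled as
$X = S + B$ with signal $S \sim \mathrm{Exp}(\theta)$ and background
$B \sim N(\mu, \sigma^2)$ truncated at zero. $\mu$ and $\sigma$ are fitted
per sample from negative-control intensities by inverting the
truncated-normal moment equations (for typical array backgrounds where
$\mu \gg \sigma$ the truncation correction is negligible and the fit
reduces to the control mean and SD); $\theta$ comes from the observed
probes by method of moments, $\theta = \bar{x} - \mu$, floored at a small
positive value (with a warning) when no signal exceeds background. The
corrected intensity is the posterior mean $E[S \mid X = x]$, evaluated
with the numerically guarded closed form; the test suite pins it against
direct quadrature of the posterior to $10^{-6}$. Negative controls are an
explicit input (the synthetic generator emits them) rather than being
derived from out-of-band manifest machinery, which would require raw IDAT
detail that is out of scope.

**Quantile normalization** equalizes each signal matrix's column
distributions to the mean order-statistic curve within a channel, across
all of that channel's samples. Per-channel normalization is the default
because the two chemistries have different intensity distributions;
pooling all 68 arrays into one normalization is available behind
`quantile_pooled = TRUE` for designs where the channels are believed to
share a scale.

**Beta and M.** $\beta = M_{sig} / (M_{sig} + U_{sig} + c)$ with offset
$c = 100$ by default (the common array stabilizer, exposed as a
configuration field), and
$M = \log_2(\beta / (1 - \beta))$ with $\beta$ clamped to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$, for heatmap
display.

## The constrained maximum-likelihood estimator

For one CpG in one tissue unit, the two channel betas are treated as
binomial fractions with pseudo-depths $w_{BS}, w_{TAB}$ and success
probabilities $p_{5mC}+p_{5hmC}$ and $p_{5hmC}$, maximized subject to
$p_{5mC}, p_{5hmC} \ge 0$, $p_{5mC}+p_{5hmC} \le 1$. The solution is
closed-form:

* interior ($\beta_{TAB} \le \beta_{BS}$): $\hat p_{5hmC} = \beta_{TAB}$,
  $\hat p_{5mC} = \beta_{BS} - \beta_{TAB}$ — the natural subtraction
  estimate, which reproduces both channel moments exactly;
* boundary ($\beta_{TAB} > \beta_{BS}$, possible only through measurement
  noise): the optimum lies on $p_{5mC} = 0$ with
  $\hat p_{5hmC} = (w_{BS}\beta_{BS} + w_{TAB}\beta_{TAB}) /
  (w_{BS}+w_{TAB})$.

Array betas carry no read depth, so the default weights are
$w_{BS} = w_{TAB} = 1$; intensity-derived weights can be supplied.
Estimation is strictly per unit — each subject-tissue's own BS and TAB
samples and nothing else; no shrinkage across units. The acceptance suite
checks the estimator against a profile-likelihood grid search at step
$10^{-4}$ over 1,000 random cases including boundary-active ones.

Per-CpG 5mC-5hmC association is summarized with Pearson correlation on
the beta scale across the 34 units. Beta is the scale on which the
modification levels are reported and compared; the correlation
coefficient itself is a package choice, as is flagging probes with a
constant profile as degenerate rather than assigning them $r = 0$.

## Paired differential testing

The 5hmC profile is tested probe-wise with a paired t-test on subject-wise
tumor-minus-adjacent differences, on the beta scale (M-values are kept for
display only). By default the per-probe variances are moderated by
empirical Bayes: $s^2_{post} = (d_0 s_0^2 + (n-1)s^2)/(d_0 + n - 1)$ with
moderated degrees of freedom $d_0 + n - 1$, where the prior $(d_0, s_0^2)$
is estimated by matching the first two moments of $\log s^2$ to a
scaled-F marginal (digamma/trigamma identities, with a Newton inversion
of the trigamma function). This is the standard moderated paired analysis for arrays of this size
and the package default; a plain unmoderated mode (`moderation = FALSE`)
exists for small-sample skepticism and for oracle testing, and the run
manifest records which was used. The test suite verifies the moderated route coefficient-for-
coefficient against an independent reference implementation and the plain
route against brute-force recomputation.

P-values are two-sided (both gains and losses are reported downstream)
and controlled family-wise by Bonferroni, $p_{adj} = \min(1, m p)$, with
the significance cutoff $p_{adj} < 0.05$. Significant loci are
partitioned by the sign of the mean difference into lower-in-tumor and
higher-in-tumor sets.

## Annotation and enrichment

Probe manifest positions are 1-based (array convention); all interval
inputs (BED, gappedPeak) are 0-based half-open, and the conversion
happens exactly once, at the overlap query. gappedPeak blocks are
ignored: colocalization is against the outer peak span. Promoters are
the strand-aware window TSS $-1500/+500$ bp (a configuration field — the
notion of "promoter" is not otherwise pinned down); gene bodies span
TSS..TES; introns are the per-gene exon complement. A probe hosted by
several genes counts for all of them — the conservative closure when no
tie-break rule is given. An exclusive class per probe, used for
stratified distribution summaries, follows the configurable precedence
promoter > exon > intron > gene body > intergenic, with CpG-island and
histone-mark labels tracked orthogonally. Sex-chromosome probes are
removed before testing, in either chromosome-naming dialect.

Enrichment of a probe set against the analyzed (post-QC, autosomal)
background uses the one-sided Fisher construction: the 2x2 table is set
vs background-minus-set against label membership, the odds ratio is
$ad/bc$ (reported as $+\infty$ when $bc = 0$ and $ad > 0$), and the
one-sided p is the hypergeometric upper tail for enrichment (lower tail,
with OR < 1, for depletion).

**Permutation gene-set tests.** The observed statistic is the number of
distinct target genes (e.g. unfavorable-prognostic genes at log-rank
p < 0.001, or "elevated in pancreatic cancer" genes) hit by the probe
set. Each of 100,000 iterations draws the same number of probes uniformly
without replacement from the background and recounts; sampling probes
rather than genes deliberately preserves gene-length/probe-density bias.
The empirical p is the fraction of null counts *strictly greater* than
the observed count — a counting rule that can return exactly 0; a
greater-or-equal rule and the $(b+1)/(n+1)$ correction are options, and
the manifest records the rule. Runs are performed per change
direction x gene-set category, with per-run seeds derived
deterministically from the master seed, so the full null is reproducible.

## The synthetic-data generator

The generator exists so that every stage runs and is testable with no
external data. It emulates, with defaults fixed once:

* 17 subjects x {tumor, adjacent} x {BS, TAB} = 68 arrays over 20,000
  probes on four autosomes plus small chrX/chrY (2% of probes, later
  dropped);
* a bimodal 5mC marginal (Beta(2,12) / Beta(10, 2.5) mixture; CpG-island
  probes favor the low mode at 0.8 vs 0.45 elsewhere) and a low unimodal
  5hmC marginal (Beta(1.3, 20), mean about 0.06), with gene-body probes'
  mean 5hmC doubled — the hydroxymethylation-in-gene-bodies signature;
* negative 5mC-5hmC dependence for 80% of probes, induced by coupling the
  per-unit logit-scale 5mC jitter (SD 0.25) into 5hmC with a negative
  sign (strength 1.0; the remaining 20% get a weak positive coupling of
  0.2), plus independent 5hmC noise (SD 0.05). The observation being
  emulated is the dependence itself; this coupling mechanism is the
  package's own construction. Probe-level 5hmC means are additionally
  damped by $0.25 + 0.75(1 - \bar m)$ so that high-5mC probes carry
  little 5hmC and the truth rarely needs clipping to the simplex
  (residual clips are counted and reported);
* planted differential loci: 2.5% of probes (500 at the default scale),
  drawn on autosomes, shifted on tumor 5hmC by $\delta = 0.15$ with a
  9:1 loss:gain ratio — the loss-dominant pattern expected of tumors.
  Losses start from baseline 5hmC in (0.20, 0.40) so the shift has
  headroom; planted probes sit at moderate 5mC for the same reason;
* measurement: binomial pseudo-counts at depth $w = 2000$ (chosen to give
  technical noise of roughly 0.01 SD on beta, typical of array replicate
  concordance), scaled to intensity 5,000 and added to Gaussian
  background $N(100, 10^2)$ — deliberately well-specified for the
  normexp correction; a t-distributed background mode exists for
  robustness checks. 1% of probes per channel are planted low-quality
  with failing detection p in more than 5% of samples; 600
  negative-control probes per channel carry pure background;
* gene sets: 6% of genes per direction get significant prognostic labels
  (log-rank p drawn below $10^{-3}$), 13% non-significant prognostic,
  15% elevated. With enrichment factor 3, loss-loci host genes triple
  their unfavorable rate (gains: favorable; all planted hosts:
  elevated); factor 1 is the null configuration. Labels are placed on
  planted hosts rather than planting loci into pre-labelled genes; the
  two constructions give the same joint enrichment and this order keeps
  the genome, truth and label stages independently seeded.

What the generator does *not* emulate: Infinium I/II probe-type
chemistry, dye bias, batch and plate effects, cell-composition mixtures,
copy-number confounding, and spatially correlated modification. Passing
tests therefore demonstrate correctness of the estimator, the test, the
counting and the bookkeeping under a clean, correctly specified noise
model — not robustness to every artefact of real arrays.

## Numerical choices and degenerate inputs

* Beta clamp $10^{-6}$ before the logit; MLE inputs validated to [0, 1],
  non-finite values are hard errors.
* Zero-variance probes: with moderation they are absorbed by the prior;
  without, they are flagged `degenerate` and pinned to the p = 0/1
  boundary by the sign of the mean difference.
* Trigamma inversion by Newton steps with asymptotic fallbacks at both
  ends; variance sets more concordant than chi-square noise give
  $d_0 = \infty$ (pooled-variance limit).
* Matrix TSVs are written at 17 significant digits and parsed with R's
  strtod so write-then-read is bitwise exact; this is what makes the
  pipeline's byte-identical determinism contract testable.
* Ties in quantile normalization are averaged; ranks are preserved
  per column.
* Empty probe subsets in directional permutation runs are skipped with a
  notice rather than producing 0-draw results.

## Problem sizes used in the shipped checks

The shipped test suite and acceptance script use the generator's default
scale — 20,000 probes, 17 pairs, pseudo-depth 2,000, 100,000
permutations for headline runs — and smaller seeded configurations
(hundreds of probes, a few hundred permutations) for contract and
round-trip checks; the null-calibration check uses 20 replicate
regenerations of the study under $\delta = 0$. These sizes are the
package's chosen testbed for desk-scale verification; all of them are
set in code, not in fixtures.

## Known limitations

* The boundary MLE depends on the pseudo-depth ratio, which array data
  cannot identify; equal weights are a convention.
* Bonferroni control with moderated tests is slightly sensitive to
  misfit of the scaled-F prior in the extreme tail; the unmoderated mode
  is the conservative fallback.
* Quantile normalization across all samples assumes the tissue groups
  share a distribution. When a non-negligible fraction of probes truly
  shifts in one group — the synthetic default plants 2.5%, and a 0.15
  loss necessarily starts in the sparse 5hmC upper tail — the vacated
  top quantiles of the shifted columns are refilled by rank, which both
  nudges the remaining top-tail probes upward and compresses their
  between-sample variance. Variance moderation then amplifies these into
  a small excess of apparent-gain false discoveries concentrated at the
  top of the 5hmC range (measured at about 5.8% of discoveries under the
  default synthetic conditions, versus 4.2% for the unmoderated test and
  none with normalization ablated). The effect scales with the
  differential fraction and inversely with probe count, so it is far
  smaller on a full-size array with sparse true differences; for data
  where substantial global 5hmC loss is expected, the unmoderated mode
  and a skeptical eye on top-tail gains are advisable.
* The permutation test conditions on the observed probe-set size only;
  it does not model per-probe selection probability beyond uniform
  sampling.
* Enrichment odds ratios for rare labels are unstable and reported as
  $+\infty$ at the boundary rather than being continuity-corrected.
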