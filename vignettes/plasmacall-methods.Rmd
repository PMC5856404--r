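---
title: "plasmacall: models and methods"
author: "plasmacall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plasmacall: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmacall)
```

# The problem

Circulating tumor DNA (ctDNA) is a small fraction of the cell-free DNA in
plasma. An amplicon assay for ctDNA interrogates a panel of short PCR
products (72–154 bp, designed for fragmented DNA) at depths of thousands of
reads, and must decide whether a handful of non-reference reads at a locus
is a real somatic variant at 0.1–1% allele fraction or sequencing/PCR error.
Two ideas make this tractable:

* **Position-specific error calibration.** Error rates vary by orders of
  magnitude between positions and substitution types. The null hypothesis at
  each (position, substitution) is learned from control samples rather than
  assumed global.
* **Replicate integration.** The DNA of a sample is split into independent
  technical replicates. A true variant contributes mutant molecules to every
  replicate in proportion to its allele fraction; a stochastic error burst
  does not. Evidence is combined across replicates in a likelihood
  framework, which suppresses replicate-level artifacts.

`plasmacall` implements the calling machinery, the digital-PCR (dPCR)
limit-of-detection statistics used to quantify input DNA, the analytical
validation statistics (exact binomial intervals, pooled sensitivity,
per-base specificity, precision, extraction efficiency), and a synthetic
data stack that emulates the reference-standard dilution experiments such
assays are validated with.

# The statistical model

## Background error model

For every panel position and substitution, control libraries give error
fractions. We model the alt count $x$ at depth $d$ as beta-binomial with
mean $\mu$ and intra-class correlation $\rho$ ("overdispersion"; $\rho = 0$
reduces to binomial). The method-of-moments fit uses pseudocounted per-library
fractions $p_i = (x_i + 0.5)/(d_i + 1)$:

$$\hat\mu = \bar p, \qquad
\hat\rho = \frac{\widehat{\mathrm{Var}}(p)/(\hat\mu(1-\hat\mu)) -
  \overline{1/d}}{\overline{(d-1)/d}},$$

clamped to $[0, 0.99]$. Three design points matter:

* **The replicate library is the fitting unit.** Pooling a control's
  replicates before fitting would average away exactly the within-library
  overdispersion the caller's null must carry, making the null
  anticonservative.
* **Pseudocounts (0.5 on the numerator, 1 on the denominator)** prevent
  zero-variance nulls at clean positions, where any single alt read would
  otherwise be "significant".
* **A panel-global floor on $\hat\rho$.** The per-locus moment estimate of
  $\rho$ is noisy with a modest control cohort and collapses to zero by
  chance at many loci. Because errors at different positions share the same
  chemistry, each locus's $\hat\rho$ is floored at the panel-wide mean of
  the raw estimates. The floor is conservative: it can only raise the null's
  variance.

Indel backgrounds are estimated from the *other samples of the same batch*,
leave-one-out, so a sample's true somatic indel never suppresses itself. A
batch needs at least 4 samples; smaller batches are directed to the control
cohort.

## Replicate-integrated calling

At a candidate locus with per-replicate alt counts $x_r$ and depths $d_r$,
the likelihood under allele fraction $f$ is beta-binomial with success rate

$$p(f) = f + (1 - f)\,\mu,$$

i.e. mutant molecules plus background error on the non-mutant molecules,
with the background's $\rho$. The joint log-likelihood sums over replicates
with a *shared* $f$; $\hat f$ (the reported `af_mle`) maximizes it, and the
decision statistic is the likelihood ratio

$$\mathrm{LR} = 2\,\{\ell(\hat f) - \ell(0)\}.$$

At $f = 0$ the likelihood reduces exactly to the null, so `lr = 0` whenever
no alt reads are observed. Replicates with zero depth are excluded from the
locus rather than failing the sample. Because the reported allele fraction
is a modeling choice the upstream literature leaves open, the pooled count
ratio (`af_pooled`) is reported side by side with the MLE.

The maximization uses vectorized golden-section search on $f \in [0, 1]$
(45 iterations, bracketing the maximizer to $\sim 4\times10^{-10}$; the
log-likelihood is unimodal because $p(f)$ is affine in $f$ and the
beta-binomial log-density is concave in $p$). All loci of a sample are
optimized simultaneously as matrix operations, which is what makes
calibration and cohort-scale simulation affordable.

## Threshold calibration to a specificity budget

The call threshold on LR is calibrated so that the expected number of false
calls per interrogated base stays within a budget (default
$3\times10^{-6}$, consistent with a per-base specificity of 99.9997%).
Wild-type samples are simulated *from the fitted background model*, the
null LR distribution is collected, and the threshold is the largest of:

1. the smallest value whose empirical per-base false-call rate meets the
   budget;
2. an exponential peaks-over-threshold extrapolation of the simulated null
   tail, evaluated at the per-test budget divided by a safety factor
   (default 2) — the budget corresponds to roughly a $10^{-6}$ per-test tail
   probability, which counting alone cannot resolve at a feasible number of
   simulations, and the discrete overdispersed LR tail is heavier than its
   asymptotic approximation;
3. the asymptotic $\chi^2_1$ quantile at the per-test budget, as a floor.

The safety factor exists because the background parameters are themselves
estimates: simulating from the fitted model cannot see estimation error.
The direction is conservative — a slightly higher threshold — and is
essentially free, because true variants at the validated allele fractions
produce LR values orders of magnitude above any of these candidates.

## Copy number, contamination

Gene copy number uses median-of-ratios normalization: amplicon factors are
baseline medians, sample factors are medians of amplicon-scaled depths, and
a gene's copy number is twice the lower median (even counts round toward
copy-neutral) of its amplicons' normalized ratios. A whole-sample depth
scaling therefore cancels exactly, and a copy-neutral panel majority is
assumed — the panel design keeps any single gene a small minority of
amplicons.

Cross-sample contamination is screened with common SNPs: a clean sample has
allele fractions near 0, 0.5 or 1 (tolerances 0.02 and 0.05 respectively);
three or more SNPs pulled toward intermediate fractions indicate
contamination, and a genotype fingerprint that disagrees with the previous
sample of the same patient at four or more loci indicates a possible swap.

# Digital PCR statistics

Droplet occupancy is Poisson: with $k$ of $n$ droplets positive,
$\lambda = -\ln(1 - k/n)$ copies per droplet, and concentration
$\lambda / 0.85\,\mathrm{nL}$ by the default partition volume. The limit of
detection combines two binomials at $\alpha = \beta = 0.05$:

* the **critical level** is the 95th percentile of
  $\mathrm{Bin}(n, \lambda_{FP})$, with the false-positive rate per droplet
  $\lambda_{FP}$ pooled from wild-type control reactions;
* the **detectable probability** $p$ is the smallest success probability
  whose 5th percentile reaches the critical level, solved by bisection on
  the exact CDF ($P(X \le c) \le \beta$) to relative tolerance $10^{-12}$;
* LOD in copies per reaction is $n \cdot (-\ln(1-p))$; as AF% it is taken
  relative to total target copies ($n\lambda_{WT}$ plus the mutant copies).

Discrete percentiles are defined as the smallest integer whose CDF reaches
the target, which makes the round trip conservative: simulated reactions at
the LOD concentration are detected in at least 95% of cases while wild-type
reactions exceed the critical level in at most 5%. With
$\lambda_{FP} = 0$ the LOD collapses to the closed form $-\ln(\beta)
\approx 3.0$ copies per reaction, independent of droplet count.

# Validation statistics

Sensitivity intervals are exact (Clopper–Pearson) via beta quantiles; the
boundary cases have closed forms ($x = n$: lower limit
$100\,(\alpha/2)^{1/n}$). Exact intervals were chosen because the boundary
behaviour of published validation tables matches them; this is a
convention choice, recorded here. Pooled sensitivity across laboratories is
$\sum x / \sum n$, which under equal trial counts is the mean of the
stratum percentages; display values round half up to two decimals while
computation keeps full precision. Per-base specificity is
$100\,(1 - FP/(\text{samples} \times \text{footprint bases}))$ — the
denominator convention is explicit in the output record so alternatives
(e.g. three substitutions per base) are one argument away. Precision is the
sample-SD coefficient of variation; extraction efficiency is measured over
expected spiked copies, with over-recovery flagged rather than clamped.

# The synthetic-data stack

The generators emulate the validation experiments end to end:

* **Dilution series**: truth sets carry stock allele fractions;
  `diluteTruth()` scales expectations by the dilution factor, mirroring
  mutant standards diluted into wild-type DNA across tiers
  (1–1.3% down to 0.06–0.08%).
* **Stochastic input sampling**: mutant molecules among the amplifiable
  copies (AC) are binomial draws; input tiers of 2,000 / 8,000 / 16,000 AC
  are the low/medium/high study conditions. At 0.06% AF and 8,000 AC the
  expected mutant count is ~5 molecules — molecule sampling, not sequencing
  depth, is what limits sensitivity there.
* **Replicate splits**: multinomial with equal probabilities, conserving
  totals exactly. The default of 8 replicates per sample is a package
  choice (the validated assays state only that regions are analysed
  multiple times).
* **Counts**: per-amplicon depth is Poisson around replicate copies times a
  mean read multiplicity (default 4 reads per molecule); alt reads are a
  binomial thinning of depth at the replicate's molecule fraction;
  substitution errors are beta-binomial draws from a per-position rate
  table (log-normal spread around $10^{-4}$, $\mathrm{sd}_{\log_{10}} =
  0.3$, $\rho = 2\times10^{-4}$ — typical of amplicon data after Q30
  filtering). Amplification is deliberately *not* a branching process: the
  caller operates on count ratios, and a per-molecule multiplicity with
  Poisson dispersion reproduces the relevant variance structure.
* **Oxidative artifact mode** multiplies only G>T and C>A error rates,
  emulating 8-oxoguanine damage from acoustic shearing of reference
  standards; fitted backgrounds from artifact-mode controls show the
  corresponding substitution-specific elevation.
* **Full-process controls**: spiked mutant standard recovered at a binomial
  extraction efficiency (default 0.5, the recovery level typical of
  spike-in controls) and diluted by the plasma's own wild-type DNA, so the
  measured AF is always below the nominal spike AF.
* **Droplets**: per-channel Poisson occupancy with false positives added to
  the mutant channel; classes (single/double positive, negative) are
  multinomial.
* **Reads**: optional paired-end FASTQ emission (2×150, primers attached,
  flat quality strings) exercises merging, primer-anchored amplicon
  assignment and the Q30 pileup; the count-level path is the default for
  speed.

What the generators do **not** model: fragment-length differences between
sheared standards and native cfDNA, PCR branching statistics,
sequence-context (e.g. trinucleotide) error structure, strand-specific
error, and real cross-sample index hopping. Passing tests on this stack
demonstrate the *statistical machinery* — calibration transfer, replicate
integration, monotone dose response — not performance on any particular
instrument's error profile.

# Numerical and convention choices

* Coordinates are 0-based half-open everywhere internally and in TSV
  formats; 1-based coordinates appear only in VCF output. Indels are
  left-aligned and emitted VCF-style with an anchor base.
* The reverse primer is stored as synthesized; all counting is on the
  reference top strand.
* Read merging takes the best ungapped overlap by matching bases (minimum
  overlap 10, mismatch fraction at most 0.1, ties unmergeable); discordant
  overlap bases keep the higher-quality base at Phred 2, which the Q30
  pileup rule then excludes.
* CNV median ties at even amplicon counts take the lower median
  (conservative toward copy number 2).
* Degenerate inputs: zero-depth replicates are dropped per locus; loci with
  a low-confidence background are reported as `low_confidence_region`
  rather than called silently; saturated dPCR reactions ($k = n$) are an
  error because occupancy is undefined.

# Problem sizes used by the test suite

The packaged tests and the acceptance script run: background fitting from
12 control samples of 8 replicates on a 1 kb, 10-amplicon toy panel;
threshold calibration from 50 simulated wild-type samples; a specificity
check over 200 fresh wild-type samples; a sensitivity grid of 5 dilution
tiers × 3 input amounts × 200 variants per cell; allele-fraction recovery
over 400 variants at depth 5,000 × 8 replicates; and 10,000 droplet
reactions for the dPCR round trip. These sizes were chosen so the full
suite completes in a few minutes while keeping Monte-Carlo noise well below
the margins being asserted.

# Known limitations

* The calibration guarantee is with respect to the *fitted* background
  model. When the true error process differs from the fit (as it always
  does slightly — the fit is from a finite cohort), the realized false-call
  rate can exceed the budget; the safety factor in the tail extrapolation
  absorbs typical estimation error, but a grossly underfitted background
  (too few controls, unmodeled artifact modes) will leak through. Fitting
  with artifact-mode controls when sheared material is analysed is the
  intended mitigation.
* The method-of-moments background fit is near-unbiased only when the
  per-library expected alt count is not far below 1; at very quiet
  positions the pseudocount floor dominates and the fitted mean is an upper
  bound, which is conservative for calling.
* Sensitivity figures from the synthetic grid are structurally comparable
  to wet-lab validation tiers (monotone in AF and input, saturating at
  high AF) but not numerically transferable: the real assay's molecule
  losses and error profile are not identified by this simulator.
* Contamination screening assumes a diploid host and bi-allelic SNPs; the
  swap heuristic needs a prior sample of the same patient.
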