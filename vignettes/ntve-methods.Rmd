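---
title: "Models and methods for vesicle-exported transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for vesicle-exported transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntve)
```

## The measurement problem

Non-destructive transcriptomics by vesicular export (NTVE) samples a cell
population's transcriptome from membrane vesicles budded into the culture
supernatant, instead of lysing the cells. The same culture therefore yields
two paired RNA-seq measurements: the *supernatant* (exported) fraction and a
conventional *lysate* control. All analyses in this package revolve around
that pairing: how faithfully does the exported fraction mirror the
intracellular transcriptome, per gene (export ratios, detection rates,
replicate CV), per position within transcripts (3'-anchored coverage), and
under perturbation or differentiation (differential expression and
time-course models)?

Because exported RNA is scarce, libraries carry characteristic artifacts —
PCR duplicates and low-complexity reads — and exported fragments are biased
toward transcript 3' ends (the export adapter binds the poly(A) tail).
The package implements the complete computational chain: read filtering,
coverage profiling, export statistics, a negative-binomial GLM testing
engine, and classifier/enrichment evaluation, all exercised end to end on a
synthetic-data generator with known ground truth.

## Read-pair filtering

Two per-mate criteria decide a pair's fate; a pair is dropped when *either*
mate fails.

* **k-mer complexity.** All overlapping k-mers of a read are tabulated; the
  read passes when at least 80% of k-mer positions carry a k-mer occurring
  exactly once in that read. The k-mer length is not critical — homopolymer
  and short-repeat artifacts fail at any standard short-read k — so the
  default is k = 21, exposed as a parameter. The "uniquely occurring"
  proportion is computed over k-mer *positions* (occurrences), matching the
  extract-and-tabulate construction; computing it over distinct k-mers
  would be a different statistic.
* **Mapped stretch.** The longest run of consecutive reference-matching
  CIGAR operations (M, =, X) must span at least 80 nt. Thresholds are
  inclusive on retention (a fraction of exactly 0.8, or a stretch of
  exactly 80 nt, passes).

Exact duplicate removal collapses pairs with identical (mate-1, mate-2)
sequences to the first pair encountered; the retained count is invariant to
input order, the surviving representative is not (and nothing downstream
depends on it).

## Coverage profiling

Per-position depth is computed in transcript coordinates; D and N CIGAR
operations consume reference (standard depth semantics), soft-clips do not.
Each transcript's depth vector $C_{ij}$ is area-under-the-curve normalized,

$$C'_{ij} = \frac{C_{ij}}{\sum_{m=1}^{L_j} C_{mj}} \cdot L_j,$$

so the normalized coverage averages exactly 1 per position regardless of
expression level or transcript length. The denominator sums over the full
transcript; the 3000-nt display window enters only at binning — this is the
only reading under which the mean-1 identity is exact. Normalized profiles
are anchored at the transcript end site (TES; distance 0 = last position)
and averaged within 10-nt bins over [0, 3000) nt upstream. Transcripts
shorter than the window contribute to the bins they reach, and the per-bin
contributing-transcript count is reported alongside so dropout is visible.
The supernatant/lysate per-bin ratio gives relative apparent enrichment;
bins with zero lysate coverage are reported as undefined, never infinite.

## Export statistics

* **Export ratio**: per matched replicate pair, supernatant/lysate
  expression per gene on the log10 scale, after excluding genes with lysate
  expression below 1 CPM/TPM. Replicate histograms (70 shared bins) are
  summarized as mean density with a 95% band (±1.96 × SEM).
* **Detection rate by quantile**: genes ranked by source-compartment
  expression (aggregated ≥ 1), 50 equal-size groups, rate = share of a
  group detected (> 0) in *all* target replicates. Ties are broken by
  feature id so groups are deterministic.
* **Length-binned concordance**: Spearman correlation for every
  supernatant × lysate replicate pair (9 for triplicates) within transcript
  length bins, mean ± sd per bin; bins with < 3 transcripts are undefined.
* **Spike-in quantification**: with spike mass $m$ (default 1 pg), sample
  RNA mass is $m \times$ (non-spike/spike fragments). Mass converts to
  molecules via the assumed mean mRNA length (1500 nt) and an average
  ribonucleotide residue mass of 340 Da — an approximation knob, exposed in
  the configuration. For per-cell per-day rates we integrate cell-days
  explicitly: with $n_0$ seeded cells and two divisions over the culture,
  cell-days $= n_0(2^0 + 2^1 + 2^2) = 7n_0$. The integration rule is a
  package decision (only the division count and length assumptions are
  given by the protocol), so it is documented and configurable. Particle
  counts derive from immunoassay monomer counts at 2500 monomers per
  particle.

## The negative-binomial GLM engine

Counts are modeled as $K \sim \mathrm{NB}(\mu, \alpha)$ with
$\mathrm{Var} = \mu + \alpha\mu^2$ and $\log\mu = X\beta + \log s$, where
$s$ are median-of-ratios size factors. Coefficients are fitted by IRLS with
a log link; standard errors come from the observed Fisher information.
Nested models are compared by the likelihood ratio
$\Lambda = 2(\ell_F - \ell_R)$ against $\chi^2_{df}$.

Three test families share this machinery:

1. **One-vs-rest lineage test** — full model: intercept + binary indicator
   for the target lineage (df = 1).
2. **Lineage-specific trajectory test** — full model adds a shared natural
   cubic spline in time plus lineage × spline interactions; the reduced
   model keeps the shared spline (df = K). Constant offsets thus never
   masquerade as trajectory effects.
3. **Time-course test** — per-replicate intercepts + shared spline versus
   per-replicate intercepts alone (df = K). The "replicate expression
   factor" is implemented as one fixed-effect intercept per replicate line,
   present in both models — the only reading that leaves the test
   well-defined with df = K.

The spline basis is the natural cubic basis (`splines::ns`): cubic between
knots, linear beyond the boundary knots, interior knots at time quantiles.
K defaults to 4 and is exposed; at least K + 1 distinct time points are
required for identifiability, and the generator demands K + 2 for
comfortable residual degrees of freedom.

**Dispersion estimation.** Per-gene dispersions maximize a Cox–Reid
adjusted profile likelihood (coefficients refitted at each candidate
$\alpha$, penalty $-\tfrac12\log\det X^\top W X$) on the log scale, floored
at $10^{-8}$. For the LRTs the dispersion is estimated under the *reduced*
design and shared by both fits, and the per-gene estimates are
empirically-Bayes moderated toward the maximizer of the summed adjusted
profile likelihood across genes (weights from the observed spread of
log-dispersions versus their trigamma sampling variance). These choices are
load-bearing: with 3 + 6 replicates, raw per-gene maximum likelihood under
the full design inflates the null rejection rate to ~12% at nominal 5%,
while the reduced-design CR-APL estimate with moderation brings the test to
oracle-level calibration (simulation results in the test suite and
acceptance script). This mirrors standard practice in the established DE
frameworks, which never use raw per-gene MLEs at these sample sizes.

**Wald tests.** Besides the standard two-sided test, interval nulls on the
log2 scale (threshold θ, default 1): `greaterAbs` tests
$|\beta| \le \theta$ via $z = (|\hat\beta| - \theta)/\mathrm{SE}$ with
doubled lower tail; `lessAbs` is an intersection–union test taking the
larger of the two one-sided p-values at ±θ. Coefficients are fitted on the
natural-log scale and reported in log2.

**Shrinkage.** Reported fold changes can be moderated by an adaptive normal
prior: $\tau^2$ is estimated from the marginal spread of the estimates
(variance of $\hat\beta$ minus mean squared SE, floored), and the posterior
mean $\hat\beta\,\tau^2/(\tau^2 + \mathrm{SE}^2)$ strictly reduces
magnitudes. This is deliberately simpler than heavy-tailed shrinkage priors
and is used only for effect-size reporting — every classification in the
pipeline comes from tests, never from shrunken values.

## Evaluation

Ground truth for classifier evaluation comes from lysate interval-null
tests: positives are genes with significant $|\mathrm{LFC}| > 1$
(`greaterAbs`, FDR < 0.05), negatives significant $|\mathrm{LFC}| < 1$
(`lessAbs`); everything else is unlabeled and excluded. Supernatant
adjusted p-values serve as scores (negated internally so larger = more
positive). ROC and PR curves sweep all unique score thresholds with
trapezoidal AUCs; the random-classifier precision equals the positive
prevalence by construction and is reported.

Preranked GSEA uses the weighted running-sum statistic (weight = |stat|,
exponent 1) with a gene-label permutation null — the appropriate null when
the input is already a ranked statistic. NES divides the ES by the mean
|null ES| of matching sign; p-values are BH-adjusted across sets and
results sorted by adjusted p. When the maximal positive and negative
running-sum deviations tie in magnitude, the positive one is reported.

Sliding-window differential expression compares each two-day bin against
the immediately preceding two-day bin with a one-day stride (T daily points
give T − 3 comparisons); non-integer times are floored to days. Contraction
frequency is estimated from a bright-field intensity trace by peak
detection with a 0.3 s refractory distance and a prominence threshold of
0.5 × trace sd — engineering defaults, exposed as parameters — and
frequency = (peaks − 1)/(time between first and last peak).

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume, with
every truth quantity returned beside the data:

* paired NB counts with log-uniform lysate abundances over three decades,
  per-gene log10 export ratios $\mathcal{N}(0, 0.3)$ by default (a sharply
  peaked, parity-centered distribution; the lognormal form is a modeling
  choice — the real ratio distribution's shape beyond "sharply peaked" is
  not constrained), mitochondrial genes depleted 100-fold in the
  supernatant, dispersion 0.05, triplicates per compartment;
* aligned read pairs whose fragment 3' ends sit at an
  exponentially-distributed distance (scale 500 nt) from the transcript 3'
  terminus in the supernatant and uniformly in the lysate — the simplest
  monotone-decay model consistent with a poly(A)-anchored export adapter —
  plus configurable exact-duplicate (5%) and homopolymer (2%) artifacts
  and a 1% spike-in read fraction;
* multi-lineage spline time courses (three lineages, seven daily points,
  triplicates) with disjoint gene classes carrying trajectory deviations,
  constant offsets, or nothing;
* two-condition datasets with arbitrary per-gene true log2 fold changes,
  unbalanced designs included.

All generators are bit-reproducible under a fixed seed. What they do *not*
emulate: sequencing error, base qualities, GC/positional quantification
bias, isoform switching, and correlated gene–gene structure. Passing tests
therefore demonstrate the correctness and calibration of the statistical
machinery under the stated model, not robustness to every artifact of real
libraries.

## Numerical choices and degenerate inputs

* IRLS converges on a max coefficient change of 1e-10 (cap 100
  iterations); linear predictors are clamped to ±30 to avoid overflow;
  all-zero genes are flagged unconverged and excluded from testing, never
  fitted.
* A dispersion passed as 0 is honored as an exact Poisson fit; estimated
  dispersions are floored at 1e-8.
* $\Lambda$ is clipped at zero (tolerance 1e-8 for warnings).
* Zero-depth transcripts are excluded from AUC normalization with a
  warning — no NaNs propagate.
* Undefined quantities (coverage ratio over empty lysate bins, Spearman in
  bins with < 3 transcripts, frequency with < 2 peaks) are reported as NA,
  never as infinities.
* Quantile group assignment and time-to-peak ordering break ties by
  feature id, so outputs are deterministic.

## Problem sizes

The bundled analyses and checks run at deliberately modest scale — 500–5000
genes, 25,000 read pairs per compartment, 2000-gene null calibrations —
chosen so the full suite completes in minutes while keeping every estimate
well inside its sampling tolerance. Each script states the sizes it uses;
scaling up only tightens the comparisons.

## Known limitations

* Calibration of the LRTs at 3 + 6 replicates is oracle-limited: even with
  the true dispersion, the $\chi^2$ reference is an approximation, and a
  2000-gene Kolmogorov–Smirnov uniformity check will occasionally flag a
  realization. The dispersion moderation brings the test to that intrinsic
  limit, not beyond it.
* Genome-coordinate (spliced) coverage is not modeled; the pipeline
  standardizes on transcriptome alignments.
* The simplified shrinkage prior is normal; strongly heavy-tailed effect
  distributions will be over-shrunk relative to adaptive-tail methods.
* Exact numerical agreement with external DE frameworks is a non-goal; the
  package demonstrates calibration and recovery by simulation instead.
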