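---
title: "Methods: conservation-acceleration scoring and clock dating of novel ORF regions"
author: "norfevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation-acceleration scoring and clock dating of novel ORF regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Novel open reading frames (nORFs) are transcribed — and sometimes translated —
regions of a genome that carry no prior annotation, arising from intergenic or
intronic sequence. Whether such regions evolve neutrally, are conserved, or
are accelerated relative to the neutral expectation is the central question
this package addresses, together with a second one: how old is the divergence
of a given nORF locus between two species under a strict molecular clock?

The package implements the full desk-scale analysis chain for a multi-species
whole-genome alignment (the motivating system is a five-cichlid alignment with
*Oreochromis niloticus* as reference):

1. **Neutral model** — extract four-fold-degenerate (4D) third codon
   positions from reference CDS annotations and fit a general time-reversible
   (REV) substitution model with branch lengths by maximum likelihood
   (`extract4dColumns()`, `fitNeutralModel()`).
2. **CONACC scoring** — for every alignment column, an all-branches
   likelihood-ratio test of a single rate-scale parameter against the neutral
   model, reported as a signed, base-wise conservation-acceleration score
   (`siteLRT()`, `scoreAlignment()`).
3. **Feature comparison** — map scores onto feature classes (CDS, UTRs,
   introns, intergenic, ancestral repeats, nORF classes), compare
   distributions by ECDF and Welch *t*-test, and run a length-matched
   ancestral-repeat resampling significance procedure
   (`mapScores()`, `welchT()`, `runResampling()`).
4. **Clock dating** — Bayesian strict-molecular-clock estimation of node ages
   on a fixed topology with a lognormal fossil calibration
   (`runClockMCMC()`, `tmrca()`).
5. **Simulation** — a generator of synthetic alignments with known
   region-wise rate multipliers and of strict-clock sequence sets with known
   node ages (`simulateAlignment()`, `simulateClockSequences()`,
   `defaultCichlidScenario()`), which makes every stage testable without
   external data.

# Models and statistics

## Substitution models

Base order is (A, C, G, T) throughout. A REV model is parameterized by
stationary frequencies $\pi$ and six symmetric exchangeabilities
$r_{ij}$, giving $Q_{ij} = r_{ij}\pi_j$; HKY85 is the special case with one
transition/transversion ratio $\kappa$. Every $Q$ is normalized so that
$-\sum_i \pi_i Q_{ii} = 1$: branch lengths are expected substitutions per
site. Transition probabilities are computed by eigendecomposition of the
symmetrized matrix $\mathrm{diag}(\sqrt{\pi})\,Q\,\mathrm{diag}(1/\sqrt{\pi})$,
which has a real spectrum for any reversible model; eigenvalues are clamped
at 0 (their analytic maximum) so that round-off can never produce divergent
probabilities at long branch lengths.

## Pruning likelihood

Column likelihoods are computed by Felsenstein pruning in compiled code, with
per-node renormalization against underflow. Gaps and `N` are treated as
missing data and marginalized (a fully missing column has probability 1).
A rate scale $\rho \ge 0$ multiplies all branch lengths; $\rho = 0$ is the
analytic no-substitution limit, which the score optimizer must be able to
reach for perfectly conserved sites. The implementation is cross-checked in
the test suite against `phangorn::pml` (an independent pruning
implementation) and against brute-force total-probability sums.

## 4D extraction and the neutral fit

Four-fold degeneracy is judged from the **reference species codon only**
(the convention of the standard alignment tooling this replaces): third
positions of the families CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN. Minus-strand
CDS are read reverse-complemented; codons that straddle alignment-block
boundaries are dropped rather than stitched — stitching would require
cross-block gap reconciliation for a negligible gain in sites at genome
scale. The hard-coded family table is verified in the tests against a
brute-force enumeration of the standard genetic code.

The fit maximizes the pruning likelihood over branch lengths and five free
exchangeabilities (one fixed at 1) with **empirical base frequencies** taken
from the 4D columns themselves, which mirrors the cited workflow and removes
three dimensions from the optimization. Optimization is multi-start (3)
BFGS on log-transformed parameters, relative tolerance $10^{-6}$, branch
lengths floored at $10^{-8}$. For a reversible model the two root-adjacent
branches are identifiable only through their sum (the pulley principle); the
fitter therefore estimates the sum and reports it split 50:50, and recovery
experiments use generating trees with an even root split so the comparison is
exact.

## CONACC scores

For a column $c$, let $\hat\rho$ maximize the likelihood over
$\rho \in [0, 20]$ (golden-section search, tolerance $10^{-6}$, single scale
shared by all branches — the "all branches" test). The statistic is
$\Lambda = 2(\log L(\hat\rho) - \log L(1)) \ge 0$ with p-value from the
$\chi^2_1$ upper tail, and the signed score is

$$\mathrm{CONACC} = \begin{cases} -\log_{10} p & \hat\rho < 1 \text{ (conservation, positive)}\\ +\log_{10} p & \hat\rho > 1 \text{ (acceleration, negative)}\\ 0 & \hat\rho = 1. \end{cases}$$

Scores are capped at $|{\cdot}| \le 20$ so WIG output stays finite when p
underflows. Columns with fewer than 2 non-missing taxa (configurable) are
unscored and simply absent from the track.

**Boundary behaviour.** Because $\rho \ge 0$ is tested against an interior
null with an unadjusted $\chi^2_1$ reference (matching the cited tool's
default rather than the statistically purer ½χ²₀+½χ²₁ mixture), null
p-values are conservative: under neutral simulation the fraction of sites
with $p < 0.05$ falls at or below 0.05. The calibration test therefore checks
a one-sided band, $0 < \widehat{\Pr}(p<0.05) \le 0.05 + 3\,\mathrm{SE}$.

## Feature mapping and the resampling procedure

Scores are held as width-1 `GRanges` and mapped to intervals with
`findOverlaps`; a site may belong to several classes, and intervals with no
scored site are flagged unmapped and excluded from distributions (the
attrition the study reports). A region-level score is the **mean of the
per-site scores** in the region — the aggregation consistent with the small
region-level values the study tabulates.

The resampling procedure draws, per iteration, one length-matched ancestral
repeat (AR) per nORF target — uniformly among ARs within
$\max(20\ \mathrm{bp},\ 10\%)$ of the target length, nearest-length fallback
with a warning — pools the drawn ARs' per-site scores, and Welch-*t* tests
them against the pooled per-site scores of the targets; the result is the
count of significant iterations out of `nIter` at $\alpha = 0.05$ (no
multiple-testing correction, matching the reported raw counts). The Welch
test uses pooled per-site scores rather than per-region means: the study
tests "distributions of CONACC scores", and with only 9 target regions a
test on region means would be severely underpowered relative to the reported
outcome. Per-iteration RNG substreams are derived from the seed by counter,
so results are reproducible and independent of iteration order.

**A statistical caveat.** With one fixed target set, per-iteration p-values
share the target sample and are therefore correlated across iterations: the
fraction significant, given one target draw, is not Binomial(`nIter`, α)
around α even under the null. Marginally over target draws the procedure is
calibrated, so the calibration test redraws the null target set across
independent batches. The power property (accelerated targets vs neutral ARs)
is insensitive to this because the per-iteration tests are then essentially
always significant.

## Strict-clock dating

Node ages of a fixed rooted topology are sampled by Metropolis–Hastings. The
likelihood is the pruning likelihood on the clock tree with branch lengths
$r \times (\text{parent age} - \text{child age})$, HKY with empirical
frequencies and fixed $\kappa$ (default 2), and a fixed clock rate $r$ in
substitutions/site/MY — the caller must state it, since a strict clock with a
fossil calibration is only meaningful with explicit units. A per-locus rate
multiplier (default 1) lets callers encode a known departure from the neutral
rate for a locus. The prior is a Yule density over ages,
$\lambda^{n-1} e^{-\lambda L}$ with $L$ the total tree duration and the birth
rate $\lambda$ sampled under a broad exponential hyperprior (rate 0.01/MY) by
default, times a lognormal calibration density on the age of one designated
MRCA. The calibration is parameterized by **real-space moments**:
$\sigma^2 = \ln(1 + (s/m)^2)$, $\mu = \ln m - \sigma^2/2$, so a mean of
45.5 MY and sd of 0.5 MY in real space are reproduced exactly by the
lognormal's moments. Only the designated MRCA is calibrated; all other ages
float, so locus trees can place uncalibrated nodes well above or below the
calibration, which is the structural behaviour the study's per-locus tables
show.

Operators: uniform age slide within the (max child age, parent age) window,
a Gaussian root-age walk, a whole-tree age scaler (with the $s^{k}$ Jacobian),
and a log-walk on $\lambda$; root and scale step sizes are auto-tuned toward
a 20–40% acceptance rate during burn-in. Prior-only sampling — the mechanism
behind the calibration-recovery checks — is a zero-column alignment whose
likelihood is identically 1. Note that the sampled marginal of the calibrated
age is the calibration density *times the Yule factor*, as in standard
Bayesian dating software; at the 45.5/0.5 calibration the tilt this induces
is an order of magnitude below the Monte-Carlo error of the runs used here.

# The synthetic-data generator

`simulateAlignment()` draws an ancestral sequence from the model's stationary
frequencies and evolves it down the tree by sampling child states from
$P(t \cdot \rho_{\text{site}})$ site-wise — exact marginally and faster than
event-level simulation, since no within-branch history is needed. Regions of
a `RegionPlan` tile a single synthetic reference chromosome and each carries
its own rate multiplier $\rho$. Codon-structured regions avoid stop codons in
the ancestor (per-codon rejection) and evolve third positions of
4-fold-family codons (judged on the ancestral codon) at $\rho = 1$ while
other positions evolve at the region's $\rho$ — so 4D extraction finds
genuinely neutral sites. Output goes through the same MAF/BED/WIG plumbing as
real data, split into blocks of at most 10 kb to exercise block-boundary
handling, with a JSON truth manifest for parameter-recovery tests.

`defaultCichlidScenario()` fixes the study conditions the package is
validated under:

* five taxa with the accepted cichlid topology; branch lengths derived once
  from a strict-clock argument — node ages 45.5 / 30 / 18 / 8 MY and a
  neutral rate of 0.002 substitutions/site/MY (within the range of fish
  neutral rates), giving a tree of total length ≈ 0.29 substitutions/site;
* a REV model with AT-rich, fish-like frequencies (0.31, 0.19, 0.20, 0.30)
  and transition-biased exchangeabilities;
* 12 protein-coding genes (CDS at $\rho = 0.3$, codon-structured; UTRs at
  0.7; introns at 0.9, three per gene), 220 ancestral repeats with a
  lognormal length distribution and intergenic background at $\rho = 1$,
  9 nORF-intergenic regions at $\rho = 2$ and 27 nORF-intronic regions at
  $\rho = 0.5$ — the mapped region counts of the motivating study.

What the generator deliberately does **not** emulate: indels and alignment
error (no gap process), GC-isochore or rate heterogeneity along the genome,
selection on specific sites within a region, and assembly/liftover artifacts.
Passing tests therefore demonstrate the correctness and calibration of the
statistical machinery under the stated generative model, not robustness of
the biological conclusions to alignment quality — on real data the unscored
fraction and the AR definition are the places such artifacts enter.

Because AR and intergenic background share $\rho = 1$, their score means tie
in expectation; the qualitative ordering checks treat intergenic as the tied
neutral class and compare AR against the constrained classes.

# Problem sizes and numerical choices

The validation suite runs at desk scale, chosen as the package's own
experiment design: neutral-fit recovery on 10,000 simulated 4D columns under
a tree with branches 0.12–0.3 substitutions/site (where the per-branch
relative standard error of the MLE is comfortably below the 10% check);
null-calibration on 10,000 columns; resampling calibration on 100 independent
null batches of 5 iterations and power at 1,000 iterations; and 20 clock
replicates of 3,000 sites with chains of 6×10⁴ single-parameter moves
(retaining ≥ 10,000 prior-only samples for calibration recovery at chains of
2–3×10⁵). Degenerate inputs are defined behaviour: all-missing columns are
unscoreable markers, not errors; a column set with no variation drives branch
lengths to the 10⁻⁸ floor; equal-length ties in the resampler are broken
uniformly at random from the seeded stream; optimizer searches are boxed
(log-parameters within [−21, 14]) to keep BFGS away from numerically
degenerate corners.

# Known limitations

* No rate heterogeneity across sites (by design — the motivating analysis
  assumed none) and no codon or amino-acid models.
* The LRT p-value uses the unadjusted $\chi^2_1$ reference; near-null sites
  have conservative p-values (documented above, and accounted for in the
  calibration band).
* Only the sum of the two root-adjacent branch lengths is estimable; the
  reported 50:50 split is a convention, not an estimate.
* The dating module fixes topology and clock rate; it estimates ages only,
  and the calibrated node's marginal includes the Yule tilt.
* MAF support covers `a`/`s` lines (the alignment content); `i`/`q`/`e`
  annotations are ignored on read and not reproduced on write.
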