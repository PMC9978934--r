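---
title: "Methods: models and design choices in indigoferm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in indigoferm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indigoferm)
```

`indigoferm` analyses bacterial succession in alkaline indigo (*sukumo*)
fermentation and links it to the vat's dyeing capacity. This vignette is the
package's own account of the models it implements, the parameters that
matter, and the design decisions taken where the methodology was genuinely
open. The README shows the user-facing workflow; here we explain what the
numbers mean.

## The dyeing phenotype

Dyeing capacity is scored from a dipped cloth swatch as the Euclidean norm
of its mean CIELAB colour, `sqrt(L*^2 + a*^2 + b*^2)`. Conversions assume
the scanner-standard pipeline: sRGB decoding with the IEC 61966-2-1
piecewise gamma, linear RGB → XYZ under D65 with the 2° observer, XYZ →
CIELAB against the D65 white. Two choices deserve note:

* **Averaging happens in Lab space** (after per-pixel conversion), not in
  sRGB, because the score is defined on L\*, a\*, b\* values. Averaging raw
  sRGB first is available via `score_image(average = "srgb")` for
  sensitivity analysis; the two differ only when the swatch is non-uniform.
* **Masking is a central crop** (`border_fraction`, default 0.15), because
  scanned swatches carry an undyed margin. No segmentation is attempted;
  the generator's `render_swatch()` emulates exactly this geometry (a light
  frame around a uniform interior), so the round trip render → score is a
  testable contract (colour error below ΔE 0.5 at zero texture noise; the
  residual error is 8-bit sRGB quantisation).

Out-of-gamut colours are clamped to the nearest representable sRGB value
and flagged; ΔE here is always the plain CIE76 Euclidean distance.

## Community metrics

Relative abundance divides each sample by its read total. The "Others"
aggregation retains a taxon iff its **maximum** proportion over the samples
in the table is at least the cutoff (default 0.041, i.e. 4.1 %) — the
"reaches the threshold in *any* sample" reading, applied separately per
analysis window (early, days 1–7; late, days 10–209), since a taxon
prominent in one phase need not be prominent in the other. The boundary is
inclusive: exactly 4.1 % is retained. Mass is conserved exactly; the
dropped taxa are summed into one `Others` row.

Alpha diversity is computed at a fixed rarefaction depth (default 8,825
reads). Rarefaction draws **without replacement** (multivariate
hypergeometric, realised as sequential hypergeometric draws), and each
sample's metric is the average over `replicates` draws (default 10; how
many draws the original workflow averaged is not documented, so the count
is exposed). Samples shallower than the depth are excluded with a warning
rather than resampled. Per-sample RNG substreams are derived from the
master seed and the sample id, so adding a sample never changes another's
draws. The Shannon index uses log base 2; the analytic expected richness
`E[S] = Σᵢ [1 − C(N−Nᵢ, d)/C(N, d)]` (evaluated in log space to avoid
overflow) provides the independent check that the Monte-Carlo mean
converges where it should.

## Redundancy analysis

The community matrix is Hellinger-transformed (`sqrt` of proportions) by
default before RDA — the standard way to make Euclidean ordination sensible
for closed compositional data; `method = "none"` is available to probe
sensitivity. Environmental constraints are standardized to zero mean and
unit variance. Wheat bran enters as a decaying pulse covariate,
`Σ_events exp(−(t − t_event)/τ)·1[t ≥ t_event]` with τ = 30 days,
reflecting that a bran addition is consumed within about a month — so a
sample's bran exposure is the superposition of all pulses it has seen.

`fit_rda()` is implemented from the definition: column-centre Y and X,
project (`Ŷ = X(XᵀX)⁻¹XᵀY` via QR), and eigendecompose `ŶᵀŶ/(n−1)` (via
SVD) for the constrained axes, with residual axes from `Y − Ŷ`. Collinear
constraint columns are dropped with a warning. Scores follow the
species-focused scaling-2 convention, and each axis's sign is fixed by
making its largest-magnitude species loading positive, so outputs are
reproducible across linear-algebra backends. The variance decomposition
(constrained + residual = total, within 1e−8) and agreement with both a
brute-force projection oracle and vegan's `rda()` are asserted in the test
suite. Permutation significance testing is deliberately omitted.

## Co-occurrence networks

Edges are Spearman rank correlations between per-taxon abundance series
over a fermentation period, kept when |rs| > 0.6 **and** p < 0.05 (both
strict, matching the stated thresholds; rs = 0.6 exactly is not an edge).
rs is the Pearson correlation of average ranks (ties get mean ranks). The
p-value is exact — full enumeration of the n! permutations of one rank
vector — for n ≤ 8, which covers both study windows (7 and 6 samples), and
a t approximation (`t = rs·√((n−2)/(1−rs²))`, n−2 df) beyond. At small n
the exact null is very coarse (at n = 4 even rs = 1 has p = 1/12), which is
the statistically honest behaviour; the t approximation would overstate
significance there. Constant series are skipped with a warning rather than
assigned rs = 0.

Whether the source workflow correlated abundance *levels* or day-to-day
*changes* is ambiguous ("relative content change trend"); both are
implemented (`mode = "level"` default, `mode = "diff"` behind a flag). Two-
sided p-values are used, sidedness being unstated. No multiple-testing
correction is applied, mirroring the published procedure. Node weight is
the taxon's abundance accumulated over the period's samples.

## Predicted metagenome and the phenotype screen

Given a taxon × KO copy-number table, the predicted metagenome is pure
arithmetic: the contribution of taxon t to gene family k in sample s is
`abundance(t,s) × copies(t,k)`; KO totals are sums over taxa, and the
stratified table retains the per-taxon records (conservation is exact and
tested to 1e−9). Hidden-state prediction of genome content is out of scope
— the package consumes PICRUSt2's `pred_metagenome_unstrat` /
`contrib.legacy` layouts bit-compatibly, or the generator's synthetic
content.

Subpathway abundances sum member KOs, with a KO mapped to k subpathways
counted fully in each; unmapped KOs are collected under `unclassified`.
Ratio screens between two samples keep subpathways with ratio strictly
above 1.05; zero denominators are reported separately as undefined, never
silently retained or dropped.

The KO–phenotype screen correlates **within-batch first differences**
between consecutive sampled days of (per-sample-normalised) KO abundance
against differences of dyeing intensity, pooled across batches, and keeps
KOs with Pearson r ≥ 0.69 (inclusive). Rationale for the defaults, all
switchable:

* *Differences, not levels* (`mode = "diff"`): the screened quantity is
  stated as *changes* in intensity against *changes* in KO abundance;
  differencing also removes the shared monotone trend that would otherwise
  make every late-rising gene family correlate.
* *Pearson, not Spearman*: the source analysis names Spearman explicitly
  for networks but only "correlation coefficient" here; the contrast
  motivates Pearson as the default.
* *Consecutive-sample pairing regardless of gap*: sampling is irregular
  (daily early, sparse late); pairs are formed between consecutive sampled
  days within a batch, whatever the calendar gap.
* *Per-sample normalisation of KO columns* before differencing, so read-
  depth variation does not masquerade as functional change.

KOs with zero variance are skipped. The oxidoreductase filter then keeps
hits whose annotation has at least one EC number in class 1.\* **and** an
explicit NAD(P)-dependence flag; NAD(P)-dependence is not mechanically
derivable from EC strings or descriptions (uronate dehydrogenase,
EC 1.1.1.203, carries no "NAD" token), so it is resolved from a packaged,
editable annotation table (`ko_annotations()`). Unannotated hits surface in
a separate bucket rather than disappearing. Day-over-day contribution
ratios use sentinel statuses: 0 → positive is a "new appearance" (infinite
ratio), 0 → 0 is "absent".

## The synthetic fermentation generator

The generator exists so every downstream stage can be tested end to end
against known ground truth. It emulates the study design: four batches
differing in pretreatment (25/60 °C, tap water vs wood-ash extract, giving
starting pH 9.7–11.2), pH maintained in [9.67, 11.2] by Ca(OH)₂ additions,
1 g wheat-bran pulses on days 5/19/51/85/194, 26 °C, sampling daily on days
1–7 then sparsely to day 209, and read depths of 10⁴–10⁵.

**Environment.** pH falls by a daily acid-production increment (default
0.3 ± 0.05 pH/day) and is reset to the ceiling the day it would cross the
floor (flagged as a Ca(OH)₂ event) — a sawtooth, like real maintenance. ORP
follows a sigmoid from +100 mV to a −550 mV plateau with midpoint day 1.5
(the study reports the qualitative shape but prints no ORP numerals in the
text, so the scale is a package choice, fully configurable). Three
substrate pools decay exponentially: labile *sukumo*-derived matter (τ = 6
d), dead cells from the pretreatment kill-off (τ = 12 d), and bran (τ = 30
d, pulsed).

**Community.** A seeded discrete-time multiplicative (replicator-type)
update rather than ODE integration — the simplest model that produces
realistic turnover. Log-fitness per taxon and day is a sum of a Gaussian pH
kernel, a signed logistic ORP term, affinity-weighted substrate terms, a
self-density penalty, and Gaussian noise; abundances are renormalised daily.
The default catalog (40 taxa, 8 indigo reducers) spans early aerobes,
facultative taxa and alkaliphilic obligate anaerobes, with initial
abundances favouring aerobes (the inoculum is aerobically composted).

Two calibration choices matter and were made once, as the generator's
definition of the study conditions:

* *Reducers are the dedicated bran degraders* (bran affinity 0.85–1 versus
  0–0.3 for everyone else). Pulsed-then-decaying bran therefore drives
  reducer share — and hence the dye phenotype — up and down across the
  sparse late samples, as bran addition does in the real system.
* *Strong self-limitation* (`density_penalty = 14`) stabilises coexistence,
  so shares track their current environmental optimum instead of drifting
  to fixation; without it, cyclic selection drives reducers extinct over
  200 days and the late phenotype signal dies with them.

**Genome content and phenotype.** Copy numbers are sparse (a KO is present
in a taxon with probability 0.1, carrying 1 + Poisson(1) copies). The five
planted causal KOs follow the biology of a phenotype-causing gene family:
every reducer carries `enrichment` (default 10) + Poisson copies, while
non-reducers carry the gene only rarely (leak probability 0.05). The dye
intensity is `baseline + (saturation − baseline)·logistic(slope·s)` of the
causal signal `s = Σ_k Σ_t abundance × copies`, plus Gaussian noise. Since
`s ≥ 0`, only the upper half of the logistic is reachable; the default
slope 0.05 keeps the whole trajectory inside the responsive region so the
phenotype neither saturates immediately nor pins to the floor. The noise SD
defaults to **10 % of the dynamic range of the noise-free signal series**
(the signal-processing meaning of dynamic range); an absolute `noise_sd`
can be given instead. Emitted L\*, a\*, b\* lie along a fixed indigo-like
direction (dark, slightly red, strongly blue, b\* < 0) whose norm equals
the intensity to 1e−6.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no mechanistic indigo/leuco-indigo chemistry or
thermodynamic ORP modelling; no 16S copy-number bias, chimeras, primer or
compositional sequencing artefacts beyond multinomial resampling; no
strain-level genome variation; taxon "ecology" is four kernels, not
metabolism. Recovery of planted causal KOs demonstrates that the screen's
arithmetic and thresholds behave as specified under the stated noise, not
that r ≥ 0.69 would isolate causal genes in a real fermentation, where
confounding between co-succeeding taxa is far stronger.

## Seeds and determinism

Every stochastic function takes a seed and restores the caller's RNG state.
Substreams are derived from the master seed by stable string hashing of
stage and batch/sample labels, so adding a batch, sample or stage never
perturbs the randomness of existing ones; identical configuration and seed
reproduce every table byte-identically (asserted in the tests).

## Problem sizes and numerical tolerances

The test and acceptance workloads use the scaled study design: 3–4 batches,
13–14 sampled days, 40 taxa, 300 KOs, 5 planted causal KOs, with 20
replicate seeds for the recovery experiment — sizes chosen to exercise
every code path while keeping a full run in seconds. Tolerances follow the
quantity's arithmetic: exact conservation laws are asserted at 1e−9–1e−12,
linear-algebra agreement at 1e−8, Monte-Carlo means within 3 standard
errors of their closed forms, and colour round trips at ΔE 0.5 (the 8-bit
quantisation budget). Threshold boundaries are asserted on constructed
exact cases: 4.1 % retained (≥), rs = 0.6 excluded (>), ratio = 1.05
excluded (>), r at the screen threshold retained (≥).

## Known limitations

* RDA omits permutation tests, partial/db-RDA and CCA by design.
* The Spearman exact p is conditional on the observed tie pattern; for
  n > 8 with heavy ties the t approximation is the only option offered.
* The colorimetry module assumes sRGB without ICC profile handling or
  illumination correction, and scores with CIE76 (no ΔE2000).
* The pipeline's subpathway screen on synthetic data uses a synthetic
  KO→subpathway map; real analyses should supply a curated map via
  `read_pathway_map()`.
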