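---
title: "Models and methods for clonal succession analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for clonal succession analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonesucc)
```

# The scientific question

Serial xenotransplantation of lentivirally marked pancreatic cancer cells
asks whether long-term tumor growth is driven by a fixed, self-renewing
hierarchy of long-term tumor-initiating cells (LT-TICs, the classical
cancer stem cell picture) or by a *succession* of transiently active TIC
clones that produce mostly non-tumorigenic progeny and are replaced by
formerly dormant clones in later generations. Each transduced cell carries
a unique vector integration site (IS) inherited by all daughters, so the
IS read table of a tumor is a census of the clones that actively produced
tumor cells. This package implements the stochastic growth model, the IS
table processing, the succession statistics, the clone-number inference
and the limiting-dilution estimator needed to run that analysis — plus a
synthetic-data generator so that every stage is testable without any
external data.

# Clone growth: the Yule process

Cell proliferation within a clone is modeled as a linear birth (Yule)
process: every cell divides independently at a constant rate
$\lambda$ over a growth period $T$. Starting from one founder cell, the
clone size $Z(T)$ is geometric on $\{1, 2, \dots\}$:

$$P(Z(T) = k) = q\,(1-q)^{k-1}, \qquad q = e^{-\lambda T},$$

with mean $e^{\lambda T}$. Only the product $\lambda T$ is identifiable
from end-point data, so all inference is parameterized by $q$. There is no
cell death in the model, and engraftment times are taken as simultaneous —
the simplest model consistent with identical division rates. `yule_size_pmf()`
and `yule_size_sample()` implement the closed form; `gillespie_yule()` is
an independent event-driven simulator kept solely as a distributional
oracle in the tests (total-variation distance and chi-square agreement at
$10^5$ draws).

# Observation model

A tumor of $N$ cells is dissociated; a fraction $f$ of cells (3–30% in the
emulated design) is used for IS analysis. Sampling is per-cell binomial
thinning — at tumor sizes vastly exceeding sample sizes this is
indistinguishable from exact without-replacement sampling, and the
generator's multinomial cell allocation (IS aliquot, daughter inocula,
remainder) conserves cells exactly while keeping the same marginals. An IS
call is valid only if its relative read abundance reaches the cutoff
$c$ (default 0.06% of total sequence counts). For the analytic detection
probability the read share of a clone is approximated by its sampled-cell
share, so a clone of size $Z$ is detected iff its sampled count
$S \sim \mathrm{Bin}(Z, f)$ satisfies $S \ge \max(1, \lceil c f N \rceil)$;
sequencing (multinomial read) noise is applied only in the synthetic-data
generator, keeping the analytic `detection_probability()` separate from
sequencing artifacts. The probability is computed by direct summation over
$Z$ with the geometric tail (where detection is within $10^{-12}$ of
certain) added in closed form.

One numerical subtlety: because the detection bar
$\lceil c f N \rceil$ is an integer, $p_{\det}$ is *not* globally monotone
in $f$ — it rises within each constant-bar stretch and drops where the bar
jumps. The supremum machinery below therefore scans $f$ exactly at the bar
breakpoints in addition to a uniform grid, which is what makes the
grid-refinement consistency check pass honestly.

# The synthetic serial-transplantation experiment

`simulate_serial_experiment()` generates a full primary → secondary →
tertiary experiment: marking of $\lfloor N_{\text{cells}} \cdot
\text{eff}\rfloor$ founders with unique genomic coordinates (uniform over
hs37d5 chromosome lengths; no integration-preference model), binomial
engraftment of marked cells in the primary recipient, growth, exact
multinomial allocation of each tumor's cells, and two enzyme-replicate
read tables (TSP509I/MSEI) with per-replicate IS dropout, mirroring the
dual-enzyme LAM-PCR protocol whose union enlarges coverage.

Clone *activity* is the package's operationalization of transient TIC
bursts. It is a clone-intrinsic state — dormant, active, or exhausted —
advanced once per transplant epoch and shared across sibling recipients:

* **succession** (default): an active clone is exhausted with probability
  `p_inactivate` per epoch; a dormant clone activates with probability
  `p_activate`; exhausted clones never return. An active clone's
  contribution to a tumor regrows from a single re-initiating cell, and an
  exhausted clone's transplanted bulk dies out in the recipient — this is
  what makes a formerly dominant clone vanish below the 0.06% cutoff
  instead of lingering as passively transferred biomass, and it makes the
  probability that a dominant clone is detected again in the next
  generation equal $1 - p_{\text{inactivate}}$.
* **hierarchy**: only an `ltic_fraction` of clones can drive growth, and
  they do so every generation — the classical stem cell alternative.
* **stochastic**: every clone is active in each generation independently
  with probability `p_activate` (memoryless contribution).

Defaults were chosen once to emulate the study's stated design and to land
the summary statistics in the reported bands, and are treated as the fixed
study conditions thereafter: $10^5$ cells transplanted at transduction
efficiency 0.6 (study range 0.355–0.975); per-cell primary engraftment
probability 0.003 (within the study's inferred 0.0069–1.56% band and
giving ≈180 engrafted clones against the reported 96–302 upper bounds);
$\lambda T = 12$ so active clones expand ~$1.6\times 10^5$-fold and a
purified tumor is a few $10^6$ cells; $f = 0.1$, cutoff 0.06%, read depth
$10^4$ per enzyme, enzyme dropout 0.05; 40% of cells re-transplanted per
daughter mouse (study: 33–50%), two daughters per tumor, three
generations. The activity rates are not measured quantities anywhere;
`p_inactivate = 0.75` is pinned to the reported 75% of dominant clones
never detected in another generation, and `p_activate = 0.06` was
calibrated once so that primary tumors detect a median of ~10 IS (reported
band 4–16) and generation exclusivity sits near the reported 78%.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: integration-site selection preferences,
mouse-cell contamination, PCR amplification bias beyond multinomial read
noise, genetic subclone evolution, microenvironment or spatial effects,
and inter-patient variability. One known mismatch is the detected-once
fraction: the generator yields ~0.8 against the reported 49%, because with
clone-intrinsic states a persisting clone is seen in every sibling tumor,
whereas the real data contain more partial sharing; matching that
additional dispersion would require a per-recipient activity component the
study gives no handle to calibrate.

# IS table processing

The pipeline order is fixed and is part of the contract: merge enzyme
replicates (union of calls, summed counts) → apply the relative-abundance
cutoff (shares against pre-filter totals, hence idempotent) → remove
collisions → build the contribution matrix (per-tumor renormalization,
genomic row order). Merging before thresholding maximizes sensitivity, in
line with the dual-enzyme protocol's purpose; the tests carry a regression
fixture showing the two orders genuinely differ.

A *collision* is the same genomic coordinate observed in independent
experiment lineages — a cross-contamination signature, since independent
transductions cannot share an exact insertion coordinate. Only
below-cutoff collision occurrences are removed; at-or-above-cutoff
occurrences are retained as their lineage's own signal, and within-lineage
recurrence is never touched. In the canonical order the cutoff has already
removed sub-threshold rows, so `remove_collisions()` acts as a safety net
there; it is meaningful (and tested) on merged, unthresholded tables.
IS identity is an exact (chromosome, position, strand) match — junction
uniqueness at base-pair resolution is the premise of the assay — with no
fuzzy matching window.

# Succession metrics

All metrics are set algebra on the detection matrix plus the generation
annotation: distinct IS counts per scope; the fraction of IS detected in
exactly one generation; detected-once fractions (per-generation variants
are denominated over the IS detected in that generation); the fraction of
dominant clones (contribution ≥ 50% in some tumor) whose detections are
confined to a single generation; the fraction of serial-tumor IS already
detected in the experiment's primary tumor; and sibling-pair overlaps.
The overlap denominator is the union (Jaccard) by default because the
published 0–13% range names no denominator; `denominator = "smaller"`
exposes the other reading, and the prior-generation fraction likewise
follows the most direct reading (share of serial-tumor IS seen in the
primary).

# Clone-number inference with nuisance suprema

The number of detected IS in a tumor is modeled as
$K \sim \mathrm{Bin}(n, p_{\det}(q, f))$ with $n$ the unknown number of
engrafted clones. Both $q$ and $f$ are treated as unobservable nuisance
parameters living in a confidence rectangle; the identity of the two
nuisance parameters is this package's choice, made explicit here. For
every grid node the exact binomial CDF is inverted in $n$ (the largest $n$
with $P(K \le k \mid n, p) \ge \alpha_{\mathrm{bin}}$), and the bound is
the supremum over the grid — attained at the minimal $p_{\det}$, scanned
at the cutoff-bar breakpoints as described above, with a doubled-resolution
refinement pass that must not move the supremum by more than $10^{-3}$
(relative). The total error budget is split Bonferroni-style between the
rectangle and the inversion (default 0.5/0.5, configurable via
`alpha_split`). The construction is conservative; the tests verify ≥ 99%
empirical coverage over $n \in \{10, 100, 300\}$ across a grid of true
$(q, f)$ values, and the exact identity $n_{\mathrm{upper}} = k$ at
$p_{\det} = 1$. Dividing $[k, n_{\mathrm{upper}}]$ by the number of marked
cells transplanted gives the seeding-efficiency percentage interval.

Three homogeneity hypotheses are tested with supremum p-values over the
same kind of grid, Monte-Carlo calibrated at each node (a p-value that is
a supremum over nodes is conservative wherever the rectangle covers the
truth; the tests verify type-I error at most $\alpha$ plus two Monte-Carlo
standard errors, and nontrivial power, under forward simulation):

* **Equal proliferation within a tumor.** Read shares are converted to
  sampled-cell counts (rounding half to even; per-IS cell counts are
  unobservable, and this reconstruction is the approximation that makes
  the count model usable). The statistic is the log-likelihood ratio of a
  saturated per-clone geometric model against a common geometric fit; the
  null is a parametric bootstrap of detection-conditioned counts at each
  node.
* **Constant growth across a transplantation step.** The statistic is the
  multinomial deviance between observed daughter shares and the parent
  shares propagated through binomial transplant thinning and common
  growth. The null simulation resamples *both* aliquots — the parent
  observation is itself a noisy sample, and conditioning on it as exact
  makes the test sharply anticonservative (type-I error near 0.5 in
  simulation); resampling the parent restores calibration.
* **Equal seeding.** Under a common per-cell rate $s$, a clone with $t$
  transplanted cells engrafts with probability $1-(1-s)^t$. Conditional on
  the number of engrafting clones, label sets are resampled by successive
  weighted sampling with the odds implied by $s$ (for $s \to 0$, sampling
  weighted by clone size), with a centered two-sided Monte-Carlo p-value
  for the size–engraftment association, supremized over a grid of rates
  around the moment-matched estimate.

Monte-Carlo seeds derive from the root seed by adding the grid-node index,
so every p-value is bit-reproducible. The default grid for the bound is
25 × 25 with refinement; the Monte-Carlo tests default to a 5-point axis
(recorded in the result) — at 2,000 bootstrap replicates per node this
keeps a full three-test analysis in seconds while the supremum, not the
grid density, carries the conservativeness.

# Limiting dilution

The single-hit Poisson model $P(\text{tumor} \mid d) = 1 - e^{-\theta d}$
is fitted by maximizing the binomial log-likelihood in $\log\theta$
(`optimize` on a wide bracket; the complementary log-log GLM with log-dose
offset is kept as an independent oracle in the tests, never as the
implementation). The printed "1 in $N$" frequency is $1/\hat\theta$
rounded half away from zero; the 95% CI uses the observed information on
$\log\theta$, the convention of the standard limiting-dilution tools.
All-negative tables give an infinite denominator, all-positive tables a
flagged boundary fit; input tables are taken at face value (mice excluded
before assay end are assumed already removed from the counts).
`compare_groups()` is the 1-df likelihood-ratio test of a common versus
separate $\theta$; its chi-square reference is asymptotic, and at four
mice per dose the discrete null makes it mildly anticonservative
(~0.08 at nominal 0.05 in simulation), so the calibration test uses twenty
mice per dose where the asymptotics hold.

# Problem sizes and reproducibility

The package's own validation runs at these sizes, chosen as the smallest
that make the Monte-Carlo margins meaningful: $10^5$ draws for sampler
agreement; 1,000 replicates per cell of the coverage grid; 500 null
experiments (199 bootstrap replicates on a 3-point grid axis) per
homogeneity test; 50 + 50 experiments for the scenario contrast; 300
two-generation experiments for the dominance-persistence rate. Every
stochastic routine consumes the global RNG, and the experiment-level
`seed` makes whole simulated experiments byte-identical.

# Known limitations

The growth model has no death, latency or slowdown; activity transitions
are per-epoch Bernoulli with no dependence on clone size or age; the
detected-once fraction of the generator overshoots the reported value (see
above); the reported 96–302 clone bounds and 0.0069–1.56% seeding
efficiencies used per-tumor inputs not printed in the main text, so the
package validates the bound's coverage property rather than those
endpoints; and the collision rule assumes lineage labels are correct —
mislabeled tumors would masquerade as collisions.
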