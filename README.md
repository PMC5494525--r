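# clonesucc

Clonal succession analysis for lentivirally marked serial xenotransplants.

Pancreatic cancer xenografts can be grown, dissociated and re-transplanted
over several mouse generations while every transduced cell carries a unique
lentiviral integration site (IS) inherited by all its daughters. The IS
read table of a tumor is therefore a census of the clones that actively
produced tumor cells, and the way IS patterns change across generations
distinguishes two organizations of the tumor-initiating cell (TIC)
compartment: a fixed, self-renewing hierarchy of long-term TICs versus a
*succession* of transiently active clones that burn out and are replaced by
formerly dormant ones. This package is for researchers analysing such
clonal-tracking experiments (or stress-testing their design by simulation).

## What it implements

* **Clone growth model.** A Yule (linear birth) process: every cell divides
  at rate λ for a period T, so a clone founded by one cell has geometric
  size, P(Z = k) = q(1−q)^(k−1) with q = exp(−λT) and mean exp(λT).
  Engraftment of transplanted marked cells is per-cell Bernoulli; detection
  of a clone is subsampled (fraction f of cells) and thresholded (read
  share ≥ 0.06% by default). `detection_probability()` gives the composite
  per-clone detection probability p_det(q, f).
* **IS table processing.** Merge dual-enzyme LAM-PCR replicates, apply the
  relative-abundance cutoff, remove cross-lineage collisions, and build an
  IS × tumor contribution matrix (`process_is_records()`).
* **Succession statistics.** Generation-exclusive fractions, detected-once
  fractions, dominant-clone persistence, prior-generation fractions,
  sibling overlaps (`succession_summary()`).
* **Inference.** With K ~ Binomial(n, p_det(q, f)) and (q, f) scanned over
  a nuisance confidence rectangle, `upper_bound_total_clones()` inverts the
  exact binomial CDF in n and takes the supremum over the grid — a
  conservative upper confidence bound on the number of engrafted clones,
  convertible to a seeding-efficiency interval. Three homogeneity tests
  (equal proliferation within a tumor, constant growth across a
  transplantation step, equal seeding) report supremum p-values over the
  same rectangles, Monte-Carlo calibrated at each node.
* **Limiting dilution.** Single-hit Poisson maximum likelihood,
  P(tumor | dose d) = 1 − exp(−θd), reported as the conventional
  "1 in 1/θ" TIC frequency with a likelihood-ratio group comparison
  (`fit_single_hit()`, `compare_groups()`).
* **Synthetic experiments.** `simulate_serial_experiment()` generates full
  three-generation experiments with ground truth under succession,
  hierarchy and stochastic scenarios, emulating the study design
  (transduction efficiency, 3–30% sampling, 33–50% re-transplantation,
  dual-enzyme read tables).

## Worked example

```r
library(clonesucc)

cfg <- simulation_config(seed = 42)          # succession scenario defaults
rec <- simulate_serial_experiment(cfg)

grouping <- setNames(rec$design$experiment, rec$design$tumor_id)
cm  <- process_is_records(rec$is_tables, grouping,
                          tumor_order = rec$design$tumor_id)
ann <- generation_annotation(rec$design)
succession_summary(cm, ann)
#> Distinct IS: 34
#> Generation-exclusive IS: 82.4%
#> Detected once: 82.4% overall (gen1: 70%; gen2: 60%; gen3: 71%)
#> Dominant (>=50%) clones confined to one generation: 0.0%
#> Serial-tumor clones already in primary: E1: 11%
#> Sibling overlap: 20-30%
```

Most IS are confined to one generation and only 11% of serial-tumor clones
were already active in the primary tumor — the succession signature. Now
bound the number of clones that actually engrafted behind the 10 IS
detected in the primary tumor, treating growth (q) and the effective
sampling fraction (f) as nuisance parameters:

```r
rect <- nuisance_rectangle(q_interval = c(exp(-13), exp(-11)),
                           f_interval = c(0.05, 0.2))
primary <- rec$design$tumor_id[rec$design$generation == 1]
k <- sum(cm$detected[, primary])
bound <- upper_bound_total_clones(k, rect, cfg$plan,
                                  tumor_size = rec$truth[[primary]]$total_cells)
bound
#> Upper 99% confidence bound on engrafted clones: 12 (observed IS: 10, p_det in [0.977, 0.9969])
seeding_efficiency(bound, nrow(rec$founders))
#> Seeding efficiency: 0.01667% - 0.02% of 60000 transplanted marked cells
```

And a limiting-dilution fit (doses 10^4 … 1 cell, positives 4/4, 4/4, 3/4,
2/4, 0/4):

```r
fit_single_hit(lda_table(c(1e4, 1e3, 1e2, 10, 1), rep(4, 5), c(4, 4, 3, 2, 0)))
#> TIC frequency: 1 in 47 cells (95% CI 1 in 18 - 1 in 124)
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/clonesucc.R` (`simulate`, `filter`, `metrics`, `lda`, `run`
subcommands); `run_pipeline()` drives the whole chain with JSON reports
and a provenance manifest.

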