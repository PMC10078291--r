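# kineticnet

Temporally resolved gene regulatory networks from kinetic chromatin
accessibility (ATAC-seq) and nascent transcription (PRO-seq) time
courses.

Rapid cellular transitions — differentiation cascades, hormone
responses — unfold as successive waves of transcription-factor (TF)
activity over minutes, far faster than conventional expression
profiling can resolve. `kineticnet` integrates replicated accessibility
and nascent-transcription measurements over a dense early time course
(seven points across 0–240 min by default) into a bipartite directed
network in which every edge is a concrete, time-stamped molecular
claim:

* **trans-edges** (TF family → regulatory element): inferred binding or
  dissociation events, called when a peak carrying the family's motif
  changes accessibility significantly in the direction implied by the
  family's chromatin function (opener/closer), during a window in which
  family members are expressed (and, for factors not directly activated
  by the stimulus, transcriptionally induced or repressed beforehand);
* **cis-edges** (regulatory element → gene): regulatory relationships
  called when the element and a nearby gene (≤ 10 kb, and within the
  factor's empirically estimated actionable distance) covary in
  accessibility and transcription over the same time interval.

Around this core the package provides:

* a negative-binomial Wald test for differential accessibility /
  transcription with median-of-ratios normalization and
  method-of-moments dispersion shrinkage, plus deterministic assignment
  of dynamic peaks to five kinetic classes (immediate / transient /
  gradual increase, transient / gradual decrease);
* log-odds PWM scanning with exact p-values from a dynamic-programming
  convolution of the discretized score distribution, motif-density
  composites around peak summits, and opener/closer assignment from
  single-motif dynamic peaks;
* pause-summit, pause-index and composite-profile computation from
  strand-specific signal tracks;
* actionable-distance estimation from the plateau of the difference
  between distance CDFs of dynamic vs unchanged genes, with a
  permutation test;
* a two-compartment model of RNA polymerase II occupancy
  (`dP/dt = k_init − (k_pre + k_rel) P`,
  `dB/dt = k_rel P − (k_elong/L) B`) whose steady state converts pause
  and gene-body densities into rate-constant fold-changes and pause
  residency times;
* stratified 2×2 factor-cooperation tables with Woolf odds-ratio
  confidence intervals;
* a synthetic time-course generator with planted ground truth (kinetic
  classes, motifs, edges, rate fold-changes) used to validate the whole
  pipeline end to end.

## Worked example

Simulate a complete data set with planted truth, run the pipeline, and
inspect the network and the compartment-model fit:

```r
library(kineticnet)

cfg <- sim_config(seed = 7)        # 150 peaks, 100 genes, 6 TF families
ds  <- simulate_dataset(cfg)
res <- run_pipeline(ds, seed = 7)

res$network
#> <kinetic_network> 263 trans-edges (62 REs, 6 families), 433 cis-edges (51 genes)

glance(res$fit)   # fold-changes fitted for the pause-release factor's targets
#> # A tibble: 1 × 7
#>   n_base_sets f_init f_init_min f_init_max f_rel f_rel_min f_rel_max
#>         <int>  <dbl>      <dbl>      <dbl> <dbl>     <dbl>     <dbl>
#> 1         520   2.00       1.78       2.01  1.50      1.50      1.50
```

The fitted `f_rel = 1.50` recovers the planted 1.5-fold pause-release
increase for those genes exactly, and `f_init ≈ 2.0` the planted
initiation change; the narrow range across 520 admissible base
parameter sets illustrates that the *fold-changes* are identified even
though the absolute rates are not.

Applying a 1.50-fold pause-release increase to a gene paused with a
29-second residency time (premature termination negligible):

```r
p  <- rate_params(k_init = 10, k_pre = 0, k_rel = 60/29)
steady_state(p)$residency_sec                    # 29 s
p2 <- apply_fold_changes(p, f_rel = 1.5)
steady_state(p2)$residency_sec                   # 19.33 s
```

Each analysis stage is also exposed directly (`differential_series()`,
`classify_kinetics()`, `scan_pwm()`, `pause_metrics()`,
`plateau_distance()`, `infer_trans_edges()`, `infer_cis_edges()`,
`downstream_reach()`, `cooperation_odds()`, …), takes a tibble first and
returns a tibble, and the main result types have `autoplot()`, `tidy()`
and `glance()` methods.

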