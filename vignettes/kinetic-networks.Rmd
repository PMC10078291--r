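---
title: "Kinetic regulatory networks: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic regulatory networks: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kineticnet)
```

This vignette is the package's own account of the science it
implements: the statistical models, the edge-inference rule sets, the
two-compartment polymerase model, what the synthetic generator does and
does not emulate, and the choices made where the design was genuinely
open.

## The data and the problem

A kinetic experiment measures chromatin accessibility (ATAC-seq peak
counts) and nascent transcription (PRO-seq signal over pause regions
and gene bodies) at closely spaced time points — by default seven
points over the first four hours of a stimulus, with three replicates
each. Changes in accessibility at a peak carrying a factor's motif are
evidence of that factor binding or leaving; changes in a nearby gene's
nascent transcription over the same interval are evidence of a
regulatory consequence. The package turns these joint observations into
a bipartite directed network whose edges carry time intervals, so
regulatory waves can be ordered and traversed.

## Differential testing and kinetic classes

Counts are normalized by median-of-ratios size factors: for sample $j$,
$s_j = \mathrm{median}_i \, (x_{ij}/g_i)$ with $g_i$ the geometric mean
of feature $i$ across samples, over features positive everywhere. Note
that only the *ratios* of size factors are invariant when one library
is rescaled — the per-feature geometric means absorb a share
$c^{1/m}$ of the change — which is the property normalization actually
relies on.

Each pair of time points is tested per feature with a
negative-binomial Wald test on the log2 ratio of normalized group
means. Dispersion is estimated by method of moments,
$\hat\alpha_i = \max(0, (s_i^2 - \hat\mu_i)/\hat\mu_i^2)$, and shrunk
50/50 on the log scale toward a log-linear trend of dispersion on mean —
a deliberately simple, monotone, documented stand-in for the empirical
Bayes machinery of dedicated count packages, which this package does
not try to reproduce numerically. A +0.5 continuity term on the group
means keeps zero-count groups finite. P-values are Benjamini–Hochberg
corrected within each comparison.

Peaks with at least one significant comparison are dynamic and receive
one of five kinetic classes by deterministic rules rather than model
clustering, so class labels are reproducible and seed-free:

* the **onset** is the endpoint of the earliest significant comparison
  against baseline (falling back to interior comparisons when no
  baseline comparison is significant); an onset at the first
  post-baseline point is *immediate*, later onsets *gradual*;
* a class is **transient** when a significant reversal follows the
  onset *and* the final level returns within 50% of the maximal
  excursion from baseline.

This yields immediate/transient/gradual increase and transient/gradual
decrease (a sustained decrease with immediate onset folds into the
gradual-decrease class, keeping five dynamic classes). Borderline
trajectories near the 50% return criterion are the known soft spot of
any such rule; the threshold is exposed as `return_fraction`.

## Motif scanning

PWMs are scored as log2 odds against a uniform background, with a
pseudo-probability of $10^{-3}$ keeping zero entries finite (a
probability-1 consensus base therefore scores 1.996 rather than 2 bits
per position). P-values are exact: per-position scores are discretized
onto a 1000-step lattice spanning the full score range, the lattice
distributions are convolved across positions, and the tail probability
of the observed lattice score is reported; both strands are scanned and
hits at $p \le 10^{-4}$ (the standard genome-scanning regime) are
returned. `N` bases contribute the background odds (score 0). The test
suite checks this machinery against full enumeration of all $4^L$
background words.

Motif-density composites weight each hit by its *score fraction*
(score over the maximum achievable score) — the package's concrete
choice for "conformity to the composite motif", which has no canonical
formula — and divide by the number of peaks in the class. Family
function is assigned from dynamic peaks carrying exactly one family's
motif: more than half in increase classes makes the family an opener,
more than half in decrease classes a closer, ties stay unassigned and
are skipped downstream. Note a dissociating activator (SP-like) is
*observed* as decrease-associated in this analysis even though its
molecular function is opening; the rule configuration carries both
facts separately.

## Edge-inference rules

Trans-edges require: (1) the RE is an accessibility peak; (2) the
family motif is present; (3) accessibility changes significantly over
the interval; (4) the direction matches the family's function (binding)
or opposes it (dissociation); (5) family members are expressed at the
relevant end of the interval — above the 25th percentile of nonzero
gene body densities at that time point, a configurable floor chosen
because no published cutoff exists — and, for families not directly
activated by the stimulus, a family gene must be significantly
activated (binding) or repressed (dissociation-by-depletion) no later
than the edge start; (6) stimulus-activated ("cocktail") families are
exempt from the transcriptional gate only for baseline edges in their
immediate-response window (0–20 min; 0–40 for the steroid-receptor
family, whose binding window ends at 40 min and whose later
accessibility losses become dissociation edges, provided a binding edge
preceded them). Only the steroid-receptor-like and SP-like families
emit dissociation edges; later reversals at other factors' REs are
treated as attenuation rather than dissociation, which matches the
narrative the defaults encode and avoids inventing dissociation events
from single noisy reversals.

Cis-edges require: a peak-to-gene-body gap of at most 10 kb; a
TSS-to-summit distance within the factor's CDF-derived limit; a
significant gene call whose interval overlaps a trans-edge interval at
the RE (closed-interval intersection on minutes — a strict-equality
switch is available, since "over the same time range" is ambiguous
between the two readings); sign consistency between every contributing
family's implied effect and the gene's direction; and the gene being
dynamic in at least one comparison where the factor showed significant
proximity signal. Factors with no significant proximity signal draw no
cis-edges — the conservative reading.

The actionable distance itself is the smallest distance at which
$\Delta(d) = \mathrm{CDF}_{dyn}(d) - \mathrm{CDF}_{unch}(d)$ reaches
99% of its maximum, evaluated on a 500-bp grid to 200 kb, with
significance from a label-permutation test (default 1,000 permutations;
200 inside the pipeline, where many factor × comparison combinations
are tested). The plateau criterion is this package's formalization of a
visually described levelling-off; 99%-of-max with a fixed grid is
monotone and tolerance-controlled.

Attenuation marks an edge whose RE or target gene later shows a
significant change of opposite sign (interval starting no earlier than
the edge's end). When summarizing attenuation fractions, judge each
RE–gene link once (its earliest interval); per-row fractions over all
call intervals are diluted by long baseline comparisons.

Time-respecting reach from a gene node traverses its family's
trans-edges and onward cis-edges, admitting an edge only if its
interval starts no earlier than the arrival interval's start, with
label-correcting updates so a node reached earlier can re-expand.

## The two-compartment polymerase model

$$\frac{dP}{dt} = k_{init} - (k_{pre} + k_{rel})\,P, \qquad
  \frac{dB}{dt} = k_{rel}\,P - \frac{k_{elong}}{L}\,B$$

$P$ is the polymerase count in the 50-bp pause region, $B$ the count in
the body of length $L$; $k_{init}$ (polymerases/min) is initiation,
$k_{pre}$ premature termination, $k_{rel}$ pause release, $k_{elong}$
(bp/min) elongation. The first-order body-exit term is the minimal
closure consistent with the steady state
$P^\ast = k_{init}/(k_{pre}+k_{rel})$,
$b^\ast = k_{rel}P^\ast/k_{elong}$ and residency
$\tau = 1/(k_{pre}+k_{rel})$ that the residency- and initiation-rate
arithmetic implies; it is a modeling choice, stated prominently.
$k_{pre} = 0$ is admissible (and is the fitted regime for
pause-release-driven activation). Measured time points are treated as
steady-state snapshots when fitting; transient fitting is available via
the integrator.

Fitting fold-changes between two snapshots holds $k_{pre}$ and
$k_{elong}$ fixed and solves, for each admissible base parameter set,
$f_{rel} = b_2 k_{elong}/(k_{rel} P_2)$ and
$f_{init} = P_2(k_{pre} + f_{rel}k_{rel})/k_{init}$. Because two
snapshots constrain four rates, the base sets consistent with the first
snapshot form a two-dimensional manifold; the default grid therefore
*constructs* exactly consistent sets from a $(k_{pre}, k_{elong})$ grid
($k_{pre}$ log-spaced over two decades plus 0; $k_{elong}$ linear,
600–6000 bp/min) and solves $k_{rel}, k_{init}$ from the snapshot,
keeping sets inside two-decade rate ranges. A user-supplied explicit
grid is instead filtered at a 1% relative tolerance on both $P^\ast$
and $b^\ast$. Identifiability: $f_{rel}$ is identical for every base
set; $f_{init}$ is exact at $k_{pre}=0$ and spreads by up to
$\rho\,|1 - 1/f_{rel}|$ across base sets with $k_{pre}/k_{rel} = \rho$
— the fold-changes are narrow even though the absolute rates are not,
and the ratio $k_{pre}/k_{rel}$ itself cannot be determined from two
occupancy snapshots. `tidy()` exposes the full per-set distribution so
this spread is never hidden behind a point estimate.

## The synthetic generator

`simulate_truth()` builds one chromosome with genes every 25 kb (gene
bodies 8 kb), so that at most one gene lies within the 10-kb cis rule
of any planted element — nearest-gene assignment is unambiguous by
construction. Six TF families mirror a stimulus-response program:
two immediate openers and a transiently bound opener activated directly
by the stimulus, a transcriptionally induced opener (gradual), a
transcriptionally induced closer acting 20–60 min whose elements
recover (transient decrease), and a repressed opener whose elements
lose accessibility from 40 min on (dissociation). The dissociating
opener's elements are planted promoter-proximal (≤ 250 bp of the TSS),
reflecting its promoter-restricted divergent-transcription signature
and short actionable range; other families place summits within 2.5 kb
of their target TSS. Each dynamic peak carries its family's consensus
at the summit (±3 bp); background sequence is scrubbed of accidental
consensus occurrences so the planted truth is self-consistent with the
inference rules — recovery in the noiseless limit is exact, by design.

Accessibility follows fixed class trajectories (3-fold excursions);
counts are negative binomial with shared dispersion 0.05 and
per-replicate log-normal library sizes (sd 0.15) around a baseline mean
of 100 — the variance structure of the real counts is not published,
so NB with shared dispersion is this package's stated assumption.
Nascent transcription is generated from the compartment model:
baseline $k_{init}$ log-normal over roughly two orders of magnitude
(median 8 polymerases/min; TF-family member genes pinned at 25, well
above the expression floor), $k_{rel} = 2$/min (30-s residency),
$k_{pre} = 0.02$/min, $k_{elong} = 2500$ bp/min. Activated targets get
$f_{init} = 2.5$ on their interval (the pause-release factor's targets
$f_{init} = 2.0, f_{rel} = 1.5$, so their pause index drops by 1/1.5),
repressed targets $f_{init} = 0.4$. Signal tracks are noiseless
densities — a uniform pause peak at TSS+35..85, uniform body signal,
and an antisense promoter peak at half the pause density — while the
pause/body *counts* carry NB noise.

What the generator does **not** emulate: read-level artifacts (GC and
Tn5 bias, duplicates, mappability), fragment-length structure, multiple
chromosomes, overlapping genes and shared enhancers, distance-dependent
regulatory strength, combinatorially bound elements in the default
program, and motif degeneracy (planted sites are exact consensus, so
scanning recall is not stressed). Passing the recovery tests therefore
demonstrates the correctness and self-consistency of the inference
machinery at realistic noise, not performance on real genomes.

## Problem sizes and numerical choices

The validation suites run at sizes chosen to exercise every code path
with stable statistics: the default program uses 150 peaks / 100 genes
(60 planted dynamic elements), module tests use 72 peaks / 60 genes;
edge recovery is pooled over 20 seeds; the rule engine is compared with
an independent brute-force applicator on 50 random instances of up to
200 elements; the closed form is checked against `deSolve` integration
(relative tolerance $10^{-6}$, horizon 25 relaxation times) on 1,000
random parameter sets; odds-ratio coverage uses 2,000 simulated tables
at $n = 200$ per stratum. At these sizes the per-factor proximity test
can genuinely lack power (the dynamic-gene class pools all factors'
targets), so occasionally a factor contributes no cis-edges in a run;
pooled recovery stays well above the documented bounds and the
limitation disappears with scale.

Other numerical details: score-lattice resolution 1000 bins; Wald
continuity term +0.5 on group means; dispersion floor $10^{-8}$ before
log-scale shrinkage; pause summit ties broken toward the TSS; gene-body
window for the pause index starts 250 bp past the summit (no published
window exists; 250 bp clears the pause shoulder); genes with zero body
density have undefined pause indices and are excluded from summaries;
the divergent-peak caller (both strands above threshold within 300 bp,
minus upstream of plus) is a labeled simple heuristic, not a substitute
for SVM-based detection on real data.

## Known limitations

Per-comparison BH correction is applied within each of the 21 pairwise
tests, as specified; across comparisons a null peak has multiple
chances to be called, so the dynamic set is anticonservative at small
scale (precision of downstream edges is protected by the motif,
window, and gate rules, as the recovery suites measure). The
opener/closer dichotomy cannot represent factors with mixed function.
The compartment model assumes steady state at each measured point and
constant $k_{elong}$ and $k_{pre}$ between points; genuinely transient
dynamics between snapshots are invisible to the fit. Real-data
headline quantities that depend on genome-scale inputs (tens of
thousands of elements) are out of reach of the desk-scale synthetic
program and are not asserted anywhere.
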