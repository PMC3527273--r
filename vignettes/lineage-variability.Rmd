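---
title: "Quantifying stress-induced variability and epigenetic memory in lineage trees"
author: "lineagevar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stress-induced variability and epigenetic memory in lineage trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagevar)
```

## The problem

Time-lapse microscopy of a micro-colony grown from a single bacterium
yields, after segmentation and tracking, a *lineage forest*: every cell's
parentage, lifetime, and per-frame measurements (length, position,
reporter intensities). Under sub-inhibitory antibiotic stress such colonies
differentiate — sibling cells diverge in stress-reporter expression and
growth, up to the point where whole sub-lineages arrest and die while their
cousins thrive. Three quantitative questions follow:

1. **Is the variability structured by lineage?** (differentiation)
2. **Did the divergence begin before the stress was applied?**
   (pre-disposition)
3. **How long is a cell's state remembered by its descendants?**
   (epigenetic memory)

`lineagevar` implements the statistics for all three on a validated
`LineageTree` container, and a stochastic simulator that generates
realistic tracking data so the whole pipeline is testable without
microscopy.

## Differentiation: SLCV versus IDCV

At a start time $s$ the colony has $N_s$ cells; at $t > s$ it has
$N_t = \sum_i n_i$ cells, grouped by their ancestor alive at $s$. With
group means $\bar x_i$ and grand mean $\bar x$ (simple mean over all $N_t$
cells),

$$\mathrm{IDCV} = \frac{1}{\bar x}\sqrt{\frac{\sum_{i,k}(x_i^k - \bar x)^2}{N_t - 1}},
\qquad
\mathrm{SLCV} = \frac{1}{\bar x}\sqrt{\frac{\sum_i n_i(\bar x_i - \bar x)^2}{N_s - 1}}.$$

The SLCV estimator is the $n_i$-weighted between-group mean square,
normalized like a CV. Two printed constraints pin this choice down: without
differentiation the between-group mean square estimates the same variance
as the all-cell sample variance, so the two curves coincide; and at
$s = t$ every group is a singleton and SLCV reduces to IDCV *exactly* (an
identity the test suite asserts on random fixtures). An unweighted variant
(plain variance of group means) is available via `weighted = FALSE`.

Two subtleties worth knowing:

* Expectation equality holds for the *squared* statistics. The square
  root's small-sample bias differs between the two (chi distributions with
  $N_s-1$ versus $N_t-1$ degrees of freedom), so with few sub-lineages the
  raw SLCV sits a few percent below IDCV even under the null; the property
  test therefore compares the squared forms.
* Dead (arrested) cells stay in the population until the record ends, as
  they do in micro-colony images; only censored cells drop out. Whether to
  keep arrested cells in growth-rate CVs is not settled experimentally; we
  keep them.

Curves over time for several starting sizes come from
`variationCurves()`; with multiple colonies, curves are averaged per
time point — cells are never pooled across colonies.

## Pre-disposition

For every division node that completed before stress induction,
`nodeProgenyTest()` compares the phenotype values of the two sisters'
descendant groups at a later time with a Welch (unequal-variance) t-test —
the safe default for unequal sub-lineage sizes; the pooled test is a flag
away. Significance of the observed tree is calibrated two ways:

* `randomizedNodeTest()` pools both groups and re-assigns members at
  random (original sizes, without replacement) 500 times; re-assignment
  destroys any lineage effect, so the significant fraction converges to
  $\alpha$ regardless of the data — a genuinely differentiated node is one
  whose *observed* test is significant while its re-assignment null stays
  at $\alpha$.
* `treeProbability(n, k, p)` gives the chance of $k$ significant nodes
  among $n$: by default the literal combinatorial product
  $\binom{n}{k} p^k$ (reproducing the printed figure-of-merit; the omitted
  $(1-p)^{n-k}$ factor is negligible at $p = 0.02$), with an exact
  binomial tail as the alternative mode.

The direction of each significant event records whether the sister that
was brighter gave rise to the more stressed progeny group. A sister's "own
brightness" is its lifetime-mean intensity: at the division instant both
daughters inherit the mother's concentration, so the birth frame alone
carries no sister-specific information — the asymmetrically partitioned
damage shows up in the reporter over the sister's life. `biasBinomialTest()`
tests the pooled directions against a fair coin, one-sided by default
(the stated hypothesis is directional). No multiple-testing correction is
applied across nodes; the tree probability and the bias test are the
combining devices.

## Epigenetic memory: the lineage autocorrelation

`lineageAF()` correlates a cell's phenotype at $s$ with its descendants'
phenotype once the colony has advanced $g$ colony-stage generations
(stage $= \lfloor \log_2 N \rfloor$, the axis used because cells
desynchronize under stress). Pairs are descendant-weighted (every cell
alive at the later frame contributes one pair); an ancestor-averaged
variant exists, and the two coincide on balanced trees. Points supported
by fewer than `minPairs = 16` pairs are dropped — correlation estimates
on smaller samples fluctuate too wildly to be useful.

`fitHalflife()` fits $\log_2 \mathrm{AF}$ against $g$ by least squares,
using only points with $\mathrm{AF} > 0.1$ (near-zero or negative
correlations carry no information about the decay rate and would wreck the
log), and returns $-1/\mathrm{slope}$ in generations.

The yardstick is the linear birth–dilution model
(`linearModelHalflife()`): a product made at constant rate, diluted at
$\ln 2 / T_d$, degraded at $d$ and amplified by a linearized feedback gain
$b$ relaxes at $\gamma = \ln2/T_d + d - b$, so its lineage autocorrelation
has half-life $\ln 2/\gamma$. With a stable product and no feedback this
is exactly one doubling time; as $b$ approaches the total removal rate the
half-life diverges. A fitted half-life of several generations is therefore
direct evidence for a positive feedback with near-critical gain.

## The simulator

`simulateTree()` grows a colony from one founder under coupled
per-cell dynamics, integrated by Euler–Maruyama at one tenth of the frame
interval with division checked every substep:

$$\dot D = u_0(1+\beta S)D_{\mathrm{out}} - kD, \quad
\dot S = \sigma_s D k + s_0 - (k + d_S) S,$$
$$\dot F = \alpha_0 + \alpha_1 \frac{S^h}{K^h + S^h} - kF + \eta\sqrt{F}\,\xi(t), \quad
k = \frac{k_{\max}}{1 + (S/K_g)^m},$$

plus exponential elongation $\dot L = kL$ and an optional passive
co-reporter $\dot F_2 = u_0(1+\beta S)A_{\mathrm{out}} - kF_2$. Drug $D$
enters at a permeability that rises with damage $S$ (the positive
feedback); damage is produced in proportion to drug times translation
(which scales with growth), diluted by growth and cleared at $d_S$
(chaperone/protease repair); the reporter $F$ is damage-induced with
multiplicative $\sqrt F$ noise (keeping $F \ge 0$ with the mean–variance
scaling of bursty expression; an additive mode would lose both); growth is
damage-inhibited. At division the volume splits at a truncated-normal
fraction $q$ and every species' molecule content is partitioned
*binomially* with success probability $q$ at a configurable
molecules-per-unit scale, so daughters' contents sum exactly to the
mother's. Cells whose growth rate stays below `deathRateFloor` for
`arrestDuration` minutes are marked arrested: they stop dividing but
remain in the record, like dead cells in images.

Defaults mirror the experimental setting: 23-min doubling time, frames
every 90 s, stress switched in when the colony reaches 8 cells (the switch
time is recorded even when the drug level is zero, so unstressed controls
share the time axis), colonies followed to 256 cells unstressed. Two
measurement-level parameters emulate microscopy artifacts without touching
the dynamics: multiplicative length noise (segmentation error, 0.5%) and a
soft intensity saturation (detector ceiling; off by default).

### What the presets encode

* **null** — no drug. Constant stochastic production diluted by steady
  growth: SLCV tracks IDCV, and the autocorrelation half-life is one
  generation — the linear model's prediction, which the acceptance suite
  verifies on 200 colonies.
* **stressed** — *calibrated, not measured*. The paper-level parameter
  values behind the original microscopy are unknown, so the preset was
  tuned once so that the stressed regime shows its qualitative signatures
  simultaneously: a bimodal growth-rate distribution with a dead
  sub-population clustered in sub-lineages, SLCV rising well above IDCV
  after induction (collapsing back under lineage randomization), a
  negative growth–expression correlation, and an autocorrelation half-life
  of three or more generations. The mechanism chosen is the linear
  near-critical one: the feedback loop gain
  $u_0 \beta \sigma_s D_{\mathrm{out}} \approx 0.023\,\mathrm{min}^{-1}$
  sits just below $k_{\max} = 0.030\,\mathrm{min}^{-1}$, giving a slow
  heterogeneous damage drift whose leading tail crosses the
  growth-inhibition knee and arrests. Damage is partitioned coarsely
  (8 molecules per unit), because rare, unevenly segregated damage
  aggregates are what seeds sub-lineage divergence. We deliberately did
  not use a bistable-escape geometry: with a linear uptake term a robust
  low state, a fast runaway and near-critical slowing cannot coexist (the
  production line can cross the removal curve only twice), and strongly
  bistable variants produce rare pre-induction runaway cells whose
  ancestry the randomization is not allowed to move. The record lasts
  300 min, the duration of the stressed experiments.
* **stressed_coreporter** — the membrane-permeability read-out analog:
  mild drug exposure of growing cells with the passive co-inducer channel
  on. With feedback, cells that take up more drug also accumulate more
  co-inducer and the two reporters correlate; with $\beta = 0$ the
  correlation vanishes. This preset intentionally avoids the
  growth-arrest regime: where cells die, both reporters correlate
  trivially through arrested dilution, which would not test the
  permeability mechanism.

### What the generator does and does not emulate

It reproduces lineage topology, realistic growth and division timing,
heritable expression states, stress-induced fate bimodality, and
measurement-level artifacts. It does not model cell shape or mechanics
(centroids come from a crude packing rule adequate only for
border-distance controls), nutrient gradients, explicit
ribosome/chaperone pools, recovery of arrested cells, or the unstressed
*positive* growth–expression correlation seen experimentally (which
reflects growth-coupled global expression outside this minimal model —
unstressed simulated colonies show no growth-rate variation to correlate
with). Passing tests on simulated data therefore validate the statistical
machinery and the feedback mechanism, not any quantitative claim about
real colonies.

## Numerical choices and degenerate inputs

* Time is minutes everywhere; a division instant belongs to the mother's
  end and the daughters' births; population counts never double-count the
  instant.
* Growth rates are least-squares slopes of log length over a centered
  5-frame window (7.5 min at 90-s cadence); windows never straddle a
  division. On exact exponentials the estimator is exact for any window.
* Promoter activity is reconstructed as $dF/dt + kF$ (central
  difference) — the standard dilution correction; treat it as this
  package's definition of the quantity.
* The growth-rate threshold separating live from dead is the
  equal-posterior point of a two-component Gaussian mixture; the fit is
  rejected (manual threshold required) if the component means are closer
  than the pooled component SD *or* the fitted mixture has no density
  antimode between the means — forcing two components onto unimodal data
  otherwise fabricates a threshold.
* The switch randomization cannot preserve the child-birth = mother-end
  identity when same-generation cells are born minutes apart; randomized
  trees carry a flag that relaxes exactly that one validity check, and
  ancestor queries on them walk by birth time.
* Border membership uses convex-hull vertices of centroids — a good
  approximation for near-convex colonies; with fewer than three cells all
  distances are zero.
* `fitMoments()` matches simulated reporter moments to targets by damped
  multiplicative coordinate descent with common random numbers across
  iterations (the objective would otherwise be too noisy to descend).

## Problem sizes used in the checks

The acceptance analyses use 200 unstressed colonies of 256 cells for the
null memory half-life (autocorrelation curves averaged in cohorts of four
colonies, the experimental averaging unit, before fitting), six stressed
colonies of up to 2000 cells for the stressed half-life and variation
ratios, 100 node-level resampling nulls of 500 re-assignments each, and
two colonies per co-reporter condition. These sizes give comfortably
stable estimates for every reported quantity while keeping a full run
around one minute.

## Known limitations

Quantities tied to the original microscopy data — the 12-of-15 significant
node count, the exact direction-bias p-value, the position of the
experimental growth-rate threshold — depend on biological parameters the
model does not know and are reproduced qualitatively, not numerically.
The node-level direction bias in simulation is real but weaker than
experimental (damage memory in the minimal model is what the feedback
makes it, and pre-induction nodes more than two generations old carry
little signal). Arrested cells never resume growth, so late "switch-on
and recover" events are absent.
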