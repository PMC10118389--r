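---
title: "Model and methods: CRISPR-phage coevolution in a chemostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CRISPRcoevo)
```

## The model

Bacteria and lytic phages interact in a well-mixed chemostat. Nutrients
flow in at concentration $C_0$ and everything washes out at rate
$F = f\,gC_0$. A bacterium divides at rate $gC$, consuming one nutrient.
A phage meets a bacterium at rate $\alpha$ per pair; every encounter
consumes the phage (adsorption is death for the phage whatever the
outcome). Against a bacterium without a spacer the phage wins with
probability $p_V$, lysing the cell and releasing a burst of $B$ new
phages; a surviving naive bacterium acquires the phage's protospacer as a
CRISPR spacer with probability $\eta$. A bacterium whose spacer matches
the protospacer reduces the phage's success to $p_V(1-e)$, where
$e \in [0,1]$ is the spacer effectiveness; spacers are lost at rate
$r = R\,gC_0$. Each phage carries a single protospacer, a binary word of
length $L = 30$; at each burst every one of the $B\!\times\!L$ offspring
bits flips independently with probability $\mu$, so new protospacer types
arise at per-offspring probability $1-(1-\mu)^L \approx \mu L$. Bacteria
carry at most one spacer.

Default parameters describe *S. thermophilus* in laboratory conditions:
doubling time $1/gC_0 = 41.7$ min, $f = 0.3$, $B = 170$, $p_V = 0.02$,
$\alpha = 2\times10^{-2}/C_0$ per minute, $R = 0.04$ per generation;
$e$, $\eta$, $\mu$ and $C_0$ are the swept axes. Internally all rates are
per minute; "bacterial generations" means $t \cdot gC_0$ and conversions
happen only at the reporting boundary, never inside a formula, which
avoids double-conversion bugs.

Cross-reactivity generalizes the all-or-nothing kernel: with an
exponential kernel the kill probability is $p_V(1 - e\,e^{-d/\theta})$ at
mutational (Hamming) distance $d$; with a step kernel it is $p_V(1-e)$
for all $d \le \theta$. $\theta = 0$ recovers the all-or-nothing case in
every mode.

## Stochastic engines

`gillespieRun()` simulates the jump process exactly and serves as the
oracle; it is practical up to about $C_0 = 10^4$. `tauLeapRun()` advances
by steps $\tau$, drawing per-channel event counts from Poisson laws with
binomial thinning for infection outcomes (kill vs. survive, acquisition
vs. not, mutant vs. parental offspring). The step size is chosen each
step so that the expected number of *consuming* events per species is at
most `epsilon` (default 0.1) times that species' current count, capped at
a quarter generation; if an update would drive any count negative the
step is halved and redrawn up to ten times, after which remaining
negatives are clamped to zero and counted in `clampEvents` (clamps are
absent in practice at the default `epsilon`). The source text we model
does not state a step-size rule or a negativity policy, so these choices
are our own and are validated purely by distributional agreement with the
exact engine (steady-state means of $n_B$ and $n_V$ within combined
standard errors, and a Kolmogorov-Smirnov check on steady-state $n_V$
samples for matched runs).

Each run uses a single seeded generator (`set.seed` at run start);
engine comparisons are distributional, so common random numbers are not
needed. Runs default to the published length rule,
$\max(10^4,\ \mathrm{round}_{1000}(10^4(\log_{10}C_0 - 3)))$ generations
with the steady-state window starting at one fifth of the run, and record
15 evenly spaced full snapshots over that window plus a denser table of
totals. Runs stop early when the phage population hits zero (the
remaining snapshots are simply not emitted) unless
`stopOnPhageExtinct = FALSE`.

Clone bookkeeping is exact where it is cheap: each clone's birth time,
parent protospacer (for phage mutants), extinction time and maximum size
are tracked online, and a type that is re-created after extinction opens
a fresh record. Establishment *times* are resolved against the snapshot
grid by `recordClones()` (first snapshot at or above the threshold), so
their resolution is the snapshot cadence; establishment *fractions* use
the exact maximum sizes. The default threshold is the measured mean clone
size over the steady-state snapshots, with the deterministic
mean-total-over-mean-clone-number as an alternative; which mean the
original analysis used is not stated, and the measured mean is the less
model-dependent choice.

## Mean-field layer

Summing the clone-resolved dynamics gives ODEs for the totals
($n_{Bs}$, $n_V$, $n_{B0}$, $C$) in which immunity enters only through
the population-averaged success probability
$p_{Va} = p_V(1-e_\mathrm{eff})$. Effective immunity $e_\mathrm{eff}$ is
an explicit argument everywhere: the theory passes $e/m$ (exact when all
clones are equal in size), the analysis layer may pass a measured average
immunity instead. Phages persist deterministically iff
$A = (Bp_V-1)(1-f)\alpha/(fg) > 1$, equivalently $p_V > p_{V0}$.

The spacer-bearing fraction $\nu^*$ solves a cubic. Rather than
transcribing printed coefficients (which are typographically fragile), we
eliminate $x^*$, $y^*$, $C^*$ from the steady-state conditions directly:
with $w = 1 - e_\mathrm{eff}\nu$, $q = Bp_Vw - 1$, $K = fg/\alpha$,
$G = (1-f)q - K$ and $H = fq + K$,
$$P(\nu) = \nu w\,(f g C_0 G - r H) + f g C_0 G\left(\tfrac{\hat\eta}{p_V}
 - \nu\big(\tfrac{\hat\eta}{p_V} + 1 - e_\mathrm{eff}\big)\right), \qquad
 \hat\eta = \eta(1-p_V).$$
Clearing the $w$ denominator introduces a spurious root at
$\nu = 1/e_\mathrm{eff}$; the physical root is real, in $[0,1]$, and
satisfies $Bp_V(1-e_\mathrm{eff}\nu) > 1$ so that the bacterial total is
positive. If several roots survive this filter the one continuous with
the $\eta\to0$ branch is returned and multiplicity is flagged. The root
is polished by Newton steps and every composed steady state is verified
against the ODE right-hand side to a relative residual below $10^{-8}$
(in practice $\sim10^{-16}$). Validation anchors: the root equals
$\tilde\nu = 1/(1 + r/(\hat\eta\alpha\tilde n_V))$ as
$e_\mathrm{eff}\to0$, and equals the $\eta = 0$ quadratic factor's root
(0.52406 at defaults) at $e_\mathrm{eff} = 1$.

`nuApproximations()` exposes the dominant-balance closed forms (dropping
the cubic term, the constant term, or both), the low-immunity form whose
denominator changes character at $\eta = 0.0113$ for the default rates,
and the exact $\eta\to0$ leading term. `criticalEffectiveE()` gives the
effective immunity $em^*$ at which the low-immunity denominator vanishes
— of order $10^{-1}$ across the parameter range — where the totals
return to their no-CRISPR values.

## Clone-level theory

A new phage mutant initially escapes all spacers, so its early fate is a
branching process with birth-event rate $\beta_0 = \alpha n_B p_V$
(one phage replaced by $B$), death rate
$\delta_0 = F + \alpha n_B(1-p_V)$ and net growth
$s_0 = \alpha n_B(Bp_V - 1) - F$. Its establishment probability is
$2s_0/(B(s_0+\delta_0))$; `branchingExtinctionOracle()` solves the exact
extinction fixed point $\delta_0 + \beta_0 q^B = (\delta_0+\beta_0)q$ and
the two agree to within 5% whenever $s_0 \le 0.2\,\delta_0$.

The mean extinction time of a large clone is read as
$T_{ext} = 2 n_{Vi}\,(1-\ln(n_{Vi}/n_V)) / ((B-1)(2\beta+\delta))$
minutes; the printed rendering of this expression is ambiguous about the
denominator, and this reading is adopted because at the deterministic
clone sizes the identity
$2\beta + \delta = \alpha p_V n_B (1-e\nu/m)(B+1)$ makes it agree with
the independent approximation
$T_{ext} \approx 2(1+\ln m)(\tilde n_V/m)(1 - 1/(Bp_V))/(f(B-1))$
generations to exactly $O(1/B)$ — kept as a unit test rather than
assumed.

Diversity self-consistency: the steady number of clones must equal the
establishment rate times the clone lifetime,
$m = P_{est}\,\bar\mu\,T_{ext}$ with
$\bar\mu = \alpha B(1-e^{-\mu L})p_V n_V n_B (1-e\nu/m)/gC_0$ new
mutants per generation. `predictDiversity()` solves this on
$m \in [1, 10^4]$ with all totals at $e_\mathrm{eff} = e/m$; when several
crossings exist the largest-$m$ crossing is taken (the branch continuous
with the large-system limit), and when none exists — small systems where
establishment, mutation or clone lifetime are too low — a flagged
`mFound = FALSE` is returned rather than an error. The closed-form chain
approximates $m^3 = a(1+\ln m)$ with
$a \approx 4e\mu L\hat\eta\,(gC_0(1-f))^3/(B^2\alpha^2 p_V^3 r)$, giving
the $(e\mu\eta)^{1/3}$ diversity scaling; the exact-$\tilde\nu$ form of
$a$ is also reported and is several-fold smaller at the defaults because
the large-burst expansion is crude at $Bp_V = 3.4$. The fully reduced
establishment probability
$[2(e\hat\eta\alpha)^2/(\mu L B r^2)]^{1/3}$ (printed corruptly in the
source) is fixed by requiring exact consistency with composing the
steady-state establishment form, $\tilde\nu$, and the closed-form $a$ —
also kept as a test. A warning note is attached when the predicted clone
lifetime is shorter than the spacer-acquisition timescale
(clonal interference at $\eta \lesssim 10^{-5}$), where the
self-consistency argument overestimates diversity.

First acquisition against an exponentially growing clone has density
$P(t) = a\,e^{s_0t}\exp(-(a/s_0)(e^{s_0t}-1))$ with
$a = \alpha\hat\eta n_{B0}$ and mean
$(1/s_0)e^{a/s_0}\Gamma(0, a/s_0)$; the density is evaluated in log
space so the $e^{s_0t}$ factor cannot overflow. The predicted speed of
evolution is $v = 1/T_{ext}$ (one establishment must come from the
leading clone, which happens once per clone lifetime), with the same
closed-form reduction giving $v \propto (e\mu\eta)^{1/3}$.

## Population analysis

Average immunity is the abundance-weighted mean pairwise immunity,
$1 - \sum_{ij} n_{Bi}n_{Vj}p_V(i,j)/(p_V\sum_{ij}n_{Bi}n_{Vj})$; the
naive success probability cancels, so only $e$ and the kernel matter.
With the all-or-nothing kernel labels are matched exactly, which is how
experiment-derived tables (opaque type labels) are handled; cross-reactive
kernels require sequence labels. Time-shifted immunity interpolates both
series linearly onto the minimum sampling interval, averages the
statistic over all pairs at each signed delay, and reports mean, sd and
pair count per delay; head/tail trimming is explicit (the published
recipe drops the first one and last two points of the laboratory
series). When real phages carry many protospacers the raw statistic is
multiplied by a user-supplied protospacers-per-phage scalar (696 and
1956 for the two published datasets); the package never derives this
from data, and multiplied values above 1 are reported as-is with a note.
Turnover is the fraction of types at $t$ still present at $t+\Delta$,
with presence meaning count $>0$ after interpolation.

Clans are single-linkage clusters under the L1 metric cut at distance 2:
groups connected by single-mutation links, merged transitively. Ties in
the signed-rank asymmetry test drop zero differences (the standard
convention, noted because the published comparisons have small $n$).
PCA trajectories normalize compositions per time point, fit axes on the
phage series only, and project both populations. The centre-of-mass
machinery weights each sequence position by abundance; speed uses the
long-interval convention (maximum distance from the ancestor over the
series divided by elapsed time) because distance does not grow linearly
with the interval.

## Synthetic fixture generator

`generateFixture()` emulates the statistical shape of experiment-derived
count tables: exponential clone sizes (rounded, floor 1), a configurable
fraction of bacterial types matched by a phage type, and geometric type
turnover (matched pairs turn over jointly so the overlap fraction is
stationary). Clone sizes are redrawn independently at each time point —
the temporal signal is carried entirely by type identity. It does *not*
emulate real-data features such as sequencing noise, fuzzy 85%-similarity
type grouping, abundance autocorrelation, or coupling between population
size and diversity; tests that pass on fixtures therefore establish the
correctness of the statistics, not their behaviour under those
artifacts.

## Problem sizes and test design

The development-scale checks use $C_0 = 10^3$ (engine cross-validation
over 300 generations, five seeds per engine; theory recovery over the
full published run length of $10^4$ generations) and $C_0 = 10^4$ for
mean-field consistency over 600 generations. At $C_0 = 10^3$ phage
stochastic extinction during the initial transient is common, as the
source model documents for small systems; recovery statistics therefore
condition on runs where phage survive to the end, scanning seeds in
order until five survivors are collected. Measured diversity, average
immunity and the establishment fraction at these conditions agree with
`predictDiversity()` well within the factor-of-two band the full-scale
sweeps report.

## Known limitations

- Single-spacer bacteria and single-protospacer phages; no arrays, no
  priming, no PAM structure, no autoimmunity or fitness costs, no
  spatial structure or immigration (all deliberately outside the null
  model). The array toy models (`arrayImmunity()`, `assortAndScore()`)
  probe multi-spacer questions combinatorially, not dynamically.
- The tau-leap step policy is validated against the exact engine at
  small $C_0$ only; at much larger systems the same leap condition
  applies but has not been cross-checked exactly.
- Establishment times are quantized to the snapshot grid.
- `predictDiversity()` inherits the documented blind spot at very low
  $\eta$ (clonal interference) and flags it instead of correcting it.
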