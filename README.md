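# CRISPRcoevo

Stochastic and analytic models of bacteria with CRISPR adaptive immunity
coevolving with lytic phages in a chemostat, for researchers studying
host–pathogen coevolution, emergent immune diversity, and immune memory
in microbial communities.

## The model

Bacteria divide at rate *gC* by consuming nutrients that flow in at
concentration *C₀*; everything washes out at rate *F = f·gC₀*. Phages
adsorb to bacteria at rate *α* per pair (the phage is consumed either
way) and kill naive bacteria with probability *p_V*, releasing a burst
of *B* offspring. Each phage carries one protospacer — a binary word of
length *L* = 30 — and each offspring bit mutates with probability *μ*.
Bacteria can hold one CRISPR spacer: a surviving naive cell acquires the
attacker's protospacer with probability *η*, a matching spacer cuts
phage success to *p_V(1−e)*, and spacers are lost at rate *r = R·gC₀*.
Optional cross-reactivity kernels (exponential or step in mutational
distance *d*, radius *θ*) soften the all-or-nothing match.

On top of the exact (Gillespie) and tau-leaping engines, the package
provides:

- the deterministic mean-field layer: steady states at a given effective
  immunity, the phage viability index *A = (Bp_V−1)(1−f)α/(fg)* and
  extinction threshold *p_V0*, the cubic for the spacer-bearing fraction
  ν\* with its dominant-balance approximations, and the critical
  effective immunity *em\**;
- clone-level theory: establishment probability
  *2s₀/(B(s₀+δ₀))* with a branching-process oracle, large-clone
  extinction time, effective mutation rate, the diversity
  self-consistency *m = P_est·μ̄·T_ext* and its closed form
  *m³ = a(1+ln m)* (hence *m ∝ (eμη)^{1/3}*), first-acquisition timing,
  and the predicted speed of evolution *v = 1/T_ext*;
- population statistics on clone-resolved abundance tables: average and
  marginal immunity, time-shifted immunity, turnover, single-linkage
  clans, centre-of-mass speed and spread, PCA trajectories,
  Morisita–Horn similarity, and a signed-rank asymmetry test;
- toy models of CRISPR array length versus immunity, and a synthetic
  generator of experiment-shaped paired abundance tables.

## Worked example

Theory first — the full prediction bundle at the default parameters
(*C₀* = 10⁴, *e* = 0.95, *η* = 10⁻³, *μ* = 10⁻⁵):

```r
library(CRISPRcoevo)
p <- simParams(C0 = 1e4, e = 0.95, eta = 1e-3, mu = 1e-5)
theoryBundle(p)
#> TheoryBundle:
#>   A=4.667 (pV0=0.008908); nB~=1500 nV~=2.2e+05
#>   Pest=3.247e-04 muBar=2.847e+01/gen Text=1.546e+03 gen
#>   m(self-consistent)=14.3 m(closed form)=29.7 a=5.97e+03
#>   v=6.468e-04 per gen; em*=0.173
```

Phages are viable (*A* > 1); without CRISPR they would settle at 22·*C₀*
against 0.15·*C₀* bacteria. A new escape mutant establishes with
probability 3.2×10⁻⁴, mutants appear at 28 per generation, and an
established clone persists for ~1500 generations, which balances at
m ≈ 14 coexisting clones turning over at *v* ≈ 6.5×10⁻⁴ mutations per
generation.

Then a stochastic run at a smaller system size, compared with the same
theory:

```r
p3 <- simParams(C0 = 1e3, e = 0.95, eta = 1e-3, mu = 1e-5)
predictDiversity(p3)$m
#> [1] 3.005653
r <- tauLeapRun(p3, tEndGen = 10000, seed = 1)
w <- r@totals[r@totals$tGen >= 2000, ]     # steady-state window
round(c(m = mean(w$mBacteria), nV = mean(w$nV)))
#>     m    nV
#>     3 20411
```

The measured diversity (about 3 clones) and phage total track the
prediction (3.0 and 2.1×10⁴). Converting the snapshots to abundance
series (`asAbundanceSeries(r)`) feeds the analysis layer, e.g.
`timeShiftImmunity()`, whose curve for this run peaks at a negative
delay — bacteria are more immune to phages of the past than of the
future — and decays to zero at large shifts.

A thin command-line wrapper over the same functions ships at
`inst/cli/crispr-coevo.R`
(`simulate | theory | analyze | toy | fixtures`).

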