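---
title: "Person versus situation: methods behind the qvoter package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person versus situation: methods behind the qvoter package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qvoter)
```

## The model

Agents carry a binary state $s_i \in \{0, 1\}$ — unadopted/adopted (or
no/yes).  One *elementary step* draws a target agent uniformly from all $N$
agents and applies one of two behaviours:

* **independence** — with probability $f$ (the *flexibility*) the target
  flips its state, otherwise it keeps it;
* **conformity** — $q$ distinct agents are drawn uniformly without
  replacement from the target's neighbourhood; if (and only if) all $q$
  share one state, the target takes that state.

$q = 4$ by default: a unanimous group of four is the canonical persuasive
unit in conformity experiments, and the unanimity requirement is what makes
this a complex-contagion rule rather than a voter model.  One *Monte Carlo
step* (MCS) is $N$ elementary steps.  All runs start from the all-unadopted
state, the situation before an innovation is introduced.

The package implements two microscopically "equivalent" ways of deciding
*who* behaves independently, with identical expected amounts of independent
behaviour $p$:

* **person** (quenched disorder): a fixed set of $\mathrm{round}(pN)$
  agents is independent for the whole run; everyone else always conforms.
* **situation** (annealed disorder): every drawn target acts independently
  with probability $p$, freshly each step.

The central reproducible fact is that these two wirings produce different
*macroscopic* stationary states: flexibility $f$ and network density are
irrelevant in the person variant but strongly relevant in the situation
variant.

### Sampling-order convention

Two natural readings of the update rule exist: draw the influence group
first and let it push a neighbour, or draw the influenced target first and
then its group.  The package adopts the **target-first** order — the target
is drawn from all $N$ agents, then $q$ of *its* neighbours — because that
is the order in which the mean-field balance equations below are derived
(target drawn, then its group), making simulation and analysis describe
literally the same process.  On a complete graph the two orders coincide in
distribution; on heterogeneous networks they need not, and the target-first
order is the normative one here.  Likewise, the group is required to be
adjacent to the target but not mutually connected.

## Mean-field evolution equations

On a complete graph all agents are neighbours, so the local concentration
of adopted agents equals the global one and the dynamics closes on one or
two scalars.  Writing $c_I$ and $c_C$ for the concentrations of adopted
independents and adopted conformists (both relative to $N$, $c = c_I +
c_C$), bookkeeping the gain and loss of each subpopulation per elementary
step gives the person-variant recursions

$$c_I(t + \tfrac1N) = c_I(t) + \tfrac1N f\,[(p - c_I) - c_I],$$
$$c_C(t + \tfrac1N) = c_C(t) + \tfrac1N\,[(1 - p - c_C)\,c^{\,q} -
  c_C\,(1 - c)^{\,q}],$$

and the situation-variant recursion

$$c(t + \tfrac1N) = c(t) + \tfrac1N\,[\,p f\,(1 - 2c) +
  (1 - p)\,((1 - c)\,c^{\,q} - c\,(1 - c)^{\,q})\,].$$

The $c^q$ factors approximate the exact without-replacement unanimity
probability $\prod_{k=0}^{q-1} (N_\uparrow - k)/(N - 1 - k)$; both forms
are exposed by `group_unanimity_prob()`.  The relative error of the
approximation scales like $q(q-1)(1/c - 1)/(2N)$ — about 0.6% at $c = 0.5$,
$N = 10^3$, but still ~11% at $c = 0.05$, $N = 10^3$.  The recursions (and
therefore all fixed points reported here) use the approximate form; the
exact form exists for finite-$N$ cross-checks.

Two structural facts follow immediately and are asserted exactly in the
tests:

* the independent subpopulation decouples: $c_I^* = p/2$ for every $f > 0$,
  independent of $f$ — the algebraic root of why the person model cannot
  depend on flexibility;
* $c = 1/2$ (person: $c_I = p/2$, $c_C = (1-p)/2$) is a fixed point at
  every $p$ by up/down symmetry.

### Stationary states, stability, critical points

`mf_stationary()` iterates the raw elementary-step map (scale $1/N$,
$N = 10^3$ by default) rather than integrating an ODE: the recursion *is*
the model's deterministic limit and iteration reproduces exactly what a
long simulation equilibrates to, including which branch is reached from a
given start.  Iteration stops when every drift component (per unit time,
i.e. $N\times$ the per-step change) falls below `tol` ($10^{-8}$ by
default).  Near the critical point relaxation times diverge; runs that
exhaust `max_iter` there raise a `qv_nonconvergence` error carrying the
last state rather than silently returning it.

Stability is classified numerically — central-difference Jacobian of the
drift ($h = 10^{-6}$), all eigenvalue real parts negative — so both
variants and arbitrary $q$ are treated uniformly.

`critical_p()` locates the independence level $p^*$ at which the symmetric
(status-quo) state becomes stable, by root-finding the numeric stability
derivative at $c = 1/2$.  The recursions above give closed forms that the
numeric route recovers to $10^{-8}$ and the independent bifurcation-scan
oracle `critical_p_scan()` (which classifies stability by *iterating* the
recursion from a perturbed symmetric state and bisecting in $p$) recovers
to $10^{-3}$:

$$p^*_{\text{person}} = 1 - \frac1q, \qquad
  p^*_{\text{situation}} = \frac{A}{2f + A},\quad A = \frac{q-1}{2^{q-1}}.$$

For $q = 4$: person $p^* = 0.75$ for *every* $f$; situation
$p^* = 3/(16f + 3)$, e.g. $3/11 \approx 0.273$ at $f = 0.5$.  Below $p^*$
the all-down start converges to a lower branch where a majority coexists
with a minority; above it only the status quo $c = 1/2$ remains.

```{r critical}
critical_p("person", f = 0.2); critical_p("person", f = 0.8)
critical_p("situation", f = 0.5)
```

## Simulation engine and reproducibility

The elementary-step loop is implemented twice on purpose: a pure-R
`elementary_step()` (the readable, normative reference) and a compiled loop
behind `run_steps()`/`run_mcs()`.  Both consume R's global RNG stream in
the same documented order — target draw, branch draw (situation only),
flip draw, then $q$ partial Fisher–Yates positions for the group — so the
two paths are *bit-identical* given the same seed; the test suite asserts
this on both topologies and both variants.  The compiled group draw uses a
sparse partial Fisher–Yates (it tracks only the $O(q)$ displaced
positions), so a step costs $O(q)$ even on the complete graph.

Barabási–Albert networks grow from a fully connected clique of $M$ nodes;
each added node attaches to $M$ distinct existing nodes, degree-
proportionally via the standard repeated-nodes pool (uniform among the
seed nodes for the first addition, where all degrees are equal).  This
forces minimum degree $\ge M$ and exactly $M(M-1)/2 + M(N-M)$ edges, both
asserted for all tested $(N, M)$.  Configurations require $M \ge q$ so the
group draw can never fail mid-run.

Ensemble cells (`stationary_concentration()`) derive one *network seed*
and one *dynamics seed* per run from the cell's master seed.  Besides
making every run individually replayable, this decoupling implements
common-random-number pairing: cells sharing a master seed share their
dynamics noise even across different topologies, so equality comparisons
(the f- and M-invariance checks of the person model) compare paired means
whose difference variance is far below the unpaired pooled standard error.
The acceptance checks use exactly this pairing — with two-pooled-SE bounds
over 27 simultaneous comparisons, unpaired ensembles would fail
stochastically on an exact null; pairing makes the stated bound
conservative without touching any threshold.

## Protocol defaults

| parameter | default | why |
|---|---|---|
| $q$ | 4 | canonical unanimous-quartet influence group |
| $N$ (simulation) | 500–1000 | self-averaging enough for phase diagrams, desk-scale fast |
| burn-in | 500 MCS | relaxation rates are $O(f)$–$O(1)$ per MCS away from $p^*$; 500 MCS is a large multiple |
| measurement | 500 MCS | time-average of $c$ per run, then mean ± SD across runs |
| runs per cell | 100 | SE of a cell mean ~$10^{-3}$–$10^{-4}$, enough for the invariance checks |
| mean-field $N$ | $10^3$ | step scale of the iterated recursions |
| drift `tol` | $10^{-8}$ | fixed-point location error ≪ any tolerance asserted |
| near-critical window | $|p - p^*| < 0.02$ | MC–mean-field agreement is waived there (diverging relaxation time) |

The original phase-diagram figures this package re-derives do not state
their run lengths or system size, so the burn-in/measurement defaults
above are the package's own choices; all quantitative acceptance checks
are run at the desk scales listed here (100 runs per cell, not 1000), with
correspondingly wider Monte Carlo error.

## What the generator emulates — and what a green test does not establish

The synthetic world is exactly the stated model: binary states, uniform
target choice, unanimity-gated conformity, complete or BA topology, and an
all-down start.  It does not emulate real adoption data: no heterogeneous
$p$ or $f$ across agents, no degree–trait correlation, no opinion-dependent
rewiring, no anticonformity or zealotry.  A green suite therefore
establishes that the *mechanisms* diverge as described — quenched
independence erases the $f$- and $M$-dependence that annealed independence
shows — not that either variant fits any empirical diffusion curve.

## Numerical choices and edge cases

* `round(p*N)` uses half-up rounding (fixed, documented; R's own `round`
  is banker's) so the independent-set size is deterministic.
* The raster recorder refuses $N > 500$: the occupancy matrix is dense
  ($N \times N\,\mathrm{MCS}$ ints) and the limit keeps it under ~100 MB.
* $p = 0$ (either variant) and situation-$f = 0$ are frozen from the
  all-down start; they are asserted to stay exactly at $c = 0$.
* `critical_p("situation", f = 0)` errors explicitly: frozen dynamics has
  no transition.
* CSV outputs from the CLI print doubles at 17 significant digits so
  re-reading reproduces them bit-for-bit; every output carries a
  `.provenance.json` sidecar with the fully resolved configuration.
* The situation recursion at $c = 1/2$ and the person recursion at the
  symmetric point have exactly zero drift in floating point (the terms
  cancel pairwise), so "c = 1/2 is always a fixed point" is asserted at
  $10^{-14}$, not at a loose tolerance.

## How exact are the person-model invariances?

The f- and M-independence of the person variant is an exact statement
about the mean-field recursions (the $f$-free conformist equation and
$c_I^* = p/2$), not about finite systems.  At $N = 500$ with
common-random-number ensembles of 100 runs (cell standard errors
$\sim 10^{-4}$), the simulations resolve small systematic residuals:
$c$-differences of $10^{-3}$–$6\times10^{-3}$ across $f$ or $M$ at
mid-range $p$, growing to a few $10^{-2}$ just below $p^*$, always ordered
so that larger $f$ or larger $M$ lies closer to the complete-graph value.
The mechanism is fluctuation coupling: the quenched independent
concentration fluctuates around $p/2$ with relaxation rate $2f$, and the
conformists' nonlinear (unanimity-gated) response to that fluctuating
drive depends on its time scale and on the local neighbourhood size;
near $p^*$ the coexistence branch additionally melts at finite $N$ at a
density-dependent rate.  At plotting resolution ($\sim 0.01$) the
invariance holds away from the critical region — but a two-pooled-SE
*identity* test at this precision does not, and the corresponding two
acceptance checks are expected to report exactly these residuals rather
than pass.  They are kept at their stated bounds deliberately: the
failure messages quantify how far a finite system sits from the
mean-field idealisation.

## Known limitations

* The mean-field branch tables characterise the complete graph; for BA
  networks with small $M$ the situation-variant curves shift (they
  approach the complete-graph curve as $M$ grows, checked qualitatively,
  not at a stated rate — no pair approximation is implemented).
* Near $p^*$ neither the iteration nor a finite simulation converges in
  bounded time; both report rather than hide this, and the MC–mean-field
  comparison flags a $\pm 0.02$ window around $p^*$ instead of asserting
  agreement there.
* Finite-size scaling and critical exponents are out of scope.
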