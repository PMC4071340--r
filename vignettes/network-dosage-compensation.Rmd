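---
title: "Modelling network-dosage compensation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling network-dosage compensation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdosage)
```

## The problem

The effective dosage of a gene network — how many copies of the whole
network a cell carries — fluctuates constantly: DNA replication doubles
it during the cell cycle, haploid/diploid transitions halve or double
it, and global expression noise perturbs it continuously. For networks
whose output level matters, cells need wiring that keeps the network's
activity invariant to *parallel* changes in the copy number of all
network genes at once. `netdosage` implements three connected analyses
of this phenomenon: an analytic treatment of N-component networks, a
Monte-Carlo survey of two-component activator–inhibitor topologies, and
a genome-scale motif search for candidate compensated units in
interaction data.

## N-component theory

We model N genes sharing one transcriptional centre with fractional
activity $f(\rho, x_1, \dots, x_N) \in [0,1]$:

$$\frac{dx_i}{dt} = (1+\delta)\,\theta_i\, f(\rho, x) - \gamma x_i,$$

where $\theta_i$ are maximal expression rates, $\gamma$ is the dilution
(cell-division) rate, $\rho$ an external control input, and $\delta$ a
parallel dosage perturbation. At steady state every component is
proportional to the first, $x_m = (\theta_m/\theta_1) x_1$, which
reduces the fixed-point problem to one scalar equation
(`steady_states()` solves it by a 1024-interval sign-change scan plus
bisection to $10^{-10}$ relative tolerance, reporting *all* roots —
under bistability the caller chooses a branch). Differentiating the
steady-state condition gives the dosage sensitivity implemented in
`dosage_sensitivity()`:

$$\frac{df}{d\delta} =
  \frac{\big[\sum_i \theta_i\, \partial f/\partial x_i\big]\, f}
       {\gamma - (1+\delta) \sum_i \theta_i\, \partial f/\partial x_i}.$$

For this to vanish identically the weighted sum
$\sum_i \theta_i\, \partial f/\partial x_i$ must be zero, and since all
$\theta_i > 0$, at least one partial derivative must be positive and at
least one negative: a compensated network needs an activator–inhibitor
pair. `necessary_condition_check()` returns this verdict from the signs
of the partials (analytic when registered, otherwise central differences
with relative step $10^{-6}$). The test suite cross-checks
`dosage_sensitivity()` against a brute-force oracle that re-solves the
steady state at $\delta$ and $\delta + 10^{-6}$ and differences the
activity — the two routes agree to $10^{-4}$ relative error over a
thousand random small networks.

## Two-component topologies and the induction model

Three topology forms connect an activator $a$ and inhibitor $i$ to the
transcriptional centre (four parameters each: scales of action $S_a$,
$S_i$ and stoichiometry exponents $\alpha$, $\beta$):

* **B** (sequestered activator): the inhibitor titrates the activator,
  $f = \left[1 + X^{-\alpha}\right]^{-1}$ with
  $X = S_a g a / (1 + (S_i i)^\beta)$;
* **C** (sequestered inhibitor, the GAL architecture — Gal3 titrates
  Gal80, Gal80 represses Gal4):
  $f = \left[1 + Y^{\beta}\right]^{-1}$ with
  $Y = S_i i / (1 + (S_a g a)^\alpha)$;
* **D** (both direct): a product of an activating and a repressing Hill
  term.

The published rendering of the two sequestration forms is
typographically ambiguous about where the exponents attach; the grouping
above was fixed because it matches the wiring diagrams (sequestration
acts on the *concentration* entering the other component's Hill term),
makes the constrained stoichiometry parameter come out as $\beta$ for
form B and $\alpha$ for form C, and reduces form C to the familiar GAL
behaviour. Two additional forms exist only as test plumbing: a
two-direct-activator `SAME_SIGN_FIXTURE` (both partials positive, so
compensation must be impossible — a property the sweep tests verify) and
a `CONSTANT_FIXTURE` with closed-form dynamics used as an integration
oracle. The same-sign fixture does not model any published topology.

Induction dynamics couple the two proteins through $f$:

$$\frac{da}{dt} = N \theta_a \left[\lambda_a (1-f) + f\right]
  - (\gamma_0 + \gamma_a)\, a$$

and analogously for $i$, with copy number $N$, basal production
coefficient $\lambda = 0.20$, dilution $\gamma_0 = 0.46\,/\mathrm{h}$
and degradation $\gamma = \ln 2 / t_{1/2}$. An inducibility curve
evaluates $f$ at $t = 24$ h (about eleven dilution half-times, so
non-bistable networks are at steady state) on the 81-point logarithmic
inducer grid $g = 10^{-2 + 0.025 C}$, $C = 0 \dots 80$.

Numerical choices: the right-hand side is compiled C driven by
`deSolve::lsoda` (relative tolerance $10^{-6}$, absolute $10^{-9}$);
all 81 grid points integrate as one block-diagonal system per call,
which is what makes million-network sweeps tractable. Two conventions
exist for the initial condition: the basal fixed point of the $N$-copy
dynamics (the default for `integrate_network()` and
`inducibility_curve()`, since it starts the system at equilibrium), and
the *literal* single-copy basal formula
$x_0 = \theta \lambda / (\gamma_0 + \gamma)$ applied regardless of $N$,
which is the sweep default (`literal_basal = TRUE` in
`sweep_config()`) because it is the canonical study convention. The
two differ only through the attractor basin selected in bistable
draws: under the literal convention the double-copy network starts
below its own basal fixed point and reaches the induced branch later
along the inducer axis, which visibly raises compensation penalties in
strongly fed-back form-B networks. Integration failures, non-finite
or negative states (beyond $-10^{-6}$) and out-of-range activities mark
a curve point `numerical_problem`; a curve with any such point is
excluded from penalty statistics but kept as an auditable row. Starting
from the basal state implicitly selects the uninduced attractor's basin
for bistable draws; no other attractors are searched.

## Penalties

Both penalties are areas between curves on the $\log_{10} g$ axis
(`curve_area_between()`):

* **compensation penalty** — area between the $N=1$ and $N=2$ curves;
  0 means perfect dosage compensation;
* **inducibility penalty** — area between the $N=1$ curve and a
  reference curve; large values flag always-OFF or always-ON,
  non-regulatory behaviour.

The area is deliberately *not* divided by the grid's log-span. On the
two-decade default grid, doubling the dosage of an uncompensated
network shifts a complete OFF→ON transition left by
$\log_{10} 2 \approx 0.30$, giving a compensation penalty of about
0.30; the span-normalized variant would cap this hallmark case near
0.15, which would make the conventional 0.10/0.15 penalty cuts
degenerate (nothing could sit far above 0.15). The span-normalized
variant is available as `normalized_area_between()` and is the
pseudometric the property tests exercise; `penalty_scores()` reports
the unnormalized scale, and the 0.10 classification thresholds apply to
it.

The reference curve is a Hill form
$f_{\mathrm{ref}}(g) = (\epsilon + (g/K)^h) / (1 + (g/K)^h)$ with
defaults $\epsilon = 0$, $K = 0.1$, $h = 2$: midpoint at the
logarithmic centre of the grid, moderately cooperative, and demanding
full OFF-to-ON switching. The basal parameter is the basal *activity*
demanded of a well-behaved network, which is conceptually distinct from
the basal production coefficient $\lambda = 0.2$ of the kinetic model:
an inducible network's activity at low inducer sits near its repressed
level, not at $\lambda$. Setting $\epsilon$ to $\lambda$ would demand
elevated basal activity that fully-switching networks do not have and
would empty the filtered sets. The reference is a genuinely free
modelling choice — there is no canonical shape — so it is configurable
everywhere (`reference_curve()`, the `reference` entry of
`sweep_config()`), every headline statistic should be quoted with the
reference used, and the acceptance script reports the sensitivity of
its sufficiency statistics to alternative references.

## The Monte-Carlo sweep

`sweep_config()` defaults encode the canonical study design:
$S_a$ log-uniform on $[10^{-3}, 10^3]$, $S_i$ log-uniform on
$[10^{-4}, 10^2]$, $\alpha, \beta$ uniform on $[0.2, 5]$;
$\theta \in \{300, 1500, 7500\}$ proteins/h and
$t_{1/2} \in \{5, 30, 120, \infty\}$ min for both proteins — a
Cartesian product of 144 kinetic combinations — with 10,000 parameter
draws per combination, i.e. 1,440,000 networks per topology at full
scale. `run_sweep()` executes the full design; `sample_sweep()` draws
each network's kinetic combination uniformly instead, which is the
right sampler for desk-scale estimates of population fractions. Row
order is fixed by (combination, sample) index and everything is
reproducible from the config seed.

`sufficiency_analysis()` reproduces the sufficiency question: restrict
to networks whose *constrained* stoichiometry parameter ($\beta$ for
form B, $\alpha$ for form C — the exponent on the sequestered side,
where 1:1 stoichiometry means a value near 1) lies in $[0.9, 1.1]$ and
whose inducibility penalty is at most 0.10, then tabulate compensation
penalties against the 0.10 and 0.15 cuts. For form B it also carries
the weak-inhibitor diagnostic: among filtered networks with high
compensation penalty, the distribution of $S_i$ and of the maximum
steady-state repression — operationalized as the minimum over the grid
of $f$ at the $N=1$ endpoint divided by $f$ with the inhibitor clamped
to zero (1 = the inhibitor never represses; the exact published formula
is not available, so this ratio definition is the package's own).
Networks with a negligible inhibitor reduce to one-component direct
activators: fully inducible, never compensated.

## Problem sizes

Full-scale sweeps (1.44M networks per topology) are hours of CPU time;
the package's own analyses and checks run at reduced scale, chosen so
that binomial noise on the reported fractions stays a few percentage
points: sufficiency statistics use 20,000 sampled networks per topology
(filtered sets of order $10^2$), the constrained-parameter histogram
uses full-range samples of the same size, and unit tests use hundreds
of networks. The desk-scale sampler draws kinetic combinations
uniformly rather than exhaustively, so its fractions estimate the same
population quantities as the full design.

## Synthetic interaction data and the motif search

The motif search consumes four tables (TF→promoter binding, physical
interactions with a low/high-throughput evidence label, genetic
interactions with free-text category labels, and a global-regulator
exclusion list). A *potentially compensated unit* (PCU) is a TF binding
the promoters of two regulators, with the four evidence conditions
described in `enumerate_pcus()`; physical support requires one
low-throughput or two high-throughput records, and regulator–regulator
links use the same threshold as TF links. Sign relations derive from
genetic-interaction classes (positive ⇒ different signs, negative ⇒
same sign, both ⇒ conflict needing a manual override, ambiguous-only ⇒
unknown), and a PCU is *compensated* when the signs differ and exactly
one regulator touches the TF physically — the sequestration wiring. A
TF is never a regulator of its own PCU: the unit needs three distinct
genes. `merge_pcus()` approximates the manual curation step by taking
connected components of the gene co-occurrence graph; it performs no
literature verification, and the global-regulator list is input-driven
because "global" is a qualitative judgement.

The synthetic generator plants compensated and non-compensated motifs
and adds uniform-random noise records, rejecting any noise record that
would change the compensated-PCU set (either creating a spurious
compensated unit or corrupting a planted one), so generator ground
truth is exact and precision/recall statements against it are
meaningful. What it does *not* emulate: realistic degree distributions,
correlated evidence (real high-throughput screens hit hubs
preferentially), missing data patterns, or the curation biases of real
interaction databases — so perfect recovery on synthetic data shows the
algorithm implements its definition, not that real-genome scans are
complete. The hand-built `gal_fixture()` encodes the galactose-network
wiring (Gal80 direct on Gal4, Gal3 acting through Gal80, different
signs) and yields exactly one compensated PCU.

## Known limitations

* The reference inducibility curve is a modelling choice; sufficiency
  fractions, especially for form B, move by several percentage points
  across reasonable references, which is why the package always reports
  the reference alongside them.
* Exclusion of numerically problematic networks is solver-dependent;
  `lsoda` converges on essentially all sampled networks here, so the
  exclusion rate is near zero and bistable edge cases are retained
  (with their genuine penalties) rather than dropped.
* The motif search trusts its input tables; it cannot detect indirect
  regulators acting through unobserved intermediaries, and sign
  inference is limited by genetic-interaction coverage.
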