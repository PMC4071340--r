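# netdosage

Tools for analysing **network-dosage compensation** in gene regulatory
networks: the ability of a gene network to keep its output activity
invariant when the copy number of *all* of its genes changes in
parallel — as happens at DNA replication, in haploid/diploid
transitions, and under global expression noise.

The package is aimed at systems biologists who want to (i) reason about
which network topologies can be dosage-compensated, (ii) survey
parameter space for two-component activator–inhibitor circuits by
simulation, and (iii) scan interaction datasets for candidate
compensated motifs.

## The models

**N-component theory.** For N genes under one transcriptional centre
with activity f(ρ, x₁…x_N) ∈ [0, 1],

    dx_i/dt = (1+δ) θ_i f(ρ, x) − γ x_i,

the sensitivity of the steady-state activity to a parallel dosage
change δ is

    df/dδ = [Σ_i θ_i ∂f/∂x_i] f / (γ − (1+δ) Σ_i θ_i ∂f/∂x_i).

Compensation (df/dδ = 0) requires the weighted sum of partials to
vanish, hence at least one activating and one inhibiting component:
same-sign networks can never be dosage-compensated
(`steady_states()`, `dosage_sensitivity()`,
`necessary_condition_check()`).

**Two-component topologies.** Activator a and inhibitor i coupled
through a shared transcriptional centre, in three wirings: the
inhibitor sequestering the activator (form B), the activator
sequestering the inhibitor (form C — the yeast GAL architecture), and
both acting directly (form D). Induction dynamics

    da/dt = N θ_a [λ_a (1−f) + f] − (γ₀ + γ_a) a   (and likewise for i)

integrate to 24 h over an 81-point logarithmic inducer grid, producing
inducibility curves f(g) at copy numbers N = 1 and N = 2
(`inducibility_curve()`). Two penalties score each network
(`penalty_scores()`): the **compensation penalty** (area between the
N = 1 and N = 2 curves on the log₁₀ g axis; 0 = perfect compensation)
and the **inducibility penalty** (area to a configurable reference
sigmoid; large = always-ON/always-OFF). Monte-Carlo sweeps over the
canonical parameter design (144 kinetic combinations × sampled
interaction parameters; `run_sweep()`, `sample_sweep()`) reproduce the
sufficiency analysis: sequestration topologies with ~1:1 stoichiometry
(the constrained exponent near 1) are compensated in the vast majority
of inducible networks, except for the form-B weak-inhibitor failure
mode (`sufficiency_analysis()`).

**Motif search.** `enumerate_pcus()` finds *potentially compensated
units* — a TF binding the promoters of two regulators, with physical
and genetic interaction evidence satisfying four conditions — then
`classify_pcus()` labels each unit compensated when the regulators have
different regulatory signs (inferred from genetic-interaction classes)
and exactly one of them contacts the TF physically.
`generate_interaction_dataset()` builds seed-controlled synthetic
datasets with planted motifs for benchmarking, and `gal_fixture()`
encodes the GAL network wiring.

## Worked example

```r
library(netdosage)

# a sequestered-inhibitor network with ~1:1 activator stoichiometry
p  <- topology_params(S_a = 8.8, S_i = 35, alpha = 1.0, beta = 1.9)
k1 <- kinetic_params(theta_a = 7500, theta_i = 300, t_half_i = 120, N = 1)
k2 <- kinetic_params(theta_a = 7500, theta_i = 300, t_half_i = 120, N = 2)

c1 <- inducibility_curve("C_seq_inhibitor", p, k1, literal_basal = TRUE)
c2 <- inducibility_curve("C_seq_inhibitor", p, k2, literal_basal = TRUE)
range(c1$f_end)
#> [1] 0.015 0.990
penalty_scores(c1, c2)
#> # A tibble: 1 × 3
#>   compensation_penalty inducibility_penalty excluded
#>                  <dbl>                <dbl> <lgl>
#> 1            0.0000807               0.0414 FALSE

# the motif scan on the GAL fixture finds the canonical compensated unit
motif_scan(gal_fixture())$pcus
#> # A tibble: 1 × 6
#>   tf    regulator1 regulator2 direct_regulator sign_relation classification
#>   <chr> <chr>      <chr>      <chr>            <chr>         <chr>
#> 1 GAL4  GAL3       GAL80      second           different     compensated
```

The network switches fully across the induction window (activity
0.015 → 0.99) while its single- and double-copy response curves are
essentially indistinguishable (compensation penalty 8e-5): this
network is both inducible and dosage compensated. The scan output
identifies (GAL4; GAL3, GAL80) as a compensated unit: Gal80 is the
direct inhibitor on Gal4, Gal3 acts indirectly by sequestering Gal80,
and the positive-class genetic interaction marks their opposite
regulatory signs.

A command-line wrapper for the pipeline lives at `inst/cli/netdosage`
(subcommands `sweep`, `sufficiency`, `curves`, `theory-check`,
`motif-scan`, `synth`), each run writing a reproducibility manifest.

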