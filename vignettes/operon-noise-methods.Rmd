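---
title: "Models and methods: operon cotranscription and intrinsic noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: operon cotranscription and intrinsic noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operonoise)
```

This vignette is the package's own account of its models, parameters,
estimators and design choices. Everything quantitative stated here is
computed by the test suite or by `scripts/acceptance.R`; nothing is quoted
from elsewhere.

## State, units, and reaction representation

The state is a vector of molecular copy numbers per cell; time is in
seconds; the cell volume `omega` defaults to 1 fL, so one copy per cell is
one copy per femtoliter and bimolecular mass-action propensities are
`k·a·b/omega`. All models are built from elementary steps
(`reaction_system()`), with three non-elementary conveniences used exactly
where the analytic treatment uses them: single-step Michaelis–Menten
propensities `k_cat·E·s/(K_m+s)` for enzymatic conversions, Hill
propensities for regulated transcription, and a probabilistic-OR
combination of two Hill activators. Promoters are species present at
exactly one copy (an on/off pair when bursting is enabled); conserved
units like these are detected from the stoichiometry matrix and checked on
every trajectory. Boundary pools (an external substrate held constant) are
clamped species: reactions read them but never change them.

## Coupling configurations

Two genes A and B are expressed in one of three configurations with
identical per-gene rates:

* **uncoupled** — two promoters, mRNAs `m1`, `m2`, proteins A, B;
* **cotranscribed** — one promoter, one polycistronic mRNA `m12`, two
  independent translation channels;
* **cotranslated** — one promoter, one mRNA, a single translation event
  producing A and B together (the strongest coupling; default coupled mode
  in comparisons).

Expression defaults (`expression_params()`): `k_tx = 0.005 /s` and
`delta_m = 0.005 /s`, giving one mRNA on average with a 200 s lifetime
(a realistic bacterial mRNA half-life of a few minutes);
`k_deg = ln 2 / 1800 /s`, dilution by a cell doubling every half hour;
`k_tl` chosen so mean protein per gene hits the preset levels 53 / 529 /
5285 (`expression_preset()`), spanning weakly to strongly expressed
bacterial proteins; the low preset is the default because intrinsic-noise
effects are largest there. With promoter bursting enabled
(`bursting_params()`), the two-state switching rates are
`k_goff = 0.0028 /s`, `k_gon = 0.00045 /s` (duty cycle 0.138, the measured
scale of slow bacterial promoter switching), and the on-state transcription
rate is divided by the duty cycle so that the mean mRNA — and hence every
mean — is invariant to turning bursting on. Bursting then purely adds
noise at fixed means, which is the property the comparisons need.

For the pure expression model without posttranslational reactions and
without bursting, the stationary normalized covariance has the closed form
implemented in `eta_operon_closed_form()` (shared-mRNA term
`(1/⟨m⟩)·τ_m/(τ_m+τ_p)`, plus `1/(2⟨A⟩)` under cotranslation); the test
suite verifies it against the Lyapunov solver to 1e-8 relative, and this
equivalence is the arbiter of the closed form's algebra.

## Interaction modules and their default parameters

Each module appends identical posttranslational reactions to the coupled
and uncoupled expression systems (`build_module()`, `comparison_pair()`),
so the two members of a pair differ only in transcription topology —
`verify_matched_controls()` checks that per-gene total protein mean and CV
agree between configurations within Monte-Carlo error. Defaults
(`module_defaults()`, versioned in `inst/extdata/module_defaults.json`)
were chosen once, by mean-field design at the low expression preset
(53 proteins/gene), to place each module in the regime its theory assumes;
they are order-of-magnitude-realistic, not fits to any dataset.

* **linear_pathway** S→I→P. S clamped at 1000 with `K_m1 = 100` (substrate
  10× above K_m1: the upstream enzyme near saturation), `k_cat1 = 0.02`,
  `k_cat2 = 0.0227`, `K_m2 = 25`, product removal 0.01 /s. At mean enzyme
  levels the production/consumption capacity ratio is r ≈ 0.80, so the
  mean intermediate sits at `K_m2·r/(1−r) ≈ 100` copies and upward enzyme
  imbalance can push r past 1 — the zero-order threshold. Readout: I.
* **redundant_enzymes** S→P via A or B, linear product removal
  (`k_cat = 0.01`, `K_m = 100`, `k_out = 0.005`). The product integrates
  total capacity `∝ A+B`; anticorrelated (uncoupled) enzymes average out.
  No threshold by construction (linear removal). Readout: P.
* **branch_point** influx J = 1.5 /s split by A and B
  (`k_cat = 0.0236`, `K_m = 20`): mean capacity ratio r ≈ 0.6, substrate
  ≈ 30 copies. The threshold is crossed when *both* enzyme levels dip
  together, which is why the cotranscribed configuration is the noisy one.
  The working point r = 0.6 keeps crossings dip-driven: at r ≈ 0.8 with
  strong bursting both configurations sit near-permanently saturated, the
  substrate distribution becomes bimodal, and the CV ranks the
  configurations misleadingly (see "Bursting and the default comparison
  regime"). Readout: s.
* **dual_regulators_or** A and B each activate mRNA production of a target
  through Hill terms combined by probabilistic OR,
  `V_max·[1−(1−h_A)(1−h_B)]` with `K = 53`, `n = 2`: the OR saturates at
  `V_max`, so either regulator alone has the full effect, which is the
  redundancy that favors uncoupling. Readout: P.
* **physical_interaction** A+B⇌AB with `k_b = 0.01`, `k_unb = 0.001`
  (K_d = 0.1 copies — strong binding; free monomers a few copies), all
  three species diluting at `k_deg`. Free monomer levels are set by the
  *difference* of totals (molecular titration), an ultrasensitive function
  of the production-flux ratio. Readouts: free A (and AB).
* **covalent_modification** B converts A→A\*, A\* relaxes back. The
  default kinetics are mass action (`k_p = 0.002`, `k_demod = 0.02`):
  modification flux ≈ 10× the dilution flux of A, the regime in which the
  unmodified form cleanly tracks the A-production / B-level ratio. Mass
  action makes the mean-field response *linear*, so the ultrasensitive
  variant of this cycle — saturating Michaelis–Menten kinetics on both
  arms (`mm_kinetics = TRUE`; `k_cat_p = 0.0094`, `K_p = K_d = 5`,
  `V_d = 0.5`), the classical zero-order modification cycle — is the one
  used for response curves. Readout: unmodified A.
* **lac_reduced** a reduced import→conversion cascade with positive
  feedback: permease (A) imports external lactose (clamped, in
  copies-per-fL converted from µM via `uM_to_copies()`; 83 µM ≈ 50,000),
  galactosidase (B) converts internal lactose to the inducer and the
  inducer to product; the inducer sequesters a 10-copy repressor that
  gates both genes. It preserves the wild-type topology, not any published
  parameterization. Readout: inducer (`Alac`).

Predicted signs of `ΔCV² = CV²(uncoupled) − CV²(cotranscribed)` per
readout are encoded in `predict_sign()`; species whose difference is small
and parameter-dependent (the linear-pathway product, the modified form
A\*) are classed `small_either` and only tested for smallness relative to
the module's dominant difference.

## Linear noise approximation

`build_lna()` computes the macroscopic steady state (damped Newton from
the initial copies, with ODE-relaxation continuation; systems whose flux
balance admits no finite fixed point are reported as diverged, never
silently), eliminates conservation laws, forms the Jacobian `M` by central
finite differences (relative step 1e-6 — uniform across rate-law kinds,
which is why differences are used instead of symbolic algebra) and the
diffusion matrix `N = S·diag(f)·Sᵀ/Ω`, and requires all eigenvalues of `M`
to have negative real part. `solve_lyapunov()` solves
`MΣ + ΣMᵀ + ΩN = 0` by Kronecker vectorization (the systems here have at
most ~15 species, so dense solves are exact and cheap) and enforces a
residual below 1e-8 of `‖ΩN‖`. Steady states with zero-copy means for a
readout are rejected rather than regularized. Bursting promoters can be
included in the LNA state space, but the analytic comparisons are run in
the no-bursting regime where the theory is cleanest. `log_gain()` returns
logarithmic sensitivities `(y/R)·∂R/∂y` of flux ratios at steady state by
central differences.

## Ultrasensitivity analysis

`response_curve()` rescales the class-specific production flux so the
capacity ratio `V⁺/V⁻` equals each grid value, with protein levels held at
their means, and solves the mean-field steady state of the readout;
divergence (r ≥ 1 for the metabolic classes) is flagged per point. For the
linear pathway this reproduces `I* = K_m·r/(1−r)` to 1e-6 relative, with
logarithmic sensitivity `1/(1−r)`. `effective_sensitivity()` is the
maximum finite-difference log-log slope; above 1 counts as ultrasensitive.
`flux_ratio_trace()` evaluates capacity fluxes (V_max-type, from enzyme
copy numbers — not instantaneous realized fluxes, so the threshold sits
exactly at 1) along trajectories; for the titration modules the governing
ratio is the protein production-capacity ratio, i.e. the mRNA ratio, which
a shared polycistronic mRNA pins at exactly 1. Spikes are runs of ≥ 60 s
(default) spent above 5× (default) the ensemble median — the spike
definition is a package decision, since excursions are otherwise only
graphical — and each event records whether the ratio exceeded 1 during it.

## Stochastic simulation and estimators

`simulate_ssa()` is an exact direct-method Gillespie sampler;
`simulate_tau_leap()` uses the ε-bounded relative-change leap criterion
with Poisson firing counts, halves the leap on negative proposals, and
takes exact SSA steps whenever any reactant of any reaction is below
10 copies — including reactions currently shut off by a zero count, since
leaping over those would decouple, say, monomer production from binding at
a titration point. For low-copy systems (every module fixture here, with
their ~1-copy mRNAs) tau-leaping therefore *is* the exact sampler,
bitwise; it accelerates only genuinely high-copy systems.
A master seed spawns per-run sub-seeds (`sample.int` under the master
seed), so ensembles are reproducible independent of execution order.
Ensembles start at the mean-field steady state with promoter states drawn
from their stationary occupancy, which shortens the burn-in; the default
sampling grid is 201 points, burn-in fraction 0.5, and
`stationary_window()` flags residual drift when the first and second
halves of the retained window differ by more than 3 pooled standard
errors.

`summarize_ensemble()` pools one statistic sample per trajectory: each
trajectory contributes its time-averaged first and second moments over the
window, with second moments centered on the ensemble grand mean — unbiased
for the stationary variance even when the window is short relative to the
autocorrelation time, unlike centering on per-trajectory means — and
bootstrap SDs come from resampling trajectories (1000 by default).
Distributions with |skewness| > 2 carry a `skewed` flag because CV is then
a fragile summary. The *degree of decorrelation* between two gene products
is reported as `1 − r(A,B)` — a stand-in definition chosen for
transparency; conclusions drawn with it are trend-level only (it decreases
with expression level for coupled pairs, which the tests check against
the LNA). `cross_correlation()` gives the ensemble-averaged normalized
lagged covariance with its SEM across trajectories.

## Bursting and the default comparison regime

`run_comparison()` defaults to the no-bursting regime, in which expression
noise arises from low mRNA copy numbers. Two reasons. First, the analytic
noise theory (closed-form covariance, Lyapunov ΔCV²) applies there, so
stochastic and analytic results are directly comparable; the coupling
effects are qualitatively the same with bursting, and the test suite
checks the covariance ordering (cotranslated ≥ cotranscribed > uncoupled
≈ 0) in both regimes. Second, with the slow measured switching rates the
off periods (~2200 s) are comparable to the protein lifetime, so enzyme
levels collapse nearly to zero in every off epoch; near-threshold
metabolic modules then sit saturated for long stretches in *both*
configurations, their readout distributions become bimodal, and the CV
ranks configurations by occupancy of the high mode rather than by
fluctuation size — the regime in which CV is explicitly a misleading
summary. Bursting comparisons remain available via
`run_config(bursting = TRUE)`.

`randomize_extrinsic()` models global extrinsic noise as one uniform
multiplier per rate class (transcription, translation) on
`[1−w, 1+w]`, shared by both genes within a run and redrawn across runs;
it induces the expected positive correlation between uncoupled gene
products (r ≈ 0.3 at w = 0.25 on the defaults) without changing any of
the module orderings.

## Enrichment statistics and synthetic data

`randomize_pairs()` implements the flatten–permute–re-pair null: the
observed pair list is flattened to its gene multiset, permuted, re-paired
consecutively, and the same-operon fraction recomputed per replicate
(1000 by default); operon identity travels with the gene, so the gene
multiset and operon size distribution are preserved exactly. The
randomized fractions are treated as normal for a parametric one-sided
p-value; replicates producing a self-pair are redrawn, since a gene does
not interact with itself in these pair classes. `median_split()` sends
copy numbers at the median to the low subset (deterministic and
conservative for the `f_low > f_high` alternative);
`bootstrap_diff_test()` resamples rows with replacement and reports the
fraction of replicates with non-positive difference (10,000 resamples by
default), and `bin_errorbars()` bootstraps each expression bin up to its
own size. All alternatives are one-sided with the direction supplied by
the caller, matching the directional nature of the hypotheses.

The generators emulate the *structure* of curated datasets, not their
content: `gen_universe()` partitions genes into operons with truncated
geometric sizes (any positive size law could be substituted — geometric is
the simplest one-parameter choice); `gen_pairs()` draws pairs with a
controllable same-operon probability (or unbiased pairs for nulls);
`gen_expression()` draws log-normal copy numbers spanning ~1–10⁴ per cell
and plants a logistic expression–coupling relationship with slope β per
log10 copies (β < 0 reproduces the higher-coupling-at-low-expression
pattern; β = −1 with 300 rows is the package's standard planted effect,
detected in essentially 100% of datasets). Calibration universes are sized
(1500 genes, mean operon size 12, 750 pairs) so the expected same-operon
count under the null is double-digit: the parametric tail of a discrete
count statistic is only trustworthy away from zero, and genes average one
pair each so self-pair redraws stay rare. Measured type-I error at
α = 0.05 over 500 null datasets is ~0.05–0.06 for the randomization test
and ~0.03 for the (slightly conservative, because of ties at zero)
bootstrap test.

What passing these tests does *not* show: the generators draw independent
rows with exact distributional forms, so they say nothing about
measurement error in single-cell copy numbers, about correlated pair
ascertainment in curated databases, or about operon size laws in real
chromosomes. The statistics are validated as *procedures*; conclusions on
real tables inherit those tables' biases.

## Problem sizes and reproducibility

Default comparisons use 2000 trajectories per configuration with 24,000 s
runs (burn-in half) — enough for every module's sign to clear three
bootstrap SEs while keeping a full six-module comparison to a few minutes
on one CPU; 10,000-run ensembles are a `run_config()` argument away.
`scripts/acceptance.R` recomputes all headline quantities from a single
`--seed`. Every simulation, randomization and bootstrap in the package
routes through that seed-spawning contract, so reports are exactly
reproducible.

## Known limitations

* The linear noise approximation underestimates the amplification of
  noise differences near ultrasensitive thresholds; the package therefore
  reports both LNA and SSA differences and asserts only sign concordance
  away from `small_either` cases.
* Intermediate translational coupling (read-through between ribosome
  binding sites) is not modeled — only the three extreme configurations.
* The reduced lac-like cascade preserves topology, not any published
  parameterization, and omits inducer-exclusion physiology.
* The covalent module's stochastic default is mass-action; its
  enzyme–substrate-complex expansion is limited to the Michaelis–Menten
  variant, with no explicit complex species.
* `1 − r` is a stand-in for the degree of decorrelation; only monotone
  trends are asserted with it.
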