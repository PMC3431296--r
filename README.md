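# operonoise

Bacterial genes are commonly organized into operons: one promoter drives a
polycistronic mRNA encoding several proteins. `operonoise` asks what this
cotranscription does to *intrinsic biochemical noise* when the encoded
proteins interact, and whether the answer leaves a footprint in how real
genomes are organized.

The package is aimed at systems biologists who want to

* simulate two-gene expression under three coupling configurations —
  cotranslated (one ribosome binding site for both proteins), cotranscribed
  with independent translation, and transcriptionally uncoupled — composed
  with six classes of protein interaction (sequential metabolic steps,
  redundant enzymes, a metabolic branch point, OR-gate gene regulation,
  heterodimer formation, covalent modification) plus a reduced lac-like
  import/conversion cascade with repressor feedback;
* compare stationary noise between configurations analytically (linear
  noise approximation) and stochastically (exact Gillespie simulation, with
  tau-leaping for large systems); and
* test operon-enrichment hypotheses on gene-pair tables with a
  flatten–permute–re-pair randomization test and an expression-level
  median-split bootstrap test, using synthetic data generators that plant
  controllable effects.

## The theory in brief

Intrinsic noise in a protein's stationary copy number is summarized by
CV = σ/μ; covariation of two proteins A, B by the normalized covariance

    η_AB = σ_AB / (⟨A⟩⟨B⟩).

For two stable proteins expressed from one operon without posttranslational
interactions, the linear noise approximation gives the closed form

    η_AB = (1/⟨m⟩) · τ_mRNA / (τ_mRNA + τ_protein)      (separate RBS)
    η_AB = the same + 1/(2⟨A⟩)                          (cotranslated)

and η_AB = 0 for uncoupled genes: shared mRNA fluctuations are the source
of covariance, so coupling is strongest when mRNAs are rare and long-lived
relative to proteins. Whether this covariance *lowers* or *raises* noise in
a physiologically relevant output depends on the interaction: cotranscribed
configurations have lower noise in a metabolic intermediate, in free
monomers under strong binding, and in the unmodified form of a covalently
modified protein, while uncoupled configurations win for redundant enzymes,
branch-point substrates and OR-redundant regulators. The noise difference
is reported as

    ΔCV²_j = CV²_j(uncoupled) − CV²_j(cotranscribed),

positive when cotranscription is the low-noise configuration. Several of
these differences are amplified by a zero-order ultrasensitive switch: the
output departs sharply when the production/consumption flux-capacity ratio
V⁺/V⁻ crosses 1, and coupling suppresses fluctuations of that ratio because
its numerator and denominator rise and fall together. Covariances are
computed by solving the stationary fluctuation–dissipation (Lyapunov)
equation M σ + σ Mᵀ + Ω N = 0 around the macroscopic steady state.

## Worked example

Compare the cotranslated and uncoupled linear metabolic pathway (substrate
→ intermediate → product, the two enzymes being the coupled gene products)
at 300 runs per configuration:

```r
library(operonoise)
cfg <- run_config("linear_pathway", n_runs = 300, seed = 11)
rep <- run_comparison(cfg)
glance(rep)
#> # A tibble: 1 × 6
#>   module_class   readout delta_cv2     z sign_ok controls_pass
#>   <chr>          <chr>       <dbl> <dbl> <lgl>   <lgl>
#> 1 linear_pathway I            1.24  5.16 TRUE    TRUE
```

`delta_cv2 = 1.24` means the uncoupled configuration's intermediate CV²
exceeds the cotranscribed one's by 1.24 (CV² 2.34 vs 1.09 here), `z = 5.16`
bootstrap standard errors from zero — the cotranscribed operon is clearly
the low-noise architecture, and `controls_pass` confirms both
configurations had matched per-gene protein mean and CV. `autoplot(rep)`
draws the per-species CV bars.

The bioinformatic track on a synthetic universe with a planted same-operon
fraction of 0.35 among interacting pairs (roughly the scale of curated
physical-interaction datasets):

```r
uni   <- gen_universe(n_genes = 1500, mu_size = 12, seed = 1)
pairs <- gen_pairs(uni, n_pairs = 750, f_target = 0.35, seed = 2)
randomize_pairs(pairs, uni, n_reps = 1000, seed = 3)
#> Operon-enrichment randomization test (1000 replicates)
#>   f observed = 0.361; randomized mu = 0.00787 +/- 0.00318
#>   z = 111.2, one-sided p (greater) = 0
tab <- gen_expression(n_rows = 300, beta = -1, seed = 4)
median_split(tab)
#> Median split: f_low = 0.533 (n = 150), f_high = 0.127 (n = 150), diff = 0.407
bootstrap_diff_test(tab, n_reps = 10000, seed = 5)$p_boot
#> [1] 0
```

The observed same-operon fraction (0.361) is over a hundred randomization
standard deviations above the re-paired null (0.008), and the planted
negative expression–coupling slope shows up as a much higher coupling
fraction below the median copy number than above it.

See `vignettes/operon-noise-methods.Rmd` for the model definitions, every
default parameter with its rationale, and known limitations.

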