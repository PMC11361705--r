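# proxiquant

Quantification tools for imaging TurboID biotin-ligase fusion proteins with
fluorophore-conjugated streptavidin versus anti-tag antibodies, and for the
matching proximity-labelling proteomics workflow.

## The problem

Phase-separated, protein-dense compartments — the FG-repeat channel of the
nuclear pore, the nucleolus, starvation stress granules — can exclude bulky
IgG antibodies while remaining accessible to small probes. A TurboID fusion
biotinylates its neighbourhood in vivo, so streptavidin reports the
protein's true location even inside such compartments, whereas anti-tag
immunofluorescence stains only their accessible periphery. `proxiquant`
makes the resulting, otherwise qualitative, contrasts measurable:

* **Granule sizing.** On a sum-slices z-projection, a line profile is drawn
  through a granule and its diameter taken at 50% fluorescence: with
  baseline `b` (mean of the lowest decile) and maximum `M`, the diameter is
  the distance between the outermost crossings of `b + (M − b)/2`. For a
  uniformly labelled sphere of radius `r` the projected profile is
  proportional to `√(r² − x²)` and the measured diameter tends to `√3·r`.
  Peripheral (shell-restricted) antibody staining reads *wider* than
  volume staining of the same granule; the per-granule **diameter
  quotient** `d_HA / d_strep > 1` and a double-peaked antibody profile are
  its signatures.
* **Signal brightness.** Per-cell maxima of z-projections are compared
  between staining conditions: fold change as ratio of group means plus an
  unpaired two-tailed Student's t-test.
* **Antibody accessibility.** Within the streptavidin-defined reference
  mask, `score = (median HA − background) / (median strep − background)`,
  binned into increments — 0 means antibody-inaccessible (putatively
  phase-separated), 1 means equally reported.
* **LFQ enrichment.** The standard proximity-labelling proteomics chain:
  filter for ≥1 valid value in the bait group, log2 transform, impute
  missing values from a per-sample downshifted normal
  `N(μ − 1.8σ, (0.3σ)²)`, Student's t-test against the untagged control
  triplicate; the **t-test difference** (mean bait − mean control, log2) is
  binned into increments and mapped onto a nuclear-pore parts list.

Every analysis stage is testable without real microscope data: the package
includes a ground-truthed scene renderer (spherical granules with volume or
shell labelling, nuclear-pore punctae, anisotropic Gaussian PSF, Poisson +
read noise) and an LFQ table simulator with intensity-dependent
(missing-not-at-random) dropout.

## Worked example

```r
library(proxiquant)

sim <- simulate_granule_experiment(n_replicates = 3,
                                   cells_per_replicate = 25, seed = 11)
fit <- granule_quant(sim$stacks, sim$replicate)
summary(fit)
#> Per-replicate summaries:
#>  replicate  n mean_quotient sd_quotient frac_double_ha frac_double_strep
#>          1 25      1.206801  0.02159050           0.84                 0
#>          2 25      1.214755  0.02869484           0.76                 0
#>          3 25      1.203383  0.02341005           0.92                 0
#> Pooled over 75 granules: quotient 1.21 +/- 0.02 (mean +/- SD)
#> Across replicate means:  1.21 +/- 0.01
```

Each of the 75 simulated cells carries one granule labelled through its
volume in the streptavidin channel and only in a peripheral shell
(thickness 25% of the radius) in the antibody channel. The mean quotient
above 1 in every replicate and the high double-peak fraction in the
antibody channel are exactly the signatures peripheral staining leaves in
line profiles; the streptavidin channel never shows a double peak.

The proteomics side:

```r
sim <- simulate_lfq_table(lfq_sim_spec(n_proteins = 300,
                                       true_effect = rep(c(0, 5), 150),
                                       seed = 7))
fit <- lfq_enrich(sim$table, bait_group = "bait", seed = 7)
#> filter_valid: removed 5/300 protein groups (< 1 valid value(s) in 'bait')
fit
#> LFQ enrichment: bait vs control, 295 protein groups
#>   enriched (difference >= 1): 155; increment edges: 1, 2, 4, 6
```

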