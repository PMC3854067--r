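# destainr

Does the local abundance of an active-zone protein predict how efficiently
a synapse releases neurotransmitter? One way to ask this at scale is to
image FM1-43 destaining — the activity-dependent loss of a styryl dye from
recycling synaptic vesicles — at thousands of individual boutons, then fix
the culture, immunostain the very same field for the protein of interest,
and match each bouton's *unloaded fraction* to its immunoreactivity (IR).

destainr is an R implementation of that post-hoc correlation pipeline for
people who run (or simulate) FM-dye experiments on dissociated neuronal
cultures:

* **Segmentation** of functional boutons from the destaining difference
  image (mean baseline − mean post-stimulus plateau), matched-filtered and
  robustly thresholded, with watershed splitting of touching puncta.
* **Kinetic quality control** per ROI on three scale-free statistics:
  baseline slope, baseline coefficient of variation, unloading extent.
* **Rolling-ball background subtraction** (grayscale opening with a
  spherical structuring element, default radius 12 px).
* **Translation registration** of the post-hoc channels to the FM
  reference by exhaustive normalized cross-correlation, with removal of
  ROIs touching the misaligned border.
* **ROI-matched IR quantification** — matched-filter (PSF-weighted)
  punctum photometry by default, classical integrated density as an
  option — mean-normalized per channel and split into high (> 2× mean) /
  low (< 0.5× mean) populations.
* **Group statistics**: unloaded fraction per population (whole / high /
  low), one-way ANOVA plus Bonferroni-adjusted pairwise t tests, group
  mean ± SEM destaining traces, and a two-channel linearity QC.
* A **synthetic-experiment generator** with exported ground truth (planted
  per-bouton unloading fractions, marker levels, and channel shift), so
  the entire chain is testable without a microscope.

The measured quantity per bouton is the unloaded fraction
`u = (F0 − mean(tail)) / F0`; the scientific readout is whether
`mean(u | IR > 2)` > `mean(u | whole)` > `mean(u | IR < 0.5)` and whether
the ANOVA across those populations is significant.

## Worked example

Simulate a field of 500 boutons (512×512 px, realistic density) in which
marker-A content is linearly coupled to release efficiency, then run the
full pipeline:

```r
library(destainr)

sim <- simulate_experiment(sim_config(n_boutons = 500,
                                      image_shape = c(512, 512),
                                      marker_slope = 1, seed = 42))
res <- run_pipeline(sim$stack,
                    list(marker_a = sim$marker_a, marker_b = sim$marker_b))
res
#> <pipeline_result> 481 ROIs (of 492 candidates) analysed
#> <group_summary> unloaded fraction by IR population
#>  group   n mean_unloaded_pct sem_unloaded_pct
#>  whole 481             32.54           0.5824
#>   high  43             36.53           1.7459
#>    low 134             29.19           1.0095
#> one-way ANOVA: F(2, 655) = 6.666, p = 0.001361

tidy(res$summary)
#>   group_1 group_2    p_raw   p_adj significant
#> 1 whole   high    0.0483   0.145   FALSE
#> 2 whole   low     0.00637  0.0191  TRUE
#> 3 high    low     0.000408 0.00122 TRUE

res$alignment$marker_a
#> <alignment_transform> 'marker_a' shift (3, -2), peak r = 0.6022
```

Reading: 481 boutons survived quality control and edge removal; the
planted channel shift of (3, −2) px was recovered exactly; boutons with
more than twice the mean marker content unload 36.5% of their dye versus
29.2% for boutons below half the mean — the planted positive coupling,
read back through the full imaging pipeline, with high vs low significant
after Bonferroni correction. With `marker_slope = 0` the same pipeline
reports no significant segregation. `plot_group_traces(res$summary)`,
`plot_unloaded_fractions(res$summary)` and `plot_channel_linearity(res$ir)`
draw the standard figures; `export_pipeline(res, "out/")` writes the
per-ROI CSV, group summary, and run metadata.

Real data enter through `read_stack()` (multi-frame grayscale TIFF plus
explicit acquisition timing) and `read_channel()`; a thin CLI wrapper with
`simulate` and `analyze` subcommands lives in `inst/scripts/destainr-cli.R`.

See the vignette (`vignettes/posthoc-correlation.Rmd`) for the models,
defaults, and design decisions.

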