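# ciliadyn

Quantification of cilia dynamics, basal-body polarity and ciliary flow from
fluorescence microscopy, for cell biologists studying ciliogenesis and
planar cell polarity.

Primary (sensory) cilia assemble when cells exit the cycle and disassemble
on cue; multiciliated epithelia additionally align their basal bodies so
that hundreds of motile cilia beat in one direction and drive fluid flow.
`ciliadyn` implements the measurement side of such studies:

* **Cilia detection and length** — a multi-step procedure on two-channel
  3D stacks (centrosome marker such as pericentrin, plus acetylated
  α-tubulin marking the axoneme): maximum-intensity z-projection, spot
  detection of centrosomes, an 11 µm peri-centrosomal crop, segmentation of
  the bright proximal axoneme cluster, contrast-limited region growing to
  the full axoneme mask, and skeleton-based length measurement. A cell is
  *ciliated* when its measured axoneme reaches 1 µm. Per-field summaries
  aggregate into disassembly time courses with s.e.m. error bars and Welch
  t-tests against a control.
* **Rotational and translational polarity** — orientation vectors (traced
  basal-rootlet→basal-body lines, or cell-centroid→basal-body-patch
  vectors) are reduced to the circular standard deviation
  CSD = √(−2 ln R), where R is the mean resultant length of the unit
  vectors. Angles are re-centred per cell (or per field of view) to a 90°
  circular mean before pooling into rose plots; conditions are compared
  with an exact or normal-approximation Mann–Whitney test.
* **Bead flow** — trajectory linking and per-track velocity (path length /
  elapsed time) and tortuosity (path length / chord; 1 = perfectly
  straight), summarised relative to a control condition.
* **LUMIER screens** — the interaction hit filter: a prey scores when its
  luminescence intensity ratio is ≥ 3 in both replicate screens.
* **Synthetic data** — generators with known ground truth for every input
  modality (rendered two-channel fields with Poisson + Gaussian camera
  noise, von Mises orientation vectors, drift + diffusion bead tracks,
  LUMIER tables), so the whole pipeline is validated by parameter
  recovery.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on summary objects, `autoplot()` for rose plots, time courses
and flow summaries.

## Worked example

Simulate a field of 100 cells at 60 % ciliation and run the detector:

```r
library(ciliadyn)

sim <- generate_cilia_field(field_params(n_centrosomes = 100,
                                         ciliation_fraction = 0.6, seed = 32))
res <- quantify_field(sim$stack)
res
#> <cilia_field> field1: 100 cells, 60.0% ciliated, mean length 4.55 um
```

The detector recovered 60 % ciliated against a true 60 %, with mean
axoneme length 4.55 µm. Rotational polarity on simulated cells at two von
Mises concentrations (κ = 50, tightly aligned rootlets, versus κ = 1,
disorganised):

```r
tight <- generate_polarity_cells(20, 30, kappa = 50, seed = 101); tight$condition <- "control"
loose <- generate_polarity_cells(20, 30, kappa = 1,  seed = 102); loose$condition <- "morphant"
rp <- rotational_polarity_summary(dplyr::bind_rows(tight, loose))
glance(rp)
#> # A tibble: 2 × 6
#>   condition mean_csd_deg sd_csd_deg n_groups  mw_U   mw_p_value
#>   <chr>            <dbl>      <dbl>    <int> <dbl>        <dbl>
#> 1 control           8.17       1.11       20     0 0.0000000680
#> 2 morphant         67.1        9.54       20     0 0.0000000680
```

A disorganised condition carries a roughly tenfold larger mean CSD
(67.1° vs 8.2°), and the Mann–Whitney comparison of per-cell CSDs is
decisive. `autoplot(rp)` draws the corresponding rose plots.

## Acceptance script

`scripts/acceptance.R` regenerates synthetic inputs from a seed and runs
the main pipeline end to end — detection recovery at three ciliation
fractions, polarity discrimination, bead-flow statistics and the LUMIER
filter — logging each stage's recovered values and writing its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
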