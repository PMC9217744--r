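# replitad

Where in the genome does DNA replication start? In human cells, origins fire
stochastically within ~40-kb initiation zones (IZs), and high-efficiency,
early-S-phase IZs concentrate at a specific subset of chromatin domain
boundaries: those flanked by corner-dot (loop-anchored) TADs/subTADs and
carrying dense arrays of CTCF+cohesin-bound motifs in convergent or
divergent ("complex") orientation. `replitad` implements that analysis as a
tested, end-to-end R pipeline for people working on replication timing and
3D genome structure:

- **Domain and loop detection** from binned Hi-C contact matrices:
  multi-scale insulation (windows of 4/8/16 bins; score
  `log2(mean of the inter-domain square / chromosome median)`) with
  cross-scale merging, and a local-background Poisson dot caller (donut,
  lower-left-quadrant and arm backgrounds; `P(X >= obs | lambda)` with BH
  correction at q <= 0.1, enrichment >= 1.75).
- **Six-class boundary stratification**: corner-dot status of the flanking
  domains (double-dot and single-dot pool into *dot* boundaries) crossed
  with CTCF+cohesin motif orientation — complex (both strands, classes
  1/4), tandem or single motif (classes 2/5), no bound motif (classes 3/6).
- **IZ calling from 16-fraction Repli-seq**: per-bin timing
  `T = sum(f * p_f)` over unit-sum fraction vectors, local timing minima
  with prominence >= 0.5 fractions, width from the `T <= T(apex) + 1`
  extent, timing classes early / early-mid / late split at T = 5.5 and
  10.5; plus the classical two-fraction `log2(E/L)` track.
- **The randomization enrichment test**: observed IZ-boundary
  colocalization counts against null IZs matched by exact width and
  majority A/B compartment label, with right-tailed empirical
  `P = (1 + #{X_r >= X_obs}) / (R + 1)`.
- **A synthetic-genome generator** that plants all of the above (domains,
  corner dots, motif grammars, compartments, a replication-timing field
  with fork slopes) and emits noisy observables, so every stage is
  validated against known truth.

## Worked example

```r
library(replitad)

# a 50-Mb genome, 50-kb bins, 16 boundaries of each of the six classes
cfg   <- simulation_config(seed = 1)
truth <- simulate_architecture(cfg)
cm    <- simulate_contact_matrix(truth)

# structure: domains -> dots -> corner-dot co-registration -> boundaries
ex    <- compute_expected(cm)
doms  <- call_domains(cm)
dots  <- call_dots(cm, ex)
bnd   <- coregister_corner_dots(doms, dots, tol_bins = 2) |>
  derive_boundaries() |>
  assign_sites_to_boundaries(simulate_binding_sites(truth), bin_width = 50000) |>
  stratify_boundaries()
table(bnd$class_index)
#>  1  2  3  4  5  6
#> 16 16 16 16 16 16

# replication: IZs from 16-fraction Repli-seq
izs <- call_izs(simulate_repliseq(truth))
table(izs$timing_class)
#>     early early_mid      late
#>        19        12         7

# the statistical core: IZ enrichment at class-1 boundaries vs matched nulls
tz    <- truth$izs[truth$izs$expressed, ]
nulls <- sample_matched_nulls(tz, truth$compartments, truth$grid,
                              R = 999, seed = 8)
enr   <- empirical_enrichment(tz, stratify_boundaries(truth$boundaries),
                              nulls, bin_width = 50000)
dplyr::filter(tidy(enr), timing_class == "early", class_index %in% c(1, 6))
#> # A tibble: 2 x 7
#>   class_index timing_class x_obs     r null_mean p_right p_left
#>         <int> <chr>        <int> <int>     <dbl>   <dbl>  <dbl>
#> 1           1 early           12   999      1.55   0.001  1
#> 2           6 early            0   999      1.32   1      0.259
```

Early IZs sit on 12 of the 16 class-1 boundaries while matched random
intervals hit ~1.5 on average, giving the floor empirical P of 1/1000;
class-6 (dotless, motif-free) boundaries show no early-IZ signal. The
`autoplot()` methods draw the boundary-centered 16-fraction heatmaps and
the observed-vs-null histograms; `plot_apa()` draws aggregate O/E maps.

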