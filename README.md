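# fibreimc

Single-fibre analysis of imaging mass cytometry (IMC) from transverse
skeletal-muscle sections, for researchers studying mitochondrial disease
and other myopathies at single-cell resolution.

IMC delivers one 16-bit pseudo-image per metal-conjugated antibody at
1 px = 1 µm². `fibreimc` segments individual muscle-fibre cross-sections
from the dystrophin membrane channel, quantifies every channel per fibre,
and classifies oxidative-phosphorylation (OXPHOS) deficiency *relative to
mitochondrial mass* (VDAC1/porin), which varies strongly between fibres.
A synthetic mosaic generator with known ground truth makes the whole
pipeline testable without patient material.

## The statistics at the core

For each target channel *c*, an ordinary-least-squares fit over control
fibres on the natural-log scale,

```
log I_c = beta_0 + beta_1 · log VDAC1 + eps,   eps ~ N(0, sigma²)
```

with the 95% predictive interval for a new control fibre at reference
value x0:

```
yhat(x0) ± t(0.975, n−2) · s · sqrt(1 + 1/n + (x0 − x̄)² / Sxx)
```

Patient fibres below the band are deficient relative to mass; above,
upregulated ("2Dmito" classification). Independently, each fibre's
**theta** — the angle `atan2(y, x)·180/π` its point makes with the origin
in the target-vs-VDAC1 plane — is classified by comparing kernel density
estimates: a fibre is *affected* when its theta is more likely under the
patient density than the control density **and** falls outside the
central 95% percentile range of control thetas. Spatial clustering of
deficient fibres is tested with an upper-tail hypergeometric test on the
neighbour graph (neighbours = centroids within 5× the average effective
radius, `sqrt(area/π)`).

## Worked example

Simulate a control section and a patient section in which 40% of fibres
have NDUFB8/MTCO1/SDHA suppressed to 15% of their control-relation level,
then run segmentation, classification and the spatial test:

```r
library(fibreimc)
library(dplyr)

ctrl <- generate_mosaic(mosaic_spec(field_size = 600, n_fibres = 50, rng_seed = 1))
pat  <- generate_mosaic(mosaic_spec(field_size = 600, n_fibres = 50, rng_seed = 2,
          deficient_fraction = 0.4, deficiency_factor = 0.15,
          spatial_clustering = list(cluster_count = 1, cluster_radius = 150)))

seg <- function(mos, id, control) {
  labs <- filter_regions(segment_fibres(mos$stack$Dystrophin))
  extract_features(labs, mos$stack) |>
    mutate(sample = id, control = control, .before = 1)
}
fibres <- bind_rows(seg(ctrl, "C01", TRUE), seg(pat, "P01", FALSE))

calls <- classify_deficiency(fibres, c("NDUFB8", "MTCO1", "SDHA"))
glance(calls)
#> # A tibble: 3 × 6
#>   channel reference sigma n_control level scale
#>   <chr>   <chr>     <dbl>     <int> <dbl> <chr>
#> 1 NDUFB8  VDAC1     0.140        30  0.95 log
#> 2 MTCO1   VDAC1     0.109        30  0.95 log
#> 3 SDHA    VDAC1     0.143        30  0.95 log

p01 <- filter(calls$calls, sample == "P01", channel == "NDUFB8")
mean(p01$call_2dmito == "below")
#> [1] 0.3846154        # 10/26 fibres below the band; ground truth: 38% deficient

fs <- filter(fibres, sample == "P01")
enr <- neighbourhood_enrichment(build_neighbour_graph(fs),
         p01$call_2dmito[match(fs$fibre, p01$fibre)] == "below")
enr
#> <enrichment_result> k = 10 deficient among n = 25 neighbours (K = 10 of N = 26); p = 0.6154
```

The per-channel residual sd (`sigma ≈ 0.11–0.14` on the log scale) is the
tightness of the control band; the `below` fraction recovers the
simulated deficient fraction; and the enrichment p-value is
uninformative here because on a 26-fibre section the neighbourhoods of
10 deficient fibres cover nearly everything (`n = 25 of N = 26`) — see
the methods vignette for when this test has power. `plot_2dmito()`,
`plot_theta_strip()`, `plot_fibre_map()` and `autoplot()` methods draw
the standard views.

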