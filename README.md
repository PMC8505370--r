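# nemacomm

Genus-level soil **nema**tode **comm**unity analysis for designed
plant-diversity experiments, as a tidyverse-native R package.

Soil nematodes occupy every trophic level of the soil food web — plant
feeders (PF), bacterial feeders (BF), fungal feeders (FF), predators (Pr)
and omnivores (Om) — and their community structure is a standard
bioindicator of how plant diversity reshapes belowground food webs.
`nemacomm` implements the complete analysis chain for such studies:

* **Sampling arithmetic.** Counts come from a soil subsample in which all
  animals are counted but at most 100 are identified to genus; identified
  shares are allocated over the total and extrapolated to individuals per
  100 g dry soil.
* **Faunal indices.** Shannon diversity H′ = −Σ qᵍ ln qᵍ, trophic-group
  abundances/richness, predator–prey ratio (Pr+Om)/PF, channel ratio
  FF/(FF+BF), grazing pressure log(PF/root mass), colonizer–persister (c–p)
  class abundances, the Maturity Index MI = Σ vᵍ qᵍ (over free-living taxa),
  and the guild-weighted Enrichment and Structure indices
  EI = 100·e/(e+b), SI = 100·s/(s+b).
* **Ordination.** Three-dimensional NMDS (Kruskal stress-1) on Bray–Curtis
  or Jaccard dissimilarity, permutation vector fitting of genera,
  IndVal indicator analysis (stat = √(A·B), label-permutation p), SD-ellipse
  areas of group scores.
* **Inference.** Linear-mixed-model likelihood-ratio tests of sown
  (log-linear) and realized plant species-richness effects with crossed
  block and mixture-identity random intercepts; Tukey HSD comparisons of
  NMDS scores; transgressive overyielding D_max = (O_T − M)/M against the
  best constituent monoculture, with a sum-to-zero ANOVA of its grand mean;
  and piecewise structural equation models judged by d-separation tests and
  Fisher's C = −2 Σ ln pᵢ.
* **Synthetic data.** A deterministic reconstruction of a 93-plot
  dominance-experiment design (richness levels 1/2/6/9 over nine grassland
  species in four blocks) and a fully seeded generator that simulates
  covariates and subsampled nematode counts with a configurable causal
  structure — so everything above runs, and is testable, without any
  download.

## Worked example

```r
library(nemacomm)
library(dplyr)

cfg <- synth_config(seed = 1)     # the simulated study conditions
ds  <- generate_dataset(cfg)      # 93 plots, covariates + counts

idx <- compute_indices(ds$counts, ds$samples, covariates = ds$covariates)
idx %>% select(plot_id, total_per_100g, shannon, bf, channel, mi, ei, si) %>% head(3)
#> # A tibble: 3 × 8
#>   plot_id   total_per_100g shannon    bf channel    mi    ei    si
#>   <chr>              <dbl>   <dbl> <dbl>   <dbl> <dbl> <dbl> <dbl>
#> 1 SR1_Ae_r1          1556.    3.10  451.   0.42   2.67  33.9  69.4
#> 2 SR1_Ae_r2          1599.    2.97  224.   0.667  2.77  39.6  71.9
#> 3 SR1_Ap_r1          1982.    2.58  238.   0.556  2.89  32.4  75.1

tab <- sem_data(ds, indices = idx)
lrt_richness(tab, "shannon", "sown")
#> # A tibble: 1 × 6
#>   response predictor    df  chi2       p singular
#>   <chr>    <chr>     <int> <dbl>   <dbl> <lgl>
#> 1 shannon  sown          1  9.31 0.00228 TRUE

fit <- fit_piecewise_sem(sem_model_trophic(), tab)
fit
#> Piecewise SEM: 86 observations (7 dropped), 10 paths, 25 claims
#> Fisher's C = 37.89, df = 50, p = 0.896
```

The per-plot metric table reads: ~1600–2000 nematodes per 100 g dry soil,
Shannon diversity around 2.6–3.1 nats, a channel ratio near 0.5 (balanced
fungal/bacterial energy channels) and a Maturity Index near 2.8 (a
moderately structured food web). The likelihood-ratio test finds a positive
sown-richness effect on nematode diversity in this simulation
(χ²₁ = 9.31, p = 0.002; the singular flag records that a random-effect
variance was estimated at zero), and the piecewise SEM's Fisher's C
(p = 0.90) shows the generated data are consistent with the trophic causal
structure they were simulated from.

Ordination and plotting follow the same grammar:

```r
prof <- genus_profiles(ds$counts, ds$samples)
ord  <- nmds(dissimilarity_matrix(prof, "bray"), k = 3, seed = 1)
glance(ord)                       # stress, convergence
autoplot(ord, groups = tibble(plot_id = ds$roster$plot_id,
                              group = ds$roster$sown_richness))
```

See the methods vignette (`vignettes/nematode-community-analysis.Rmd`) for
the model definitions, conventions (transformation ledger, permutation p
estimators, SEM claim testing) and the generator's assumptions.

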