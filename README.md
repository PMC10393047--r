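# ednaflow

Interaction networks and their temperature sensitivity from quantitative
environmental-DNA (eDNA) time series.

Coastal fish communities can be monitored almost non-invasively by
metabarcoding the DNA that fish shed into seawater. When an internal
spike-in standard of known concentration is sequenced alongside, read
counts become estimates of absolute eDNA concentration, and a multi-year,
multi-site survey yields a quantitative multispecies time series. This
package implements the downstream inference for such data:

* **Quantification** — reads are converted to eDNA copies per µL via the
  spike-in (`reads_to_copies()`), dominant species selected
  (`select_top_species()`), and per-species series merged across sites and
  standardized (`standardize_merge()`).
* **Interaction detection** — a directed interaction from species *y* to
  species *x* is detected as conditional transfer entropy

  $$TE = \frac{1}{T}\sum_t \log\frac{p(y_{t+tp}\mid x_t, x_{t-\tau},\dots,x_{t-(E-1)\tau},\,z_t)}{p(y_{t+tp}\mid x_{t-\tau},\dots,x_{t-E\tau},\,z_t)}$$

  estimated by nearest-neighbour cross mapping on time-delay embeddings of
  the effect series, scanning causal lags *tp* = 0…−6, conditioning on
  environmental covariates (temperature, salinity, wave, tide) that clearly
  influence the effect species, and testing *TE* > 0 by bootstrap
  (`uic_test()`, `all_pairs()`).
* **Interaction strength** — for each detected edge, the multiview distance
  regularized (MDR) S-map fits, at every time point, a locally weighted
  ridge regression
  $\hat x_{1,t^*+1} = IS_0 + \sum_j IS_j\, x_{j,t^*}$
  whose coefficients $IS_j$ are time-varying interaction strengths
  (`interaction_strengths()`, `mdr_smap_fit()`, `multiview_distance()`).
* **Temperature sensitivity** — |IS| is modelled against temperature (or
  richness, total eDNA, …) with gamma-family additive models with random
  intercepts (community level: site + species; species level: site +
  partner), and each species' smooth is classified increasing / decreasing
  / non-monotone (`fit_strength_model()`,
  `species_temperature_effects()`, `build_network()`).
* **Synthetic truth** — a temperature-modulated multispecies Ricker
  simulator with analytic interaction Jacobians
  (`simulate_community()`, `jacobian_oracle()`) provides ground truth for
  validating every stage.

## Worked example

```r
library(ednaflow)

# a small synthetic survey: 5 species, 2 sites, ~4 years of half-monthly
# sampling, with temperature-modulated couplings
sim <- simulate_community(n_species = 5, n_sites = 2, n_steps = 100,
                          connectance = 0.35, gamma_scale = 0.5, seed = 42)
sim$truth
#> Community parameters: 5 species, 10 of 20 off-diagonal couplings,
#>   gamma range [ -0.598 , 0.415 ], process noise sd 0.05 , 0 stability rejections

pan   <- reads_to_copies(sim$panel, spike_species = "sp01")
panel <- standardize_merge(pan, select_top_species(pan, 5))
panel
#> Standardized panel: 5 species + 4 covariates, 200 merged time points over 2 site segment(s)

net <- all_pairs(panel, alpha = 0.05, tp_range = 0:-2, n_boot = 200, seed = 7)
net
#> Interaction set: 20 ordered pairs tested, 5 statistically clear at alpha = 0.05
clear_edges(net)[, c("cause", "effect", "tp", "E", "te", "p_value")]
#>    cause effect tp E     te p_value
#> 12  sp04   sp05 -1 2 0.1140    0.00
#> 13  sp03   sp01  0 2 0.2400    0.00
#> 16  sp04   sp01  0 2 0.1047    0.04
#> 17  sp03   sp04 -2 2 0.0497    0.00
#> 20  sp01   sp04 -1 2 0.0641    0.03
```

Each clear edge is one directed interaction: `sp04 -> sp05` at lag −1 means
sp04's abundance carries clear information about sp05 one half-month later,
beyond sp05's own history and the selected environmental conditioners. At
this deliberately small scale detection is noisy (two of the five edges
match true couplings of this community; power and false-positive rates at
the package's validated scales are quantified by the acceptance
experiments below).

```r
rec <- interaction_strengths(panel, net, targets = unique(clear_edges(net)$effect),
                             seed = 7)
st  <- strength_table(rec, pan)
fit_strength_model(st, predictor = "temperature", direction = "in")
#> Gamma GAMM of |IS| (in-strength) ~ s(temperature): n = 986,
#> smooth p = 0.129 (not clear), endpoint difference = 0.0448
```

Here 986 per-time-point strength observations show no clear community-level
temperature effect — unsurprising for one small community; the generative
recovery experiments below measure when the method does detect one.

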