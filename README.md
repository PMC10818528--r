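# ssfra — species sensitivity factor read-across for acute aquatic toxicity

`ssfra` predicts the acute aquatic toxicity (LC50) of a data-poor
**target** chemical from a structurally and mechanistically similar
**source** chemical, and quantifies how well such predictions agree with
held-out measured values. It is written for ecotoxicologists and
regulatory risk assessors doing screening-level hazard assessment of
category chemicals — here, acetylcholinesterase (AChE)-inhibiting
organophosphates and carbamates — where animal testing for every
chemical × species combination is not an option.

## The method

Within a category selected by mode of action, functional group and
log Kow ≤ 5, chemicals are paired so the higher-log Kow (expectedly more
toxic) member is the target. For each species *i* with aggregated LC50s
for both chemicals, the **species sensitivity ratio** is

    SSR_i = LC50_target,i / LC50_source,i

A matched species with SSR > 1 (more sensitive to the source) is excluded
as uninformative for the category's log Kow–potency premise. The
**species sensitivity factor** of a donor set D is the geometric mean

    SSF = ( prod_{i in D} SSR_i )^(1/|D|)

and the prediction for a species *s* of interest is

    LC50_hat_target,s = SSF × LC50_source,s

Donors always come from taxa other than the predicted species' own taxon.
With matched species in ≥ 3 taxa (*Case I*), every cross-combination of
one donor per other taxon is enumerated; with exactly 2 (*Case II*), the
single donor taxon's species are pooled. A prediction below the known
value *overestimates* toxicity (conservative), above it *underestimates*;
row decisions are strict majorities, ties giving "nd".

Agreement of log10 predictions `e` with log10 known values `a` is
summarized by bias `mean(e−a)`, relative bias `(exp(bias)−1)×100%`,
precision `sd(e−a)`, accuracy `mean(|e−a|)` (MAE), Bland–Altman limits
`mean ± 1.96 sd`, and Pearson *r*.

## Worked example

```r
library(ssfra)

chems <- load_chemicals(ssfra_example("chemicals_table1.csv"))
registry_summary(select_category(chems))
#> Chemical registry: 25 chemicals
#>   log Kow range: -0.85 to 4.96
#>   by functional group:
#>     carbamate        7
#>     ester_phosphate  6
#>     thiophosphate    12
#>   by Verhaar class:
#>     class 4          19
#>     class 5          6
```

All 25 bundled AChE inhibitors survive category selection (the registry
maximum, chlorpyrifos at log Kow 4.96, sits below the cutoff), and 19
carry Verhaar class 4 (specifically acting).

On synthetic data with a known multiplicative sensitivity structure and
all noise switched off, the pipeline recovers every held-out value
exactly — the method's exactness regime:

```r
cfg <- synthetic_config(n_chemicals = 6, species_per_taxon = 3,
                        replicates_per_species = 1,
                        interaction_sd = 0, replicate_sd = 0, seed = 42)
syn <- generate_synthetic(cfg)
run <- run_pipeline(syn$chemicals, syn$toxicity, quiet = TRUE)
run$agreement[run$agreement$group == "overall",
              c("scenario", "n", "bias", "precision", "pearson_r")]
#>   scenario    n         bias    precision pearson_r
#> 1   case_I 1215 3.564821e-17 2.325978e-16         1
```

Zero bias and spread (to machine precision) and r = 1: every one of the
1215 predictions equals its held-out truth. At the full study-scale
default conditions (25 chemicals, realistic noise):

```r
syn2 <- generate_synthetic(synthetic_config(seed = 1))
run2 <- run_pipeline(syn2$chemicals, syn2$toxicity, quiet = TRUE)
run2
#> SSF read-across run: ok
#>   chemicals: 25  pairs: 300
#>   scenarios: 298 Case I, 2 Case II, 0 ineligible
#>   predictions: 48154
#>   agreement (overall rows):
#>     case_I   n=48144 bias=7.789e-18 precision=0.5858 MAE=0.4686 r=0.8703
#>     case_II  n=10 bias=0.001773 precision=0.2566 MAE=0.2107 r=0.972
```

Here the bias stays near zero (the estimator is unbiased on the log
scale under the generative model), the precision of ~0.59 log10 units
reflects the injected species-interaction and replicate noise, and the
log-scale correlation between predictions and held-out truths is ~0.87.
`plot_bland_altman()` and `plot_agreement_scatter()` draw the standard
agreement figures from any `residual_set()`.

A thin command-line wrapper is included at `inst/cli/ssfra.R`
(`run` and `simulate` subcommands).

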