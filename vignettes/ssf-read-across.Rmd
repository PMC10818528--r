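---
title: "Species sensitivity factor read-across: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species sensitivity factor read-across: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssfra)
```

## The problem

Acute aquatic toxicity (LC50) data are unevenly distributed across
chemicals: a handful of well-studied compounds carry dozens of species
records while structurally similar neighbours carry few or none.
Read-across fills such gaps by transferring measured endpoints from a
data-rich *source* chemical to a data-poor *target* chemical inside a
category of structurally and mechanistically similar compounds.

Classical read-across copies the source value directly for the same
species. That ignores a robust empirical pattern: within a category
sharing a specific mode of action, toxicity scales with hydrophobicity
(log Kow), and different species respond to that scaling in a strongly
correlated way. `ssfra` implements a read-across variant that measures the
source-to-target potency shift on species the two chemicals share, and
transfers that shift — not the raw value — to the species of interest.

The packaged registry (`ssfra_example("chemicals_table1.csv")`) defines
the category used throughout: 25 organophosphate and carbamate pesticides
acting by acetylcholinesterase (AChE) inhibition, spread over three
functional groups (phosphate esters, carbamates, thiophosphates) with
log Kow from −0.85 to 4.96.

## The method

For an ordered pair with `log_kow(source) < log_kow(target)`:

1. **Aggregate.** Replicate LC50 records are pooled per (chemical,
   species) by geometric mean on the canonical µg/L scale; 24/48/96 h
   acute windows are treated as one endpoint.
2. **Match.** Per taxon (fish, crustacean, insect; amphibian supported as
   data), species with values for both chemicals form donor candidates,
   each with a species sensitivity ratio
   `SSR = LC50_target / LC50_source`.
3. **Exclude.** A matched species with `SSR > 1` is more sensitive to the
   *source* chemical, contradicting the category's log Kow–potency
   premise; its sensitivity is evidently driven by something else, so the
   species (not the pair) is set aside. `SSR = 1` exactly is retained as
   neutral evidence.
4. **Scenario.** With matched species in ≥ 3 prediction taxa the pair is
   *Case I* (every prediction taxon is served by two donor taxa); with
   exactly 2 it is *Case II*; otherwise it is ineligible.
5. **Predict.** The species sensitivity factor (SSF) is the geometric mean
   of donor SSRs, and
   `predicted LC50 = SSF × LC50_source(species of interest)`. Donors
   never come from the predicted species' own taxon. Under Case I each
   prediction uses exactly one matched species from each other prediction
   taxon, and all cross-combinations are enumerated, so a taxon's
   prediction count is the product of the other taxa's matched counts.
   Under Case II the single donor taxon's matched species are pooled into
   one geometric-mean SSF (see Design choices).
6. **Classify.** A predicted LC50 below the known value *overestimates*
   toxicity (conservative); above it, toxicity is *underestimated*.
   Species-level decisions are taken by strict majority over a species'
   predictions, row (pair × taxon) decisions by strict majority over
   species decisions, with equal counts recorded as `nd`.

## Agreement evaluation

All evaluation happens on log-transformed values, with
`e = log10(predicted)`, `a = log10(known)` and residuals `e − a`:

* **bias** — mean residual;
* **relative bias (%)** — `(exp(bias) − 1) × 100`;
* **precision** — sample standard deviation of the residuals;
* **accuracy** — mean absolute residual (MAE);
* **Bland–Altman** — mean difference with limits at ±1.96 sample SD,
  differences oriented predicted − known;
* **Pearson r** between `e` and `a`;
* an **Anderson–Darling gate** (`nortest::ad.test`) annotates whether the
  pooled log values look normal; it never blocks computation and is
  inconclusive below n = 8.

Two accuracy-flavoured statistics are reported side by side: the MAE and
`mean_offset = |mean(e) − mean(a)|`. By the triangle inequality
`MAE ≥ |bias| = mean_offset`; published summaries of this kind of analysis
sometimes report accuracy values smaller than their own bias, which is
only possible for a mean-level statistic, so both are exposed and the MAE
is the documented default. The bundled
`reference_agreement.csv` table exhibits exactly this inconsistency and is
shipped as-is for validation of the *transforms*, not reproduced by the
package's own definitions.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `max_log_kow` | 5 (inclusive) | Baseline-toxicity regime; the bound is inclusive because the category definition is stated both as "5 or less" and "less than 5" in common usage, the registry maximum is 4.96 under either reading, and the permissive reading is the safer default for a *configurable* cutoff. |
| `prediction_taxa` | fish, crustacean, insect | Amphibian acute data for AChE inhibitors are too sparse to anchor donor ratios; amphibians remain available as input data and can be added. |
| `solubility_filter` | on | LC50s at or above water solubility cannot be maintained in solution; strict `<` comparison. The switch exists because published per-chemical ranges often contain such records, so reproducing a published extract can require the filter off. |
| `donor_selection` | `"all"` | Case II pooling uses every matched donor species (geometric mean); `"closest"` instead picks the donor whose source-chemical LC50 is nearest in log units to the target species' own source value. |
| `durations` | 24, 48, 96 h pooled | The acute windows are treated as one endpoint; restrict to a single window to study duration sensitivity. |
| `log_base` | 10 | Toxicology convention for concentration data; relative bias always uses the natural exponential of the bias, independent of this choice, because that is how the transform is defined. |
| tie tolerance | 1e−12 (relative) | Predicted = known within floating-point noise counts as a tie, feeding `nd` rather than either direction. |

## Design choices at genuinely open points

* **Geometric mean for any n.** Gating aggregation on a minimum record
  count changes nothing for n = 1 (identity) and would make the estimator
  discontinuous in n; the geometric mean is used throughout.
* **Cross-functional-group pairing.** Pairing spans the whole AChE
  category because the mechanism, not the functional group, carries the
  species-sensitivity structure; the pair's reporting label is the source
  chemical's group.
* **Per-species exclusion.** The `SSR > 1` rule removes the offending
  species only, never the whole pair.
* **Case II donor pooling.** When the predicted taxon is itself one of
  the two matched taxa, the "other matched taxon" is unique and pooling
  equals the single-donor-taxon geometric mean. When the predicted taxon
  is the unmatched third, two matched taxa remain; the package pools over
  both rather than inventing a priority order, which reduces to the same
  geometric-mean principle and keeps the estimator symmetric in taxa.
* **Prediction targets.** Every species with a source-chemical value is
  predicted for; known values attach where the target chemical has data
  (matched species), and source-only species yield predictions with
  `classification = "unknown"` that are excluded from decisions and
  agreement metrics. Species excluded by the sensitivity rule are not
  predicted for — they were judged uninformative for this pair.
* **"Under" beyond the source value.** Predictions above the source
  chemical's own LC50 are still "under" but flagged `beyond_source`,
  since the reporting convention does not distinguish them.

## The synthetic generator

`synthetic_config()` / `generate_synthetic()` draw from

```
log10 LC50(c, s, k) = alpha − beta·logKow_c + tau_taxon + u_s + w_{c,s} + e_k
```

with species effects `u_s ~ N(0, species_sd²)`, chemical-by-species
interactions `w ~ N(0, interaction_sd²)` and replicate noise
`e_k ~ N(0, replicate_sd²)`, all driven by one seed that is restored
afterwards (no global RNG pollution).

Defaults — 25 chemicals over log Kow −0.85…4.96, three taxa, 4 species
per taxon, 3 replicates, `alpha = 3` log10 µg/L, `beta = 0.7` decades per
log Kow unit, taxon offsets (fish 0, crustacean −1, insect −0.5,
amphibian +0.5), and 0.3–0.5 log10-unit effect SDs — were chosen once as
a realistic acute-pesticide landscape: potency slopes for specifically
acting compounds sit below the ~0.9 of baseline narcosis QSARs,
crustaceans and insects are systematically more sensitive to AChE
inhibitors than fish, and inter-laboratory spread of acute LC50s is a
factor of ~2–3 (≈ 0.3–0.5 log10 units). Species universes overlap fully
by default; `dropout_prob` removes cells at random to create data-poor
(Case II) sparsity.

Because taxon and species effects are additive in log space, they cancel
in every within-species ratio: with `interaction_sd = 0` the true SSR of
a pair is `10^(−beta·Δlog Kow)` for every species (`true_ssf()`), and
with replicate noise also zero the full pipeline reproduces every
held-out value exactly — zero residuals, r = 1, all ties. This exactness
regime is the package's strongest end-to-end test. What the generator
does *not* emulate: study metadata and quality heterogeneity, censored or
rounded reporting, non-lognormal outliers, and correlated species
coverage (real data lose species non-randomly). Passing tests therefore
demonstrate the estimator's correctness under the stated model, not the
field accuracy of read-across on any particular extract.

## Numerical notes

* The per-species geometric mean is clamped into `[min, max]` of its
  inputs; `exp(mean(log(x)))` can drift one ulp outside.
* Statistics with minimum-n requirements (`precision`, Bland–Altman at
  n ≥ 2, Pearson r at n ≥ 3 with nonzero variance) error when called
  directly below their minimum but are reported as `NA` inside grouped
  summaries.
* Artifacts are byte-stable: pairs sort by source then target CAS,
  predictions by pair, taxon, species, donor label.
* An empty pairing (fewer than two selectable chemicals, or all log Kow
  tied) is a status (`no_eligible_pairs`) with empty artifacts, not an
  error; missing files and schema violations are errors.

Test and vignette problem sizes (4–8 chemicals, 2–3 species per taxon for
unit tests; the full 25-chemical default for the study-scale runs) are
the package's own choice of the smallest sizes at which every code path —
both scenarios, exclusions, dropouts, and all metric branches — is
exercised.

## Worked micro-example

```{r}
chems <- load_chemicals(ssfra_example("chemicals_table1.csv"))
registry_summary(select_category(chems))

cfg <- synthetic_config(n_chemicals = 6, species_per_taxon = 3,
                        replicates_per_species = 1,
                        interaction_sd = 0, replicate_sd = 0, seed = 42)
syn <- generate_synthetic(cfg)
run <- run_pipeline(syn$chemicals, syn$toxicity, quiet = TRUE)
run$agreement[run$agreement$group == "overall",
              c("scenario", "n", "bias", "precision", "pearson_r")]
```

## Known limitations

* The decision layer reports direction only; no uncertainty accompanies a
  prediction (none is defined for the estimator).
* The bundled reference tables are exemplar rows, not a full record-level
  extract, so dataset-scale published summaries cannot be recomputed from
  them; the package validates definitions, transforms, and worked rows
  instead. One bundled data-poor reference pair carries printed decision
  labels inconsistent with its own counts and values; it is retained
  verbatim and excluded from semantic checks.
* Verhaar classes, modes of action and functional groups are input data;
  the package performs no structure-based classification.
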