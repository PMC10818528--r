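test_that("toxicity loader canonicalizes units and validates rows", {
  path <- write_tox_csv(data.frame(value = c(0.11, 5, 2),
                                   unit = c("mg_per_L", "ug_per_L",
                                            "mg_per_L"),
                                   species = c("a", "b", "c")))
  recs <- load_toxicity(path)
  expect_equal(recs$value_ug_L, c(110, 5, 2000))
  expect_equal(recs$species, c("a", "b", "c"))  # order preserved

  expect_error(load_toxicity(write_tox_csv(data.frame(value = -1))),
               "nonpositive")
  expect_error(load_toxicity(write_tox_csv(data.frame(taxon = "mollusc"))),
               "taxon")
  expect_error(load_toxicity(write_tox_csv(data.frame(unit = "ppm"))),
               "unit")
  expect_error(load_toxicity(write_tox_csv(data.frame(duration_h = 12))),
               "duration")
})

test_that("solubility filter drops records at or above solubility, strictly", {
  registry <- load_chemicals(ssfra_example("chemicals_table1.csv"))
  # Dichlorvos: solubility 8 mg/L = 8000 ug/L
  recs <- data.frame(cas = "62-73-7", species = c("a", "b", "c"),
                     taxon = "fish", endpoint = "LC50", duration_h = 96,
                     value_ug_L = c(5000, 9000, 8000),
                     stringsAsFactors = FALSE)
  kept <- filter_solubility(recs, registry, quiet = TRUE)
  expect_equal(kept$value_ug_L, 5000)  # 9000 above, 8000 equal -> dropped
  expect_equal(attr(kept, "dropped")$n_dropped, 2L)

  empty <- filter_solubility(recs[0, ], registry, quiet = TRUE)
  expect_equal(nrow(empty), 0L)

  recs$cas <- "999-99-9"
  expect_error(filter_solubility(recs, registry, quiet = TRUE), "999-99-9")
})

test_that("species aggregation takes geometric means within [min, max]", {
  recs <- data.frame(cas = "62-73-7",
                     species = c("a", "a", "b", rep("c", 4)),
                     taxon = c(rep("fish", 3), rep("crustacean", 4)),
                     endpoint = "LC50", duration_h = 96,
                     value_ug_L = c(10, 1000, 7, 1, 10, 100, 1000),
                     stringsAsFactors = FALSE)
  agg <- aggregate_species(recs)
  expect_equal(agg$lc50_ug_L[agg$species == "a"], 100)
  expect_equal(agg$lc50_ug_L[agg$species == "b"], 7)     # singleton identity
  expect_equal(agg$n_values[agg$species == "b"], 1L)
  # independent oracle: exp of the mean log
  expect_equal(agg$lc50_ug_L[agg$species == "c"],
               exp(mean(log(c(1, 10, 100, 1000)))))
  expect_equal(agg$lc50_ug_L[agg$species == "c"], 10^1.5)
  expect_true(all(agg$min_ug_L <= agg$lc50_ug_L &
                    agg$lc50_ug_L <= agg$max_ug_L))
})

test_that("aggregation is scale-equivariant and commutes with filtering", {
  withr::local_seed(11)
  for (i in 1:5) {
    n <- sample(2:12, 1)
    recs <- data.frame(cas = "62-73-7",
                       species = sample(letters[1:3], n, replace = TRUE),
                       taxon = "fish", endpoint = "LC50", duration_h = 96,
                       value_ug_L = exp(stats::rnorm(n, 3, 2)),
                       stringsAsFactors = FALSE)
    scaled <- recs
    cc <- exp(stats::runif(1, -2, 2))
    scaled$value_ug_L <- recs$value_ug_L * cc
    expect_equal(aggregate_species(scaled)$lc50_ug_L,
                 aggregate_species(recs)$lc50_ug_L * cc)
  }

  registry <- load_chemicals(ssfra_example("chemicals_table1.csv"))
  recs <- data.frame(cas = "62-73-7",
                     species = rep(c("a", "b"), each = 4),
                     taxon = "fish", endpoint = "LC50", duration_h = 96,
                     value_ug_L = c(100, 5000, 9000, 200,
                                    12000, 50, 70, 8500),
                     stringsAsFactors = FALSE)
  filtered_first <- aggregate_species(filter_solubility(recs, registry,
                                                        quiet = TRUE))
  manual <- recs[recs$value_ug_L < 8000, ]
  expect_equal(filtered_first, aggregate_species(manual))
})
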