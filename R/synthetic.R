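#' Configuration for the synthetic ecotoxicity generator
#'
#' Defines a generative model with a known multiplicative species
#' sensitivity structure:
#' \deqn{\log_{10} LC50(c, s, k) = \alpha - \beta\,\mathrm{logKow}_c +
#'   \tau_{taxon(s)} + u_s + w_{c,s} + \epsilon_k}
#' with species effects \eqn{u_s \sim N(0, species\_sd^2)},
#' chemical-by-species interactions \eqn{w_{c,s} \sim N(0,
#' interaction\_sd^2)} and replicate noise \eqn{\epsilon_k \sim N(0,
#' replicate\_sd^2)}. Because the taxon and species effects are additive on
#' the log scale, they cancel in every within-species source/target ratio:
#' with zero interaction variance the true SSR of a pair is
#' `10^(-beta * delta_log_kow)` for every species, which is what makes
#' exact end-to-end recovery testable.
#'
#' Defaults mirror the study conditions of the packaged registry: 25
#' chemicals spanning log Kow -0.85 to 4.96, three prediction taxa, and a
#' potency slope under one toxicity decade per log Kow unit.
#'
#' @param n_chemicals number of chemicals (>= 2).
#' @param log_kow_range numeric length-2, chemicals are spread evenly over
#'   this interval (even spacing guarantees distinct values, so every
#'   unordered pair is orderable).
#' @param taxa subset of fish/crustacean/insect/amphibian.
#' @param species_per_taxon species simulated per taxon.
#' @param replicates_per_species LC50 records per (chemical, species).
#' @param intercept_alpha intercept, log10 ug/L.
#' @param potency_slope_beta toxicity decades gained per log Kow unit
#'   (>= 0).
#' @param taxon_offsets named vector of log10 offsets covering `taxa`;
#'   defaults make crustaceans and insects more sensitive than fish and
#'   amphibians less so, as acute AChE-inhibitor data typically show.
#' @param species_sd,interaction_sd,replicate_sd standard deviations
#'   (log10 units) of the three random effects, all >= 0.
#' @param dropout_prob probability of removing a (chemical, species) cell,
#'   creating realistic Case II sparsity (default 0: full overlap).
#' @param seed integer seed governing every draw.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chemicals = 25,
                             log_kow_range = c(-0.85, 4.96),
                             taxa = c("fish", "crustacean", "insect"),
                             species_per_taxon = 4,
                             replicates_per_species = 3,
                             intercept_alpha = 3,
                             potency_slope_beta = 0.7,
                             taxon_offsets = c(fish = 0, crustacean = -1,
                                               insect = -0.5,
                                               amphibian = 0.5),
                             species_sd = 0.5,
                             interaction_sd = 0.3,
                             replicate_sd = 0.3,
                             dropout_prob = 0,
                             seed = 1L) {
  stopifnot(length(n_chemicals) == 1L, n_chemicals >= 2,
            length(log_kow_range) == 2L,
            log_kow_range[1] < log_kow_range[2],
            length(taxa) >= 1L, all(taxa %in% ssfra_taxa()),
            species_per_taxon >= 1, replicates_per_species >= 1,
            potency_slope_beta >= 0,
            all(taxa %in% names(taxon_offsets)),
            species_sd >= 0, interaction_sd >= 0, replicate_sd >= 0,
            dropout_prob >= 0, dropout_prob < 1,
            length(seed) == 1L, is.finite(seed))
  cfg <- list(n_chemicals = as.integer(n_chemicals),
              log_kow_range = as.numeric(log_kow_range),
              taxa = taxa,
              species_per_taxon = as.integer(species_per_taxon),
              replicates_per_species = as.integer(replicates_per_species),
              intercept_alpha = intercept_alpha,
              potency_slope_beta = potency_slope_beta,
              taxon_offsets = taxon_offsets[ssfra_taxa()[ssfra_taxa() %in%
                                                           names(taxon_offsets)]],
              species_sd = species_sd,
              interaction_sd = interaction_sd,
              replicate_sd = replicate_sd,
              dropout_prob = dropout_prob,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic registry, toxicity table, and ground truth
#'
#' Draws one realization of the model described in [synthetic_config()].
#' The chemical and toxicity tables use the exact external CSV schemas of
#' [load_chemicals()] and [load_toxicity()] (values emitted in ug/L), so
#' the output round-trips through the loaders and the whole pipeline.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements
#'   \describe{
#'     \item{chemicals}{registry data frame (water solubility set high so
#'       the solubility filter is neutral on synthetic data).}
#'     \item{toxicity}{record-level table `cas, species, taxon, endpoint,
#'       duration_h, value, unit`.}
#'     \item{truth}{per ordered pair and species: `source_cas`,
#'       `target_cas`, `species`, `taxon`, `true_ssr` (exact, including
#'       interactions), `true_ssf` (the geometric mean of the pair's true
#'       SSRs over all species), `true_lc50_ug_L` (the target chemical's
#'       noise-free value for that species).}
#'   }
#'   The config is attached as the `"config"` attribute. Identical configs
#'   (same seed) give identical output.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    n <- config$n_chemicals
    log_kow <- seq(config$log_kow_range[1], config$log_kow_range[2],
                   length.out = n)
    cas <- sprintf("%d-%02d-%d", 900000 + seq_len(n), seq_len(n) %% 100,
                   seq_len(n) %% 10)
    chemicals <- data.frame(
      name = sprintf("SYN-%02d", seq_len(n)),
      cas = cas,
      molecular_weight = 150 + 10 * seq_len(n),
      log_kow = log_kow,
      water_solubility_mg_L = 1e6,
      moa = "AChE_inhibition",
      functional_group = rep(ssfra_functional_groups(), length.out = n),
      subgroup = NA_character_,
      verhaar_class = 4L,
      stringsAsFactors = FALSE
    )

    species <- do.call(rbind, lapply(config$taxa, function(tx) {
      data.frame(species = sprintf("%s_s%02d", tx,
                                   seq_len(config$species_per_taxon)),
                 taxon = tx, stringsAsFactors = FALSE)
    }))
    species$effect <- stats::rnorm(nrow(species), 0, config$species_sd)
    interaction <- matrix(stats::rnorm(n * nrow(species), 0,
                                       config$interaction_sd),
                          nrow = n, ncol = nrow(species))

    cells <- expand.grid(chem = seq_len(n), sp = seq_len(nrow(species)),
                         KEEP.OUT.ATTRS = FALSE)
    if (config$dropout_prob > 0) {
      keep <- stats::runif(nrow(cells)) >= config$dropout_prob
      cells <- cells[keep, , drop = FALSE]
    }
    mu <- config$intercept_alpha -
      config$potency_slope_beta * log_kow[cells$chem] +
      config$taxon_offsets[species$taxon[cells$sp]] +
      species$effect[cells$sp] +
      interaction[cbind(cells$chem, cells$sp)]

    k <- config$replicates_per_species
    rep_idx <- rep(seq_len(nrow(cells)), each = k)
    noise <- stats::rnorm(length(rep_idx), 0, config$replicate_sd)
    toxicity <- data.frame(
      cas = cas[cells$chem[rep_idx]],
      species = species$species[cells$sp[rep_idx]],
      taxon = species$taxon[cells$sp[rep_idx]],
      endpoint = "LC50",
      duration_h = 96,
      value = 10^(mu[rep_idx] + noise),
      unit = "ug_per_L",
      stringsAsFactors = FALSE
    )

    # expected (noise-free) log10 LC50 per chemical x species cell
    full_mu <- outer(seq_len(n), seq_len(nrow(species)),
                     function(i, j) {
                       config$intercept_alpha -
                         config$potency_slope_beta * log_kow[i] +
                         config$taxon_offsets[species$taxon[j]] +
                         species$effect[j]
                     }) + interaction

    pairs <- expand.grid(s = seq_len(n), t = seq_len(n),
                         KEEP.OUT.ATTRS = FALSE)
    pairs <- pairs[log_kow[pairs$s] < log_kow[pairs$t], , drop = FALSE]
    truth <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
      i <- pairs$s[p]; j <- pairs$t[p]
      log_ssr <- full_mu[j, ] - full_mu[i, ]
      data.frame(source_cas = cas[i], target_cas = cas[j],
                 species = species$species, taxon = species$taxon,
                 true_ssr = 10^log_ssr,
                 true_ssf = 10^mean(log_ssr),
                 true_lc50_ug_L = 10^full_mu[j, ],
                 stringsAsFactors = FALSE)
    }))
    rownames(truth) <- NULL

    out <- list(chemicals = chemicals, toxicity = toxicity, truth = truth)
    attr(out, "config") <- config
    out
  })
}

#' Closed-form true SSF of a pair
#'
#' Under the generative model with zero interaction variance, the taxon and
#' species effects cancel in every SSR, so the true SSF of a pair depends
#' only on its log Kow gap: `10^(-beta * delta_log_kow)`. With interaction
#' variance the ratio is species-specific and no closed form exists, so
#' calling this is an error.
#'
#' @param config a [synthetic_config()] with `interaction_sd = 0`.
#' @param pair anything with a `delta_log_kow` element (e.g. a row of
#'   [enumerate_pairs()] output), or a single number taken as the gap.
#' @return single positive number.
#' @export
true_ssf <- function(config, pair) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$interaction_sd > 0) {
    stop("true SSF has no closed form when interaction_sd > 0",
         call. = FALSE)
  }
  delta <- if (is.numeric(pair)) pair else pair$delta_log_kow
  stopifnot(length(delta) == 1L, delta >= 0)
  10^(-config$potency_slope_beta * delta)
}
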