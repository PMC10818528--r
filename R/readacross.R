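#' Species sensitivity ratio (SSR)
#'
#' The per-species toxicity ratio of a matched source-target couple:
#' `lc50_target / lc50_source` on the canonical (ug/L) scale. With the
#' target being the higher log Kow - hence typically more toxic - chemical,
#' retained SSRs are at most 1; ratios above 1 are handed to the caller's
#' exclusion rule (see [match_species()]).
#'
#' @param lc50_target,lc50_source positive LC50 values (ug/L), vectorized.
#' @return numeric vector of ratios.
#' @export
compute_ssr <- function(lc50_target, lc50_source) {
  if (any(!is.finite(lc50_target)) || any(lc50_target <= 0) ||
      any(!is.finite(lc50_source)) || any(lc50_source <= 0)) {
    stop("LC50 values must be finite and > 0", call. = FALSE)
  }
  lc50_target / lc50_source
}

#' Species sensitivity factor (SSF)
#'
#' The geometric mean of a set of species sensitivity ratios. Multiplied by
#' the source chemical's LC50 for a species of interest, it predicts the
#' target chemical's LC50 for that species.
#'
#' @param ssrs non-empty vector of positive ratios.
#' @return single positive number.
#' @examples
#' compute_ssf(c(0.25, 1)) # 0.5
#' @export
compute_ssf <- function(ssrs) {
  if (length(ssrs) == 0L) {
    stop("cannot compute an SSF from zero SSRs", call. = FALSE)
  }
  geo_mean(ssrs)
}

#' Classify a prediction as over- or underestimation
#'
#' A predicted LC50 below the known value overstates toxicity
#' (`"over"`, the conservative direction); above it, toxicity is
#' understated (`"under"`). Exact agreement (within a relative tolerance
#' for floating point) is a `"tie"` and counts toward neither direction.
#'
#' @param predicted,known positive LC50 values (ug/L), vectorized.
#' @param tol relative tolerance for declaring a tie.
#' @return character vector in `over`/`under`/`tie`.
#' @export
classify_prediction <- function(predicted, known, tol = 1e-12) {
  if (any(!is.finite(predicted)) || any(predicted <= 0) ||
      any(!is.finite(known)) || any(known <= 0)) {
    stop("predicted and known LC50 values must be finite and > 0",
         call. = FALSE)
  }
  out <- ifelse(abs(predicted - known) <= tol * pmax(predicted, known),
                "tie", ifelse(predicted < known, "over", "under"))
  as.character(out)
}

#' Predict target-chemical LC50s for one pair and taxon
#'
#' Applies the SSF read-across to every species of `taxon` that has a
#' source-chemical value (matched species and source-only species alike).
#' Donor SSRs always come from the *other* prediction taxa, never from the
#' predicted species' own taxon.
#'
#' Under Case I, each prediction uses exactly one matched species from each
#' other prediction taxon, and all cross-combinations are enumerated: the
#' number of predictions per target species is the product of the other
#' taxa's matched-species counts. Under Case II a single donor taxon is
#' available; by default its matched species are pooled into one SSF
#' (geometric mean), giving one prediction per target species, while
#' `donor_selection = "closest"` instead uses the single matched species
#' whose source-chemical LC50 is nearest (in log) to the target species' own
#' source-chemical value.
#'
#' @param pair one row of [enumerate_pairs()] output.
#' @param matches output of [match_species()] for this pair.
#' @param taxon the prediction taxon.
#' @param scenario `"case_I"` or `"case_II"`, as returned by
#'   [classify_scenario()].
#' @param donor_selection Case II donor policy, `"all"` (default) or
#'   `"closest"`.
#' @param prediction_taxa the taxa participating in prediction.
#' @return a data frame with one row per prediction: `source_cas`,
#'   `target_cas`, `taxon`, `target_species`, `donor_species` (label),
#'   `n_donors`, `ssf`, `predicted_lc50_ug_L`, `known_lc50_ug_L` (`NA` when
#'   the target chemical has no value for that species), `classification`
#'   (`over`/`under`/`tie`, or `unknown` when no known value), and
#'   `beyond_source` (`TRUE` when the prediction exceeds the source
#'   chemical's own LC50 for that species). Zero rows (with a message) when
#'   no donor SSR is available.
#' @export
predict_target <- function(pair, matches, taxon, scenario,
                           donor_selection = c("all", "closest"),
                           prediction_taxa = c("fish", "crustacean",
                                               "insect")) {
  donor_selection <- match.arg(donor_selection)
  stopifnot(taxon %in% ssfra_taxa())
  empty <- empty_predictions()
  if (!scenario %in% c("case_I", "case_II")) {
    message("pair ", pair$source_cas, " -> ", pair$target_cas,
            " is ineligible; no predictions")
    return(empty)
  }
  tm <- matches[[taxon]]
  targets <- rbind(
    tm$matched[, c("species", "lc50_source_ug_L")],
    tm$prediction_species
  )
  if (nrow(targets) == 0L) {
    message("no species with source-chemical data in taxon '", taxon, "'")
    return(empty)
  }
  known <- tm$matched$lc50_target_ug_L[match(targets$species,
                                             tm$matched$species)]

  donor_taxa <- setdiff(prediction_taxa, taxon)
  donor_pool <- lapply(donor_taxa, function(tx) matches[[tx]]$matched)
  names(donor_pool) <- donor_taxa
  donor_pool <- donor_pool[vapply(donor_pool, nrow, integer(1)) > 0L]
  if (length(donor_pool) == 0L) {
    message("no donor SSRs available for taxon '", taxon, "' in pair ",
            pair$source_cas, " -> ", pair$target_cas)
    return(empty)
  }

  one_species_block <- function(sp, lc_src, kn, ssf, labels, n_donors) {
    predicted <- ssf * lc_src
    cls <- if (is.na(kn)) rep("unknown", length(ssf)) else {
      classify_prediction(predicted, rep(kn, length(predicted)))
    }
    data.frame(
      source_cas = pair$source_cas, target_cas = pair$target_cas,
      taxon = taxon, target_species = sp, donor_species = labels,
      n_donors = n_donors, ssf = ssf, predicted_lc50_ug_L = predicted,
      known_lc50_ug_L = kn, classification = cls,
      beyond_source = predicted > lc_src, stringsAsFactors = FALSE)
  }

  blocks <- list()
  if (scenario == "case_I") {
    # one matched species drawn from each donor taxon; all cross-combinations
    grid <- expand.grid(lapply(donor_pool, function(d) seq_len(nrow(d))),
                        KEEP.OUT.ATTRS = FALSE)
    log_ssr <- vapply(names(donor_pool), function(tx) {
      log(donor_pool[[tx]]$ssr)[grid[[tx]]]
    }, numeric(nrow(grid)))
    log_ssr <- matrix(log_ssr, nrow = nrow(grid))
    ssf <- exp(rowMeans(log_ssr))
    label_parts <- vapply(names(donor_pool), function(tx) {
      paste(tx, donor_pool[[tx]]$species[grid[[tx]]], sep = ":")
    }, character(nrow(grid)))
    labels <- apply(matrix(label_parts, nrow = nrow(grid)), 1L, paste,
                    collapse = " + ")
    for (i in seq_len(nrow(targets))) {
      blocks[[i]] <- one_species_block(targets$species[i],
                                       targets$lc50_source_ug_L[i],
                                       known[i], ssf, labels,
                                       length(donor_pool))
    }
  } else {
    donors <- do.call(rbind, lapply(names(donor_pool), function(tx) {
      d <- donor_pool[[tx]]
      data.frame(taxon = tx, species = d$species, ssr = d$ssr,
                 lc50_source_ug_L = d$lc50_source_ug_L,
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_len(nrow(targets))) {
      lc_src <- targets$lc50_source_ug_L[i]
      d <- donors
      if (donor_selection == "closest") {
        dist <- abs(log(d$lc50_source_ug_L) - log(lc_src))
        d <- d[which.min(dist), , drop = FALSE]
      }
      blocks[[i]] <- one_species_block(
        targets$species[i], lc_src, known[i], compute_ssf(d$ssr),
        paste(d$taxon, d$species, sep = ":", collapse = " + "), nrow(d))
    }
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$target_species, out$donor_species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# zero-row predictions table with the canonical columns
empty_predictions <- function() {
  data.frame(source_cas = character(), target_cas = character(),
             taxon = character(), target_species = character(),
             donor_species = character(), n_donors = integer(),
             ssf = numeric(), predicted_lc50_ug_L = numeric(),
             known_lc50_ug_L = numeric(), classification = character(),
             beyond_source = logical(), stringsAsFactors = FALSE)
}

#' Majority decision over classified predictions
#'
#' Counts over/under/tie outcomes and decides by strict majority of over
#' vs under; equal counts (including the all-tie case) give `"nd"` (not
#' determined). Predictions without a known value (`"unknown"`) are
#' excluded before counting.
#'
#' @param x either a character vector of classifications or a predictions
#'   data frame with a `classification` column.
#' @return a list `n_over`, `n_under`, `n_tie`, `decision`
#'   (`over`/`under`/`nd`).
#' @export
decide_row <- function(x) {
  if (is.data.frame(x)) x <- x$classification
  x <- x[x != "unknown"]
  if (length(x) == 0L) {
    stop("no classified predictions to decide on", call. = FALSE)
  }
  if (!all(x %in% c("over", "under", "tie"))) {
    stop("classifications must be over/under/tie", call. = FALSE)
  }
  n_over <- sum(x == "over")
  n_under <- sum(x == "under")
  n_tie <- sum(x == "tie")
  decision <- if (n_over > n_under) "over"
              else if (n_under > n_over) "under"
              else "nd"
  list(n_over = n_over, n_under = n_under, n_tie = n_tie,
       decision = decision)
}

#' Two-level decision table for a set of predictions
#'
#' First decides each target species from its own predictions (in Case I a
#' species has one prediction per donor combination; in Case II exactly
#' one), then aggregates species-level decisions per (pair, taxon) row.
#'
#' @param predictions data frame from [predict_target()] (possibly several
#'   pairs/taxa row-bound together).
#' @return a list of two data frames: `species` (one row per pair, taxon,
#'   species with prediction counts and the species decision) and `rows`
#'   (one row per pair and taxon with counts of species decided over, under
#'   and nd, plus the majority row decision).
#' @export
decision_table <- function(predictions) {
  stopifnot(is.data.frame(predictions))
  known <- predictions[predictions$classification != "unknown", ,
                       drop = FALSE]
  empty_species <- data.frame(source_cas = character(),
                              target_cas = character(), taxon = character(),
                              target_species = character(),
                              n_over = integer(), n_under = integer(),
                              n_tie = integer(), decision = character(),
                              stringsAsFactors = FALSE)
  empty_rows <- data.frame(source_cas = character(),
                           target_cas = character(), taxon = character(),
                           n_species_over = integer(),
                           n_species_under = integer(),
                           n_species_nd = integer(), decision = character(),
                           stringsAsFactors = FALSE)
  if (nrow(known) == 0L) {
    return(list(species = empty_species, rows = empty_rows))
  }
  key <- interaction(known$source_cas, known$target_cas, known$taxon,
                     known$target_species, drop = TRUE, sep = "\r")
  species <- do.call(rbind, lapply(split(known, key), function(d) {
    dec <- decide_row(d)
    data.frame(source_cas = d$source_cas[1L], target_cas = d$target_cas[1L],
               taxon = d$taxon[1L], target_species = d$target_species[1L],
               n_over = dec$n_over, n_under = dec$n_under,
               n_tie = dec$n_tie, decision = dec$decision,
               stringsAsFactors = FALSE)
  }))
  rkey <- interaction(species$source_cas, species$target_cas, species$taxon,
                      drop = TRUE, sep = "\r")
  rows <- do.call(rbind, lapply(split(species, rkey), function(d) {
    counts <- c(over = sum(d$decision == "over"),
                under = sum(d$decision == "under"),
                nd = sum(d$decision == "nd"))
    decision <- if (counts["over"] > counts["under"]) "over"
                else if (counts["under"] > counts["over"]) "under"
                else "nd"
    data.frame(source_cas = d$source_cas[1L], target_cas = d$target_cas[1L],
               taxon = d$taxon[1L],
               n_species_over = unname(counts["over"]),
               n_species_under = unname(counts["under"]),
               n_species_nd = unname(counts["nd"]),
               decision = decision, stringsAsFactors = FALSE)
  }))
  ord <- order(species$source_cas, species$target_cas, species$taxon,
               species$target_species)
  species <- species[ord, , drop = FALSE]
  rownames(species) <- NULL
  ord <- order(rows$source_cas, rows$target_cas, rows$taxon)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  list(species = species, rows = rows)
}

#' Packaged worked-example reference tables
#'
#' Loads the bundled per-pair, per-taxon reference tables of exemplar
#' read-across results for the data-rich (`case_I`) and data-poor
#' (`case_II`) scenarios: matched-species counts per taxon, the exemplar
#' species' known and predicted LC50s (a min/max envelope in Case I, a
#' single value in Case II), and the printed over/under/nd bookkeeping.
#' These tables serve as fixed validation inputs for the decision semantics
#' and the Case I combination-count law.
#'
#' @param case `"case_I"` or `"case_II"`.
#' @return a data frame.
#' @export
reference_predictions <- function(case = c("case_I", "case_II")) {
  case <- match.arg(case)
  file <- if (case == "case_I") "reference_predictions_case1.csv"
          else "reference_predictions_case2.csv"
  utils::read.csv(ssfra_example(file), stringsAsFactors = FALSE)
}
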