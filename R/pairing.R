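#' Enumerate ordered source-target chemical pairs
#'
#' Builds every ordered pair (source, target) of category chemicals with
#' `log_kow(source) < log_kow(target)`. The chemical with the higher log Kow
#' is expected to be the more toxic of the two and is treated as the
#' data-poor target; pairing spans the whole mode-of-action category, not a
#' single functional group. Exact ties in log Kow produce no pair in either
#' direction.
#'
#' @param records category-selected registry (see [select_category()]).
#' @return a data frame, one row per pair, sorted by source then target CAS:
#'   `source_cas`, `target_cas`, `source_name`, `target_name`,
#'   `source_log_kow`, `target_log_kow`, `delta_log_kow` (target - source,
#'   always > 0), and `functional_group` (the source chemical's group, the
#'   label used for reporting). Fewer than two chemicals yield an empty
#'   table, not an error.
#' @export
enumerate_pairs <- function(records) {
  stopifnot(is.data.frame(records))
  empty <- data.frame(source_cas = character(), target_cas = character(),
                      source_name = character(), target_name = character(),
                      source_log_kow = numeric(), target_log_kow = numeric(),
                      delta_log_kow = numeric(),
                      functional_group = character(),
                      stringsAsFactors = FALSE)
  n <- nrow(records)
  if (n < 2L) return(empty)
  idx <- expand.grid(s = seq_len(n), t = seq_len(n))
  idx <- idx[records$log_kow[idx$s] < records$log_kow[idx$t], , drop = FALSE]
  if (nrow(idx) == 0L) return(empty)
  out <- data.frame(
    source_cas = records$cas[idx$s],
    target_cas = records$cas[idx$t],
    source_name = records$name[idx$s],
    target_name = records$name[idx$t],
    source_log_kow = records$log_kow[idx$s],
    target_log_kow = records$log_kow[idx$t],
    delta_log_kow = records$log_kow[idx$t] - records$log_kow[idx$s],
    functional_group = records$functional_group[idx$s],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$source_cas, out$target_cas), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match shared species between a source and a target chemical
#'
#' For one ordered pair, lists per taxon the species with aggregated LC50
#' values for both chemicals (donor candidates, each with its species
#' sensitivity ratio `ssr = lc50_target / lc50_source`), the species
#' excluded by the sensitivity rule, the species with source-chemical data
#' only (prediction candidates without a held-out truth), and the species
#' with target-chemical data only.
#'
#' The exclusion rule: a matched species whose SSR exceeds 1 is more
#' sensitive to the source chemical than to the (higher log Kow, expectedly
#' more toxic) target; its sensitivity is evidently driven by something
#' other than the shared mode of action and hydrophobicity, so it is set
#' aside per species (reason `"source_more_sensitive"`). An SSR of exactly 1
#' is retained as neutral evidence.
#'
#' @param pair one row of the table from [enumerate_pairs()] (or any list
#'   with `source_cas` and `target_cas`).
#' @param profiles aggregated per-species values from [aggregate_species()].
#' @param exclude_source_more_sensitive apply the SSR > 1 exclusion
#'   (default TRUE).
#' @return a named list with one element per taxon (all four taxa, possibly
#'   empty), each a list with elements `taxon`, `matched` (data frame
#'   `species`, `lc50_source_ug_L`, `lc50_target_ug_L`, `ssr`), `excluded`
#'   (data frame `species`, `reason`), `prediction_species` (data frame
#'   `species`, `lc50_source_ug_L`; source-only species), and `target_only`
#'   (character). Class `taxon_matches`.
#' @export
match_species <- function(pair, profiles,
                          exclude_source_more_sensitive = TRUE) {
  stopifnot(is.data.frame(profiles))
  src <- profiles[profiles$cas == pair$source_cas, , drop = FALSE]
  tgt <- profiles[profiles$cas == pair$target_cas, , drop = FALSE]
  out <- lapply(ssfra_taxa(), function(tx) {
    s <- src[src$taxon == tx, , drop = FALSE]
    t <- tgt[tgt$taxon == tx, , drop = FALSE]
    shared <- sort(intersect(s$species, t$species))
    lc_s <- s$lc50_ug_L[match(shared, s$species)]
    lc_t <- t$lc50_ug_L[match(shared, t$species)]
    ssr <- if (length(shared)) compute_ssr(lc_t, lc_s) else numeric()
    matched <- data.frame(species = shared,
                          lc50_source_ug_L = lc_s,
                          lc50_target_ug_L = lc_t,
                          ssr = ssr, stringsAsFactors = FALSE)
    excluded <- data.frame(species = character(), reason = character(),
                           stringsAsFactors = FALSE)
    if (exclude_source_more_sensitive && nrow(matched) > 0L) {
      drop <- matched$ssr > 1
      if (any(drop)) {
        excluded <- data.frame(species = matched$species[drop],
                               reason = "source_more_sensitive",
                               stringsAsFactors = FALSE)
        matched <- matched[!drop, , drop = FALSE]
      }
    }
    rownames(matched) <- NULL
    source_only <- sort(setdiff(s$species, t$species))
    pred <- data.frame(
      species = source_only,
      lc50_source_ug_L = s$lc50_ug_L[match(source_only, s$species)],
      stringsAsFactors = FALSE
    )
    list(taxon = tx, matched = matched, excluded = excluded,
         prediction_species = pred,
         target_only = sort(setdiff(t$species, s$species)))
  })
  names(out) <- ssfra_taxa()
  class(out) <- "taxon_matches"
  out
}

#' Classify the data-availability scenario of a pair
#'
#' A pair is a Case I (data-rich) candidate when at least three prediction
#' taxa have at least one matched species with data for both chemicals, so
#' every prediction taxon is served by at least two donor taxa (two SSRs
#' feeding the SSF). Exactly two qualifying taxa give Case II (single donor
#' taxon); fewer make the pair ineligible.
#'
#' @param matches output of [match_species()].
#' @param prediction_taxa taxa counted towards the scenario. The default
#'   excludes amphibians, whose coverage in acute AChE-inhibitor data is too
#'   sparse to anchor donor ratios.
#' @return one of `"case_I"`, `"case_II"`, `"ineligible"`.
#' @export
classify_scenario <- function(matches,
                              prediction_taxa = c("fish", "crustacean",
                                                  "insect")) {
  stopifnot(inherits(matches, "taxon_matches") || is.list(matches))
  n_matched_taxa <- sum(vapply(prediction_taxa, function(tx) {
    tm <- matches[[tx]]
    !is.null(tm) && nrow(tm$matched) >= 1L
  }, logical(1)))
  if (n_matched_taxa >= 3L) "case_I"
  else if (n_matched_taxa == 2L) "case_II"
  else "ineligible"
}

#' @export
print.taxon_matches <- function(x, ...) {
  cat("Species matches by taxon:\n")
  for (tm in x) {
    cat(sprintf("  %-10s matched %d, excluded %d, source-only %d\n",
                tm$taxon, nrow(tm$matched), nrow(tm$excluded),
                nrow(tm$prediction_species)))
  }
  invisible(x)
}
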