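#' Run the full read-across pipeline
#'
#' Chains the whole workflow: load and category-select the chemical
#' registry, load (and optionally solubility-filter) the toxicity records,
#' aggregate per species, enumerate source-target pairs, match species and
#' classify each pair's scenario, predict target-chemical LC50s, decide
#' over/underestimation, and compute the agreement summary per scenario
#' (overall and by functional group).
#'
#' @param chemicals registry: a file path (read with [load_chemicals()]) or
#'   an already-loaded data frame.
#' @param toxicity toxicity records: a file path (read with
#'   [load_toxicity()]) or a canonical data frame (with `value_ug_L`) or a
#'   raw record table (with `value` + `unit`, as [generate_synthetic()]
#'   emits).
#' @param out_dir directory for CSV artifacts and a JSON manifest; `NULL`
#'   (default) writes nothing and just returns the results.
#' @param max_log_kow,moa,functional_groups category selection, see
#'   [select_category()].
#' @param prediction_taxa taxa predicted for (default excludes amphibians).
#' @param donor_selection Case II donor policy, see [predict_target()].
#' @param solubility_filter apply [filter_solubility()] (default TRUE).
#' @param log_base log base for the agreement summary.
#' @param durations exposure durations pooled by [aggregate_species()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list of class `ssfra_run`: `status` (`"ok"` or
#'   `"no_eligible_pairs"`), `registry`, `profiles`, `pairs` (with a
#'   `scenario` column), `predictions`, `decisions` (species- and row-level,
#'   see [decision_table()]), `agreement` (per scenario x group), and
#'   `normality` (Anderson-Darling gate per scenario on the pooled
#'   log-transformed values). Artifacts, when written, are byte-stable for
#'   identical inputs and configuration: pairs are sorted by source then
#'   target CAS, predictions by pair, taxon, species, donor.
#' @export
run_pipeline <- function(chemicals, toxicity, out_dir = NULL,
                         max_log_kow = 5, moa = "AChE_inhibition",
                         functional_groups = ssfra_functional_groups(),
                         prediction_taxa = c("fish", "crustacean", "insect"),
                         donor_selection = c("all", "closest"),
                         solubility_filter = TRUE,
                         log_base = 10,
                         durations = c(24, 48, 96),
                         quiet = FALSE) {
  donor_selection <- match.arg(donor_selection)
  chem_path <- if (is.character(chemicals)) chemicals else NA_character_
  tox_path <- if (is.character(toxicity)) toxicity else NA_character_
  if (is.character(chemicals)) chemicals <- load_chemicals(chemicals)
  if (is.character(toxicity)) toxicity <- load_toxicity(toxicity)
  if (is.null(toxicity$value_ug_L)) {
    # raw schema (value + unit): canonicalize in-memory the same way the
    # loader does
    stopifnot(all(c("value", "unit") %in% names(toxicity)))
    toxicity$value_ug_L <- ifelse(toxicity$unit == "mg_per_L",
                                  toxicity$value * 1000, toxicity$value)
  }

  registry <- select_category(chemicals, max_log_kow = max_log_kow,
                              moa = moa,
                              functional_groups = functional_groups)
  say <- function(...) if (!quiet) message(...)
  say("category selection retained ", nrow(registry), " of ",
      nrow(chemicals), " chemicals")

  records <- toxicity[toxicity$cas %in% registry$cas, , drop = FALSE]
  if (solubility_filter) {
    records <- filter_solubility(records, registry, quiet = quiet)
  }
  profiles <- aggregate_species(records, durations = durations)
  say("aggregated ", nrow(profiles), " (chemical, species) profiles from ",
      nrow(records), " records")

  pairs <- enumerate_pairs(registry)
  result <- list(status = "ok", registry = registry, profiles = profiles)
  if (nrow(pairs) == 0L) {
    say("no eligible pairs")
    result$status <- "no_eligible_pairs"
    result$pairs <- pairs
    result$predictions <- empty_predictions()
    result$decisions <- decision_table(result$predictions)
    result$agreement <- NULL
    class(result) <- "ssfra_run"
    if (!is.null(out_dir)) {
      write_artifacts(result, out_dir, chem_path, tox_path,
                      list(max_log_kow = max_log_kow,
                           donor_selection = donor_selection,
                           solubility_filter = solubility_filter,
                           log_base = log_base))
    }
    return(invisible(result))
  }

  pairs$scenario <- NA_character_
  all_predictions <- list()
  for (i in seq_len(nrow(pairs))) {
    pair <- pairs[i, , drop = FALSE]
    matches <- match_species(pair, profiles)
    scenario <- classify_scenario(matches, prediction_taxa)
    pairs$scenario[i] <- scenario
    if (scenario == "ineligible") next
    for (tx in prediction_taxa) {
      preds <- suppressMessages(
        predict_target(pair, matches, tx, scenario,
                       donor_selection = donor_selection,
                       prediction_taxa = prediction_taxa)
      )
      if (nrow(preds) > 0L) {
        preds$scenario <- scenario
        preds$functional_group <- pair$functional_group
        all_predictions[[length(all_predictions) + 1L]] <- preds
      }
    }
  }
  predictions <- if (length(all_predictions)) {
    do.call(rbind, all_predictions)
  } else {
    cbind(empty_predictions(),
          data.frame(scenario = character(), functional_group = character(),
                     stringsAsFactors = FALSE))
  }
  if (nrow(predictions) > 0L) {
    ord <- order(predictions$source_cas, predictions$target_cas,
                 predictions$taxon, predictions$target_species,
                 predictions$donor_species)
    predictions <- predictions[ord, , drop = FALSE]
    rownames(predictions) <- NULL
  }
  say(nrow(predictions), " predictions across ",
      sum(pairs$scenario != "ineligible"), " eligible pairs (",
      sum(pairs$scenario == "case_I"), " Case I, ",
      sum(pairs$scenario == "case_II"), " Case II)")

  decisions <- decision_table(predictions)

  agreement <- NULL
  normality <- list()
  for (sc in c("case_I", "case_II")) {
    d <- predictions[predictions$scenario == sc &
                       !is.na(predictions$known_lc50_ug_L), , drop = FALSE]
    if (nrow(d) == 0L) next
    overall <- summarize_agreement(d, "overall", log_base = log_base)
    by_fg <- if (length(unique(d$functional_group)) >= 1L) {
      summarize_agreement(d, "functional_group", log_base = log_base)
    }
    block <- rbind(overall, by_fg)
    block <- cbind(scenario = sc, block, stringsAsFactors = FALSE)
    agreement <- rbind(agreement, block)
    normality[[sc]] <- normality_gate(
      c(log(d$predicted_lc50_ug_L, base = log_base),
        log(d$known_lc50_ug_L, base = log_base)))
  }

  result$pairs <- pairs
  result$predictions <- predictions
  result$decisions <- decisions
  result$agreement <- agreement
  result$normality <- normality
  class(result) <- "ssfra_run"
  if (!is.null(out_dir)) {
    write_artifacts(result, out_dir, chem_path, tox_path,
                    list(max_log_kow = max_log_kow,
                         donor_selection = donor_selection,
                         solubility_filter = solubility_filter,
                         log_base = log_base))
  }
  invisible(result)
}

# write CSV artifacts plus a JSON manifest with input hashes and config
write_artifacts <- function(result, out_dir, chem_path, tox_path, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, file) {
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
  }
  w(result$pairs, "pairs.csv")
  w(result$predictions, "predictions.csv")
  w(result$decisions$species, "decisions_species.csv")
  w(result$decisions$rows, "decisions_rows.csv")
  if (!is.null(result$agreement)) w(result$agreement, "agreement.csv")
  hash <- function(p) {
    if (is.na(p)) "in-memory" else unname(tools::md5sum(p))
  }
  manifest <- list(
    status = result$status,
    inputs = list(chemicals = hash(chem_path), toxicity = hash(tox_path)),
    config = config,
    normality = result$normality,
    n_pairs = nrow(result$pairs),
    n_predictions = nrow(result$predictions)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(NULL)
}

#' @export
print.ssfra_run <- function(x, ...) {
  cat("SSF read-across run:", x$status, "\n")
  cat("  chemicals:", nrow(x$registry), " pairs:", nrow(x$pairs), "\n")
  if (!is.null(x$pairs$scenario)) {
    cat("  scenarios: ", sum(x$pairs$scenario == "case_I"), " Case I, ",
        sum(x$pairs$scenario == "case_II"), " Case II, ",
        sum(x$pairs$scenario == "ineligible"), " ineligible\n", sep = "")
  }
  cat("  predictions:", nrow(x$predictions), "\n")
  if (!is.null(x$agreement)) {
    cat("  agreement (overall rows):\n")
    ov <- x$agreement[x$agreement$group == "overall", , drop = FALSE]
    for (i in seq_len(nrow(ov))) {
      cat(sprintf("    %-8s n=%d bias=%.4g precision=%.4g MAE=%.4g r=%.4g\n",
                  ov$scenario[i], ov$n[i], ov$bias[i], ov$precision[i],
                  ov$accuracy_mae[i], ov$pearson_r[i]))
    }
  }
  invisible(x)
}

#' Bland-Altman plot
#'
#' Standard agreement plot: per-point differences (log predicted minus log
#' known) against per-point means, with dashed lines at the mean difference
#' and the 95% limits of agreement.
#'
#' @param rs a [residual_set()].
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(rs) {
  ba <- bland_altman(rs)
  ggplot2::ggplot(ba$points,
                  ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$ba_mean, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(ba$ba_lower, ba$ba_upper),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Mean of log predicted and log known",
                  y = "Difference (log predicted - log known)")
}

#' Scatter plot of log predictions against log known values
#'
#' Scatter with a fitted linear line and its 95% confidence band; the
#' Pearson correlation is shown in the subtitle.
#'
#' @param rs a [residual_set()].
#' @return a ggplot object.
#' @export
plot_agreement_scatter <- function(rs) {
  df <- data.frame(a = rs$a, e = rs$e)
  r <- tryCatch(pearson_r(rs), error = function(e) NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(x = a, y = e)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, level = 0.95,
                         colour = "black") +
    ggplot2::labs(x = "Log known toxicity", y = "Log predicted toxicity",
                  subtitle = if (is.na(r)) NULL else sprintf("r = %.2f", r))
}

utils::globalVariables(c("mean", "difference", "a", "e"))
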