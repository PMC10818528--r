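#' Load acute toxicity records
#'
#' Reads per-study LC50 records in the ECOTOX-extract style: one row per
#' (chemical, species, study) with taxon, endpoint, exposure duration and a
#' concentration with its unit. All concentrations are converted to the
#' canonical unit (ug/L) on read; mg/L values are multiplied by exactly 1000.
#'
#' @param path path to a CSV file with header
#'   `cas,species,taxon,endpoint,duration_h,value,unit`.
#' @return a data frame with columns `cas`, `species`, `taxon`, `endpoint`,
#'   `duration_h`, `value_ug_L`.
#' @details Accepted vocabularies: `taxon` in fish/crustacean/insect/
#'   amphibian; `endpoint` `LC50`; `duration_h` one of 24, 48, 96; `unit`
#'   `mg_per_L` or `ug_per_L`. Nonpositive concentrations and unknown
#'   vocabulary values are row-level errors reported with row indices.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("cas,species,taxon,endpoint,duration_h,value,unit",
#'              "62-73-7,Daphnia magna,crustacean,LC50,48,0.11,mg_per_L"), f)
#' load_toxicity(f)$value_ug_L # 110
#' @export
load_toxicity <- function(path) {
  required <- c("cas", "species", "taxon", "endpoint", "duration_h",
                "value", "unit")
  df <- read_csv_checked(path, required)
  if (nrow(df) == 0L) {
    return(data.frame(cas = character(), species = character(),
                      taxon = character(), endpoint = character(),
                      duration_h = numeric(), value_ug_L = numeric(),
                      stringsAsFactors = FALSE))
  }
  value <- parse_numeric_column(df$value, "value")
  duration <- parse_numeric_column(df$duration_h, "duration_h")
  taxon <- trimws(df$taxon)
  unit <- trimws(df$unit)
  endpoint <- trimws(df$endpoint)

  problems <- character()
  add_problem <- function(rows, what) {
    if (length(rows) > 0L) {
      problems <<- c(problems, paste0(what, " at row(s) ",
                                      paste(rows, collapse = ", ")))
    }
  }
  add_problem(which(value <= 0), "nonpositive LC50 value")
  add_problem(which(!taxon %in% ssfra_taxa()), "unknown taxon")
  add_problem(which(!unit %in% c("mg_per_L", "ug_per_L")), "unknown unit")
  add_problem(which(endpoint != "LC50"), "unsupported endpoint")
  add_problem(which(!duration %in% c(24, 48, 96)),
              "unsupported exposure duration")
  if (length(problems) > 0L) {
    stop("invalid toxicity record(s): ", paste(problems, collapse = "; "),
         call. = FALSE)
  }

  data.frame(
    cas = trimws(df$cas),
    species = trimws(df$species),
    taxon = taxon,
    endpoint = endpoint,
    duration_h = duration,
    value_ug_L = ifelse(unit == "mg_per_L", value * 1000, value),
    stringsAsFactors = FALSE
  )
}

#' Apply the water-solubility filter
#'
#' Retains only toxicity records whose LC50 is strictly below the chemical's
#' water solubility. Concentrations above solubility cannot be maintained in
#' true solution during an acute test, so such records are treated as
#' unreliable. A record exactly equal to the solubility is dropped (strict
#' inequality).
#'
#' @param records canonical toxicity records from [load_toxicity()].
#' @param registry chemical registry supplying `water_solubility_mg_L` per
#'   CAS; every CAS in `records` must be present.
#' @param quiet suppress the per-chemical message about dropped records.
#' @return the retained records; the number dropped per chemical is attached
#'   as the `"dropped"` attribute (a data frame `cas`, `n_dropped`).
#' @export
filter_solubility <- function(records, registry, quiet = FALSE) {
  stopifnot(is.data.frame(records), is.data.frame(registry))
  if (nrow(records) == 0L) {
    out <- records
    attr(out, "dropped") <- data.frame(cas = character(),
                                       n_dropped = integer(),
                                       stringsAsFactors = FALSE)
    return(out)
  }
  unknown <- setdiff(unique(records$cas), registry$cas)
  if (length(unknown) > 0L) {
    stop("toxicity records reference CAS number(s) absent from the ",
         "registry: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sol_ug_L <- registry$water_solubility_mg_L[match(records$cas,
                                                   registry$cas)] * 1000
  keep <- records$value_ug_L < sol_ug_L
  dropped <- records[!keep, , drop = FALSE]
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  tab <- table(dropped$cas)
  dropped_df <- data.frame(cas = names(tab),
                           n_dropped = as.integer(tab),
                           stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped_df
  if (!quiet && nrow(dropped_df) > 0L) {
    message("solubility filter dropped ", sum(dropped_df$n_dropped),
            " record(s) across ", nrow(dropped_df), " chemical(s)")
  }
  out
}

#' Aggregate toxicity records per species
#'
#' Collapses replicate LC50 records to one value per (chemical, species):
#' the geometric mean of all canonical (ug/L) values, pooling the 24/48/96 h
#' durations as one acute endpoint. The geometric mean is used for any
#' number of records (it is the identity for a single record).
#'
#' @param records canonical toxicity records from [load_toxicity()].
#' @param durations durations (hours) to include before aggregation;
#'   defaults to pooling all three acute windows.
#' @return a data frame with one row per (cas, species): `cas`, `species`,
#'   `taxon`, `lc50_ug_L` (geometric mean), `n_values`, `min_ug_L`,
#'   `max_ug_L`, sorted by cas, taxon, species.
#' @examples
#' recs <- data.frame(cas = "62-73-7", species = "Daphnia magna",
#'                    taxon = "crustacean", endpoint = "LC50",
#'                    duration_h = 48, value_ug_L = c(10, 1000))
#' aggregate_species(recs)$lc50_ug_L # 100
#' @export
aggregate_species <- function(records, durations = c(24, 48, 96)) {
  stopifnot(is.data.frame(records))
  records <- records[records$duration_h %in% durations, , drop = FALSE]
  if (nrow(records) == 0L) {
    return(data.frame(cas = character(), species = character(),
                      taxon = character(), lc50_ug_L = numeric(),
                      n_values = integer(), min_ug_L = numeric(),
                      max_ug_L = numeric(), stringsAsFactors = FALSE))
  }
  key <- interaction(records$cas, records$species, drop = TRUE, sep = "\r")
  parts <- split(records, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    lo <- min(d$value_ug_L)
    hi <- max(d$value_ug_L)
    data.frame(cas = d$cas[1L], species = d$species[1L], taxon = d$taxon[1L],
               # clamp: the geometric mean lies in [min, max] exactly, but
               # exp(mean(log(x))) can drift a ulp outside
               lc50_ug_L = min(max(geo_mean(d$value_ug_L), lo), hi),
               n_values = nrow(d),
               min_ug_L = lo,
               max_ug_L = hi,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$cas, out$taxon, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}
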