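#' Load a chemical registry
#'
#' Reads the registry CSV that defines the read-across category: one row per
#' chemical with its CAS number, physicochemical descriptors (molecular
#' weight, log Kow, water solubility), mode of action, functional group,
#' optional subgroup, and Verhaar class. The packaged registry of 25
#' acetylcholinesterase-inhibiting organophosphates and carbamates is
#' available via `ssfra_example("chemicals_table1.csv")`.
#'
#' @param path path to a CSV file with header
#'   `name,cas,molecular_weight,log_kow,water_solubility_mg_L,moa,functional_group,subgroup,verhaar_class`.
#' @return a data frame with one row per chemical. Numeric columns are
#'   parsed (scientific notation accepted); `subgroup` is `NA` when empty.
#' @details Validation: CAS numbers must match the registry pattern
#'   (digits-digits-digit) and be unique; molecular weight and water
#'   solubility must be positive; when the mode of action is
#'   `AChE_inhibition` the functional group must be one of
#'   `ester_phosphate`, `carbamate`, `thiophosphate`; the Verhaar class is
#'   stored as an integer 1-5 (it is input data, never computed here).
#' @seealso [select_category()], [registry_summary()]
#' @examples
#' chems <- load_chemicals(ssfra_example("chemicals_table1.csv"))
#' nrow(chems)
#' @export
load_chemicals <- function(path) {
  required <- c("name", "cas", "molecular_weight", "log_kow",
                "water_solubility_mg_L", "moa", "functional_group",
                "subgroup", "verhaar_class")
  df <- read_csv_checked(path, required)
  if (nrow(df) == 0L) {
    out <- data.frame(name = character(), cas = character(),
                      molecular_weight = numeric(), log_kow = numeric(),
                      water_solubility_mg_L = numeric(), moa = character(),
                      functional_group = character(), subgroup = character(),
                      verhaar_class = integer(), stringsAsFactors = FALSE)
    return(out)
  }

  out <- data.frame(
    name = trimws(df$name),
    cas = trimws(df$cas),
    molecular_weight = parse_numeric_column(df$molecular_weight,
                                            "molecular_weight"),
    log_kow = parse_numeric_column(df$log_kow, "log_kow"),
    water_solubility_mg_L = parse_numeric_column(df$water_solubility_mg_L,
                                                 "water_solubility_mg_L"),
    moa = trimws(df$moa),
    functional_group = trimws(df$functional_group),
    subgroup = ifelse(nzchar(trimws(df$subgroup)), trimws(df$subgroup),
                      NA_character_),
    verhaar_class = as.integer(parse_numeric_column(df$verhaar_class,
                                                    "verhaar_class")),
    stringsAsFactors = FALSE
  )

  bad_cas <- which(!grepl("^[0-9]+-[0-9]+-[0-9]$", out$cas))
  if (length(bad_cas) > 0L) {
    stop("invalid CAS number at row(s) ", paste(bad_cas, collapse = ", "),
         ": ", paste(unique(out$cas[bad_cas]), collapse = ", "),
         call. = FALSE)
  }
  dup <- out$cas[duplicated(out$cas)]
  if (length(dup) > 0L) {
    stop("duplicated CAS number(s) in registry: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(out$molecular_weight <= 0)) {
    stop("molecular_weight must be > 0 (row(s) ",
         paste(which(out$molecular_weight <= 0), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(out$water_solubility_mg_L <= 0)) {
    stop("water_solubility_mg_L must be > 0 (row(s) ",
         paste(which(out$water_solubility_mg_L <= 0), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(out$verhaar_class < 1L | out$verhaar_class > 5L)) {
    stop("verhaar_class must be an integer in 1..5", call. = FALSE)
  }
  ache <- out$moa == "AChE_inhibition"
  bad_fg <- ache & !(out$functional_group %in% ssfra_functional_groups())
  if (any(bad_fg)) {
    stop("functional_group must be one of ",
         paste(ssfra_functional_groups(), collapse = ", "),
         " for AChE_inhibition chemicals (row(s) ",
         paste(which(bad_fg), collapse = ", "), ")", call. = FALSE)
  }
  out
}

#' Select the read-across category
#'
#' Filters a chemical registry down to the chemicals eligible for read-across
#' pairing: log Kow at or below a cutoff, a required mode of action, and an
#' allowed set of functional groups. Row order is preserved and the filter
#' is idempotent.
#'
#' @param records registry data frame as returned by [load_chemicals()].
#' @param max_log_kow inclusive upper bound on log Kow. The default of 5
#'   reflects the baseline-toxicity regime in which acute aquatic toxicity
#'   still increases with hydrophobicity; the bound is inclusive (a chemical
#'   at exactly 5 is retained).
#' @param moa required mode of action (default `"AChE_inhibition"`).
#' @param functional_groups allowed functional groups.
#' @return the retained rows, in their original order.
#' @examples
#' chems <- load_chemicals(ssfra_example("chemicals_table1.csv"))
#' nrow(select_category(chems)) # all 25 survive the default criteria
#' @export
select_category <- function(records,
                            max_log_kow = 5,
                            moa = "AChE_inhibition",
                            functional_groups = ssfra_functional_groups()) {
  stopifnot(is.data.frame(records))
  keep <- records$log_kow <= max_log_kow &
    records$moa %in% moa &
    records$functional_group %in% functional_groups
  records[keep, , drop = FALSE]
}

#' Summarize a chemical registry
#'
#' @param records non-empty registry data frame.
#' @return an object of class `registry_summary`: total count, min/max
#'   log Kow, and per-functional-group and per-Verhaar-class counts.
#' @examples
#' chems <- load_chemicals(ssfra_example("chemicals_table1.csv"))
#' registry_summary(chems)
#' @export
registry_summary <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    stop("cannot summarize an empty registry", call. = FALSE)
  }
  out <- list(
    n = nrow(records),
    log_kow_min = min(records$log_kow),
    log_kow_max = max(records$log_kow),
    n_by_functional_group = table(records$functional_group),
    n_by_verhaar_class = table(records$verhaar_class)
  )
  class(out) <- "registry_summary"
  out
}

#' @export
print.registry_summary <- function(x, ...) {
  cat("Chemical registry:", x$n, "chemicals\n")
  cat(sprintf("  log Kow range: %.2f to %.2f\n", x$log_kow_min,
              x$log_kow_max))
  cat("  by functional group:\n")
  fg <- x$n_by_functional_group
  for (g in names(fg)) cat(sprintf("    %-16s %d\n", g, fg[[g]]))
  cat("  by Verhaar class:\n")
  vc <- x$n_by_verhaar_class
  for (g in names(vc)) cat(sprintf("    class %-10s %d\n", g, vc[[g]]))
  invisible(x)
}
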