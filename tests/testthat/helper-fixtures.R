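# in-code fixture builders shared across test files

# write a registry CSV from a data.frame of (subsets of) registry columns
write_chem_csv <- function(df) {
  defaults <- data.frame(name = paste0("chem", seq_len(nrow(df))),
                         cas = sprintf("100-%02d-%d", seq_len(nrow(df)),
                                       seq_len(nrow(df)) %% 10),
                         molecular_weight = 200, log_kow = 1,
                         water_solubility_mg_L = 100,
                         moa = "AChE_inhibition",
                         functional_group = "carbamate",
                         subgroup = "", verhaar_class = 4,
                         stringsAsFactors = FALSE)
  for (col in names(df)) defaults[[col]] <- df[[col]]
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(defaults, path, row.names = FALSE, na = "")
  path
}

write_tox_csv <- function(df) {
  defaults <- data.frame(cas = "100-01-1", species = "sp1", taxon = "fish",
                         endpoint = "LC50", duration_h = 96, value = 1,
                         unit = "ug_per_L", stringsAsFactors = FALSE)
  out <- defaults[rep(1L, nrow(df)), , drop = FALSE]
  for (col in names(df)) out[[col]] <- df[[col]]
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(out, path, row.names = FALSE, na = "")
  path
}

# aggregated per-species profile table for two chemicals, built from a
# per-taxon count of matched species; source LC50s are distinct per species,
# target LC50s are source * ssr (<= 1 keeps every species matched)
make_matched_profiles <- function(source_cas, target_cas,
                                  n_fish, n_crustacean, n_insect,
                                  ssr = 0.1) {
  counts <- c(fish = n_fish, crustacean = n_crustacean, insect = n_insect)
  rows <- list()
  for (tx in names(counts)) {
    n <- counts[[tx]]
    if (n == 0L) next
    sp <- sprintf("%s_sp%02d", tx, seq_len(n))
    src <- 100 * seq_len(n)
    rows[[length(rows) + 1L]] <- data.frame(
      cas = source_cas, species = sp, taxon = tx, lc50_ug_L = src,
      n_values = 1L, min_ug_L = src, max_ug_L = src,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      cas = target_cas, species = sp, taxon = tx, lc50_ug_L = src * ssr,
      n_values = 1L, min_ug_L = src * ssr, max_ug_L = src * ssr,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

make_pair <- function(source_cas = "1-11-1", target_cas = "2-22-2") {
  data.frame(source_cas = source_cas, target_cas = target_cas,
             functional_group = "carbamate", delta_log_kow = 1,
             stringsAsFactors = FALSE)
}
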