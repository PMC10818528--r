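#' Geometric mean
#'
#' Geometric mean of strictly positive values, computed as
#' `exp(mean(log(x)))`. This is the aggregation rule used both for pooling
#' replicate LC50 records of one species and for collapsing species
#' sensitivity ratios (SSRs) into a species sensitivity factor (SSF).
#'
#' @param x numeric vector, all elements finite and > 0.
#' @return single numeric value.
#' @examples
#' geo_mean(c(1, 10, 100, 1000)) # 10^1.5
#' @export
geo_mean <- function(x) {
  if (length(x) == 0L) {
    stop("geometric mean of an empty vector is undefined", call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean requires finite, strictly positive values",
         call. = FALSE)
  }
  exp(mean(log(x)))
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path, or a character vector of file names.
#' @export
ssfra_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "ssfra")))
  }
  path <- system.file("extdata", file, package = "ssfra")
  if (!nzchar(path)) {
    stop("no packaged example file '", file, "'", call. = FALSE)
  }
  path
}

# supported taxa and functional-group vocabularies (shared across modules)
ssfra_taxa <- function() c("fish", "crustacean", "insect", "amphibian")
ssfra_functional_groups <- function() {
  c("ester_phosphate", "carbamate", "thiophosphate")
}

# evaluate `expr` under `seed`, restoring the caller's RNG state afterwards;
# keeps simulation draws out of the global random stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# read a CSV with required columns, erroring on missing columns
read_csv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

# parse a character column to numeric; unparseable entries reported with
# their (1-based data) row indices
parse_numeric_column <- function(x, column) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & nzchar(x))
  bad <- c(bad, which(!nzchar(x)))
  if (length(bad) > 0L) {
    stop("column '", column, "': unparseable numeric value at row(s) ",
         paste(sort(unique(bad)), collapse = ", "), call. = FALSE)
  }
  out
}
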