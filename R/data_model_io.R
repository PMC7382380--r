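# Plant-organ tables: schema, validation, CSV round-trip.
#
# One row per plant x organ. The model is strictly three-compartment
# (rosette, stem, seeds); roots are never part of the budget.

ORGANS <- c("rosette", "stem", "seeds")

DATASET_COLUMNS <- c("plant_id", "genotype", "condition", "experiment",
                     "organ", "dw_mg", "n_pct", "c_pct", "a15_pct")

NUMERIC_COLUMNS <- c("dw_mg", "n_pct", "c_pct", "a15_pct")

#' Assemble a validated plant-organ dataset
#'
#' Bundles a table of per-organ records with the natural-abundance baseline
#' used for enrichment. Every record is validated; any violation aborts with
#' row-addressed messages.
#'
#' @param records data.frame with columns `plant_id`, `genotype`, `condition`,
#'   `experiment`, `organ`, `dw_mg`, `n_pct`, `c_pct`, `a15_pct`. `a15_pct`
#'   may be `NA` (unlabelled material). Dry weight is in mg; `n_pct` and
#'   `c_pct` are mg per 100 mg DW; `a15_pct` is the 15N atom percent.
#' @param a15_control_pct natural-abundance atom percent, default 0.3660.
#' @return an object of class `nue_dataset`: a list with elements `records`
#'   and `a15_control_pct`.
#' @export
nue_dataset <- function(records, a15_control_pct = 0.3660) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(DATASET_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[, DATASET_COLUMNS]
  for (col in c("plant_id", "genotype", "condition", "experiment", "organ")) {
    records[[col]] <- as.character(records[[col]])
  }
  for (col in NUMERIC_COLUMNS) {
    if (!is.numeric(records[[col]])) {
      stop("parse error: column '", col, "' is not numeric")
    }
    records[[col]] <- as.numeric(records[[col]])
  }
  if (!is.numeric(a15_control_pct) || length(a15_control_pct) != 1 ||
      a15_control_pct < 0 || a15_control_pct > 100) {
    stop("a15_control_pct must be a single atom percent in [0, 100]")
  }
  problems <- validate_records(records)
  if (length(problems) > 0) {
    stop("invalid records:\n", paste(problems, collapse = "\n"))
  }
  structure(list(records = records, a15_control_pct = a15_control_pct),
            class = "nue_dataset")
}

#' Validate plant-organ records
#'
#' Checks typed bounds and structural invariants row by row. Nothing is
#' dropped silently: the return value names every offending row.
#'
#' @param records data.frame with the dataset columns.
#' @return character vector of row-addressed problem messages; empty when
#'   everything validates.
#' @export
validate_records <- function(records) {
  problems <- character(0)
  say <- function(rows, msg) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0("row ", rows, ": ", msg))
    }
  }
  say(which(!records$organ %in% ORGANS),
      paste0("organ must be one of ", paste(ORGANS, collapse = "/")))
  say(which(is.na(records$dw_mg) | records$dw_mg < 0), "dw_mg must be >= 0")
  say(which(is.na(records$n_pct) | records$n_pct < 0 | records$n_pct > 100),
      "n_pct must be in [0, 100]")
  say(which(is.na(records$c_pct) | records$c_pct < 0 | records$c_pct > 100),
      "c_pct must be in [0, 100]")
  ok_nc <- !is.na(records$n_pct) & !is.na(records$c_pct)
  say(which(ok_nc & records$n_pct + records$c_pct > 100),
      "n_pct + c_pct must be <= 100")
  say(which(!is.na(records$a15_pct) &
              (records$a15_pct < 0 | records$a15_pct > 100)),
      "a15_pct must be in [0, 100]")
  key <- paste(records$plant_id, records$organ, sep = "\r")
  say(which(duplicated(key)), "duplicate (plant_id, organ) pair")
  problems
}

#' Read a plant-organ dataset from CSV
#'
#' Expects the exact header
#' `plant_id,genotype,condition,experiment,organ,dw_mg,n_pct,c_pct,a15_pct`
#' (comma-separated, UTF-8, '.' decimal). Empty numeric fields become `NA`,
#' the literal `NaN` becomes `NaN`.
#'
#' @param path CSV file path.
#' @param a15_control_pct natural-abundance atom percent, default 0.3660.
#' @return a [nue_dataset()].
#' @export
read_dataset <- function(path, a15_control_pct = 0.3660) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error in '", path, "': missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in NUMERIC_COLUMNS) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val) & !is.na(raw[[col]]) &
                   toupper(trimws(raw[[col]])) != "NAN")
    if (length(bad) > 0) {
      stop("parse error in '", path, "', column '", col, "': non-numeric at ",
           paste0("row ", bad, collapse = ", "))
    }
    raw[[col]] <- val
  }
  nue_dataset(raw, a15_control_pct = a15_control_pct)
}

#' Write a derived table (or dataset) to CSV
#'
#' Floats are serialized with 15 significant digits so a read-back agrees to
#' at least 12; `NaN` is written as the literal `NaN` and missing values as
#' empty fields, so the two survive a round trip distinctly.
#'
#' @param table data.frame or `nue_dataset` (its records are written).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  if (inherits(table, "nue_dataset")) table <- table$records
  stopifnot(is.data.frame(table))
  out <- table
  for (col in names(out)) {
    x <- out[[col]]
    if (is.double(x)) {
      s <- vapply(x, function(v) {
        if (is.nan(v)) "NaN"
        else if (is.na(v)) ""
        else format(v, digits = 15, scientific = FALSE, trim = TRUE)
      }, character(1))
      out[[col]] <- s
    } else if (is.logical(x) || is.integer(x)) {
      out[[col]] <- ifelse(is.na(x), "", as.character(x))
    } else {
      x <- as.character(x)
      out[[col]] <- ifelse(is.na(x), "", x)
    }
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("I/O error: cannot open '", path,
                                           "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read back a derived table written by [write_results()]
#'
#' @param path CSV path.
#' @return data.frame with `""` as `NA` and `NaN` as `NaN`.
#' @export
read_results <- function(path) {
  utils::read.csv(path, na.strings = "", check.names = FALSE,
                  fileEncoding = "UTF-8")
}

#' @export
print.nue_dataset <- function(x, ...) {
  rec <- x$records
  n_plants <- length(unique(rec$plant_id))
  complete <- sum(tapply(rec$organ, rec$plant_id,
                         function(o) all(ORGANS %in% o)))
  cat("<nue_dataset> ", nrow(rec), " organ records, ", n_plants, " plants (",
      complete, " with all three organs)\n", sep = "")
  cat("  genotypes:   ", paste(sort(unique(rec$genotype)), collapse = ", "), "\n")
  cat("  conditions:  ", paste(sort(unique(rec$condition)), collapse = ", "), "\n")
  cat("  experiments: ", paste(sort(unique(rec$experiment)), collapse = ", "), "\n")
  cat("  A%control:   ", x$a15_control_pct, "\n")
  invisible(x)
}
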