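CORPUS_REQUIRED <- c(
  "record_id", "study_id", "year_online", "year_print", "scale_type",
  "control_mean", "treatment_mean", "control_sd", "treatment_sd",
  "control_n", "treatment_n", "co2_uatm"
)
CORPUS_FLAGS <- c("is_sham", "is_fluctuating_co2", "is_procedural_control",
                  "direction_opposite")
CORPUS_STRINGS <- c("species", "life_stage", "cue_type", "behaviour_metric")
SCALE_TYPES <- c("percentage", "proportion", "continuous")

#' Describe how a source CSV maps onto the study-record schema
#'
#' Meta-analytic source tables differ in column naming and in whether the
#' variability column holds a standard deviation or a standard error. A
#' schema object adapts any such table to the canonical record layout
#' without code changes; it can also be loaded from a YAML file with keys
#' `columns:` (canonical: source name), `variability:` and `year_source:`.
#'
#' @param columns Named character vector mapping canonical column names to
#'   the names used in the source file (only the differing ones need be
#'   listed). `NULL` means the file already uses canonical names.
#' @param variability Is the variability column an `"sd"` (default) or an
#'   `"se"`? Standard errors are converted at load time via
#'   `SD = SE * sqrt(n)`.
#' @param year_source Which year column drives analysis-year binning:
#'   `"online"` (default, the usual meta-analytic convention) or `"print"`.
#' @param year_range Inclusive integer range of admissible publication
#'   years; rows outside it are rejected. Default 2009-2019.
#' @param file Optional path to a YAML file supplying any of the above keys;
#'   explicit arguments override file values.
#' @return An object of class `corpus_schema`.
#' @examples
#' corpus_schema(columns = c(control_mean = "ctrl.avg"), variability = "se")
#' @export
corpus_schema <- function(columns = NULL, variability = c("sd", "se"),
                          year_source = c("online", "print"),
                          year_range = c(2009L, 2019L), file = NULL) {
  from_file <- list()
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    if (!is.null(from_file$columns)) from_file$columns <- unlist(from_file$columns)
  }
  if (is.null(columns)) columns <- from_file$columns
  if (missing(variability) && !is.null(from_file$variability)) {
    variability <- from_file$variability
  }
  if (missing(year_source) && !is.null(from_file$year_source)) {
    year_source <- from_file$year_source
  }
  if (!is.null(from_file$year_range)) year_range <- from_file$year_range
  variability <- match.arg(variability, c("sd", "se"))
  year_source <- match.arg(year_source, c("online", "print"))
  stopifnot(length(year_range) == 2, year_range[1] <= year_range[2])
  if (!is.null(columns) &&
      (is.null(names(columns)) || any(!nzchar(names(columns))))) {
    abort("`columns` must be a named vector: canonical name = source name.")
  }
  structure(
    list(columns = columns, variability = variability,
         year_source = year_source, year_range = as.integer(year_range)),
    class = "corpus_schema"
  )
}

#' Read and validate a study-record corpus from CSV
#'
#' Loads a flat table of control-vs-treatment contrasts (one row per
#' experiment contrast), maps source columns through the schema, coerces
#' types, and validates every row against the record invariants: means
#' within scale bounds, SDs >= 0, per-arm n >= 2, CO2 level > 0, years
#' within the configured range, unique record ids. Rows violating an
#' invariant are rejected with row-level diagnostics rather than failing
#' the whole load; a missing required column is a hard error.
#'
#' Missing inclusion/exclusion flag columns default to `FALSE` (the record
#' is treated as a genuine ocean-acidification contrast). The analysis year
#' column `year` is set from `year_online` or `year_print` per the schema.
#'
#' @param path Path to a UTF-8 comma-separated file with one header row.
#' @param schema A [corpus_schema()]; default assumes canonical column names
#'   with SD variability and online-year binning.
#' @return A tibble of validated records with attribute `"load_report"`
#'   (counts read/accepted/rejected and a tibble of rejects with reasons),
#'   retrievable via [load_report()].
#' @examples
#' path <- system.file("extdata", "example_corpus.csv", package = "declineRR")
#' corpus <- read_corpus(path)
#' load_report(corpus)
#' @export
read_corpus <- function(path, schema = corpus_schema()) {
  stopifnot(inherits(schema, "corpus_schema"))
  if (!file.exists(path)) abort(sprintf("Corpus file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)

  # map source column names -> canonical
  if (!is.null(schema$columns)) {
    for (canon in names(schema$columns)) {
      src <- schema$columns[[canon]]
      if (!src %in% names(raw)) {
        abort(sprintf("Schema maps '%s' to source column '%s', which is absent.", canon, src))
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(CORPUS_REQUIRED, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Required column(s) missing from %s: %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  for (col in CORPUS_STRINGS) if (!col %in% names(raw)) raw[[col]] <- NA_character_
  for (col in CORPUS_FLAGS) if (!col %in% names(raw)) raw[[col]] <- "FALSE"

  n_read <- nrow(raw)
  reasons <- rep(NA_character_, n_read)
  note <- function(bad, msg) {
    fresh <- bad & is.na(reasons)
    reasons[fresh] <<- msg
    invisible(NULL)
  }

  num_cols <- c("control_mean", "treatment_mean", "control_sd", "treatment_sd",
                "control_n", "treatment_n", "co2_uatm", "year_online", "year_print")
  parsed <- raw
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    note(is.na(v) | !is.finite(v), sprintf("non-numeric or missing value in '%s'", col))
    parsed[[col]] <- v
  }
  for (col in CORPUS_FLAGS) {
    v <- toupper(trimws(raw[[col]]))
    v[v == "" | is.na(v)] <- "FALSE"
    ok <- v %in% c("TRUE", "FALSE", "T", "F", "1", "0")
    note(!ok, sprintf("unparseable logical in '%s'", col))
    parsed[[col]] <- v %in% c("TRUE", "T", "1")
  }
  parsed$scale_type <- tolower(trimws(raw$scale_type))
  note(!parsed$scale_type %in% SCALE_TYPES,
       sprintf("scale_type must be one of %s", paste(SCALE_TYPES, collapse = "/")))

  # SE -> SD conversion before bound checks (SDs only; means untouched)
  if (schema$variability == "se") {
    parsed$control_sd <- parsed$control_sd * sqrt(parsed$control_n)
    parsed$treatment_sd <- parsed$treatment_sd * sqrt(parsed$treatment_n)
  }

  bound <- scale_bound(parsed$scale_type)
  for (arm in c("control", "treatment")) {
    m <- parsed[[paste0(arm, "_mean")]]
    out_of_bounds <- !is.na(bound) & !is.na(m) & (m < 0 | m > bound)
    note(out_of_bounds, sprintf("%s_mean outside [0, bound] for its scale", arm))
    note(parsed[[paste0(arm, "_sd")]] < 0, sprintf("%s_sd is negative", arm))
    note(parsed[[paste0(arm, "_n")]] < 2, sprintf("%s_n below 2", arm))
  }
  note(parsed$co2_uatm <= 0, "co2_uatm must be > 0")
  yr <- parsed[[paste0("year_", schema$year_source)]]
  note(yr < schema$year_range[1] | yr > schema$year_range[2],
       sprintf("analysis year outside [%d, %d]", schema$year_range[1], schema$year_range[2]))
  note(duplicated(raw$record_id), "duplicate record_id")

  accepted <- parsed[is.na(reasons), , drop = FALSE]
  accepted$control_n <- as.integer(accepted$control_n)
  accepted$treatment_n <- as.integer(accepted$treatment_n)
  accepted$year_online <- as.integer(accepted$year_online)
  accepted$year_print <- as.integer(accepted$year_print)
  accepted$year <- accepted[[paste0("year_", schema$year_source)]]
  accepted <- accepted[, c(CORPUS_REQUIRED, "year", CORPUS_STRINGS, CORPUS_FLAGS)]

  rejects <- tibble::tibble(
    row = which(!is.na(reasons)),
    record_id = raw$record_id[!is.na(reasons)],
    reason = reasons[!is.na(reasons)]
  )
  report <- structure(
    list(n_read = n_read, n_accepted = nrow(accepted),
         n_rejected = nrow(rejects), rejects = rejects,
         year_source = schema$year_source),
    class = "load_report"
  )
  inform(sprintf("read_corpus: %d row(s) read, %d accepted, %d rejected.",
                 n_read, nrow(accepted), nrow(rejects)))
  attr(accepted, "load_report") <- report
  accepted
}

#' Retrieve the load report attached by [read_corpus()]
#' @param corpus A corpus tibble returned by [read_corpus()].
#' @return The `load_report` object (counts and per-row rejection reasons).
#' @export
load_report <- function(corpus) attr(corpus, "load_report")

#' @export
print.load_report <- function(x, ...) {
  cat(sprintf("<load_report> %d read, %d accepted, %d rejected (year source: %s)\n",
              x$n_read, x$n_accepted, x$n_rejected, x$year_source))
  if (x$n_rejected > 0) print(x$rejects, n = 10)
  invisible(x)
}

#' Write a result table as a deterministic CSV
#'
#' Writes any uniform result table (corpus, effect sizes, yearly summaries,
#' sensitivity comparisons) with a fixed column order and full-precision
#' numeric formatting, so identical inputs produce byte-identical files.
#'
#' @param rows A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  rows <- tibble::as_tibble(rows)
  tryCatch(
    readr::write_csv(rows, path, progress = FALSE),
    error = function(e) abort(sprintf("Cannot write table to '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Check that a record table satisfies the study-record invariants
#'
#' Validates an in-memory corpus (for example one produced by
#' [simulate_corpus()]) against the same invariants [read_corpus()] enforces
#' row-wise: required columns present, means within scale bounds, SDs
#' non-negative, per-arm n >= 2, positive CO2, unique record ids.
#'
#' @param records A record tibble.
#' @param year_range Admissible analysis-year range.
#' @return `records`, invisibly; aborts with the first violated invariant.
#' @export
validate_corpus <- function(records, year_range = c(2009L, 2019L)) {
  miss <- setdiff(c(CORPUS_REQUIRED, "year", CORPUS_FLAGS), names(records))
  if (length(miss)) abort(sprintf("Corpus missing column(s): %s", paste(miss, collapse = ", ")))
  fail <- function(cond, msg) if (any(cond)) abort(sprintf("Corpus invariant violated: %s", msg))
  fail(duplicated(records$record_id), "duplicate record_id")
  fail(!records$scale_type %in% SCALE_TYPES, "invalid scale_type")
  bound <- scale_bound(records$scale_type)
  for (arm in c("control", "treatment")) {
    m <- records[[paste0(arm, "_mean")]]
    fail(!is.finite(m), sprintf("non-finite %s_mean", arm))
    fail(!is.na(bound) & (m < 0 | m > bound), sprintf("%s_mean outside scale bounds", arm))
    fail(records[[paste0(arm, "_sd")]] < 0, sprintf("negative %s_sd", arm))
    fail(records[[paste0(arm, "_n")]] < 2, sprintf("%s_n below 2", arm))
  }
  fail(records$co2_uatm <= 0, "non-positive co2_uatm")
  fail(records$year < year_range[1] | records$year > year_range[2],
       "analysis year outside configured range")
  invisible(records)
}
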