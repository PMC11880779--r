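# Delimited-text input/output for cohorts and landmark datasets: one
# tab-separated file per table, ISO-8601 dates, header row.

.COHORT_TABLES <- c("persons", "coverage", "clinical_events", "blood_tests",
                    "registry")

#' Write / read a raw cohort as delimited text
#'
#' Writes the five cohort tables as tab-separated files
#' (`persons.tsv`, `coverage.tsv`, `clinical_events.tsv`,
#' `blood_tests.tsv`, `registry.tsv`) with ISO-8601 dates, plus the
#' simulation configuration as `sim_config.yaml` when the cohort carries
#' one.
#'
#' @param cohort a `raw_cohort`.
#' @param dir output directory (created if absent).
#' @param path,dir directory holding the five files.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   `raw_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in .COHORT_TABLES)
    data.table::fwrite(cohort[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", dateTimeAs = "ISO", na = "NA")
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) write_sim_config(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- lapply(.COHORT_TABLES, function(nm) {
    df <- as.data.frame(data.table::fread(file.path(path,
                                                    paste0(nm, ".tsv")),
                                          na.strings = c("", "NA")))
    for (cl in names(df))
      if (inherits(df[[cl]], "IDate") || grepl("date$", cl))
        df[[cl]] <- as.Date(df[[cl]])
    df
  })
  names(out) <- .COHORT_TABLES
  cfg_path <- file.path(path, "sim_config.yaml")
  cfg <- if (file.exists(cfg_path)) read_sim_config(cfg_path) else NULL
  structure(out, config = cfg, class = "raw_cohort")
}

#' Write / read a super-landmark dataset as delimited text
#'
#' One row per (person, landmark age); tab-separated, ISO dates. Categorical
#' predictors are stored as their labels and re-encoded as factors on read
#' using the supplied codebook.
#'
#' @param data a `super_landmark` data.frame.
#' @param file file path.
#' @param codebook codebook used to restore factor encodings on read.
#' @return `write_landmark` returns `file` invisibly; `read_landmark`
#'   returns a `super_landmark` data.frame.
#' @export
write_landmark <- function(data, file) {
  data.table::fwrite(as.data.frame(data), file, sep = "\t",
                     dateTimeAs = "ISO", na = "NA")
  invisible(file)
}

#' @rdname write_landmark
#' @export
read_landmark <- function(file, codebook = default_codebook()) {
  df <- as.data.frame(data.table::fread(file, na.strings = c("", "NA")))
  df$index_date <- as.Date(df$index_date)
  for (k in which(codebook$encoding == "categorical")) {
    nm <- codebook$predictor[k]
    if (!nm %in% names(df)) next
    lv <- .FACTOR_LEVELS[[nm]]
    if (is.null(lv)) lv <- sort(unique(df[[nm]]))
    if (nm %in% .MISSING_CATEGORY_PREDICTORS) lv <- c(lv, "missing")
    df[[nm]] <- factor(df[[nm]], levels = lv)
  }
  attr(df, "codebook") <- codebook
  class(df) <- c("super_landmark", "data.frame")
  df
}
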