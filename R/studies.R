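#' @keywords internal
"_PACKAGE"

# Column schema for the one-row-per-study CSV. Blank cells mean "not
# reported" (never zero); a study must carry at least one complete block.
.meta_cols <- c("study_id", "year", "ethnicity", "genotyping_method",
                "control_source", "nos_score", "language")
.allele_cols <- c("case_S", "case_M", "case_L", "ctrl_S", "ctrl_M", "ctrl_L")
.genotype_cols <- c("case_typeI", "case_typeII", "ctrl_typeI", "ctrl_typeII")
.severity_cols <- c("less_typeI", "less_typeII", "more_typeI", "more_typeII")
.count_cols <- c(.allele_cols, .genotype_cols, .severity_cols)
.study_cols <- c(.meta_cols, .count_cols)

.ethnicity_levels <- c("Asian", "Caucasian")
.method_levels <- c("automated_sequencing", "pcr_page")
.source_levels <- c("general_population", "hospital")
.language_levels <- c("Chinese", "English")

#' Read a per-study case-control count table
#'
#' Reads and validates a CSV with one row per primary study: metadata
#' covariates (ethnicity, genotyping method, control source,
#' Newcastle-Ottawa quality score, publication language) and up to three
#' count blocks -- S/M/L allele counts (chromosomes), type I/type II
#' L-carrier genotype counts (subjects), and severity-stratum genotype
#' counts. Blank count cells encode "not reported" and are kept as `NA`.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A `study_table`: a data frame with one validated row per study.
#' @details A block (allele, genotype, severity) is used only when all of
#'   its cells are present; partially reported blocks are a validation
#'   error. Every study must carry at least one complete block. All counts
#'   must be non-negative integers. Error messages carry the offending row
#'   number and study id.
#' @seealso [hmox1_studies()] for the packaged fixture,
#'   [write_studies()] for the inverse.
#' @examples
#' studies <- hmox1_studies()
#' nrow(studies)
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) stop("study file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  if (nrow(df) == 0L) stop("empty study table: ", path, " has a header but no rows")
  missing_cols <- setdiff(.study_cols, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  df <- df[.study_cols]
  df[df == ""] <- NA_character_
  for (col in c("year", "nos_score", .count_cols)) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & (is.na(num) | num != floor(num) | num < 0))
    if (length(bad) > 0L)
      stop(sprintf("row %d (%s): column '%s' must be a non-negative integer, got '%s'",
                   bad[1], df$study_id[bad[1]], col, raw[bad[1]]))
    df[[col]] <- as.integer(num)
  }
  validate_studies(df)
  class(df) <- c("study_table", "data.frame")
  df
}

#' Validate a study table
#'
#' Checks the invariants every analysis in the package assumes: known
#' factor levels, NOS score in 0--9, non-negative integer counts, complete
#' blocks, and at least one block per study.
#'
#' @param df A data frame with the `study_table` columns.
#' @return The input, invisibly, if valid; otherwise an error naming the
#'   first offending row.
#' @export
validate_studies <- function(df) {
  check_enum <- function(col, levels) {
    bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% levels))
    if (length(bad) > 0L)
      stop(sprintf("row %d (%s): '%s' must be one of {%s}, got '%s'",
                   bad[1], df$study_id[bad[1]], col,
                   paste(levels, collapse = ", "), df[[col]][bad[1]]))
  }
  if (anyNA(df$study_id)) stop("row ", which(is.na(df$study_id))[1], ": study_id is required")
  if (anyDuplicated(df$study_id))
    stop("duplicated study_id: ", df$study_id[anyDuplicated(df$study_id)])
  check_enum("ethnicity", .ethnicity_levels)
  check_enum("genotyping_method", .method_levels)
  check_enum("control_source", .source_levels)
  check_enum("language", .language_levels)
  bad_nos <- which(!is.na(df$nos_score) & (df$nos_score < 0 | df$nos_score > 9))
  if (length(bad_nos) > 0L)
    stop(sprintf("row %d (%s): nos_score must be in [0, 9], got %d",
                 bad_nos[1], df$study_id[bad_nos[1]], df$nos_score[bad_nos[1]]))
  for (i in seq_len(nrow(df))) {
    blocks <- c(allele = block_complete(df[i, ], .allele_cols),
                genotype = block_complete(df[i, ], .genotype_cols),
                severity = block_complete(df[i, ], .severity_cols))
    partial <- c(allele = block_partial(df[i, ], .allele_cols),
                 genotype = block_partial(df[i, ], .genotype_cols),
                 severity = block_partial(df[i, ], .severity_cols))
    if (any(partial))
      stop(sprintf("row %d (%s): %s block is partially reported; a block must be complete or fully blank",
                   i, df$study_id[i], names(partial)[partial][1]))
    if (!any(blocks))
      stop(sprintf("row %d (%s): no complete allele, genotype or severity block",
                   i, df$study_id[i]))
  }
  invisible(df)
}

block_complete <- function(row, cols) all(!is.na(unlist(row[cols])))
block_partial <- function(row, cols) {
  present <- !is.na(unlist(row[cols]))
  any(present) && !all(present)
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("Study table: %d studies (%d with allele counts, %d with genotype counts, %d with severity counts)\n",
              nrow(x), sum(has_block(x, "allele")), sum(has_block(x, "genotype")),
              sum(has_block(x, "severity"))))
  print.data.frame(x[, .meta_cols], row.names = FALSE, ...)
  invisible(x)
}

#' Which studies carry a given count block
#'
#' @param studies A `study_table`.
#' @param block `"allele"`, `"genotype"` or `"severity"`.
#' @return Logical vector, one element per study.
#' @export
has_block <- function(studies, block = c("allele", "genotype", "severity")) {
  block <- match.arg(block)
  cols <- switch(block, allele = .allele_cols, genotype = .genotype_cols,
                 severity = .severity_cols)
  apply(!is.na(studies[cols]), 1L, all)
}

#' The packaged HMOX1/COPD study fixture
#'
#' Seven case-control studies of the HMOX1 promoter (GT)n polymorphism and
#' COPD risk: study metadata (ethnicity, genotyping method, control
#' source, NOS quality score, publication language), S/M/L allele counts
#' for the five studies that report them, and type I (L-allele carrier)
#' vs type II genotype counts for all seven. Severity-stratum counts are
#' not part of the fixture (they were not published as counts); the
#' severity schema is exercised with simulated data.
#'
#' @return A validated `study_table` with 7 rows.
#' @examples
#' studies <- hmox1_studies()
#' studies$study_id
#' @export
hmox1_studies <- function() {
  path <- system.file("extdata", "hmox1_copd_studies.csv",
                      package = "hmoxmeta", mustWork = TRUE)
  read_studies(path)
}

#' Write a study table to CSV
#'
#' Inverse of [read_studies()]: absent counts are written as blank cells,
#' never zero, so a round trip is the identity.
#'
#' @param studies A `study_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path) {
  out <- as.data.frame(studies)[.study_cols]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
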