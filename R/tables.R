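# 2x2 table construction: the unit the meta-analysis pools.

#' Construct a 2x2 exposure-by-status table
#'
#' @param a Exposed cases.
#' @param b Unexposed cases.
#' @param c Exposed controls.
#' @param d Unexposed controls.
#' @return A `fourfold` object. Degenerate tables (all four cells zero)
#'   are flagged; downstream effect computation rejects them.
#' @export
fourfold <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells)) stop("fourfold table cells must not be NA")
  if (any(cells < 0)) stop("fourfold table cells must be non-negative")
  structure(list(a = a, b = b, c = c, d = d,
                 degenerate = all(cells == 0)),
            class = "fourfold")
}

#' @export
print.fourfold <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2L, 2L, byrow = TRUE,
              dimnames = list(c("case", "control"), c("exposed", "unexposed")))
  print(m)
  if (x$degenerate) cat("(degenerate: all cells zero)\n")
  invisible(x)
}

#' Allele-level 2x2 table for one study
#'
#' Contrasts one (GT)n allele class against the other two, counting each
#' of the 2N chromosomes in a group as one observation (the standard
#' allele-counting model; within-subject correlation between the two
#' chromosomes is ignored).
#'
#' @param study One row of a `study_table` with a complete allele block.
#' @param target `"S"`, `"M"` or `"L"`: the allele treated as exposure.
#' @return A `fourfold` with a = case chromosomes carrying the target
#'   allele, b = case chromosomes carrying either other allele, and c, d
#'   the same for controls.
#' @examples
#' du <- hmox1_studies()[hmox1_studies()$study_id == "Du", ]
#' allele_table(du, "L")
#' @export
allele_table <- function(study, target = c("S", "M", "L")) {
  target <- match.arg(target)
  if (!block_complete(study, .allele_cols))
    stop("study ", study$study_id, ": no complete allele block")
  others <- setdiff(c("S", "M", "L"), target)
  fourfold(a = study[[paste0("case_", target)]],
           b = sum(unlist(study[paste0("case_", others)])),
           c = study[[paste0("ctrl_", target)]],
           d = sum(unlist(study[paste0("ctrl_", others)])))
}

#' Genotype-level 2x2 table for one study
#'
#' Type I (carrier of at least one L allele) versus type II (no L allele),
#' cases versus controls; one subject is one observation.
#'
#' @param study One row of a `study_table` with a complete genotype block.
#' @return A `fourfold` (a = case type I, b = case type II, c = control
#'   type I, d = control type II).
#' @export
genotype_table <- function(study) {
  if (!block_complete(study, .genotype_cols))
    stop("study ", study$study_id, ": no complete genotype block")
  fourfold(a = study$case_typeI, b = study$case_typeII,
           c = study$ctrl_typeI, d = study$ctrl_typeII)
}

#' Severity 2x2 table for one study
#'
#' Contrasts the type I genotype between more-severe and less-severe COPD
#' strata. The more-severe stratum plays the "case" role, so OR > 1 means
#' type I is enriched in severe disease.
#'
#' @param study One row of a `study_table` with a complete severity block.
#' @return A `fourfold` (a = more-severe type I, b = more-severe type II,
#'   c = less-severe type I, d = less-severe type II).
#' @export
severity_table <- function(study) {
  if (!block_complete(study, .severity_cols))
    stop("study ", study$study_id, ": no complete severity block")
  fourfold(a = study$more_typeI, b = study$more_typeII,
           c = study$less_typeI, d = study$less_typeII)
}

#' Derive the L-carrier genotype split from printed marginals
#'
#' Published tables often print only the L-allele count and the type I /
#' type II carrier split for a group. Those marginals determine the full
#' bi-allelic (L vs non-L) genotype distribution exactly:
#' `LL = L_alleles - typeI`, `L_het = 2 * typeI - L_alleles`,
#' `nonL_hom = typeII`.
#'
#' @param L_alleles L-allele (chromosome) count in the group.
#' @param typeI Number of subjects carrying at least one L allele.
#' @param typeII Number of subjects carrying no L allele.
#' @param study_id Optional label used in error messages.
#' @return Named integer vector `c(LL, L_het, nonL_hom)`.
#' @details A negative derived count means the printed marginals are
#'   mutually inconsistent; that is reported as an error naming the study.
#' @export
collapse_to_biallelic <- function(L_alleles, typeI, typeII, study_id = NULL) {
  LL <- L_alleles - typeI
  L_het <- 2L * typeI - L_alleles
  if (LL < 0 || L_het < 0) {
    who <- if (is.null(study_id)) "" else paste0(" in study ", study_id)
    stop(sprintf("inconsistent marginals%s: L_alleles=%d, typeI=%d imply LL=%d, L_het=%d",
                 who, L_alleles, typeI, LL, L_het))
  }
  c(LL = LL, L_het = L_het, nonL_hom = typeII)
}

# Pull the fourfold for a named comparison; NULL when the study lacks
# the block (the study is then silently excluded from that comparison).
comparison_table <- function(study, comparison) {
  block <- switch(comparison,
                  allele_S = , allele_M = , allele_L = "allele",
                  genotype = "genotype", severity = "severity",
                  stop("unknown comparison: ", comparison))
  cols <- switch(block, allele = .allele_cols, genotype = .genotype_cols,
                 severity = .severity_cols)
  if (!block_complete(study, cols)) return(NULL)
  switch(comparison,
         allele_S = allele_table(study, "S"),
         allele_M = allele_table(study, "M"),
         allele_L = allele_table(study, "L"),
         genotype = genotype_table(study),
         severity = severity_table(study))
}

.comparisons <- c("allele_S", "allele_M", "allele_L", "genotype", "severity")
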