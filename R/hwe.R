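# Hardy-Weinberg equilibrium chi-square tests, bi- and multi-allelic.

#' Bi-allelic Hardy-Weinberg chi-square test
#'
#' Pearson goodness-of-fit test of observed genotype counts against the
#' Hardy-Weinberg proportions implied by the sample allele frequencies,
#' with 1 degree of freedom.
#'
#' @param hom1 Count of homozygotes for allele 1.
#' @param het Count of heterozygotes.
#' @param hom2 Count of homozygotes for allele 2.
#' @return An `hwe_test` with the chi-square statistic, df, upper-tail
#'   p-value, and observed/expected counts.
#' @examples
#' hwe_biallelic(25, 50, 25)  # exact HWE proportions: chi-square 0
#' @export
hwe_biallelic <- function(hom1, het, hom2) {
  obs <- c(hom1 = hom1, het = het, hom2 = hom2)
  if (any(obs < 0)) stop("genotype counts must be non-negative")
  n <- sum(obs)
  if (n == 0) stop("Hardy-Weinberg test undefined for an empty sample")
  p <- (2 * hom1 + het) / (2 * n)
  q <- 1 - p
  expected <- n * c(hom1 = p^2, het = 2 * p * q, hom2 = q^2)
  chisq <- sum((obs - expected)^2 / expected, na.rm = TRUE)
  new_hwe_test(chisq, df = 1L, observed = obs, expected = expected,
               method = "bi-allelic")
}

#' Multi-allelic Hardy-Weinberg chi-square test
#'
#' Generalizes the Pearson test to a k-allele locus (k = 3 for the S/M/L
#' classes of the (GT)n tract): allele frequencies are estimated from the
#' genotype counts, expected counts are `N p_i^2` for homozygotes and
#' `2 N p_i p_j` for heterozygotes, and the statistic has k(k-1)/2
#' degrees of freedom.
#'
#' @param counts Named numeric vector of genotype counts. Names are
#'   two-letter allele pairs, e.g. `c(SS=25, SM=30, SL=20, MM=9, ML=12,
#'   LL=4)`; order within a pair does not matter.
#' @param alleles Optional character vector fixing the allele set (useful
#'   when an allele is absent from every genotype).
#' @return An `hwe_test`.
#' @examples
#' hwe_multiallelic(c(SS = 25, SM = 30, SL = 20, MM = 9, ML = 12, LL = 4))
#' @export
hwe_multiallelic <- function(counts, alleles = NULL) {
  if (is.null(names(counts)) || any(nchar(names(counts)) != 2L))
    stop("genotype counts must be named by two-letter allele pairs, e.g. 'SM'")
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("Hardy-Weinberg test undefined for an empty sample")
  pairs <- strsplit(names(counts), "")
  seen <- sort(unique(unlist(pairs)))
  alleles <- if (is.null(alleles)) seen else sort(alleles)
  if (!all(seen %in% alleles))
    stop("genotype names use alleles outside the declared set")
  k <- length(alleles)
  # Allele counts: each homozygote contributes two copies, heterozygote one.
  ac <- stats::setNames(numeric(k), alleles)
  for (i in seq_along(counts)) {
    ac[pairs[[i]][1]] <- ac[pairs[[i]][1]] + counts[i]
    ac[pairs[[i]][2]] <- ac[pairs[[i]][2]] + counts[i]
  }
  p <- ac / (2 * n)
  geno <- t(utils::combn(alleles, 2L))
  geno_names <- c(paste0(alleles, alleles), paste0(geno[, 1], geno[, 2]))
  expected <- stats::setNames(
    c(n * p[alleles]^2, 2 * n * p[geno[, 1]] * p[geno[, 2]]), geno_names)
  obs <- stats::setNames(numeric(length(geno_names)), geno_names)
  for (i in seq_along(counts)) {
    key <- paste(sort(pairs[[i]]), collapse = "")
    key <- if (key %in% geno_names) key else paste(rev(sort(pairs[[i]])), collapse = "")
    obs[key] <- obs[key] + counts[i]
  }
  nz <- expected > 0
  chisq <- sum((obs[nz] - expected[nz])^2 / expected[nz])
  new_hwe_test(chisq, df = as.integer(k * (k - 1) / 2), observed = obs,
               expected = expected, method = sprintf("%d-allele", k))
}

new_hwe_test <- function(chisq, df, observed, expected, method) {
  structure(list(chi_square = chisq, df = df,
                 p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
                 observed = observed, expected = expected, method = method),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("Hardy-Weinberg %s chi-square test\n", x$method))
  cat(sprintf("  X-squared = %.4g, df = %d, p-value = %s\n",
              x$chi_square, x$df, format_p(x$p_value)))
  invisible(x)
}

format_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
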