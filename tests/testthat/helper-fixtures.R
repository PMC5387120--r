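# Shared fixtures and independent oracles used across test files.

fixture <- hmox1_studies()

study_row <- function(id) fixture[fixture$study_id == id, , drop = FALSE]

# Brute-force inverse-variance weighted mean, written out longhand so it
# stays independent of the pooling implementation.
brute_fixed_pool <- function(log_or, var) {
  w <- 1 / var
  num <- 0; den <- 0
  for (i in seq_along(log_or)) {
    num <- num + w[i] * log_or[i]
    den <- den + w[i]
  }
  list(est = num / den, se = sqrt(1 / den))
}

# DerSimonian-Laird tau^2 by the method-of-moments closed form.
brute_dl_tau2 <- function(log_or, var) {
  w <- 1 / var
  theta_bar <- sum(w * log_or) / sum(w)
  Q <- sum(w * (log_or - theta_bar)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - (length(log_or) - 1)) / C)
}

# A tiny synthetic effect set with no ties, used by bias tests.
toy_effects <- function(log_or, se) {
  data.frame(study_id = paste0("t", seq_along(log_or)), log_or = log_or,
             var = se^2, se = se, or = exp(log_or),
             ci_low = exp(log_or - 1.959964 * se),
             ci_high = exp(log_or + 1.959964 * se),
             corrected = FALSE, stringsAsFactors = FALSE)
}

round2 <- function(x) round(x, 2)
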