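# Shared fixtures, generated once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

# Default-condition training cohort (310 P / 310 B, planted contrasts).
shared_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- gen_labeled_cohort(cohort_spec(), seed = 101L)
  .fixtures$cohort
}

# Imbalanced held-out cohort (187 P / 371 B), independent seed.
shared_test_cohort <- function() {
  if (is.null(.fixtures$test_cohort))
    .fixtures$test_cohort <- gen_labeled_cohort(
      cohort_spec(n_pathogenic = 187L, n_benign = 371L), seed = 202L)
  .fixtures$test_cohort
}

# Forest trained on the shared cohort at the shipped hyperparameters.
shared_model <- function() {
  if (is.null(.fixtures$model)) {
    coh <- shared_cohort()
    .fixtures$model <- train_forest(coh$features, coh$labels, seed = 7L)
  }
  .fixtures$model
}

# Spec with every planted contrast switched off: labels carry no signal.
null_spec <- function(n_pathogenic = 310L, n_benign = 310L) {
  cohort_spec(n_pathogenic = n_pathogenic, n_benign = n_benign,
              gc_shift = 0, ext_multiplier = 1, utr_len_multiplier = 1,
              aa_tilt = 1, score_shift = 0,
              idp_rate_pathogenic = 0.013, idp_rate_benign = 0.013)
}

random_utr <- function(len, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

# Independent brute-force oracle: check every in-frame triplet.
brute_scan <- function(seq) {
  n <- nchar(seq)
  k <- n %/% 3L
  if (k == 0L) return(NA_integer_)
  for (i in seq_len(k)) {
    codon <- substr(seq, 3L * i - 2L, 3L * i)
    if (codon %in% c("TAA", "TAG", "TGA")) return(i - 1L)
  }
  NA_integer_
}

# Independent all-pairs Mann-Whitney U count (ties count one half).
brute_mwu_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Benjamini-Hochberg step-up by the hand formula.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}
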