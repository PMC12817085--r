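test_that("the transition table tallies original vs downstream stop usage", {
  t1 <- validate_transcript(transcript("a", "ATGTGA", "TAACCC"))
  tt <- transition_table(list(t1))
  expect_equal(tt$downstream_fractions[["TAA"]], 1)
  expect_equal(tt$none_fraction, 0)
  expect_equal(sum(tt$original_fractions), 1)
  expect_equal(sum(tt$downstream_fractions), 1)
  # GC-only UTRs can never terminate: everything is NSD-susceptible
  gc_only <- lapply(1:5, function(i) {
    validate_transcript(transcript(paste0("g", i), "ATGTAA", "GGCCGGCC"))
  })
  expect_equal(transition_table(gc_only)$none_fraction, 1)
})

test_that("usage-weighted stop-retained fraction reproduces the printed split", {
  pct <- weighted_stop_retained_fraction(c(TGA = 0.492, TAA = 0.284,
                                           TAG = 0.224))
  expect_equal(round(pct, 1), 14.3)
  expect_equal(pct, 100 * (0.492 * 1 + 0.284 * 2 + 0.224 * 1) / 9)
  # TAA-only usage: 2 of 9
  expect_equal(weighted_stop_retained_fraction(c(TGA = 0, TAA = 1, TAG = 0)),
               100 * 2 / 9)
  # complement is the stop-loss fraction, exactly
  expect_equal(100 - pct, 85.73333, tolerance = 1e-6)
  expect_error(weighted_stop_retained_fraction(c(TGA = 0.5, TAA = 0.2,
                                                 TAG = 0.2)), "sum to 1")
})

test_that("the random-model expected scan length is geometric in the stop probability", {
  u <- expected_scan_length()
  expect_equal(u$p_stop, 3 / 64)
  expect_equal(u$expected_codons, 64 / 3)
  expect_equal(round(u$expected_codons, 1), 21.3)
  # no T -> no stop codon possible
  v <- expected_scan_length(c(A = 0, C = 0, G = 0, T = 1))
  expect_true(v$nsd_certain)
  expect_identical(v$expected_codons, Inf)
  # biased composition: p = P(TAA)+P(TAG)+P(TGA)
  f <- c(A = 0.4, C = 0.1, G = 0.2, T = 0.3)
  expect_equal(expected_scan_length(f)$p_stop,
               0.3 * 0.4 * 0.4 + 0.3 * 0.4 * 0.2 + 0.3 * 0.2 * 0.4)
  expect_error(expected_scan_length(c(A = 0.5, C = 0.5, G = 0.2, T = -0.2)),
               "negative")
})

test_that("Monte-Carlo scan lengths match the analytic expectation within 1%", {
  for (freqs in list(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                     c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                     c(A = 0.2, C = 0.3, G = 0.3, T = 0.2))) {
    lens <- simulate_scan_lengths(50000, freqs, max_codons = 2000, seed = 7)
    expect_lt(mean(is.na(lens)), 1e-4)
    analytic <- expected_scan_length(freqs)$expected_codons
    expect_lt(abs(mean(lens, na.rm = TRUE) - analytic) / analytic, 0.01)
  }
})

test_that("extension-length summaries track the iid expectation and flag NSD", {
  set.seed(303)
  txs <- lapply(1:2000, function(i) {
    transcript(paste0("t", i), "ATGTGA", random_utr(900))
  })
  summ <- extension_length_summary(txs, frame = 0L)
  # scan length before the stop: mean = 64/3 - 1 under uniform iid bases
  expect_lt(abs(summ$mean - (64 / 3 - 1)) / (64 / 3 - 1), 0.05)
  expect_identical(sum(summ$histogram$count) + summ$n_nsd, 2000L)
  # shifted frames share the same iid expectation
  for (fr in c(1L, -1L)) {
    s <- extension_length_summary(txs[1:1000], frame = fr)
    expect_lt(abs(s$mean - (64 / 3 - 1)) / (64 / 3 - 1), 0.1)
  }
  # all-NSD cohort: empty summary, full NSD count
  gc_txs <- lapply(1:4, function(i) transcript(paste0("g", i), "ATGTGA",
                                               "GGCCGGCC"))
  s0 <- extension_length_summary(gc_txs)
  expect_identical(s0$n_nsd, 4L)
  expect_true(is.na(s0$median))
})

test_that("Spearman correlation matches a brute-force rank computation", {
  x <- 1:20
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  xf <- c(3.1, 5.2, 1.0, 4.4, 4.4, 2.2, 9.9, 0.5, 7.7, 6.6)
  yf <- c(1.2, 0.8, 3.3, 2.1, 5.5, 5.5, 0.1, 4.2, 2.2, 3.0)
  oracle <- stats::cor(rank(xf), rank(yf))  # Pearson on average ranks
  expect_equal(spearman_cor(xf, yf)$rho, oracle)
  expect_error(spearman_cor(1:3, 1:4), "length mismatch")
})

test_that("group comparison uses MWU/Fisher with BH adjustment", {
  # Mann-Whitney U equals the all-pairs count at small n
  set.seed(61)
  for (i in 1:10) {
    xp <- round(runif(sample(3:10, 1)), 1)
    xb <- round(runif(sample(3:10, 1)), 1)
    df <- data.frame(f = c(xp, xb))
    y <- c(rep("P", length(xp)), rep("B", length(xb)))
    got <- group_compare(df, y)
    expect_equal(got$statistic[1], brute_mwu_u(xp, xb))
  }
  # BH step-up agrees with the hand formula
  expect_equal(brute_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))

  # identical groups: nothing significant
  df2 <- data.frame(a = rep(c(1, 2, 3), 4), b = rep(c(0, 1), 6))
  y2 <- rep(c("P", "B"), each = 6)
  got2 <- group_compare(df2, y2)
  expect_true(all(got2$p_adj > 0.9))
  expect_identical(got2$test, c("mann_whitney", "fisher"))

  # planted hydrophobicity shift is detected at BH 0.05
  coh <- shared_cohort()
  res <- group_compare(coh$features[c("kd_mean", "mj_mean", "ext_len",
                                      "idp_flag")], coh$labels)
  expect_true(all(res$p_adj[res$feature %in% c("kd_mean", "ext_len")] < 0.05))
  expect_equal(res$direction[res$feature == "kd_mean"], 1)
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
})
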