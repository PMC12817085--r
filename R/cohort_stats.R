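#' Stop-codon transition table for a transcript cohort
#'
#' For each transcript, tallies its native stop codon against the first
#' downstream in-frame (frame 0) stop codon of its 3' UTR (or `none` when
#' the UTR harbors no in-frame stop — the NSD-susceptible class).
#'
#' @param transcripts List of validated `transcript` objects.
#' @return A list: `counts` (3 x 4 matrix, original TAA/TAG/TGA by
#'   downstream TAA/TAG/TGA/none), `original_fractions`,
#'   `downstream_fractions` (each summing to 1), `none_fraction`.
#' @export
transition_table <- function(transcripts) {
  stopifnot(length(transcripts) >= 1L)
  orig <- vapply(transcripts, stop_codon_of, "")
  down <- vapply(transcripts, function(t) {
    hit <- scan_for_stop(t$utr3)
    if (is.na(hit$index)) "none" else hit$stop_codon
  }, "")
  counts <- table(factor(orig, levels = STOP_CODONS),
                  factor(down, levels = c(STOP_CODONS, "none")))
  counts <- unclass(as.matrix(counts))
  n <- sum(counts)
  list(counts = counts,
       original_fractions = rowSums(counts) / n,
       downstream_fractions = colSums(counts) / n,
       none_fraction = sum(counts[, "none"]) / n)
}

#' Usage-weighted fraction of stop-retained substitutions
#'
#' Enumerates all nine single-nucleotide substitutions for each stop codon,
#' counts the stop-retained outcomes per codon (2 of 9 for TAA, 1 of 9 for
#' TAG and TGA), and weights these per-codon fractions by the cohort's
#' stop-codon usage. With the transcriptome-wide usage TGA 49.2%, TAA
#' 28.4%, TAG 22.4% this gives 14.3%.
#'
#' @param usage_weights Named weights over `TGA`, `TAA`, `TAG` summing to 1.
#' @return Percentage of substitutions that are stop-retained.
#' @export
weighted_stop_retained_fraction <- function(usage_weights) {
  stopifnot(all(STOP_CODONS %in% names(usage_weights)))
  if (abs(sum(usage_weights[STOP_CODONS]) - 1) > 1e-9)
    stop("usage weights must sum to 1", call. = FALSE)
  frac <- vapply(STOP_CODONS, function(sc) {
    # A long enough GC-only UTR never matters here: only the substitution's
    # consequence class is read.
    t <- transcript(paste0("w_", sc), paste0("ATG", sc), "CCC")
    snvs <- enumerate_snvs(t)
    mean(snvs$consequence == "stop_retained")
  }, numeric(1))
  100 * sum(usage_weights[STOP_CODONS] * frac)
}

#' Expected scan length until the first stop codon under iid bases
#'
#' Under independent bases with the given frequencies, each codon is a stop
#' with probability `p = P(TAA) + P(TAG) + P(TGA)` and the number of codons
#' read until and including the terminating codon is geometric with mean
#' `1/p`. With uniform base frequencies this is `64/3 ~ 21.3` codons.
#'
#' @param nt_freqs Named frequencies over `A`, `C`, `G`, `T` summing to 1.
#' @return A list: `expected_codons` (`Inf` when no stop is possible),
#'   `p_stop`, `nsd_certain`.
#' @export
expected_scan_length <- function(nt_freqs = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25)) {
  stopifnot(all(BASES %in% names(nt_freqs)))
  if (any(nt_freqs < 0)) stop("negative frequencies", call. = FALSE)
  if (abs(sum(nt_freqs[BASES]) - 1) > 1e-9)
    stop("frequencies must sum to 1", call. = FALSE)
  p_stop <- sum(vapply(STOP_CODONS, function(sc) {
    prod(nt_freqs[strsplit(sc, "")[[1]]])
  }, numeric(1)))
  if (p_stop == 0)
    list(expected_codons = Inf, p_stop = 0, nsd_certain = TRUE)
  else
    list(expected_codons = 1 / p_stop, p_stop = p_stop, nsd_certain = FALSE)
}

#' Monte-Carlo scan lengths under iid bases
#'
#' Simulates sequences of independent codons (codon probability = product
#' of its base frequencies) and records, per sequence, the 1-based index of
#' the first stop codon — the scan length including the terminating codon.
#' Sequences with no stop within `max_codons` return `NA` (NSD).
#'
#' @param n Number of sequences.
#' @param nt_freqs Named base frequencies summing to 1.
#' @param max_codons Scan horizon per sequence.
#' @param seed Integer seed.
#' @return Integer vector of length `n` (with `NA` for NSD).
#' @export
simulate_scan_lengths <- function(n, nt_freqs = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                                  max_codons = 1000L, seed = 1L) {
  codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  probs <- vapply(codons, function(cd) {
    prod(nt_freqs[strsplit(cd, "")[[1]]])
  }, numeric(1))
  is_stop <- codons %in% STOP_CODONS
  set.seed(seed)
  out <- rep(NA_integer_, n)
  pending <- seq_len(n)
  chunk <- 50L
  pos <- 0L
  while (length(pending) && pos < max_codons) {
    m <- min(chunk, max_codons - pos)
    draws <- matrix(sample.int(64L, length(pending) * m, replace = TRUE,
                               prob = probs),
                    nrow = length(pending))
    hit <- apply(draws, 1L, function(row) {
      w <- which(is_stop[row])
      if (length(w)) w[1L] else NA_integer_
    })
    found <- !is.na(hit)
    out[pending[found]] <- pos + hit[found]
    pending <- pending[!found]
    pos <- pos + m
  }
  out
}

#' Summarize extension lengths across a cohort
#'
#' Per-transcript scan length (codons strictly before the first in-frame
#' stop) in the requested reading frame; NSD transcripts are excluded from
#' the summary statistics and reported as a count.
#'
#' @param transcripts List of validated `transcript` objects.
#' @param frame `0`, `+1` or `-1`.
#' @return A list: `lengths`, `median`, `mean`, `histogram` (data frame of
#'   bin/count), `n_nsd`, `n`.
#' @export
extension_length_summary <- function(transcripts, frame = 0L) {
  stopifnot(length(transcripts) >= 1L, frame %in% c(0L, 1L, -1L))
  lens <- vapply(transcripts, function(t) {
    if (frame == 0L) {
      hit <- scan_for_stop(t$utr3)
      if (is.na(hit$index)) NA_integer_ else hit$index
    } else {
      ext <- frameshift_extension(t, frame)
      if (ext$nsd) NA_integer_ else ext$ext_len
    }
  }, integer(1))
  obs <- lens[!is.na(lens)]
  hist_df <- if (length(obs)) {
    tab <- table(obs)
    data.frame(bin = as.integer(names(tab)), count = as.integer(tab))
  } else data.frame(bin = integer(0), count = integer(0))
  list(lengths = lens,
       median = if (length(obs)) median(obs) else NA_real_,
       mean = if (length(obs)) mean(obs) else NA_real_,
       histogram = hist_df,
       n_nsd = sum(is.na(lens)), n = length(lens))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, with the p-value from
#' [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list: `rho`, `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Two-group feature comparison with FDR control
#'
#' Compares each feature column between two label groups: Mann-Whitney U
#' (two-sided Wilcoxon rank-sum) for continuous features, Fisher's exact
#' test for binary 0/1 features (e.g. the IDP flag). P-values are adjusted
#' across the tested family with the Benjamini-Hochberg step-up procedure.
#'
#' @param features Data frame of numeric feature columns.
#' @param labels `"B"`/`"P"` vector (or logical pathogenic flags).
#' @return Data frame: `feature`, `test`, `statistic`, `direction`
#'   (sign of pathogenic-minus-benign location shift), `p`, `p_adj`.
#' @export
group_compare <- function(features, labels) {
  features <- as.data.frame(features)
  y <- as_binary_labels(labels)
  if (nlevels(droplevels(y)) < 2L)
    stop("both groups must be present", call. = FALSE)
  rows <- lapply(names(features), function(nm) {
    v <- features[[nm]]
    ok <- !is.na(v)
    vp <- v[ok & y == "P"]; vb <- v[ok & y == "B"]
    if (length(vp) == 0L || length(vb) == 0L)
      return(data.frame(feature = nm, test = NA_character_,
                        statistic = NA_real_, direction = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    binary <- all(v[ok] %in% c(0, 1))
    if (binary) {
      tab <- table(factor(v[ok], levels = c(0, 1)), droplevels(y[ok]))
      ft <- fisher.test(tab)
      data.frame(feature = nm, test = "fisher",
                 statistic = unname(ft$estimate),
                 direction = sign(mean(vp) - mean(vb)),
                 p = ft$p.value, stringsAsFactors = FALSE)
    } else {
      wt <- suppressWarnings(wilcox.test(vp, vb, exact = FALSE))
      data.frame(feature = nm, test = "mann_whitney",
                 statistic = unname(wt$statistic),
                 direction = sign(median(vp) - median(vb)),
                 p = wt$p.value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
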