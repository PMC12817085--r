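# Transcriptome-wide stop-codon usage used as the generator default.
STOP_USAGE <- c(TGA = 0.492, TAA = 0.284, TAG = 0.224)

sense_codons <- function() {
  if (is.null(.stoplossr_cache$sense)) {
    ct <- codon_table()
    .stoplossr_cache$sense <- names(ct)[ct != "*"]
  }
  .stoplossr_cache$sense
}

codons_for_aa <- function(aa) {
  if (is.null(.stoplossr_cache$by_aa)) {
    ct <- codon_table()
    .stoplossr_cache$by_aa <- split(names(ct), unname(ct))
  }
  .stoplossr_cache$by_aa[[aa]]
}

#' Synthetic cohort specification
#'
#' Parameters of the seeded generators. Defaults mirror the published study
#' conditions: 310 pathogenic + 310 benign training variants (619 in the
#' source cohort), stop-codon usage TGA/TAA/TAG = 49.2/28.4/22.4%,
#' log-normal 3' UTR lengths and benign extension lengths with median ~15
#' codons, and a pathogenic tilt of longer (x2), more hydrophobic
#' (Leu/Pro/Ala/Cys-enriched vs Ser/Lys/Glu/Tyr-enriched) and more
#' aggregation-prone extensions with shifted annotation-score proxies —
#' the planted contrast structure of the curated-cohort comparison.
#'
#' @param n_pathogenic,n_benign Cohort composition.
#' @param utr_len_meanlog,utr_len_sdlog Log-normal 3' UTR tail length.
#' @param gc_shape1,gc_shape2 Beta parameters of the per-transcript GC
#'   target (benign; the pathogenic tilt adds `gc_shift`).
#' @param gc_shift Additive GC-target shift for pathogenic rows.
#' @param ext_meanlog,ext_sdlog Log-normal benign extension length (codons).
#' @param ext_multiplier Pathogenic extension-length multiplier.
#' @param utr_len_multiplier Pathogenic 3' UTR tail-length multiplier.
#' @param aa_tilt Multiplicative enrichment of L/P/A/C (pathogenic) or
#'   S/K/E/Y (benign) residue frequencies.
#' @param score_shift Mean shift (in SD units) of the pathogenic
#'   annotation-score and constraint proxies; 0 plants no contrast at all
#'   on these columns.
#' @param idp_rate_pathogenic,idp_rate_benign IDP-flag rates (10.0% vs
#'   1.3% in the curated cohorts).
#' @param stop_usage Stop-codon usage weights.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_pathogenic = 310L, n_benign = 310L,
                        utr_len_meanlog = log(250), utr_len_sdlog = 0.6,
                        gc_shape1 = 5, gc_shape2 = 6, gc_shift = 0.06,
                        ext_meanlog = log(15), ext_sdlog = 0.7,
                        ext_multiplier = 2,
                        utr_len_multiplier = 1.3,
                        aa_tilt = 2.5,
                        score_shift = 1.2,
                        idp_rate_pathogenic = 0.10,
                        idp_rate_benign = 0.013,
                        stop_usage = STOP_USAGE) {
  structure(as.list(environment()), class = "cohort_spec")
}

# Label-specific residue frequencies of the planted extension peptides.
aa_probs_for_label <- function(label, tilt) {
  w <- setNames(rep(1, 20), AA_ALPHABET)
  if (label == "P") w[c("L", "P", "A", "C")] <- tilt
  else w[c("S", "K", "E", "Y")] <- tilt
  w / sum(w)
}

random_sense_cds <- function(n_codons, stop_codon) {
  body <- sample(sense_codons(), n_codons, replace = TRUE)
  body[1L] <- "ATG"
  paste0(paste(body, collapse = ""), stop_codon)
}

# UTR tail with an exact GC quota: round(len * gc) G/C bases shuffled among
# A/T bases, so the realized GC tracks the target to rounding error.
gc_quota_seq <- function(len, gc_target) {
  if (len <= 0L) return("")
  n_gc <- round(len * gc_target)
  gc_part <- sample(c("G", "C"), n_gc, replace = TRUE)
  at_part <- sample(c("A", "T"), len - n_gc, replace = TRUE)
  paste(sample(c(gc_part, at_part)), collapse = "")
}

#' Generate a cohort of valid synthetic transcripts
#'
#' Coding sequences are random sense codons (ATG-initiated, no internal
#' stop) terminated by a stop codon drawn at the transcriptome-wide usage
#' frequencies; 3' UTRs are log-normal in length with a beta-distributed
#' per-transcript GC target realized by quota sampling (within ~2% of the
#' target at the generated lengths).
#'
#' @param n Number of transcripts.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; identical `(n, spec, seed)` regenerate
#'   byte-identical transcripts.
#' @return List of validated `transcript` objects.
#' @export
gen_transcripts <- function(n, spec = cohort_spec(), seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sc <- sample(names(spec$stop_usage), 1L, prob = spec$stop_usage)
    cds <- random_sense_cds(sample(100:400, 1L), sc)
    len <- max(30L, round(rlnorm(1, spec$utr_len_meanlog, spec$utr_len_sdlog)))
    gc <- rbeta(1, spec$gc_shape1, spec$gc_shape2)
    validate_transcript(transcript(sprintf("syn_tx_%04d", i), cds,
                                   gc_quota_seq(len, gc)))
  })
}

#' Generate a labeled synthetic variant cohort with planted contrasts
#'
#' Builds one synthetic stop-loss substitution per row and runs it through
#' the real pipeline (enumeration, extension scanning, feature assembly).
#' Pathogenic rows receive longer extensions, hydrophobic/aggregation-prone
#' residue enrichment, GC-richer and longer 3' UTRs, shifted
#' annotation-score proxies, higher constraint (pLI, s_het; lower LOEUF),
#' a higher IDP rate, and an allele-frequency proxy concentrated at rare
#' values — so the planted direction of every feature matches
#' [planted_direction()].
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A list: `features` (data frame, [feature_registry()] columns),
#'   `labels` (`"B"`/`"P"`), `af_proxy`, `meta` (per-row transcript id,
#'   variant HGVS, peptide), `transcripts`.
#' @export
gen_labeled_cohort <- function(spec = cohort_spec(), seed = 1L) {
  set.seed(seed)
  labels <- c(rep("P", spec$n_pathogenic), rep("B", spec$n_benign))
  rows <- vector("list", length(labels))
  txs <- vector("list", length(labels))
  meta <- vector("list", length(labels))
  af <- numeric(length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    # planted extension peptide
    ml <- spec$ext_meanlog + if (lab == "P") log(spec$ext_multiplier) else 0
    ext_len <- max(1L, round(rlnorm(1, ml, spec$ext_sdlog)))
    pep <- paste(sample(AA_ALPHABET, ext_len, replace = TRUE,
                        prob = aa_probs_for_label(lab, spec$aa_tilt)),
                 collapse = "")
    pep_dna <- paste(vapply(strsplit(pep, "")[[1]],
                            function(a) sample(codons_for_aa(a), 1L), ""),
                     collapse = "")
    new_stop <- sample(names(spec$stop_usage), 1L, prob = spec$stop_usage)
    gc <- min(0.95, rbeta(1, spec$gc_shape1, spec$gc_shape2) +
                if (lab == "P") spec$gc_shift else 0)
    tail_len <- max(10L, round(rlnorm(1, spec$utr_len_meanlog,
                                      spec$utr_len_sdlog) *
                                 (if (lab == "P") spec$utr_len_multiplier
                                  else 1)))
    utr3 <- paste0(pep_dna, new_stop, gc_quota_seq(tail_len, gc))
    sc <- sample(names(spec$stop_usage), 1L, prob = spec$stop_usage)
    t <- validate_transcript(transcript(sprintf("syn_var_%04d", i),
                                        random_sense_cds(sample(100:400, 1L),
                                                         sc),
                                        utr3))
    snvs <- enumerate_snvs(t)
    loss <- snvs[snvs$consequence == "stop_loss", ]
    v <- loss[sample(nrow(loss), 1L), ]
    ext <- extension_for_variant(t, v)
    shift <- if (lab == "P") spec$score_shift else 0
    ann <- annotation_record(
      cadd = rnorm(1, 15 + 8 * shift, 6),
      gerp = rnorm(1, 2 + 1.5 * shift, 1.5),
      phylop100 = rnorm(1, 1 + 2 * shift, 1.5),
      phastcons100 = min(1, max(0, rnorm(1, 0.4 + 0.25 * shift, 0.25))),
      mrna_stability_z = rnorm(1, 0 + 0.8 * shift, 1),
      pli = rbeta(1, 0.5 + shift, max(0.2, 2 - shift)),
      loeuf = max(0.01, rnorm(1, 1.1 - 0.4 * shift, 0.3)),
      s_het = rlnorm(1, log(0.01) + 0.7 * shift, 0.8),
      tango_max = min(100, max(0, rnorm(1, 15 + 20 * shift, 12))),
      canya = min(1, max(0, rnorm(1, 0.3 + 0.25 * shift, 0.15))),
      idp_flag = rbinom(1, 1, if (lab == "P") spec$idp_rate_pathogenic
                        else spec$idp_rate_benign))
    rows[[i]] <- assemble_features(t, ext, ann)
    txs[[i]] <- t
    af[i] <- if (lab == "P") 10^runif(1, -6, -4) else 10^runif(1, -3.2, -1.3)
    meta[[i]] <- data.frame(transcript_id = t$id, hgvs_c = v$hgvs_c,
                            hgvs_p = v$hgvs_p, substituted_aa = ext$substituted_aa,
                            peptide = ext$peptide, label = lab,
                            stringsAsFactors = FALSE)
  }
  list(features = as.data.frame(do.call(rbind, rows)),
       labels = labels,
       af_proxy = af,
       meta = do.call(rbind, meta),
       transcripts = txs)
}

#' Planted feature directions of the synthetic cohort
#'
#' Expected sign of the pathogenic-minus-benign location shift for each
#' feature the generator tilts (+1 higher in pathogenic, -1 higher in
#' benign). For the `aa_*` entries the direction refers to composition
#' fractions (count / extension length): residue enrichment is a statement
#' about proportions, and raw counts confound enrichment with the longer
#' pathogenic extensions. Shipped with the generator so tests can assert
#' that the planted structure matches the direction reported for the
#' curated cohorts.
#'
#' @return Named numeric vector of +1/-1.
#' @export
planted_direction <- function() {
  c(cadd = 1, gerp = 1, phylop100 = 1, phastcons100 = 1,
    utr3_len = 1, utr3_gc = 1, mrna_stability_z = 1,
    pli = 1, loeuf = -1, s_het = 1,
    ext_len = 1,
    aa_A = 1, aa_C = 1, aa_L = 1, aa_P = 1,
    aa_E = -1, aa_K = -1, aa_S = -1, aa_Y = -1,
    kd_mean = 1, mj_mean = 1, tango_max = 1, canya = 1, idp_flag = 1)
}
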