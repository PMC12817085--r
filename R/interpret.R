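#' Construct a known-variant database
#'
#' A table of previously classified stop-loss variants used for
#' same-extension evidence matching: PS1 requires a pathogenic record with
#' byte-identical substituted residue and extension peptide; PM5 requires a
#' byte-identical extension peptide with a different substituted residue.
#'
#' @param df Data frame with columns `transcript_id`, `substituted_aa`
#'   (one-letter), `peptide` (extension, may be `""`), `classification`
#'   (one of P, LP, B, LB, VUS). Duplicate `(transcript_id, substituted_aa)`
#'   pairs with conflicting classifications are rejected.
#' @return The validated data frame, class `"known_variant_db"`.
#' @export
known_variant_db <- function(df) {
  req <- c("transcript_id", "substituted_aa", "peptide", "classification")
  stopifnot(all(req %in% names(df)))
  if (!all(df$classification %in% c("P", "LP", "B", "LB", "VUS")))
    stop("classification must be one of P/LP/B/LB/VUS", call. = FALSE)
  key <- paste(df$transcript_id, df$substituted_aa)
  conflict <- tapply(df$classification, key,
                     function(cl) length(unique(cl)) > 1L)
  if (any(conflict))
    stop("conflicting classifications for: ",
         paste(names(conflict)[conflict], collapse = "; "), call. = FALSE)
  structure(df, class = c("known_variant_db", "data.frame"))
}

#' Read / write a known-variant database TSV
#' @param path TSV with columns `transcript_id`, `substituted_aa`,
#'   `peptide`, `classification` (and optionally `hgvs_p`).
#' @return A `known_variant_db`.
#' @export
read_known_db_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  df$peptide[is.na(df$peptide)] <- ""
  known_variant_db(df)
}

#' @rdname read_known_db_tsv
#' @param db A `known_variant_db`.
#' @export
write_known_db_tsv <- function(db, path) {
  write_tsv(as.data.frame(db), path)
  invisible(path)
}

#' Assign ACMG/AMP-style evidence codes to a stop-loss variant
#'
#' Implements the interpretation flowchart. A variant with no downstream
#' in-frame stop codon (NSD) qualifies for PVS1 and the flowchart
#' terminates. Otherwise the C-terminal extension is matched against the
#' known-variant database: an identical protein consequence (same
#' substituted residue and extension peptide) carried by a P/LP record
#' gives PS1; an identical extension peptide with a different residue at
#' the original stop position gives PM5; with no match the variant falls
#' back to PM4 (protein length change). Independently of the match branch,
#' a classifier score >= 0.7 adds PP3 as supporting computational
#' evidence. When the gene is marked autosomal recessive, the PP3
#' rationale carries a caution that computational evidence should be
#' applied in a context-dependent manner.
#'
#' @param ext An `extension_result` for the query variant.
#' @param score Classifier score in `[0, 1]`, or `NA` when unscored.
#' @param db A `known_variant_db` (may have zero rows).
#' @param transcript_id Transcript of the query variant.
#' @param recessive Optional flag: gene is autosomal recessive
#'   (pass-through annotation; adds a caution to PP3).
#' @return A list of class `"evidence_assignment"`: `codes` (character
#'   vector) and `rationale` (named character vector, one entry per code).
#' @export
assign_evidence <- function(ext, score, db, transcript_id,
                            recessive = FALSE) {
  stopifnot(inherits(ext, "extension_result"))
  if (!is.na(score) && (score < 0 || score > 1))
    stop("score must lie in [0, 1]", call. = FALSE)
  codes <- character(0)
  rationale <- character(0)
  if (isTRUE(ext$nsd)) {
    codes <- "PVS1"
    rationale <- c(PVS1 = paste(
      "no downstream in-frame stop codon in the 3' UTR: nonstop decay is",
      "expected to degrade the transcript"))
    return(structure(list(codes = codes, rationale = rationale),
                     class = "evidence_assignment"))
  }
  hits <- db[db$transcript_id == transcript_id &
               db$classification %in% c("P", "LP") &
               db$peptide == ext$peptide, , drop = FALSE]
  if (nrow(hits) && any(hits$substituted_aa == ext$substituted_aa)) {
    codes <- c(codes, "PS1")
    rationale <- c(rationale, PS1 = paste(
      "C-terminal extension (including the residue substituted at the",
      "original stop codon) is identical to that of an established",
      "pathogenic variant"))
  } else if (nrow(hits)) {
    codes <- c(codes, "PM5")
    rationale <- c(rationale, PM5 = paste(
      "C-terminal extension is identical to that of an established",
      "pathogenic variant except for the amino acid at the stop codon"))
  } else {
    codes <- c(codes, "PM4")
    rationale <- c(rationale, PM4 = "protein length change (stop-loss)")
  }
  if (!is.na(score) && score >= 0.7) {
    codes <- c(codes, "PP3")
    msg <- sprintf("classifier score %.3f >= 0.7: supporting computational evidence",
                   score)
    if (isTRUE(recessive))
      msg <- paste(msg, "| caution: gene is autosomal recessive;",
                   "apply computational evidence in a context-dependent manner")
    rationale <- c(rationale, PP3 = msg)
  }
  structure(list(codes = codes, rationale = rationale),
            class = "evidence_assignment")
}

#' @export
print.evidence_assignment <- function(x, ...) {
  cat("<evidence:", paste(x$codes, collapse = ", "), ">\n")
  for (code in x$codes) cat(sprintf("  %s: %s\n", code, x$rationale[[code]]))
  invisible(x)
}

#' Benign/likely-benign labeling by population frequency
#'
#' A stop-loss variant is labeled B/LB when its maximum population allele
#' frequency exceeds 0.1% or it has been observed in the homozygous state.
#'
#' @param af_max Maximum population allele frequency in `[0, 1]`.
#' @param n_hom Number of homozygous observations (>= 0).
#' @return `TRUE` iff the B/LB rule applies.
#' @export
label_by_frequency <- function(af_max, n_hom = 0L) {
  stopifnot(af_max >= 0, af_max <= 1, n_hom >= 0)
  af_max > 0.001 | n_hom >= 1
}
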