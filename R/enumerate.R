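BASES <- c("A", "C", "G", "T")

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

# Skeleton rows (one per variant, vectorized); extension columns are filled
# by annotate_extensions().
variant_rows <- function(t, kind, position, ref, alt) {
  k <- max(length(position), length(ref), length(alt))
  data.frame(transcript_id = rep(t$id, k), kind = rep(kind, k),
             position = position, ref = ref, alt = alt,
             mutant_codon = NA_character_,
             consequence = NA_character_, new_aa = NA_character_,
             ext_len = NA_integer_, new_stop = NA_character_,
             nsd = NA, frame_offset = NA_integer_,
             hgvs_c = NA_character_, hgvs_p = NA_character_,
             stringsAsFactors = FALSE)
}

# Mutant reading context: the edited stop-codon region concatenated with the
# 3' UTR. The first complete codon of this string is what the ribosome reads
# at the original termination position.
mutant_region <- function(stop_codon, kind, position, alt) {
  s <- strsplit(stop_codon, "")[[1]]
  switch(kind,
    substitution = {
      s[position] <- alt
      paste(s, collapse = "")
    },
    insertion = {
      # position here is the insertion point: 0 = before nt1,
      # 1 = between nt1 and nt2, 2 = between nt2 and nt3.
      paste(c(s[seq_len(position)], alt, s[setdiff(1:3, seq_len(position))]),
            collapse = "")
    },
    deletion = paste(s[-position], collapse = ""),
    stop("unknown variant kind: ", kind))
}

#' Enumerate all single-nucleotide substitutions at a stop codon
#'
#' Each of the three stop-codon positions admits three substitutions, giving
#' exactly nine variants. A variant whose mutated codon is still TAA/TAG/TGA
#' is `stop_retained`; otherwise it is a stop-loss variant and the mutated
#' codon encodes the residue substituted at the original termination
#' position. Extension columns (`ext_len`, `new_stop`, `nsd`, and the
#' refinement of `stop_loss` to `stop_loss_nsd`) are filled by scanning the
#' 3' UTR.
#'
#' @param t A validated `transcript`.
#' @return A 9-row data frame of classified variants.
#' @examples
#' tx <- transcript("tx", "ATGTGA", "TTTTAA")
#' enumerate_snvs(tx)
#' @export
enumerate_snvs <- function(t) {
  validate_transcript(t)
  sc <- strsplit(stop_codon_of(t), "")[[1]]
  pos <- rep(1:3, each = 3L)
  ref <- sc[pos]
  alt <- unlist(lapply(1:3, function(p) setdiff(BASES, sc[p])),
                use.names = FALSE)
  annotate_extensions(t, variant_rows(t, "substitution", pos, ref, alt))
}

#' Enumerate all single-nucleotide insertions disrupting a stop codon
#'
#' Four bases at each of the three insertion points that change the codon
#' read at the stop position (before nt1, between nt1-nt2, between nt2-nt3)
#' give exactly twelve variants. Insertion after nt3 lies in the 3' UTR and
#' never alters the stop codon, so it is excluded. Classification
#' reconstructs the mutant reading: an insertion can resurrect a stop codon
#' using downstream bases (`stop_retained`), otherwise translation continues
#' in the +1-shifted frame.
#'
#' @inheritParams enumerate_snvs
#' @return A 12-row data frame of classified variants.
#' @export
enumerate_insertions <- function(t) {
  validate_transcript(t)
  annotate_extensions(t, variant_rows(t, "insertion",
                                      rep(0:2, each = 4L), "",
                                      rep(BASES, times = 3L)))
}

#' Enumerate all single-nucleotide deletions at a stop codon
#'
#' One deletion per stop-codon position gives exactly three variants.
#' Classification reads the first mutant codon from the two remaining stop
#' bases plus the first 3' UTR base; a resurrected stop is `stop_retained`,
#' otherwise translation continues in the -1-shifted frame. With an empty
#' 3' UTR no complete codon can be read and the variant is
#' `stop_loss_nsd` by construction.
#'
#' @inheritParams enumerate_snvs
#' @return A 3-row data frame of classified variants.
#' @export
enumerate_deletions <- function(t) {
  validate_transcript(t)
  sc <- strsplit(stop_codon_of(t), "")[[1]]
  annotate_extensions(t, variant_rows(t, "deletion", 1:3, sc, ""))
}

#' Enumerate every possible stop-codon variant of a transcript
#'
#' Convenience wrapper combining the 9 substitutions, 12 insertions and 3
#' deletions (24 variants total).
#'
#' @inheritParams enumerate_snvs
#' @return A 24-row data frame.
#' @export
enumerate_stop_variants <- function(t) {
  rbind(enumerate_snvs(t), enumerate_insertions(t), enumerate_deletions(t))
}

#' Classify an insertion or deletion at the stop codon
#'
#' Reconstructs the mutant sequence from the first base of the stop codon
#' through the 3' UTR and reads its first complete codon: a stop codon means
#' the allele is `stop_retained`; otherwise translation continues into the
#' shifted frame and the variant is stop-loss.
#'
#' @param stop_codon The original stop codon (TAA/TAG/TGA).
#' @param kind `"insertion"` or `"deletion"`.
#' @param position Insertion point (0..2) or deleted position (1..3).
#' @param alt Inserted base (insertions) or `""` (deletions).
#' @param utr3 The 3' UTR sequence.
#' @return A list: `consequence`, `region` (edited stop-codon bases),
#'   `read` (region + UTR), `first_codon` (or `NA` when incomplete).
#' @export
classify_indel <- function(stop_codon, kind, position, alt, utr3) {
  region <- mutant_region(stop_codon, kind, position, alt)
  read <- paste0(region, toupper(utr3))
  if (nchar(read) < 3L) {
    return(list(consequence = "stop_loss_nsd", region = region, read = read,
                first_codon = NA_character_))
  }
  first <- substr(read, 1L, 3L)
  cons <- if (first %in% STOP_CODONS) "stop_retained" else "stop_loss"
  list(consequence = cons, region = region, read = read, first_codon = first)
}

# Fill consequence, extension and HGVS columns for enumerated variants.
annotate_extensions <- function(t, vars) {
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    region <- mutant_region(stop_codon_of(t), v$kind, v$position, v$alt)
    read <- paste0(region, t$utr3)
    if (nchar(read) < 3L) {
      vars$consequence[i] <- "stop_loss_nsd"
      vars$nsd[i] <- TRUE
      vars$frame_offset[i] <- frame_offset_of(v$kind)
    } else if (substr(read, 1L, 3L) %in% STOP_CODONS) {
      vars$consequence[i] <- "stop_retained"
      vars$mutant_codon[i] <- substr(read, 1L, 3L)
    } else {
      ext <- extension_from_read(read, frame_offset_of(v$kind))
      vars$mutant_codon[i] <- substr(read, 1L, 3L)
      vars$consequence[i] <- if (ext$nsd) "stop_loss_nsd" else "stop_loss"
      vars$new_aa[i] <- ext$substituted_aa
      vars$ext_len[i] <- ext$ext_len
      vars$new_stop[i] <- ext$new_stop
      vars$nsd[i] <- ext$nsd
      vars$frame_offset[i] <- ext$frame_offset
    }
    vars$hgvs_c[i] <- hgvs_c_of(t, vars[i, ])
    vars$hgvs_p[i] <- hgvs_p_of(t, vars[i, ])
  }
  vars
}

frame_offset_of <- function(kind) {
  switch(kind, substitution = 0L, insertion = 1L, deletion = -1L)
}

# Transcript-space HGVS coding notation; the stop codon occupies CDS
# positions L-2..L.
hgvs_c_of <- function(t, v) {
  L <- nchar(t$cds)
  base <- L - 3L
  switch(v$kind,
    substitution = sprintf("c.%d%s>%s", base + v$position, v$ref, v$alt),
    insertion = sprintf("c.%d_%dins%s", base + v$position,
                        base + v$position + 1L, v$alt),
    deletion = sprintf("c.%ddel", base + v$position))
}

# p.Ter{N}{Aa}extTer{M}: N is the stop's residue number (protein length + 1),
# M counts codons from the old stop position to the new one, i.e. extension
# length + 1 (the substituted residue occupies the old stop position).
hgvs_p_of <- function(t, v) {
  ter_n <- nchar(t$cds) %/% 3L
  if (v$consequence == "stop_retained") return(sprintf("p.Ter%d=", ter_n))
  aa3 <- if (is.na(v$new_aa)) "?" else AA_THREE[[v$new_aa]]
  if (isTRUE(v$nsd)) sprintf("p.Ter%d%sext?", ter_n, aa3)
  else sprintf("p.Ter%d%sextTer%d", ter_n, aa3, v$ext_len + 1L)
}

#' Write an enumerated-variant table to TSV
#' @param vars Data frame from the `enumerate_*` functions.
#' @param path Output path.
#' @export
write_variant_tsv <- function(vars, path) {
  write_tsv(vars, path)
  invisible(path)
}
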