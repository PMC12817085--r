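#' @importFrom stats median p.adjust fisher.test wilcox.test kmeans dnorm
#'   rbinom rnbinom rlnorm rbeta rnorm runif sd cor predict setNames quantile
#' @importFrom utils read.delim write.table head
#' @importFrom randomForest randomForest importance
NULL

# The three canonical termination codons of the standard nuclear genetic code.
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Codon -> one-letter amino acid ("*" for stop), standard nuclear code.
# Cached: the S4-backed lookup behind Biostrings::GENETIC_CODE is costly to
# touch in per-codon loops.
.stoplossr_cache <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(.stoplossr_cache$ct))
    .stoplossr_cache$ct <- Biostrings::GENETIC_CODE
  .stoplossr_cache$ct
}

#' Construct a transcript record
#'
#' A transcript is the minimal unit this package operates on: a coding
#' sequence (CDS) that includes its terminal stop codon, plus the 3' UTR
#' downstream of it. Sequences are transcript-space, 5'->3', sense strand.
#'
#' @param id Transcript identifier (non-empty string).
#' @param cds Coding sequence including the terminal stop codon; length must
#'   be a positive multiple of 3 and the final codon one of TAA/TAG/TGA.
#' @param utr3 3' UTR sequence; may be empty (such transcripts validate with
#'   a warning flag and are excluded from scoring).
#' @param gene_id Optional gene identifier.
#' @return An object of class `"transcript"`: a list with fields `id`,
#'   `cds`, `utr3`, `gene_id`.
#' @examples
#' tx <- transcript("tx1", "ATGAAATGA", "TTTTAAGG")
#' validate_transcript(tx)
#' @export
transcript <- function(id, cds, utr3 = "", gene_id = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  obj <- structure(
    list(id = id,
         cds = toupper(as.character(cds)),
         utr3 = toupper(as.character(utr3)),
         gene_id = gene_id),
    class = "transcript")
  obj
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s: CDS %d nt (stop %s), 3'UTR %d nt>\n",
              x$id, nchar(x$cds), stop_codon_of(x), nchar(x$utr3)))
  invisible(x)
}

#' Terminal stop codon of a transcript
#' @param t A `transcript`.
#' @return The last codon of the CDS as a 3-character string.
#' @export
stop_codon_of <- function(t) {
  n <- nchar(t$cds)
  substr(t$cds, n - 2L, n)
}

check_dna <- function(seq, what = "sequence", allow_empty = FALSE) {
  if (!allow_empty && !nzchar(seq))
    stop(what, " is empty", call. = FALSE)
  if (nzchar(seq) && grepl("[^ACGT]", seq))
    stop(what, " contains non-ACGT characters ",
         "(ambiguity codes are rejected)", call. = FALSE)
  invisible(seq)
}

#' Validate a transcript
#'
#' Enforces the structural invariants: the CDS has length a positive multiple
#' of three, ends in one of the three standard stop codons, contains no
#' internal in-frame stop codon, and both sequences use only A/C/G/T.
#' An empty 3' UTR is legal but flagged: every stop-loss variant on such a
#' transcript has no downstream sequence to terminate in, so it is excluded
#' from scoring (not from the data model).
#'
#' @param t A `transcript`.
#' @return `t`, invisibly unchanged, with attribute `empty_utr3` set to
#'   `TRUE`/`FALSE`.
#' @export
validate_transcript <- function(t) {
  stopifnot(inherits(t, "transcript"))
  check_dna(t$cds, sprintf("CDS of '%s'", t$id))
  check_dna(t$utr3, sprintf("3'UTR of '%s'", t$id), allow_empty = TRUE)
  n <- nchar(t$cds)
  if (n < 3L || n %% 3L != 0L)
    stop(sprintf("CDS of '%s' has length %d, not a positive multiple of 3",
                 t$id, n), call. = FALSE)
  if (!stop_codon_of(t) %in% STOP_CODONS)
    stop(sprintf("CDS of '%s' does not end in a stop codon (TAA/TAG/TGA)",
                 t$id), call. = FALSE)
  if (n > 3L) {
    body <- substr(t$cds, 1L, n - 3L)
    tr <- translate_dna(body)
    if (tr$stop_reached)
      stop(sprintf("CDS of '%s' contains an internal in-frame stop codon",
                   t$id), call. = FALSE)
  }
  attr(t, "empty_utr3") <- !nzchar(t$utr3)
  invisible(t)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  k <- n %/% 3L
  if (k == 0L) return(character(0))
  starts <- seq.int(1L, by = 3L, length.out = k)
  substring(seq, starts, starts + 2L)
}

#' Translate a DNA sequence with the standard genetic code
#'
#' Translates codon by codon, stopping at (and excluding) the first stop
#' codon encountered. A trailing partial codon (< 3 nt) is ignored for
#' translation but never counts as a stop.
#'
#' @param seq DNA string (A/C/G/T only; case-insensitive).
#' @return A list: `peptide` (one-letter string), `stop_reached` (logical),
#'   `stop_codon` (the terminating codon, or `NA`).
#' @examples
#' translate_dna("AAATTTTAG")  # "KF", stop reached
#' @export
translate_dna <- function(seq) {
  seq <- toupper(seq)
  check_dna(seq, "sequence", allow_empty = TRUE)
  codons <- split_codons(seq)
  if (length(codons) == 0L)
    return(list(peptide = "", stop_reached = FALSE, stop_codon = NA_character_))
  aas <- unname(codon_table()[codons])
  stop_idx <- which(aas == "*")
  if (length(stop_idx)) {
    i <- stop_idx[1L]
    list(peptide = paste(aas[seq_len(i - 1L)], collapse = ""),
         stop_reached = TRUE,
         stop_codon = codons[i])
  } else {
    list(peptide = paste(aas, collapse = ""),
         stop_reached = FALSE,
         stop_codon = NA_character_)
  }
}

#' Read transcripts from paired FASTA files
#'
#' Reads a CDS FASTA and a 3' UTR FASTA keyed by identical record ids.
#' Records present in only one file are dropped with a message reporting the
#' count. Each retained pair is validated.
#'
#' @param cds_fasta,utr3_fasta Paths to FASTA files.
#' @return A list of validated `transcript` objects.
#' @export
read_transcripts_fasta <- function(cds_fasta, utr3_fasta) {
  cds <- Biostrings::readDNAStringSet(cds_fasta)
  utr <- Biostrings::readDNAStringSet(utr3_fasta)
  ids_cds <- sub("\\s.*$", "", names(cds))
  ids_utr <- sub("\\s.*$", "", names(utr))
  common <- intersect(ids_cds, ids_utr)
  dropped <- length(union(ids_cds, ids_utr)) - length(common)
  if (dropped > 0L)
    message(dropped, " record id(s) present in only one FASTA were dropped")
  lapply(common, function(i) {
    validate_transcript(transcript(
      id = i,
      cds = as.character(cds[[match(i, ids_cds)]]),
      utr3 = as.character(utr[[match(i, ids_utr)]])))
  })
}

#' Read transcripts from a TSV table
#'
#' Expects columns `id`, `cds`, `utr3` and optionally `gene_id`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A list of validated `transcript` objects.
#' @export
read_transcripts_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  stopifnot(all(c("id", "cds", "utr3") %in% names(df)))
  if (!"gene_id" %in% names(df)) df$gene_id <- NA_character_
  df$utr3[is.na(df$utr3)] <- ""
  lapply(seq_len(nrow(df)), function(i) {
    validate_transcript(transcript(df$id[i], df$cds[i], df$utr3[i],
                                   df$gene_id[i]))
  })
}

#' Write transcripts to a TSV table
#' @param transcripts A list of `transcript` objects.
#' @param path Output path.
#' @export
write_transcripts_tsv <- function(transcripts, path) {
  df <- data.frame(
    id = vapply(transcripts, `[[`, "", "id"),
    cds = vapply(transcripts, `[[`, "", "cds"),
    utr3 = vapply(transcripts, `[[`, "", "utr3"),
    gene_id = vapply(transcripts, `[[`, "", "gene_id"),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}
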