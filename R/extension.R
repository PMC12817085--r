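#' Find the first in-frame stop codon in a sequence
#'
#' Scans complete codons of `seq` from its first base and returns the 0-based
#' codon index of the first TAA/TAG/TGA encountered. A trailing partial codon
#' (< 3 nt) can never terminate translation.
#'
#' @param seq DNA string scanned in frame 0 of its own first base. For
#'   shifted frames pass the frame-shifted suffix (as produced by
#'   [classify_indel()] or [frameshift_extension()]).
#' @return A list: `index` (0-based codon index of the first stop, or `NA`
#'   when none exists — the nonstop-decay case) and `stop_codon`.
#' @examples
#' scan_for_stop("AAATAGCC")$index  # 1
#' @export
scan_for_stop <- function(seq) {
  seq <- toupper(seq)
  check_dna(seq, "scanned sequence", allow_empty = TRUE)
  codons <- split_codons(seq)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit)) list(index = hit[1L] - 1L, stop_codon = codons[hit[1L]])
  else list(index = NA_integer_, stop_codon = NA_character_)
}

extension_result <- function(substituted_aa, peptide, ext_len, new_stop,
                             nsd, frame_offset) {
  structure(list(substituted_aa = substituted_aa, peptide = peptide,
                 ext_len = ext_len, new_stop = new_stop, nsd = nsd,
                 frame_offset = frame_offset),
            class = "extension_result")
}

#' @export
print.extension_result <- function(x, ...) {
  if (x$nsd)
    cat(sprintf("<extension: Ter>%s, no downstream stop (NSD), %d codon(s) read>\n",
                x$substituted_aa, x$ext_len))
  else
    cat(sprintf("<extension: Ter>%s + %d codon(s), new stop %s>\n",
                x$substituted_aa, x$ext_len, x$new_stop))
  invisible(x)
}

# Core reconstruction: `read` starts at the first base of the (edited) stop
# codon and runs through the 3' UTR. Its first codon is the substituted
# residue; the remainder is scanned for the next in-frame stop.
extension_from_read <- function(read, frame_offset) {
  stopifnot(nchar(read) >= 3L)
  first <- substr(read, 1L, 3L)
  if (first %in% STOP_CODONS)
    stop("stop_retained allele: nothing to extend", call. = FALSE)
  sub_aa <- codon_table()[[first]]
  tail_seq <- substr(read, 4L, nchar(read))
  tr <- translate_dna(tail_seq)
  extension_result(
    substituted_aa = sub_aa,
    peptide = tr$peptide,
    ext_len = nchar(tr$peptide),
    new_stop = tr$stop_codon,
    nsd = !tr$stop_reached,
    frame_offset = frame_offset)
}

#' Compute the C-terminal extension produced by a stop-loss variant
#'
#' Reconstructs the mutant reading context (edited stop-codon bases followed
#' by the 3' UTR), takes its first codon as the residue substituted at the
#' original termination position, translates until the nearest downstream
#' in-frame stop codon, and flags nonstop decay (NSD) when no stop exists.
#' `ext_len` counts codons translated from the UTR strictly before the new
#' stop; the substituted residue is reported separately.
#'
#' @param t A validated `transcript`.
#' @param v A single variant row as produced by the `enumerate_*` functions
#'   (or a list with fields `kind`, `position`, `alt`, `consequence`).
#' @return An `extension_result`.
#' @examples
#' tx <- transcript("tx", "ATGTGA", "TTTTAA")
#' v <- enumerate_snvs(tx)
#' extension_for_variant(tx, v[v$mutant_codon == "TGG", ])
#' @export
extension_for_variant <- function(t, v) {
  validate_transcript(t)
  if (is.data.frame(v)) {
    stopifnot(nrow(v) == 1L)
    v <- as.list(v)
  }
  if (identical(v$consequence, "stop_retained"))
    stop("stop_retained variant: nothing to extend", call. = FALSE)
  region <- mutant_region(stop_codon_of(t), v$kind, v$position, v$alt)
  read <- paste0(region, t$utr3)
  if (nchar(read) < 3L) {
    return(extension_result(NA_character_, "", 0L, NA_character_, TRUE,
                            frame_offset_of(v$kind)))
  }
  extension_from_read(read, frame_offset_of(v$kind))
}

#' Frameshifted 3' UTR scan from the stop codon
#'
#' Cohort-level helper for comparing extension-length distributions across
#' reading frames. A +1 shift reads one base earlier relative to the UTR
#' (the last stop-codon base is prepended, as after a single-base
#' insertion); a -1 shift starts at the second UTR base (as after a
#' single-base deletion). Frame 0 is the ordinary [scan_for_stop()] on the
#' UTR itself and is rejected here.
#'
#' @param t A validated `transcript`.
#' @param shift `+1` or `-1`.
#' @return An `extension_result` (no substituted residue: this models the
#'   downstream scan only, so `substituted_aa` is `NA`).
#' @export
frameshift_extension <- function(t, shift) {
  validate_transcript(t)
  if (!shift %in% c(1L, -1L))
    stop("shift must be +1 or -1; use scan_for_stop() for frame 0",
         call. = FALSE)
  scanned <- if (shift == 1L) {
    sc <- stop_codon_of(t)
    paste0(substr(sc, 3L, 3L), t$utr3)
  } else {
    substr(t$utr3, 2L, nchar(t$utr3))
  }
  tr <- translate_dna(scanned)
  extension_result(
    substituted_aa = NA_character_,
    peptide = tr$peptide,
    ext_len = nchar(tr$peptide),
    new_stop = tr$stop_codon,
    nsd = !tr$stop_reached,
    frame_offset = as.integer(shift))
}
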