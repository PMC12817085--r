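AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte & Doolittle (1982) J Mol Biol 157:105-132. Hydropathy index;
# Ile = +4.5, Arg = -4.5 span the scale.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
              L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Miyazawa & Jernigan (1985) Macromolecules 18:534-552. Effective
# inter-residue contact-energy hydrophobicity, as tabulated by the R
# peptide-analysis ecosystem ("Miyazawa" scale in the Peptides package).
MJ_SCALE <- c(A = 5.33, R = 4.18, N = 3.71, D = 3.59, C = 7.93,
              Q = 3.87, E = 3.65, G = 4.48, H = 5.10, I = 8.83,
              L = 8.47, K = 2.95, M = 8.95, F = 9.03, P = 3.87,
              S = 4.09, T = 4.49, W = 7.66, Y = 5.89, V = 7.63)

#' Hydrophobicity scales
#'
#' Returns the per-residue hydrophobicity table for the Kyte-Doolittle
#' (`"KD"`) or Miyazawa-Jernigan (`"MJ"`) scale, as a named numeric vector
#' over the 20 standard amino acids.
#'
#' @param name `"KD"` or `"MJ"`.
#' @return Named numeric vector of length 20.
#' @export
hydrophobicity_scale <- function(name = c("KD", "MJ")) {
  switch(match.arg(name), KD = KD_SCALE, MJ = MJ_SCALE)
}

#' GC content of a DNA sequence
#' @param seq Non-empty DNA string.
#' @return Percentage of G+C bases, in `[0, 100]`.
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  check_dna(seq, "sequence")
  b <- strsplit(seq, "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

#' Amino-acid composition of a peptide
#' @param peptide One-letter peptide string over the 20 standard residues
#'   (may be empty).
#' @return Named integer vector of length 20 (order A R N D C Q E G H I L K
#'   M F P S T W Y V); counts sum to `nchar(peptide)`.
#' @export
aa_counts <- function(peptide) {
  counts <- setNames(integer(20L), AA_ALPHABET)
  if (!nzchar(peptide)) return(counts)
  aas <- strsplit(toupper(peptide), "")[[1]]
  bad <- setdiff(aas, AA_ALPHABET)
  if (length(bad))
    stop("unknown amino-acid letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  tab <- table(factor(aas, levels = AA_ALPHABET))
  counts[] <- as.integer(tab)
  counts
}

#' Mean per-residue hydrophobicity of a peptide
#'
#' Arithmetic mean of the scale values over the residues. An empty peptide
#' has no defined mean and returns `NA` (median-imputed downstream).
#'
#' @param peptide One-letter peptide string.
#' @param scale `"KD"` or `"MJ"`.
#' @return A real, or `NA_real_` for the empty peptide.
#' @export
mean_hydrophobicity <- function(peptide, scale = c("KD", "MJ")) {
  if (!nzchar(peptide)) return(NA_real_)
  tab <- hydrophobicity_scale(scale)
  aas <- strsplit(toupper(peptide), "")[[1]]
  bad <- setdiff(aas, AA_ALPHABET)
  if (length(bad))
    stop("unknown amino-acid letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  mean(tab[aas])
}

#' The fixed 37-feature registry
#'
#' Order and names of the model's input vector: four variant-level
#' annotation scores, six transcript-level properties, and 27 peptide-level
#' properties of the C-terminal extension (protein length, extension
#' length, 20 amino-acid counts, KD/MJ mean hydrophobicity, TANGO maximum,
#' CANYA score, intrinsically-disordered-protein flag).
#'
#' @return Character vector of length 37.
#' @export
feature_registry <- function() {
  c("cadd", "gerp", "phylop100", "phastcons100",
    "utr3_len", "utr3_gc", "mrna_stability_z", "pli", "loeuf", "s_het",
    "protein_len", "ext_len",
    paste0("aa_", AA_ALPHABET),
    "kd_mean", "mj_mean", "tango_max", "canya", "idp_flag")
}

# Columns supplied by external annotation sources (pass-through, may be NA).
ANNOTATION_COLS <- c("cadd", "gerp", "phylop100", "phastcons100",
                     "mrna_stability_z", "pli", "loeuf", "s_het",
                     "tango_max", "canya", "idp_flag")

#' Construct an annotation record
#'
#' External per-variant and per-gene scores enter the pipeline as
#' pass-through columns; none are computed here. Missing scores stay `NA`
#' until median imputation at training/prediction time. `tango_profile`, if
#' given, is a per-residue TANGO score vector reduced to its maximum.
#'
#' @param cadd,gerp,phylop100,phastcons100 Variant-level scores.
#' @param mrna_stability_z mRNA-stability Z-score.
#' @param pli pLI in `[0, 1]`.
#' @param loeuf LOEUF (> 0).
#' @param s_het Heterozygous selection coefficient (> 0).
#' @param tango_max Maximum per-residue TANGO aggregation score.
#' @param canya CANYA aggregation score.
#' @param idp_flag 0/1 DisProt intrinsically-disordered-protein flag.
#' @param tango_profile Optional per-residue TANGO profile; overrides
#'   `tango_max` with its maximum.
#' @return A named list of class `"annotation_record"`.
#' @export
annotation_record <- function(cadd = NA_real_, gerp = NA_real_,
                              phylop100 = NA_real_, phastcons100 = NA_real_,
                              mrna_stability_z = NA_real_, pli = NA_real_,
                              loeuf = NA_real_, s_het = NA_real_,
                              tango_max = NA_real_, canya = NA_real_,
                              idp_flag = NA_real_, tango_profile = NULL) {
  if (!is.na(pli) && (pli < 0 || pli > 1))
    stop("pli must lie in [0, 1]", call. = FALSE)
  if (!is.na(idp_flag) && !idp_flag %in% c(0, 1))
    stop("idp_flag must be 0 or 1", call. = FALSE)
  if (!is.null(tango_profile)) tango_max <- max(tango_profile)
  structure(list(cadd = cadd, gerp = gerp, phylop100 = phylop100,
                 phastcons100 = phastcons100,
                 mrna_stability_z = mrna_stability_z, pli = pli,
                 loeuf = loeuf, s_het = s_het, tango_max = tango_max,
                 canya = canya, idp_flag = idp_flag),
            class = "annotation_record")
}

#' Assemble the 37-dimensional feature vector for a stop-loss variant
#'
#' Combines the transcript (3' UTR length and GC, original protein length),
#' the computed C-terminal extension (length, amino-acid composition, mean
#' KD/MJ hydrophobicity), and the pass-through annotation record into the
#' fixed-order model input. Variants with no downstream in-frame stop codon
#' (NSD) are not scored by the classifier; use the evidence-assignment
#' module for those (PVS1 path).
#'
#' @param t A validated `transcript`.
#' @param ext An `extension_result` with `nsd = FALSE`.
#' @param ann An `annotation_record` (defaults to all-missing).
#' @return Named numeric vector of length 37 in registry order; unavailable
#'   annotations are `NA`.
#' @export
assemble_features <- function(t, ext, ann = annotation_record()) {
  validate_transcript(t)
  stopifnot(inherits(ext, "extension_result"))
  if (isTRUE(ext$nsd))
    stop("NSD variant: not scored; assign evidence via assign_evidence() ",
         "(PVS1 path)", call. = FALSE)
  if (!nzchar(t$utr3))
    stop("transcript has an empty 3' UTR and is excluded from scoring",
         call. = FALSE)
  counts <- aa_counts(ext$peptide)
  x <- c(ann$cadd, ann$gerp, ann$phylop100, ann$phastcons100,
         nchar(t$utr3), gc_content(t$utr3), ann$mrna_stability_z,
         ann$pli, ann$loeuf, ann$s_het,
         nchar(t$cds) / 3 - 1, ext$ext_len,
         as.numeric(counts),
         mean_hydrophobicity(ext$peptide, "KD"),
         mean_hydrophobicity(ext$peptide, "MJ"),
         ann$tango_max, ann$canya, ann$idp_flag)
  setNames(x, feature_registry())
}

#' Median imputation fitted on training rows only
#'
#' Computes per-column medians on `fit_rows` and substitutes them for every
#' `NA` in the full table, so that prediction-time rows never influence the
#' imputation values (no leakage).
#'
#' @param x Data frame or matrix of features (numeric columns).
#' @param fit_rows Row indices used to compute the medians (default: all).
#' @return A list: `imputed` (same shape as `x`) and `medians` (named
#'   vector, reusable at prediction time via [apply_medians()]).
#' @export
impute_median <- function(x, fit_rows = seq_len(nrow(x))) {
  x <- as.data.frame(x)
  stopifnot(length(fit_rows) > 0L)
  medians <- vapply(x, function(col) median(col[fit_rows], na.rm = TRUE),
                    numeric(1))
  if (anyNA(medians)) {
    stop("column(s) entirely missing in the fitting rows: ",
         paste(names(medians)[is.na(medians)], collapse = ", "),
         call. = FALSE)
  }
  list(imputed = apply_medians(x, medians), medians = medians)
}

#' Apply stored imputation medians to a feature table
#' @param x Data frame of features.
#' @param medians Named vector from [impute_median()].
#' @return `x` with every `NA` replaced by the stored column median.
#' @export
apply_medians <- function(x, medians) {
  x <- as.data.frame(x)
  for (nm in names(medians)) {
    miss <- is.na(x[[nm]])
    if (any(miss)) x[[nm]][miss] <- medians[[nm]]
  }
  x
}

#' Read an annotation TSV into annotation records
#'
#' One row per variant (or gene); columns matching [annotation_record()]
#' argument names are used, unknown columns are ignored with a warning.
#' Missing values are `"."` or empty.
#'
#' @param path Path to a tab-separated file with a header.
#' @return Data frame with one recognized column per annotation field.
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c(".", "NA", ""))
  known <- c("variant_id", "transcript_id", "gene_id", ANNOTATION_COLS)
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    warning("ignoring unknown annotation column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  df[intersect(known, names(df))]
}

#' Write a feature matrix to TSV
#' @param x Data frame whose feature columns follow [feature_registry()].
#' @param path Output path.
#' @export
write_features_tsv <- function(x, path) {
  write_tsv(x, path)
  invisible(path)
}

#' Read a feature matrix from TSV
#' @param path Path written by [write_features_tsv()].
#' @return Data frame.
#' @export
read_features_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
}
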