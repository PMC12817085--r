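# Canonical tabular dialect: tab-separated, header row, "." for missing.
write_tsv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.numeric(col)) col <- format(col, digits = 15, trim = TRUE,
                                       scientific = FALSE)
    col <- as.character(col)
    col[is.na(out[[nm]]) | col == "NA"] <- "."
    out[[nm]] <- col
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a minimal substitution-only VCF
#'
#' Supports the pre-computed-database workflow for substitution input in
#' transcript space: CHROM is ignored; the ID column must carry
#' `transcript_id:offset` where `offset` (1..3) is the position within the
#' stop codon. Only single-base REF/ALT records are accepted.
#'
#' @param path Path to an uncompressed VCF file.
#' @return Data frame: `transcript_id`, `position`, `ref`, `alt`.
#' @export
read_stop_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(transcript_id = character(0), position = integer(0),
                      ref = character(0), alt = character(0)))
  fields <- strsplit(lines, "\t")
  bad <- which(vapply(fields, length, 0L) < 5L)
  if (length(bad))
    stop("malformed VCF record at data line ", bad[1L], call. = FALSE)
  ids <- vapply(fields, `[[`, "", 3L)
  parts <- strsplit(ids, ":", fixed = TRUE)
  badid <- which(vapply(parts, length, 0L) != 2L)
  if (length(badid))
    stop("VCF ID column must be 'transcript_id:offset' (line ", badid[1L],
         ")", call. = FALSE)
  ref <- toupper(vapply(fields, `[[`, "", 4L))
  alt <- toupper(vapply(fields, `[[`, "", 5L))
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("only single-base substitutions are supported", call. = FALSE)
  data.frame(
    transcript_id = vapply(parts, `[[`, "", 1L),
    position = as.integer(vapply(parts, `[[`, "", 2L)),
    ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' JSON record of a pipeline invocation (subcommand, parameters, seed,
#' input/output paths, package version) sufficient to reproduce the output.
#'
#' @param path Output path.
#' @param subcommand Name of the operation.
#' @param params Named list of parameters (must include `seed` when the
#'   operation is stochastic).
#' @export
write_run_manifest <- function(path, subcommand, params) {
  jsonlite::write_json(list(
    tool = "stoplossr",
    version = as.character(utils::packageVersion("stoplossr")),
    subcommand = subcommand,
    params = params,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
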