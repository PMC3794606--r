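#' Read a FASTA file of DNA sequences
#'
#' Order-preserving, tolerant of line wrapping and CRLF; sequences are
#' uppercased. Duplicate record names and non-IUPAC characters are rejected
#' with messages naming the offending record (and offset).
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))   # record id = first header token
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate record name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(x))
  for (i in seq_along(seqs)) {
    .checkDNA(seqs[i], allowed = .IUPAC_LETTERS,
              what = paste0("record '", nm[i], "'"))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Write DNA sequences to FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# Shared TSV reader: header required, '#'-prefixed metadata lines captured,
# schema (column names and types) validated with row-level error messages.
.readTSV <- function(path, required, numericCols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  metaLines <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) stop("empty table: ", path, call. = FALSE)
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in numericCols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop("non-numeric value '", df[[col]][bad[1]], "' in column '", col,
           "' at data row ", bad[1], " of ", path, call. = FALSE)
    df[[col]] <- v
  }
  meta <- list()
  kv <- regmatches(metaLines,
                   regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", metaLines))
  for (m in kv) if (length(m) == 3L) {
    val <- suppressWarnings(as.numeric(m[3]))
    meta[[m[2]]] <- if (is.na(val)) m[3] else val
  }
  attr(df, "metadata") <- meta
  df
}

#' Read an RE table
#'
#' TSV with header `name  sequence  spacer  provenance`.
#'
#' @param path TSV path.
#' @return data.frame (metadata lines, if any, in the `"metadata"`
#'   attribute).
#' @export
readRETable <- function(path) {
  df <- .readTSV(path, c("name", "sequence", "spacer", "provenance"),
                 numericCols = "spacer")
  df$sequence <- toupper(df$sequence)
  df
}

#' Read a replicate-level transactivation activity table
#'
#' TSV with header `re_name allele replicate activity normalizer background`.
#'
#' @param path TSV path.
#' @return data.frame suitable for [classifyActivities()].
#' @export
readActivityTable <- function(path) {
  .readTSV(path,
           c("re_name", "allele", "replicate", "activity", "normalizer",
             "background"),
           numericCols = c("replicate", "activity", "normalizer",
                           "background"))
}

#' Read a titration curve table
#'
#' TSV with header `concentration_nM response replicate`; leading
#' `# key=value` lines (e.g. `# dna_conc_nM=50`) are captured in the
#' `"metadata"` attribute.
#'
#' @param path TSV path.
#' @return data.frame with the metadata attribute.
#' @export
readCurveTable <- function(path) {
  .readTSV(path, c("concentration_nM", "response", "replicate"),
           numericCols = c("concentration_nM", "response", "replicate"))
}

#' Write assembled sites as BED6
#'
#' 0-based half-open coordinates per the BED standard; the score column
#' carries the mismatch count and the name column
#' `architecture` (or `siteSeq` for unnamed ranges).
#'
#' @param sites `GRanges` from [assembleSites()] or [scanSites()].
#' @param path output path (or `""` for stdout).
#' @export
writeBED <- function(sites, path = "") {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = GenomicRanges::start(sites) - 1L,
    end = GenomicRanges::end(sites),
    name = if (!is.null(sites$architecture)) sites$architecture
           else sites$decamer,
    score = sites$mismatches,
    strand = as.character(GenomicRanges::strand(sites)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a site report as JSON
#'
#' One object per site with architecture, coordinates, spacer and
#' spacer-removed sequence.
#'
#' @param sites `GRanges` of assembled sites.
#' @param path output path.
#' @export
writeSitesJSON <- function(sites, path) {
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(sites)),
    start = GenomicRanges::start(sites),
    end = GenomicRanges::end(sites),
    strand = as.character(GenomicRanges::strand(sites)),
    architecture = sites$architecture,
    spacer = sites$spacer,
    siteSeq = sites$siteSeq,
    re20 = sites$re20,
    mismatches = sites$mismatches)
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
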