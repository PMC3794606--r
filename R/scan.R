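#' Count mismatches of a decamer against an IUPAC pattern
#'
#' A base mismatches when it does not belong to the IUPAC class at its
#' position; 0 means full consensus conformance.
#'
#' @param decamer DNA string over ACGT, same length as `pattern`.
#' @param pattern IUPAC pattern string (e.g. `"RRRCWWGYYY"`).
#' @return Integer mismatch count.
#' @examples
#' mismatchCount("GGGCATGCCC", "RRRCWWGYYY")  # 0
#' mismatchCount("CCCCATGCCC", "RRRCWWGYYY")  # 3
#' @export
mismatchCount <- function(decamer, pattern) {
  decamer <- toupper(decamer)
  pattern <- toupper(pattern)
  if (nchar(decamer) != nchar(pattern))
    stop("decamer and pattern lengths differ (", nchar(decamer), " vs ",
         nchar(pattern), ")", call. = FALSE)
  .checkDNA(decamer, what = "decamer")
  .checkDNA(pattern, allowed = .IUPAC_LETTERS, what = "pattern")
  .windowMismatches(strsplit(decamer, "")[[1]], pattern)
}

#' Reverse complement of a DNA string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()]; the empty string maps to itself.
#'
#' @param seq character vector of DNA strings over ACGTN.
#' @return Reverse-complemented character vector.
#' @examples
#' revComp("GAACA")       # "TGTTC"
#' revComp("GGGCATGCCC")  # palindrome
#' @export
revComp <- function(seq) {
  seq <- toupper(seq)
  vapply(seq, function(s) {
    if (!nzchar(s)) return("")
    .checkDNA(s, allowed = c("A", "C", "G", "T", "N"))
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Scan a sequence for consensus half-sites on both strands
#'
#' Slides a 10-nt window over every position of both strands and reports
#' windows with at most `maxMismatches` mismatches against the half-site
#' pattern. N in the scanned sequence counts as a mismatch. Coordinates are
#' 1-based inclusive on the forward strand; the `decamer` column is the site
#' as read 5'->3' on its own strand.
#'
#' @param sequence a single DNA string (character or
#'   [Biostrings::DNAString]) over ACGTN.
#' @param model a [ConsensusModel-class].
#' @param seqname sequence name used in the result.
#' @param dedupe collapse palindromic duplicates (same window, minus-strand
#'   decamer identical to the plus-strand one) to the plus strand.
#' @return A [GenomicRanges::GRanges] with metadata columns `decamer` and
#'   `mismatches`, sorted by start then strand (+ before -). Sequences
#'   shorter than 10 nt give an empty result.
#' @examples
#' scanHalfSites("GGGCATGCCCGGGCATGCCC")
#' @export
scanHalfSites <- function(sequence, model = consensusModel(),
                          seqname = "seq", dedupe = FALSE) {
  stopifnot(is(model, "ConsensusModel"))
  seq <- toupper(as.character(sequence))
  if (length(seq) != 1L)
    stop("scanHalfSites expects a single sequence", call. = FALSE)
  .checkDNA(seq, allowed = c("A", "C", "G", "T", "N"))
  L <- nchar(seq)
  k <- nchar(model@halfSitePattern)
  empty <- GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges(),
    strand = character(0), decamer = character(0), mismatches = integer(0))
  if (L < k) return(empty)

  chars <- strsplit(seq, "")[[1]]
  rcchars <- rev(unname(.COMPLEMENT[chars]))

  mmP <- .windowMismatches(chars, model@halfSitePattern)
  mmM <- .windowMismatches(rcchars, model@halfSitePattern)
  nw <- L - k + 1L

  hitP <- which(mmP <= model@maxMismatches)
  hitM <- which(mmM <= model@maxMismatches)
  # rc window i starts at forward position L - k + 2 - i
  startM <- L - k + 2L - hitM

  starts <- c(hitP, startM)
  if (!length(starts)) return(empty)
  strands <- rep(c("+", "-"), c(length(hitP), length(hitM)))
  mism <- c(mmP[hitP], mmM[hitM])
  dec <- character(length(starts))
  if (length(hitP))
    dec[seq_along(hitP)] <- substring(seq, hitP, hitP + k - 1L)
  if (length(hitM))
    dec[length(hitP) + seq_along(hitM)] <-
      substring(paste(rcchars, collapse = ""), hitM, hitM + k - 1L)

  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = starts, width = k),
    strand = strands, decamer = dec, mismatches = mism)
  ord <- order(GenomicRanges::start(gr),
               as.integer(GenomicRanges::strand(gr)))
  gr <- gr[ord]
  if (dedupe && length(gr)) {
    minus <- as.character(GenomicRanges::strand(gr)) == "-"
    key <- paste(GenomicRanges::start(gr), gr$decamer)
    dup <- minus & key %in% key[!minus]
    gr <- gr[!dup]
  }
  gr
}

#' Assemble half-site matches into full, three-quarter and half sites
#'
#' Every same-strand pair of half-sites separated by a spacer of 0 to
#' `maxSpacer` nt becomes a full site carrying its spacer-removed 20-mer
#' (`re20`). Half-sites in no full site are reported alone; when such a
#' half-site has an immediately adjacent (spacer 0) consensus-conforming
#' quarter (pentamer matching `RRRCW` 3' of it or `WGYYY` 5' of it, in the
#' half-site's own orientation), it is promoted to a three-quarter site.
#' Overlapping assemblies are all reported; full sites are ordered
#' smallest-spacer-first, then leftmost.
#'
#' @param halfSites a `GRanges` from [scanHalfSites()] over `sequence`.
#' @param sequence the scanned sequence (single DNA string).
#' @param model the [ConsensusModel-class] used for scanning.
#' @return A `GRanges` with metadata columns `architecture` (`full`,
#'   `three_quarter`, `half`), `spacer`, `siteSeq` (spacer-removed site as
#'   read on its strand), `re20` (20-mer, full sites only) and `mismatches`.
#' @examples
#' hs <- scanHalfSites("GAACATGTTCGAACATGTTC")
#' assembleSites(hs[GenomicRanges::strand(hs) == "+"],
#'               "GAACATGTTCGAACATGTTC")
#' @export
assembleSites <- function(halfSites, sequence, model = consensusModel()) {
  stopifnot(is(model, "ConsensusModel"))
  seq <- toupper(as.character(sequence))
  k <- nchar(model@halfSitePattern)
  out <- list()
  n <- length(halfSites)
  emptyRes <- GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges(),
    strand = character(0), architecture = character(0), spacer = integer(0),
    siteSeq = character(0), re20 = character(0), mismatches = integer(0))
  if (n == 0L) return(emptyRes)

  st <- GenomicRanges::start(halfSites)
  en <- GenomicRanges::end(halfSites)
  strnd <- as.character(GenomicRanges::strand(halfSites))
  dec <- halfSites$decamer
  mm <- halfSites$mismatches
  seqn <- as.character(GenomicRanges::seqnames(halfSites))[1]

  paired <- logical(n)
  fulls <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || strnd[i] != strnd[j]) next
    sp <- st[j] - en[i] - 1L
    if (sp < 0L || sp > model@maxSpacer) next
    paired[i] <- paired[j] <- TRUE
    re20 <- if (strnd[i] == "+") paste0(dec[i], dec[j])
            else paste0(dec[j], dec[i])
    fulls[[length(fulls) + 1L]] <- data.frame(
      start = st[i], end = en[j], strand = strnd[i],
      architecture = "full", spacer = sp, siteSeq = re20, re20 = re20,
      mismatches = mm[i] + mm[j], stringsAsFactors = FALSE)
  }
  if (length(fulls)) {
    f <- do.call(rbind, fulls)
    f <- f[order(f$spacer, f$start, f$strand), , drop = FALSE]
    out <- c(out, list(f))
  }

  q5 <- substr(model@halfSitePattern, 1L, 5L)          # RRRCW
  q3 <- substr(model@halfSitePattern, k - 4L, k)       # WGYYY
  L <- nchar(seq)
  singles <- list()
  for (i in which(!paired)) {
    plus <- strnd[i] == "+"
    # pentamer 3' of the half-site in site orientation must match RRRCW;
    # pentamer 5' of it must match WGYYY
    after <- if (plus) c(en[i] + 1L, en[i] + 5L) else c(st[i] - 5L, st[i] - 1L)
    before <- if (plus) c(st[i] - 5L, st[i] - 1L) else c(en[i] + 1L, en[i] + 5L)
    found <- FALSE
    if (after[1] >= 1L && after[2] <= L) {
      pent <- substr(seq, after[1], after[2])
      if (!plus) pent <- revComp(pent)
      if (!grepl("N", pent) && .windowMismatches(strsplit(pent, "")[[1]], q5) == 0L) {
        siteSeq <- paste0(dec[i], pent)
        singles[[length(singles) + 1L]] <- data.frame(
          start = min(st[i], after[1]), end = max(en[i], after[2]),
          strand = strnd[i], architecture = "three_quarter", spacer = 0L,
          siteSeq = siteSeq, re20 = NA_character_, mismatches = mm[i],
          stringsAsFactors = FALSE)
        found <- TRUE
      }
    }
    if (before[1] >= 1L && before[2] <= L) {
      pent <- substr(seq, before[1], before[2])
      if (!plus) pent <- revComp(pent)
      if (!grepl("N", pent) && .windowMismatches(strsplit(pent, "")[[1]], q3) == 0L) {
        siteSeq <- paste0(pent, dec[i])
        singles[[length(singles) + 1L]] <- data.frame(
          start = min(st[i], before[1]), end = max(en[i], before[2]),
          strand = strnd[i], architecture = "three_quarter", spacer = 0L,
          siteSeq = siteSeq, re20 = NA_character_, mismatches = mm[i],
          stringsAsFactors = FALSE)
        found <- TRUE
      }
    }
    if (!found) {
      singles[[length(singles) + 1L]] <- data.frame(
        start = st[i], end = en[i], strand = strnd[i],
        architecture = "half", spacer = NA_integer_, siteSeq = dec[i],
        re20 = NA_character_, mismatches = mm[i], stringsAsFactors = FALSE)
    }
  }
  if (length(singles)) {
    s <- do.call(rbind, singles)
    s <- s[order(s$start, s$strand), , drop = FALSE]
    out <- c(out, list(s))
  }
  if (!length(out)) return(emptyRes)
  d <- do.call(rbind, out)
  GenomicRanges::GRanges(
    seqnames = seqn,
    ranges = IRanges::IRanges(start = d$start, end = d$end),
    strand = d$strand, architecture = d$architecture, spacer = d$spacer,
    siteSeq = d$siteSeq, re20 = d$re20, mismatches = d$mismatches)
}

#' Scan sequences and assemble response-element sites
#'
#' Convenience wrapper running [scanHalfSites()] and [assembleSites()] over
#' each record of a sequence set.
#'
#' @param seqs named character vector, [Biostrings::DNAStringSet], or path to
#'   a FASTA file.
#' @param model a [ConsensusModel-class].
#' @param dedupe collapse palindromic duplicate half-sites before assembly.
#' @return A `GRanges` of sites across all records (seqnames = record names).
#' @examples
#' scanSites(c(myRE = "TTGAACATGTTCGAACATGTTCAA"))
#' @export
scanSites <- function(seqs, model = consensusModel(), dedupe = FALSE) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- readFasta(seqs)
  if (is(seqs, "XStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  res <- lapply(names(seqs), function(nm) {
    hs <- scanHalfSites(seqs[[nm]], model, seqname = nm, dedupe = dedupe)
    gr <- assembleSites(hs, seqs[[nm]], model)
    GenomeInfoDb::seqlevels(gr) <- names(seqs)
    gr
  })
  do.call(c, res)
}
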