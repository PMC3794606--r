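.LOGO_SLOTS <- list(RR1 = 2L, WW1 = 5L, YY1 = 8L,
                    RR2 = 12L, WW2 = 15L, YY2 = 18L)

.SLOT_CLASS <- c(RR1 = "R", WW1 = "W", YY1 = "Y",
                 RR2 = "R", WW2 = "W", YY2 = "Y")

.BASE_COLORS <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")

#' Paired-dinucleotide frequencies of aligned 20-mer REs
#'
#' Computes the empirical dinucleotide frequency of each signature slot (RR
#' at positions 2-3 / 12-13, WW at 5-6 / 15-16, YY at 8-9 / 18-19) over a set
#' of spacer-removed 20-mers, together with the conventional independent
#' per-position mononucleotide frequency matrix computed on the same set.
#'
#' @param res character vector (or `DNAStringSet`) of 20-mers over ACGT.
#' @return A [DinucleotideLogo-class].
#' @examples
#' dinucleotideFrequencies(c("GGGCATGCCCGGGCATGCCC",
#'                           "GAACATGTTCGAACATGTTC"))
#' @export
dinucleotideFrequencies <- function(res) {
  if (is(res, "XStringSet")) res <- as.character(res)
  res <- toupper(res)
  if (!length(res)) stop("RE set is empty", call. = FALSE)
  if (any(nchar(res) != 20L))
    stop("all REs must be spacer-removed 20-mers; lengths seen: ",
         paste(sort(unique(nchar(res))), collapse = ", "), call. = FALSE)
  for (s in res) .checkDNA(s, what = "RE")
  n <- length(res)
  counts <- lapply(.LOGO_SLOTS, function(p) {
    tab <- table(substr(res, p, p + 1L))
    stats::setNames(as.integer(tab), names(tab))
  })
  freqs <- lapply(counts, function(k) k / n)
  chars <- matrix(unlist(strsplit(res, "")), nrow = n, byrow = TRUE)
  mono <- t(apply(chars, 2, function(col) {
    tabulate(factor(col, levels = c("A", "C", "G", "T")), nbins = 4L) / n
  }))
  colnames(mono) <- c("A", "C", "G", "T")
  rownames(mono) <- paste0("pos", 1:20)
  new("DinucleotideLogo", slotFreqs = freqs, slotCounts = counts,
      n = n, mono = mono)
}

#' Export a dinucleotide logo as a table
#'
#' @param logo a [DinucleotideLogo-class].
#' @return data.frame with columns `slot`, `dinucleotide`, `count`,
#'   `fraction`.
#' @export
logoToTable <- function(logo) {
  stopifnot(is(logo, "DinucleotideLogo"))
  rows <- lapply(names(logo@slotFreqs), function(s) {
    f <- logo@slotFreqs[[s]]
    data.frame(slot = s, dinucleotide = names(f),
               count = unname(logo@slotCounts[[s]]),
               fraction = unname(f), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.isConsensusDinuc <- function(dinuc, class) {
  b <- strsplit(dinuc, "")[[1]]
  all(b %in% .IUPAC[[class]])
}

#' Render a dinucleotide logo as an SVG document
#'
#' One glyph column per signature slot; glyph height is strictly proportional
#' to the dinucleotide frequency. By default all dinucleotides at or above
#' `minFreq` are drawn, consensus-compatible ones (both bases within the
#' slot's R/W/Y class) in full colour and the rest greyed; `consensusOnly`
#' drops the non-compatible ones entirely. Rendering is a pure function of
#' the logo object (no timestamps), so identical logos give byte-identical
#' documents.
#'
#' @param logo a [DinucleotideLogo-class].
#' @param consensusOnly draw only consensus-compatible dinucleotides.
#' @param minFreq omit dinucleotides below this fraction (in \[0, 1\]).
#' @param file optional path; when given the SVG is also written there.
#' @return The SVG document as a single character string (invisibly when
#'   `file` is given).
#' @export
renderLogo <- function(logo, consensusOnly = FALSE, minFreq = 0.05,
                       file = NULL) {
  stopifnot(is(logo, "DinucleotideLogo"))
  if (!is.numeric(minFreq) || length(minFreq) != 1L ||
      minFreq < 0 || minFreq > 1)
    stop("minFreq must be a single value in [0, 1]", call. = FALSE)
  colW <- 70; plotH <- 200; marginX <- 10; marginTop <- 30; marginBottom <- 24
  slots <- names(logo@slotFreqs)
  width <- marginX * 2 + colW * length(slots)
  height <- marginTop + plotH + marginBottom
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%d" height="%d" viewBox="0 0 %d %d">'),
                   width, height, width, height),
           sprintf(paste0('<text x="%d" y="18" font-family="monospace" ',
                          'font-size="12">dinucleotide logo, n = %d</text>'),
                   marginX, logo@n))
  for (i in seq_along(slots)) {
    s <- slots[i]
    x0 <- marginX + (i - 1) * colW
    f <- logo@slotFreqs[[s]]
    ord <- order(-f, names(f))
    f <- f[ord]
    keep <- f >= minFreq
    y <- marginTop
    for (j in which(keep)) {
      dinuc <- names(f)[j]
      compat <- .isConsensusDinuc(dinuc, .SLOT_CLASS[[s]])
      if (consensusOnly && !compat) next
      h <- f[[j]] * plotH
      bases <- strsplit(dinuc, "")[[1]]
      cols <- if (compat) .BASE_COLORS[bases] else c("#999999", "#999999")
      # a full-height glyph is a 28px-tall monospace pair scaled to h
      scale <- h / 28
      out <- c(out, sprintf(
        paste0('<g transform="translate(%.4f,%.4f) scale(1,%.6f)">',
               '<text x="0" y="24" font-family="monospace" font-size="28" ',
               'font-weight="bold" fill="%s">%s</text>',
               '<text x="17" y="24" font-family="monospace" font-size="28" ',
               'font-weight="bold" fill="%s">%s</text></g>'),
        x0, y, scale, cols[1], bases[1], cols[2], bases[2]))
      y <- y + h
    }
    out <- c(out, sprintf(
      paste0('<text x="%.4f" y="%d" font-family="monospace" ',
             'font-size="11">%s</text>'),
      x0, marginTop + plotH + 16, s))
  }
  out <- c(out, "</svg>")
  svg <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(svg, file)
    return(invisible(svg))
  }
  svg
}
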