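# IUPAC degenerate-base machinery shared by the scanner and the generator.

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_LETTERS <- names(.IUPAC)

# 4 x 15 lookup: does base (ACGT) belong to the IUPAC class?
.IUPAC_MATCH <- local({
  m <- matrix(FALSE, nrow = 4L, ncol = length(.IUPAC),
              dimnames = list(c("A", "C", "G", "T"), names(.IUPAC)))
  for (cl in names(.IUPAC)) m[.IUPAC[[cl]], cl] <- TRUE
  m
})

.checkDNA <- function(x, allowed = c("A", "C", "G", "T"), what = "sequence") {
  bad <- which(!strsplit(x, "")[[1]] %in% allowed)
  if (length(bad)) {
    stop(sprintf("%s contains non-%s character '%s' at position %d",
                 what, paste(allowed, collapse = ""),
                 substr(x, bad[1], bad[1]), bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

# Per-window mismatch counts of every decamer (length-`k` window) of `chars`
# against an IUPAC pattern, vectorised over windows. Any character not in the
# pattern class at a position (including N in the sequence) is a mismatch.
.windowMismatches <- function(chars, pattern) {
  k <- nchar(pattern)
  L <- length(chars)
  nw <- L - k + 1L
  if (nw < 1L) return(integer(0))
  pat <- strsplit(pattern, "")[[1]]
  mm <- integer(nw)
  idx <- seq_len(nw) - 1L
  for (j in seq_len(k)) {
    ok <- .IUPAC_MATCH[, pat[j]][chars[idx + j]]
    ok[is.na(ok)] <- FALSE   # N or other non-ACGT base in the sequence
    mm <- mm + as.integer(!ok)
  }
  mm
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
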