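#' RY/WW signature profile of spacer-removed 20-mer response elements
#'
#' Computes the sequence code of a full-site RE: the four RY-signature slots
#' (GG at positions 2-3 and 12-13; CC at positions 8-9 and 18-19; 1-based on
#' the spacer-removed 20-mer), the WW motifs of the two CWWG cores (positions
#' 5-6 and 15-16), and the core 4-mers themselves (positions 4-7 and 14-17).
#' `innerOnly` is TRUE when exactly one RY slot is set and it is one of the
#' two inner slots (positions 8-9 or 12-13, i.e. between the two cores).
#'
#' @param re20 character vector of 20-mers over ACGT (spacers already
#'   removed).
#' @return A [S4Vectors::DataFrame] with one row per RE: `re20`, logical
#'   `ry1`..`ry4`, `ryCount`, `ww1`, `ww2` (each one of AT, TA, AA, TT,
#'   other), `core1`, `core2`, `innerOnly`.
#' @examples
#' ryProfile("GGGCATGCCCGGGCATGCCC")$ryCount  # 4
#' ryProfile("GAACATGTTCGAACATGTTC")$ryCount  # 0
#' @export
ryProfile <- function(re20) {
  re20 <- toupper(re20)
  if (!length(re20)) stop("re20 is empty", call. = FALSE)
  bad <- which(nchar(re20) != 20L)
  if (length(bad))
    stop("re20[", bad[1], "] has length ", nchar(re20[bad[1]]),
         "; a spacer-removed full site must be 20 nt", call. = FALSE)
  for (s in re20) .checkDNA(s, what = "re20")

  sub2 <- function(i) substr(re20, i, i + 1L)
  ry1 <- sub2(2L) == "GG"
  ry2 <- sub2(8L) == "CC"
  ry3 <- sub2(12L) == "GG"
  ry4 <- sub2(18L) == "CC"
  wwLab <- function(x) ifelse(x %in% c("AT", "TA", "AA", "TT"), x, "other")
  ww1 <- wwLab(sub2(5L))
  ww2 <- wwLab(sub2(15L))
  ryCount <- ry1 + ry2 + ry3 + ry4
  S4Vectors::DataFrame(
    re20 = re20,
    ry1 = ry1, ry2 = ry2, ry3 = ry3, ry4 = ry4,
    ryCount = as.integer(ryCount),
    ww1 = ww1, ww2 = ww2,
    core1 = substr(re20, 4L, 7L), core2 = substr(re20, 14L, 17L),
    innerOnly = ryCount == 1L & (ry2 | ry3))
}

#' Ordinal rank of a WW core motif by expected wild-type transactivation
#'
#' AT supports the highest wild-type activity and TA the lowest among the
#' consensus WW dinucleotides; AA and TT tie in between, and non-consensus
#' cores rank last by construction.
#'
#' @param label character vector over AT, TA, AA, TT, other.
#' @return Integer ranks: AT = 1, AA = TT = 2, TA = 3, other = 4.
#' @examples
#' wwRank(c("AT", "TA", "other"))
#' @export
wwRank <- function(label) {
  ranks <- c(AT = 1L, AA = 2L, TT = 2L, TA = 3L, other = 4L)
  unknown <- setdiff(unique(label), names(ranks))
  if (length(unknown))
    stop("unknown WW label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  unname(ranks[label])
}

#' Predict the S139F-class transactivation response of an RE
#'
#' Applies the RE-transactivation code: the change-of-spectrum mutant shows
#' reduced transactivation on REs lacking any RY signature (0/4) and enhanced
#' transactivation on REs with at least one, scaling with the RY count. The
#' numeric score is a package convention, `ryCount + 0.5` when at least one
#' half-site core WW is AA or TT; its only contract is monotonicity in the
#' RY count with the AA/TT core as a secondary bonus, matching the observed
#' qualitative ordering.
#'
#' @param profile a `DataFrame` from [ryProfile()].
#' @return A [S4Vectors::DataFrame] with `predictedClass` (factor: enhanced,
#'   reduced, indeterminate) and `score`.
#' @examples
#' s139fPredict(ryProfile("GAGCATGTCCGAGCATGTCC"))$predictedClass  # reduced
#' @export
s139fPredict <- function(profile) {
  stopifnot(all(c("ryCount", "ww1", "ww2") %in% colnames(profile)))
  anyWW <- profile$ww1 %in% c("AA", "TT") | profile$ww2 %in% c("AA", "TT")
  klass <- ifelse(profile$ryCount == 0L, "reduced", "enhanced")
  S4Vectors::DataFrame(
    predictedClass = factor(klass,
                            levels = c("enhanced", "reduced", "indeterminate")),
    score = profile$ryCount + 0.5 * anyWW)
}
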