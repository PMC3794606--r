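#' @include AllGenerics.R utils-iupac.R
NULL

#' ConsensusModel: the degenerate response-element half-site model
#'
#' Defines what counts as a p53-family half-site: a 10-base IUPAC pattern
#' (default `RRRCWWGYYY`), the maximum spacer between the two half-sites of a
#' full site (0--13 nt), and the per-half-site mismatch tolerance used when
#' scanning.
#'
#' @slot halfSitePattern single 10-character IUPAC string.
#' @slot maxSpacer maximum spacer length in nucleotides (0--13).
#' @slot maxMismatches maximum mismatches tolerated per half-site window.
#' @export
setClass("ConsensusModel",
  representation(halfSitePattern = "character",
                 maxSpacer = "integer",
                 maxMismatches = "integer"),
  prototype(halfSitePattern = "RRRCWWGYYY",
            maxSpacer = 13L,
            maxMismatches = 0L))

setValidity("ConsensusModel", function(object) {
  msg <- character(0)
  p <- object@halfSitePattern
  if (length(p) != 1L || nchar(p) != 10L)
    msg <- c(msg, "halfSitePattern must be a single 10-character string")
  else if (!all(strsplit(p, "")[[1]] %in% .IUPAC_LETTERS))
    msg <- c(msg, "halfSitePattern must use IUPAC letters only")
  if (length(object@maxSpacer) != 1L || is.na(object@maxSpacer) ||
      object@maxSpacer < 0L || object@maxSpacer > 13L)
    msg <- c(msg, "maxSpacer must be a single integer in [0, 13]")
  if (length(object@maxMismatches) != 1L || is.na(object@maxMismatches) ||
      object@maxMismatches < 0L)
    msg <- c(msg, "maxMismatches must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Construct a ConsensusModel
#'
#' @param halfSitePattern 10-character IUPAC pattern for one half-site.
#' @param maxSpacer maximum spacer (nt) between the half-sites of a full site.
#' @param maxMismatches mismatches tolerated per half-site when scanning.
#' @return A [ConsensusModel-class] object.
#' @examples
#' consensusModel()
#' consensusModel(maxMismatches = 2)
#' @export
consensusModel <- function(halfSitePattern = "RRRCWWGYYY",
                           maxSpacer = 13,
                           maxMismatches = 0) {
  new("ConsensusModel",
      halfSitePattern = toupper(as.character(halfSitePattern)),
      maxSpacer = as.integer(maxSpacer),
      maxMismatches = as.integer(maxMismatches))
}

setMethod("show", "ConsensusModel", function(object) {
  cat("ConsensusModel\n",
      "  half-site pattern : ", object@halfSitePattern, "\n",
      "  max spacer        : ", object@maxSpacer, " nt\n",
      "  max mismatches    : ", object@maxMismatches, " per half-site\n",
      sep = "")
})

#' HillFit: a fitted cooperative binding curve
#'
#' Result of fitting the four-parameter Hill model
#' \eqn{f(c) = f_0 + (f_{max} - f_0)\, c^h / (EC_{50}^h + c^h)} to a
#' titration, with the EC50 reported as the dissociation constant Kd under
#' the assumed stoichiometry. Curves that never approach saturation within
#' the tested concentration range are censored and reported as a Kd lower
#' bound instead of a point estimate.
#'
#' @slot estimates named numeric: `ec50` (nM), `hill`, `f0`, `fmax`.
#' @slot se named numeric standard errors (NA when the curvature is singular).
#' @slot censored logical; TRUE when saturation was not approached or the
#'   EC50 exceeds the top tested concentration.
#' @slot kdLowerBound numeric; top tested concentration when censored, NA
#'   otherwise.
#' @slot rss residual sum of squares at the optimum.
#' @slot residuals per-point residuals (response minus fit).
#' @slot nPoints number of data points used.
#' @export
setClass("HillFit",
  representation(estimates = "numeric", se = "numeric",
                 censored = "logical", kdLowerBound = "numeric",
                 rss = "numeric", residuals = "numeric",
                 nPoints = "integer"))

setValidity("HillFit", function(object) {
  est <- object@estimates
  msg <- character(0)
  if (!all(c("ec50", "hill", "f0", "fmax") %in% names(est)))
    msg <- c(msg, "estimates must be named ec50, hill, f0, fmax")
  else {
    if (!(est[["ec50"]] > 0)) msg <- c(msg, "ec50 must be positive")
    if (!(est[["hill"]] > 0)) msg <- c(msg, "hill must be positive")
    if (!(est[["f0"]] < est[["fmax"]])) msg <- c(msg, "f0 must be < fmax")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn HillFit EC50 (nM), reported as Kd.
#' @param object a `HillFit`.
#' @export
setMethod("ec50", "HillFit", function(object) unname(object@estimates["ec50"]))

#' @describeIn HillFit Hill coefficient.
#' @export
setMethod("hillCoefficient", "HillFit",
          function(object) unname(object@estimates["hill"]))

#' @describeIn HillFit TRUE when the Kd is only bounded from below.
#' @export
setMethod("isCensored", "HillFit", function(object) object@censored)

#' @describeIn HillFit Kd lower bound (nM) for censored fits, NA otherwise.
#' @export
setMethod("kdLowerBound", "HillFit", function(object) object@kdLowerBound)

#' @describeIn HillFit residual sum of squares.
#' @export
setMethod("fitRSS", "HillFit", function(object) object@rss)

setMethod("show", "HillFit", function(object) {
  e <- object@estimates; s <- object@se
  cat("HillFit (", object@nPoints, " points)\n", sep = "")
  if (object@censored) {
    cat(sprintf("  Kd        : > %.6g nM (censored)\n", object@kdLowerBound))
  } else {
    cat(sprintf("  Kd (EC50) : %.6g nM (se %.3g)\n", e["ec50"], s["ec50"]))
  }
  cat(sprintf("  Hill h    : %.4g (se %.3g)\n", e["hill"], s["hill"]))
  cat(sprintf("  f0, fmax  : %.4g, %.4g\n", e["f0"], e["fmax"]))
  cat(sprintf("  rss       : %.6g\n", object@rss))
})

#' DinucleotideLogo: paired-nucleotide frequency summary of aligned REs
#'
#' A generalisation of a per-position sequence logo for 20-mer response
#' elements: empirical frequencies of the dinucleotides occupying the six
#' signature slots (RR at positions 2-3 and 12-13, WW at 5-6 and 15-16, YY at
#' 8-9 and 18-19), together with the conventional independent per-position
#' mononucleotide frequency matrix as the baseline.
#'
#' @slot slotFreqs named list (RR1, WW1, YY1, RR2, WW2, YY2) of named numeric
#'   dinucleotide fractions, each summing to 1.
#' @slot slotCounts same shape, integer counts.
#' @slot n number of REs summarised.
#' @slot mono 20 x 4 per-position base-frequency matrix (columns A, C, G, T).
#' @export
setClass("DinucleotideLogo",
  representation(slotFreqs = "list", slotCounts = "list",
                 n = "integer", mono = "matrix"))

setValidity("DinucleotideLogo", function(object) {
  msg <- character(0)
  if (!identical(names(object@slotFreqs),
                 c("RR1", "WW1", "YY1", "RR2", "WW2", "YY2")))
    msg <- c(msg, "slotFreqs must be named RR1, WW1, YY1, RR2, WW2, YY2")
  for (s in names(object@slotFreqs)) {
    f <- object@slotFreqs[[s]]
    if (abs(sum(f) - 1) > 1e-9)
      msg <- c(msg, sprintf("slot %s fractions do not sum to 1", s))
    k <- object@slotCounts[[s]]
    if (any(abs(f - k / object@n) > 1e-12))
      msg <- c(msg, sprintf("slot %s fractions are not counts/n", s))
  }
  if (!identical(dim(object@mono), c(20L, 4L)))
    msg <- c(msg, "mono must be a 20 x 4 matrix")
  else if (any(abs(rowSums(object@mono) - 1) > 1e-9))
    msg <- c(msg, "mono rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn DinucleotideLogo per-slot dinucleotide fractions.
#' @param object a `DinucleotideLogo`.
#' @export
setMethod("slotFrequencies", "DinucleotideLogo",
          function(object) object@slotFreqs)

#' @describeIn DinucleotideLogo 20 x 4 per-position base frequencies.
#' @export
setMethod("monoFrequencies", "DinucleotideLogo", function(object) object@mono)

#' @describeIn DinucleotideLogo number of REs summarised.
#' @export
setMethod("nSequences", "DinucleotideLogo", function(object) object@n)

setMethod("show", "DinucleotideLogo", function(object) {
  cat("DinucleotideLogo over", object@n, "REs\n")
  for (s in names(object@slotFreqs)) {
    f <- sort(object@slotFreqs[[s]], decreasing = TRUE)
    top <- paste(sprintf("%s %.2f", names(f), f), collapse = ", ")
    cat(sprintf("  %s: %s\n", s, top))
  }
})

#' AssociationReport: signature-vs-class association statistics
#'
#' Holds the half-site-resolution 2x2 contingency table between a sequence
#' feature and a transactivation-class contrast, the two-sided Fisher exact
#' p-value, and the Spearman trend of the transactivation ratio against the
#' RY-signature count.
#'
#' @slot table 2x2 integer contingency matrix with informative dimnames.
#' @slot fisherP two-sided Fisher exact p-value.
#' @slot trendRho Spearman rank correlation of ratio vs RY count.
#' @slot trendP p-value of the trend test.
#' @slot feature label of the half-site feature tested.
#' @slot groups the two classes contrasted.
#' @export
setClass("AssociationReport",
  representation(table = "matrix", fisherP = "numeric",
                 trendRho = "numeric", trendP = "numeric",
                 feature = "character", groups = "character"))

setValidity("AssociationReport", function(object) {
  msg <- character(0)
  if (!identical(dim(object@table), c(2L, 2L)))
    msg <- c(msg, "table must be 2x2")
  if (any(object@table < 0)) msg <- c(msg, "table cells must be non-negative")
  if (!(object@fisherP > 0 && object@fisherP <= 1))
    msg <- c(msg, "fisherP must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn AssociationReport two-sided Fisher exact p-value.
#' @param object an `AssociationReport`.
#' @export
setMethod("fisherP", "AssociationReport", function(object) object@fisherP)

#' @describeIn AssociationReport the 2x2 half-site contingency table.
#' @export
setMethod("contingencyTable", "AssociationReport",
          function(object) object@table)

#' @describeIn AssociationReport Spearman trend (rho, p) of ratio vs RY count.
#' @export
setMethod("trendTest", "AssociationReport",
          function(object) c(rho = object@trendRho, p = object@trendP))

setMethod("show", "AssociationReport", function(object) {
  cat("AssociationReport:", object@feature, "vs",
      paste(object@groups, collapse = "/"), "\n")
  print(object@table)
  cat(sprintf("  Fisher exact (two-sided) p = %.4g\n", object@fisherP))
  cat(sprintf("  Spearman trend ratio~RY: rho = %.3f, p = %.4g\n",
              object@trendRho, object@trendP))
})
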