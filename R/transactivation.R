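#' Fold induction of a reporter over the empty-vector background
#'
#' Mean of normalizer-corrected replicate readings divided by the
#' normalizer-corrected background, as in yeast luciferase assays where
#' light units are normalised to soluble protein or OD600.
#'
#' @param activity numeric vector of replicate reporter readings (light
#'   units), all positive.
#' @param normalizer per-replicate normaliser (protein ug or OD600);
#'   recycled.
#' @param background empty-vector reading.
#' @param backgroundNormalizer normaliser of the background reading.
#' @return Positive fold induction.
#' @examples
#' foldInduction(c(90, 110), 1, background = 10)  # 10
#' @export
foldInduction <- function(activity, normalizer = 1, background,
                          backgroundNormalizer = 1) {
  if (!length(activity) || any(!is.finite(activity)) || any(activity <= 0))
    stop("replicate activities must be positive", call. = FALSE)
  if (any(normalizer <= 0) || backgroundNormalizer <= 0)
    stop("normalizers must be positive", call. = FALSE)
  bg <- background / backgroundNormalizer
  if (!is.finite(bg) || bg <= 0)
    stop("normalized background must be positive", call. = FALSE)
  mean(activity / normalizer) / bg
}

#' Classify a mutant/WT transactivation ratio
#'
#' The ratio of mutant to wild-type fold induction is classified as
#' `enhanced` when strictly above `upper` (default 1.5), `reduced` when
#' strictly below `lower` (default 0.67) and `similar` in between (both
#' boundaries inclusive for `similar`).
#'
#' @param mutFold,wtFold positive fold inductions (vectorised).
#' @param upper,lower classification thresholds, `upper > lower > 0`.
#' @return data.frame with columns `ratio` and `class` (factor enhanced /
#'   reduced / similar).
#' @examples
#' classifyRatio(c(20, 5, 15), 10)$class
#' @export
classifyRatio <- function(mutFold, wtFold, upper = 1.5, lower = 0.67) {
  if (any(mutFold <= 0) || any(wtFold <= 0))
    stop("fold inductions must be positive", call. = FALSE)
  if (!(upper > lower && lower > 0))
    stop("thresholds must satisfy upper > lower > 0", call. = FALSE)
  ratio <- mutFold / wtFold
  klass <- ifelse(ratio > upper, "enhanced",
                  ifelse(ratio < lower, "reduced", "similar"))
  data.frame(ratio = ratio,
             class = factor(klass, levels = c("enhanced", "reduced",
                                              "similar")))
}

#' Classify a replicate-level activity table between two alleles
#'
#' Computes per-RE fold inductions for the wild-type and mutant alleles from
#' replicate readings ([foldInduction()]) and classifies their ratio
#' ([classifyRatio()]).
#'
#' @param records data.frame with columns `re_name`, `allele`, `replicate`,
#'   `activity`, `normalizer`, `background` (one row per replicate).
#' @param wt,mut allele labels to contrast.
#' @param upper,lower thresholds passed to [classifyRatio()].
#' @return data.frame with `re_name`, `wtFold`, `mutFold`, `ratio`, `class`.
#' @export
classifyActivities <- function(records, wt = "WT", mut = "S139F",
                               upper = 1.5, lower = 0.67) {
  need <- c("re_name", "allele", "replicate", "activity", "normalizer",
            "background")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  fold <- function(allele, re) {
    r <- records[records$re_name == re & records$allele == allele, ]
    if (!nrow(r))
      stop("no '", allele, "' records for RE ", re, call. = FALSE)
    foldInduction(r$activity, r$normalizer, r$background[1])
  }
  res <- unique(records$re_name)
  wtF <- vapply(res, fold, numeric(1), allele = wt)
  mutF <- vapply(res, fold, numeric(1), allele = mut)
  cl <- classifyRatio(mutF, wtF, upper, lower)
  data.frame(re_name = res, wtFold = wtF, mutFold = mutF,
             ratio = cl$ratio, class = cl$class, row.names = NULL)
}

#' Fraction of REs super-transactivated by an allele
#'
#' Share of REs whose mutant/WT ratio exceeds the super-transactivation
#' threshold (strictly), as used to summarise uniformly hyperactive alleles
#' such as p73 S260N.
#'
#' @param ratio numeric vector of mutant/WT fold-induction ratios.
#' @param threshold super-transactivation cutoff (default 1.5).
#' @return Fraction in \[0, 1\].
#' @export
superTransRate <- function(ratio, threshold = 1.5) {
  if (any(ratio <= 0)) stop("ratios must be positive", call. = FALSE)
  mean(ratio > threshold)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact enumeration with the point-probability convention: the two-sided
#' p-value is the sum, over all tables with the observed margins, of
#' hypergeometric point probabilities not exceeding that of the observed
#' table (relative tolerance 1e-7 guards floating-point ties). No
#' approximation is used at any table size.
#'
#' @param table 2x2 non-negative integer matrix.
#' @return The two-sided p-value.
#' @examples
#' fisherExactTwoSided(matrix(c(28, 16, 5, 13), 2, byrow = TRUE))  # 0.013
#' @export
fisherExactTwoSided <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L)))
    stop("table must be 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("table cells must be non-negative integers", call. = FALSE)
  N <- sum(table)
  if (N == 0L) stop("all-zero table", call. = FALSE)
  a <- table[1, 1]
  r1 <- sum(table[1, ])
  c1 <- sum(table[, 1])
  k <- max(0L, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(k, c1, N - c1, r1)
  pObs <- stats::dhyper(a, c1, N - c1, r1)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Association between a half-site sequence feature and transactivation class
#'
#' Builds the 2x2 contingency table at half-site resolution (two half-sites
#' per RE, so group denominators are twice the group sizes), contrasting the
#' two named classes on a core-WW feature, runs the exact two-sided Fisher
#' test, and computes the Spearman rank trend of the transactivation ratio
#' against the RY-signature count across all REs.
#'
#' @param classified data.frame with columns `ratio` and `class` (one row per
#'   RE), e.g. from [classifyActivities()].
#' @param profiles matching [ryProfile()] output, same row order.
#' @param feature half-site feature; currently `"ww-AA-TT"` (core WW is AA or
#'   TT).
#' @param groups the two classes contrasted (rows of the table).
#' @return An [AssociationReport-class].
#' @export
signatureAssociation <- function(classified, profiles,
                                 feature = "ww-AA-TT",
                                 groups = c("enhanced", "reduced")) {
  stopifnot(nrow(classified) == nrow(profiles), length(groups) == 2L)
  feature <- match.arg(feature)
  ww <- cbind(profiles$ww1, profiles$ww2)
  hit <- matrix(ww %in% c("AA", "TT"), ncol = 2L)
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(group = groups,
                                feature = c("AA/TT", "other")))
  for (g in seq_along(groups)) {
    sel <- classified$class == groups[g]
    if (!any(sel))
      stop("group '", groups[g], "' contains no REs", call. = FALSE)
    tab[g, 1] <- sum(hit[sel, ])
    tab[g, 2] <- sum(!hit[sel, ])
  }
  p <- fisherExactTwoSided(tab)
  tr <- suppressWarnings(
    stats::cor.test(classified$ratio, profiles$ryCount,
                    method = "spearman", exact = FALSE))
  new("AssociationReport", table = tab, fisherP = p,
      trendRho = unname(tr$estimate), trendP = tr$p.value,
      feature = feature, groups = groups)
}
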