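#' Convert fluorescence polarization to fraction bound
#'
#' Linear interpolation between the free-DNA and fully-bound polarization
#' endpoints, clipped to \[0, 1\]; points outside the range before clipping
#' are flagged in the `"clipped"` attribute.
#'
#' @param polarization numeric polarization readings.
#' @param pFree polarization of free DNA.
#' @param pBound polarization of the saturated complex (must differ from
#'   `pFree`).
#' @return Numeric fractions in \[0, 1\] with a logical `"clipped"`
#'   attribute.
#' @examples
#' fractionBound(c(100, 150, 200), pFree = 100, pBound = 200)
#' @export
fractionBound <- function(polarization, pFree, pBound) {
  if (pBound == pFree)
    stop("pBound must differ from pFree", call. = FALSE)
  f <- (polarization - pFree) / (pBound - pFree)
  clipped <- f < 0 | f > 1
  f <- pmin(pmax(f, 0), 1)
  attr(f, "clipped") <- clipped
  f
}

#' Hill binding isotherm
#'
#' \eqn{f(c) = f_0 + (f_{max} - f_0)\, c^h / (EC_{50}^h + c^h)}. At
#' `conc = ec50` the response is the midpoint `(f0 + fmax)/2`; `h = 1`
#' recovers the simple hyperbola.
#'
#' @param conc protein concentration (nM), non-negative; vectorised.
#' @param ec50 half-saturation concentration (nM), positive.
#' @param hill Hill coefficient, positive.
#' @param f0,fmax lower and upper asymptotes of fraction bound.
#' @return Fraction bound at each concentration.
#' @examples
#' hillFraction(230, ec50 = 230, hill = 1.9)  # 0.5
#' @export
hillFraction <- function(conc, ec50, hill, f0 = 0, fmax = 1) {
  if (any(conc < 0)) stop("conc must be non-negative", call. = FALSE)
  if (ec50 <= 0) stop("ec50 must be positive", call. = FALSE)
  if (hill <= 0) stop("hill must be positive", call. = FALSE)
  s <- conc^hill / (ec50^hill + conc^hill)
  s[conc == 0] <- 0
  f0 + (fmax - f0) * s
}

#' Fit a cooperative Hill binding curve to titration data
#'
#' Unweighted least-squares fit of the four-parameter Hill model by bounded
#' Levenberg-Marquardt ([minpack.lm::nlsLM]) with five multi-starts (EC50
#' initialised at the half-max crossing, jittered by factors 0.2, 0.5, 1, 2,
#' 5; Hill coefficient started at 1; asymptotes at the response extremes).
#' Bounds: h in \[0.2, 5\], EC50 in \[min positive conc / 10, 100 x max
#' conc\]. Replicates are pooled. The zero-concentration points anchor the
#' lower asymptote only. A fit is censored - the Kd reported as a lower
#' bound equal to the top tested concentration - when the curve never
#' approaches saturation (maximum observed response below 60% of the fitted
#' span above `f0`) or the fitted EC50 exceeds the top concentration.
#'
#' With `depletion = TRUE` the quadratic exact-binding model is fitted
#' instead, accounting for the labelled-DNA concentration (`dnaConc`, nM)
#' being non-negligible against the Kd:
#' \eqn{bound = (P + D + K_d - \sqrt{(P + D + K_d)^2 - 4 P D}) / (2 D)}.
#' Cooperativity is not identifiable in this mode, so the Hill coefficient
#' is fixed at 1. The default (`depletion = FALSE`) treats total protein as
#' free protein, matching the EC50-as-Kd convention of the emulated assay.
#'
#' @param concentration protein concentrations (nM), at least 5 distinct
#'   values.
#' @param response fraction bound (same length).
#' @param depletion fit the ligand-depletion (quadratic) model instead of
#'   the Hill model.
#' @param dnaConc labelled-DNA concentration in nM (depletion model only).
#' @return A [HillFit-class].
#' @examples
#' conc <- defaultTitrationGrid()
#' fitHill(conc, hillFraction(conc, 230, 1.9))
#' @export
fitHill <- function(concentration, response, depletion = FALSE,
                    dnaConc = 50) {
  if (length(concentration) != length(response))
    stop("concentration and response lengths differ", call. = FALSE)
  ok <- is.finite(concentration) & is.finite(response)
  concentration <- concentration[ok]
  response <- response[ok]
  if (length(unique(concentration)) < 5L)
    stop("need at least 5 distinct concentrations", call. = FALSE)
  if (any(concentration < 0))
    stop("concentrations must be non-negative", call. = FALSE)

  maxc <- max(concentration)
  minpos <- min(concentration[concentration > 0])
  f0i <- min(response)
  fmaxi <- max(response)
  if (fmaxi <= f0i) stop("response has no dynamic range", call. = FALSE)

  # EC50 init: linear interpolation of the half-max crossing on pooled means
  agg <- stats::aggregate(response, list(conc = concentration), mean)
  agg <- agg[order(agg$conc), ]
  half <- (f0i + fmaxi) / 2
  above <- which(agg$x >= half & agg$conc > 0)
  ec50i <- if (length(above)) {
    i <- above[1]
    if (i > 1 && agg$x[i] > agg$x[i - 1] && agg$conc[i - 1] > 0) {
      w <- (half - agg$x[i - 1]) / (agg$x[i] - agg$x[i - 1])
      agg$conc[i - 1] + w * (agg$conc[i] - agg$conc[i - 1])
    } else agg$conc[i]
  } else maxc
  ec50i <- min(max(ec50i, minpos / 5), 50 * maxc)

  lower <- c(ec50 = minpos / 10, hill = 0.2, f0 = -0.5, fmax = f0i)
  upper <- c(ec50 = 100 * maxc, hill = 5, f0 = fmaxi, fmax = 2)
  dat <- data.frame(conc = concentration, resp = response)
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     maxiter = 500)
  best <- NULL
  trace <- numeric(0)
  for (jit in c(0.2, 0.5, 1, 2, 5)) {
    startEC <- min(max(jit * ec50i, lower["ec50"]), upper["ec50"])
    fit <- tryCatch({
      if (depletion) {
        minpack.lm::nlsLM(
          resp ~ depletionFraction(conc, ec50, dnaConc, f0, fmax),
          data = dat,
          start = list(ec50 = startEC, f0 = f0i, fmax = fmaxi),
          lower = lower[c("ec50", "f0", "fmax")],
          upper = upper[c("ec50", "f0", "fmax")], control = ctrl)
      } else {
        minpack.lm::nlsLM(
          resp ~ hillFraction(conc, ec50, hill, f0, fmax),
          data = dat,
          start = list(ec50 = startEC, hill = 1, f0 = f0i, fmax = fmaxi),
          lower = lower, upper = upper, control = ctrl)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    if (cf["f0"] >= cf["fmax"]) next
    rss <- sum(stats::residuals(fit)^2)
    trace <- c(trace, rss)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("Hill fit did not converge from any start (ec50 starts: ",
         paste(signif(ec50i * c(0.2, 0.5, 1, 2, 5), 4), collapse = ", "),
         "; rss trace: ", paste(signif(trace, 4), collapse = ", "), ")",
         call. = FALSE)

  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  if (depletion) {
    cf <- c(cf, hill = 1)
    se <- c(se, hill = NA_real_)
  }
  span <- cf["fmax"] - cf["f0"]
  censored <- max(response) < cf["f0"] + 0.6 * span || cf["ec50"] > maxc
  new("HillFit",
      estimates = cf[c("ec50", "hill", "f0", "fmax")],
      se = se[c("ec50", "hill", "f0", "fmax")],
      censored = censored,
      kdLowerBound = if (censored) maxc else NA_real_,
      rss = best$rss,
      residuals = as.numeric(stats::residuals(best$fit)),
      nPoints = length(response))
}

#' Fraction bound under ligand depletion
#'
#' Exact-binding quadratic solution for the complex fraction when the
#' labelled-DNA concentration is not negligible relative to the Kd.
#'
#' @param conc total protein concentration (nM).
#' @param kd dissociation constant (nM).
#' @param dnaConc total labelled-DNA concentration (nM).
#' @param f0,fmax response asymptotes.
#' @return Fraction bound at each concentration.
#' @export
depletionFraction <- function(conc, kd, dnaConc = 50, f0 = 0, fmax = 1) {
  if (any(conc < 0)) stop("conc must be non-negative", call. = FALSE)
  if (kd <= 0) stop("kd must be positive", call. = FALSE)
  if (dnaConc <= 0) stop("dnaConc must be positive", call. = FALSE)
  s <- conc + dnaConc + kd
  bound <- (s - sqrt(pmax(s^2 - 4 * conc * dnaConc, 0))) / (2 * dnaConc)
  f0 + (fmax - f0) * bound
}

#' Ratio of binding affinities from two Hill fits
#'
#' `ec50(fitB) / ec50(fitA)`: how much tighter `fitA` binds than `fitB`.
#' When one fit is censored its Kd lower bound is used and the result is a
#' one-sided bound (`qualifier` `">="` when B is censored, `"<="` when A is);
#' when both are censored the ratio is undefined.
#'
#' @param fitA,fitB [HillFit-class] objects.
#' @return list with `ratio` and `qualifier` (`"none"`, `">="`, `"<="`).
#' @export
affinityRatio <- function(fitA, fitB) {
  stopifnot(is(fitA, "HillFit"), is(fitB, "HillFit"))
  if (isCensored(fitA) && isCensored(fitB))
    stop("both fits are censored; the affinity ratio is undefined",
         call. = FALSE)
  kdA <- if (isCensored(fitA)) kdLowerBound(fitA) else ec50(fitA)
  kdB <- if (isCensored(fitB)) kdLowerBound(fitB) else ec50(fitB)
  qualifier <- if (isCensored(fitB)) ">=" else if (isCensored(fitA)) "<="
               else "none"
  list(ratio = kdB / kdA, qualifier = qualifier)
}

#' Default fluorescence-polarization titration grid
#'
#' Eighteen protein concentrations spanning 0 to 20,000 nM: a zero anchor
#' plus 17 log-spaced points from 1 to 20,000 nM.
#'
#' @return Numeric vector of 18 concentrations (nM).
#' @export
defaultTitrationGrid <- function() {
  c(0, 10^seq(0, log10(20000), length.out = 17))
}
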