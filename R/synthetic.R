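# Seeded generators emulating the study's three data layers: RE sets with
# controlled RY/WW composition, noisy WT/mutant transactivation values whose
# ratio follows the signature, and 18-point titration curves.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.checkMix <- function(x, what) {
  if (any(x < 0) || abs(sum(x) - 1) > 1e-9)
    stop(what, " must be a probability distribution summing to 1",
         call. = FALSE)
  invisible(TRUE)
}

#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the generators with defaults reflecting the study
#' conditions: RE composition (about a quarter of full sites carry no RY
#' signature, the remainder spread over 1-4), core WW motifs with AT most
#' common and roughly half of half-sites AA/TT, no spacer, and a
#' log-linear transactivation-ratio model whose defaults place 0/4-RY REs in
#' the reduced class and >=3/4-RY REs in the enhanced class in the absence of
#' noise.
#'
#' @param seed integer RNG seed; every generator is a pure function of its
#'   config including the seed.
#' @param nRes number of REs to generate.
#' @param ryMix probabilities of RY counts 0..4.
#' @param wwMix probabilities of core WW motifs (names AT, TA, AA, TT).
#' @param spacerMix probabilities of spacer lengths 0..13 (names "0".."13").
#' @param mismatchRate per-position substitution probability at the four
#'   positions (1, 10, 11, 20) outside the RY slots, WW motifs and invariant
#'   core C/G, so truth labels stay exact.
#' @param beta0,betaRY,betaWW coefficients of the log mutant/WT ratio model:
#'   `log ratio = beta0 + betaRY * ryCount + betaWW * [any core WW in
#'   {AA,TT}] + N(0, noiseSD)`.
#' @param noiseSD standard deviation of the log-ratio noise.
#' @param wtLogMean,wtLogSD lognormal parameters of the WT fold induction.
#' @param replicates replicate readings per (RE, allele).
#' @param replicateCV multiplicative (lognormal sd on log scale) replicate
#'   noise on raw readings.
#' @param background empty-vector reading used when emitting raw records.
#' @return A list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1L,
                            nRes = 50L,
                            ryMix = c(0.24, 0.19, 0.19, 0.19, 0.19),
                            wwMix = c(AT = 0.35, TA = 0.12,
                                      AA = 0.265, TT = 0.265),
                            spacerMix = c("0" = 1),
                            mismatchRate = 0.1,
                            beta0 = log(0.5),
                            betaRY = log(1.6),
                            betaWW = log(1.3),
                            noiseSD = 0.2,
                            wtLogMean = log(20),
                            wtLogSD = 0.8,
                            replicates = 4L,
                            replicateCV = 0.1,
                            background = 100) {
  .checkMix(ryMix, "ryMix")
  if (length(ryMix) != 5L) stop("ryMix must have 5 entries (RY count 0..4)",
                                call. = FALSE)
  .checkMix(wwMix, "wwMix")
  if (!all(names(wwMix) %in% c("AT", "TA", "AA", "TT")))
    stop("wwMix names must be among AT, TA, AA, TT", call. = FALSE)
  .checkMix(spacerMix, "spacerMix")
  sp <- as.integer(names(spacerMix))
  if (any(is.na(sp)) || any(sp < 0L) || any(sp > 13L))
    stop("spacerMix names must be spacer lengths in 0..13", call. = FALSE)
  if (mismatchRate < 0 || mismatchRate > 1)
    stop("mismatchRate must be in [0, 1]", call. = FALSE)
  if (noiseSD < 0 || replicateCV < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  structure(list(seed = as.integer(seed), nRes = as.integer(nRes),
                 ryMix = ryMix, wwMix = wwMix, spacerMix = spacerMix,
                 mismatchRate = mismatchRate, beta0 = beta0,
                 betaRY = betaRY, betaWW = betaWW, noiseSD = noiseSD,
                 wtLogMean = wtLogMean, wtLogSD = wtLogSD,
                 replicates = as.integer(replicates),
                 replicateCV = replicateCV, background = background),
            class = "SyntheticConfig")
}

#' Generate a synthetic RE set with known signature truth
#'
#' Builds consensus-conforming 20-mers by sampling an RY count from `ryMix`,
#' choosing uniformly which slots carry it, forcing those slots to GG/CC and
#' the remaining slots to non-signature same-class dinucleotides, forcing the
#' two core WW motifs from `wwMix`, and sampling the four remaining
#' class-constrained positions; consensus mismatches are then applied only at
#' those four positions so the recorded truth (RY flags, WW labels) is exact
#' by construction. Spacers sampled from `spacerMix` are inserted between the
#' half-sites of the emitted sequence but excluded from `re20`.
#'
#' @param config a [syntheticConfig()].
#' @return list with `sequences` (named [Biostrings::DNAStringSet], spacer
#'   included) and `truth` (`DataFrame`: name, re20, spacer, ryCount,
#'   ry1..ry4, ww1, ww2).
#' @export
generateRESet <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  .withSeed(config$seed, {
    n <- config$nRes
    ryCount <- sample(0:4, n, replace = TRUE, prob = config$ryMix)
    slotOn <- t(vapply(ryCount, function(k) {
      on <- logical(4)
      if (k > 0) on[sample.int(4, k)] <- TRUE
      on
    }, logical(4)))
    offRR <- c("AA", "AG", "GA")
    offYY <- c("TT", "TC", "CT")
    pick <- function(on, onVal, offVals) {
      ifelse(on, onVal, sample(offVals, length(on), replace = TRUE))
    }
    slot1 <- pick(slotOn[, 1], "GG", offRR)   # positions 2-3
    slot2 <- pick(slotOn[, 2], "CC", offYY)   # positions 8-9
    slot3 <- pick(slotOn[, 3], "GG", offRR)   # positions 12-13
    slot4 <- pick(slotOn[, 4], "CC", offYY)   # positions 18-19
    wwNames <- names(config$wwMix)
    ww1 <- sample(wwNames, n, replace = TRUE, prob = config$wwMix)
    ww2 <- sample(wwNames, n, replace = TRUE, prob = config$wwMix)
    rBase <- function() sample(c("A", "G"), n, replace = TRUE)
    yBase <- function() sample(c("C", "T"), n, replace = TRUE)
    p1 <- rBase(); p10 <- yBase(); p11 <- rBase(); p20 <- yBase()
    # consensus mismatches only at the free class positions 1, 10, 11, 20
    mut <- function(x, offClass) {
      hit <- stats::runif(n) < config$mismatchRate
      x[hit] <- sample(offClass, sum(hit), replace = TRUE)
      x
    }
    p1 <- mut(p1, c("C", "T")); p11 <- mut(p11, c("C", "T"))
    p10 <- mut(p10, c("A", "G")); p20 <- mut(p20, c("A", "G"))

    half1 <- paste0(p1, slot1, "C", ww1, "G", slot2, p10)
    half2 <- paste0(p11, slot3, "C", ww2, "G", slot4, p20)
    re20 <- paste0(half1, half2)
    spacerLen <- as.integer(sample(names(config$spacerMix), n, replace = TRUE,
                                   prob = config$spacerMix))
    spacerSeq <- vapply(spacerLen, function(k) {
      if (k == 0L) "" else paste(sample(c("A", "C", "G", "T"), k,
                                        replace = TRUE), collapse = "")
    }, character(1))
    seqs <- paste0(half1, spacerSeq, half2)
    name <- sprintf("SRE%03d", seq_len(n))
    names(seqs) <- name
    list(sequences = Biostrings::DNAStringSet(seqs),
         truth = S4Vectors::DataFrame(
           name = name, re20 = re20, spacer = spacerLen,
           ryCount = as.integer(rowSums(slotOn)),
           ry1 = slotOn[, 1], ry2 = slotOn[, 2],
           ry3 = slotOn[, 3], ry4 = slotOn[, 4],
           ww1 = ww1, ww2 = ww2))
  })
}

#' Generate transactivation measurements for a synthetic RE set
#'
#' WT fold induction is lognormal; the log mutant/WT ratio follows the
#' signature model `beta0 + betaRY * ryCount + betaWW * [any WW in {AA,TT}] +
#' N(0, noiseSD)`. Raw replicate records (readings over a fixed background,
#' with multiplicative replicate noise) are emitted alongside the truth.
#'
#' @param truth the `truth` table from [generateRESet()].
#' @param config the same [syntheticConfig()].
#' @return list with `truth` (input plus `wtFold`, `mutFold`, `ratio`,
#'   `class`) and `records` (replicate-level data.frame with columns
#'   `re_name`, `allele`, `replicate`, `activity`, `normalizer`,
#'   `background`).
#' @export
generateTransactivation <- function(truth, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (!nrow(truth)) stop("truth table is empty", call. = FALSE)
  .withSeed(config$seed + 1L, {
    n <- nrow(truth)
    anyWW <- truth$ww1 %in% c("AA", "TT") | truth$ww2 %in% c("AA", "TT")
    logRatio <- config$beta0 + config$betaRY * truth$ryCount +
      config$betaWW * anyWW + stats::rnorm(n, 0, config$noiseSD)
    wtFold <- stats::rlnorm(n, config$wtLogMean, config$wtLogSD)
    ratio <- exp(logRatio)
    mutFold <- wtFold * ratio
    cl <- classifyRatio(mutFold, wtFold)
    truth$wtFold <- wtFold
    truth$mutFold <- mutFold
    truth$ratio <- cl$ratio
    truth$class <- cl$class
    reps <- config$replicates
    mk <- function(fold, allele) {
      act <- rep(fold, each = reps) * config$background *
        exp(stats::rnorm(n * reps, 0, config$replicateCV))
      data.frame(re_name = rep(truth$name, each = reps),
                 allele = allele,
                 replicate = rep(seq_len(reps), n),
                 activity = act,
                 normalizer = 1,
                 background = config$background)
    }
    list(truth = truth,
         records = rbind(mk(wtFold, "WT"), mk(mutFold, "S139F")))
  })
}

#' Generate a noisy fluorescence-polarization titration curve
#'
#' Evaluates [hillFraction()] on the concentration grid and adds i.i.d.
#' Gaussian noise per replicate, mirroring the 18-sample 0-20,000 nM
#' titration design.
#'
#' @param ec50,hill,f0,fmax generating Hill parameters.
#' @param grid concentrations (nM); default [defaultTitrationGrid()].
#' @param noiseSD Gaussian noise sd in fraction-bound units.
#' @param replicates replicate curves.
#' @param seed RNG seed.
#' @return data.frame with `concentration_nM`, `response`, `replicate`.
#' @export
generateBindingCurve <- function(ec50, hill, f0 = 0, fmax = 1,
                                 grid = defaultTitrationGrid(),
                                 noiseSD = 0.02, replicates = 3L,
                                 seed = 1L) {
  .withSeed(seed, {
    mu <- hillFraction(grid, ec50, hill, f0, fmax)
    data.frame(
      concentration_nM = rep(grid, replicates),
      response = rep(mu, replicates) +
        stats::rnorm(length(grid) * replicates, 0, noiseSD),
      replicate = rep(seq_len(replicates), each = length(grid)))
  })
}
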