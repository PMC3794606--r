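# Independent oracles used across the suite. Each takes a different route
# than the implementation it checks.

# Half-site scan oracle: Biostrings IUPAC matching on both strands.
oracleScanStartsStrands <- function(seq, mm, pattern = "RRRCWWGYYY") {
  pat <- Biostrings::DNAString(pattern)
  s <- Biostrings::DNAString(seq)
  L <- nchar(seq)
  plus <- Biostrings::matchPattern(pat, s, max.mismatch = mm,
                                   fixed = "subject")
  minus <- Biostrings::matchPattern(pat, Biostrings::reverseComplement(s),
                                    max.mismatch = mm, fixed = "subject")
  sort(c(sprintf("%d +", IRanges::start(plus)),
         sprintf("%d -", L - IRanges::end(minus) + 1)))
}

scanKey <- function(gr) {
  sort(sprintf("%d %s", GenomicRanges::start(gr),
               as.character(GenomicRanges::strand(gr))))
}

# Literal hypergeometric enumeration (binomial coefficients, no dhyper).
oracleFisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- choose(c1, ks) * choose(N - c1, r1 - ks) / choose(N, r1)
  po <- choose(c1, a) * choose(N - c1, r1 - a) / choose(N, r1)
  min(1, sum(pr[pr <= po * (1 + 1e-7)]))
}

# Dense grid search over (ec50, hill) with the asymptotes profiled out by
# linear least squares; returns the minimum rss found.
oracleHillGridRSS <- function(conc, resp,
                              ec50Grid = 10^seq(-1, 6, length.out = 120),
                              hillGrid = seq(0.2, 5, length.out = 60)) {
  best <- Inf
  for (e in ec50Grid) for (h in hillGrid) {
    s <- conc^h / (e^h + conc^h)
    s[conc == 0] <- 0
    fit <- stats::lm.fit(cbind(1, s), resp)
    rss <- sum(fit$residuals^2)
    if (rss < best) best <- rss
  }
  best
}

# Random ACGT sequence of length n.
randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
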