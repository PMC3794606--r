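test_that("mismatchCount follows the IUPAC classes", {
  expect_identical(mismatchCount("GGGCATGCCC", "RRRCWWGYYY"), 0L)
  expect_identical(mismatchCount("GAGCATGTCC", "RRRCWWGYYY"), 0L)
  expect_identical(mismatchCount("CCCCATGCCC", "RRRCWWGYYY"), 3L)
  expect_error(mismatchCount("GGGCATGCC", "RRRCWWGYYY"), "lengths differ")
  expect_error(mismatchCount("GGGCATGCCX", "RRRCWWGYYY"), "position 10")
})

test_that("revComp is the Watson-Crick reverse complement", {
  expect_identical(revComp("GGGCATGCCC"), "GGGCATGCCC")
  expect_identical(revComp("GAACA"), "TGTTC")
  expect_identical(revComp(""), "")
  expect_error(revComp("GAXCA"))
})

test_that("scanHalfSites finds palindromic half-sites on both strands", {
  hs <- scanHalfSites("GGGCATGCCCGGGCATGCCC")
  expect_length(hs, 4L)
  expect_identical(sort(unique(GenomicRanges::start(hs))), c(1L, 11L))
  expect_setequal(as.character(GenomicRanges::strand(hs)), c("+", "-"))
  expect_true(all(hs$mismatches == 0L))
  # A-run fails the pyrimidine positions
  expect_length(scanHalfSites("AAAAAAAAAA"), 0L)
  # shorter than a decamer: empty, not an error
  expect_length(scanHalfSites("GGGCATGCC"), 0L)
  # dedupe collapses palindromic duplicates to the plus strand
  dd <- scanHalfSites("GGGCATGCCCGGGCATGCCC", dedupe = TRUE)
  expect_length(dd, 2L)
  expect_true(all(as.character(GenomicRanges::strand(dd)) == "+"))
})

test_that("scanHalfSites equals the window oracle on random sequences", {
  set.seed(11)
  for (i in 1:10) {
    seq <- randomDNA(500)
    for (mm in 0:2) {
      mine <- scanHalfSites(seq, consensusModel(maxMismatches = mm))
      expect_identical(scanKey(mine), oracleScanStartsStrands(seq, mm))
    }
  }
})

test_that("scanning the reverse complement mirrors the match set", {
  set.seed(12)
  for (i in 1:5) {
    seq <- randomDNA(300)
    mm <- sample(0:2, 1)
    fwd <- scanHalfSites(seq, consensusModel(maxMismatches = mm))
    rev <- scanHalfSites(revComp(seq), consensusModel(maxMismatches = mm))
    # reflect rev coordinates back onto the forward sequence, swap strands
    L <- nchar(seq)
    reflected <- sort(sprintf("%d %s", L - GenomicRanges::end(rev) + 1,
                              c("+" = "-", "-" = "+")[
                                as.character(GenomicRanges::strand(rev))]))
    expect_identical(scanKey(fwd), reflected)
  }
})

test_that("N in the scanned sequence counts as a mismatch", {
  expect_length(scanHalfSites("GGGCATGCCN"), 0L)
  hs <- scanHalfSites("GGGCATGCCN", consensusModel(maxMismatches = 1))
  expect_true(any(GenomicRanges::start(hs) == 1 & hs$mismatches == 1L))
})

test_that("assembleSites builds full sites with spacer-removed re20", {
  seq <- "GAACATGTTCGAACATGTTC"
  hs <- scanHalfSites(seq)
  plus <- hs[as.character(GenomicRanges::strand(hs)) == "+"]
  sites <- assembleSites(plus, seq)
  expect_length(sites, 1L)
  expect_identical(sites$architecture, "full")
  expect_identical(sites$spacer, 0L)
  expect_identical(sites$re20, seq)

  # spacer between the half-sites is removed from re20
  sp <- "GAACATGTTCTTAGAACATGTTC"
  hs2 <- scanHalfSites(sp)
  plus2 <- hs2[as.character(GenomicRanges::strand(hs2)) == "+"]
  sites2 <- assembleSites(plus2, sp)
  expect_identical(sites2$spacer, 3L)
  expect_identical(sites2$re20, "GAACATGTTCGAACATGTTC")
})

test_that("unpaired half-sites become half or three-quarter sites", {
  # lone half-site in a non-conforming background
  seq <- "TTTTGAACATGTTCTTTT"
  hs <- scanHalfSites(seq)
  plus <- hs[as.character(GenomicRanges::strand(hs)) == "+"]
  sites <- assembleSites(plus, seq)
  expect_identical(sites$architecture, "half")
  expect_identical(sites$siteSeq, "GAACATGTTC")

  # adjacent RRRCW pentamer promotes it to a three-quarter site
  seq34 <- "GGGCATGCCCGGGCA"
  hs34 <- scanHalfSites(seq34)
  plus34 <- hs34[as.character(GenomicRanges::strand(hs34)) == "+"]
  sites34 <- assembleSites(plus34, seq34)
  expect_identical(sites34$architecture, "three_quarter")
  expect_identical(sites34$siteSeq, "GGGCATGCCCGGGCA")
  expect_identical(GenomicRanges::width(sites34), 15L)
})

test_that("full-site count is monotone in spacer and mismatch allowance", {
  set.seed(13)
  for (i in 1:5) {
    seq <- randomDNA(400)
    nFull <- function(sp, mm) {
      m <- consensusModel(maxSpacer = sp, maxMismatches = mm)
      s <- assembleSites(scanHalfSites(seq, m), seq, m)
      sum(s$architecture == "full")
    }
    bySpacer <- vapply(c(0, 3, 7, 13), nFull, numeric(1), mm = 1)
    expect_true(all(diff(bySpacer) >= 0))
    byMM <- vapply(0:2, nFull, numeric(1), sp = 13)
    expect_true(all(diff(byMM) >= 0))
  }
})

test_that("re20 of every full site conforms to the doubled pattern", {
  set.seed(14)
  pat2 <- "RRRCWWGYYYRRRCWWGYYY"
  for (i in 1:5) {
    seq <- randomDNA(600)
    m <- consensusModel(maxMismatches = 2)
    sites <- assembleSites(scanHalfSites(seq, m), seq, m)
    full <- sites[sites$architecture == "full"]
    for (re in full$re20)
      expect_lte(mismatchCount(re, pat2), 2L * m@maxMismatches)
  }
})

test_that("scanSites combines records and names seqnames after them", {
  sites <- scanSites(c(a = "GAACATGTTCGAACATGTTC", b = "TTTTTTTTTTTT"))
  expect_true(all(as.character(GenomicRanges::seqnames(sites)) == "a"))
  expect_true(any(sites$architecture == "full"))
})
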