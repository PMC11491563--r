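mkTpl <- function(seed, n = 2000) { set.seed(seed); randDNA(n) }

test_that("a convergent pair spans 5' end to 5' end, footprints included", {
  tpl <- mkTpl(61)
  p1 <- substr(tpl, 101, 120)
  p2 <- reverseComplementSeq(substr(tpl, 401, 420))
  idx <- buildKmerIndex(c(F1 = p1, R1 = p2))
  cfg <- searchConfig()
  a <- pairHits(scanTemplate(tpl, idx, cfg, "t"), tpl, cfg)
  expect_identical(length(a), 1L)
  expect_identical(GenomicRanges::start(a), 101L)
  expect_identical(GenomicRanges::end(a), 420L)
  expect_identical(S4Vectors::mcols(a)$length, 320L)
  mc <- S4Vectors::mcols(a)
  expect_equal(mc$ta, min(mc$fwdTm, mc$revTm) + log(320))
})

test_that("size bounds filter products; defaults are 50-5000", {
  tpl <- mkTpl(62, 8000)
  # back-to-back pair (30 bp) and a 6 kb pair: both outside defaults
  p1 <- substr(tpl, 101, 115)
  p2 <- reverseComplementSeq(substr(tpl, 116, 130))
  p3 <- substr(tpl, 501, 520)
  p4 <- reverseComplementSeq(substr(tpl, 6982, 7001))
  idx <- buildKmerIndex(c(a = p1, b = p2, c = p3, d = p4), k = 9)
  cfg <- searchConfig()
  a <- pairHits(scanTemplate(tpl, idx, cfg, "t"), tpl, cfg)
  expect_false(any(S4Vectors::mcols(a)$length == 30L))
  expect_false(any(S4Vectors::mcols(a)$length > 5000L))
  # widening the window admits the 30-bp product (IRAP-style short bands)
  cfg2 <- searchConfig(minLen = 30, maxLen = 200)
  a2 <- pairHits(scanTemplate(tpl, idx, cfg2, "t"), tpl, cfg2)
  expect_true(30L %in% S4Vectors::mcols(a2)$length)
})

test_that("circular templates produce origin-wrapping products, linear do not", {
  set.seed(63)
  tpl <- randDNA(1000)
  dbl <- paste0(tpl, tpl)
  pF <- substr(dbl, 901, 920)
  pR <- reverseComplementSeq(substr(dbl, 1081, 1100))  # i.e. 81..100
  idx <- buildKmerIndex(c(F1 = pF, R1 = pR))
  cfgC <- searchConfig(topology = "circular")
  hC <- scanTemplate(tpl, idx, cfgC, "t")
  aC <- pairHits(hC, tpl, cfgC)
  wrap <- aC[S4Vectors::mcols(aC)$wrapsOrigin]
  expect_identical(length(wrap), 1L)
  expect_identical(GenomicRanges::start(wrap), 901L)
  expect_identical(GenomicRanges::end(wrap), 1100L)
  expect_identical(S4Vectors::mcols(wrap)$length, 200L)
  cfgL <- searchConfig()
  aL <- pairHits(scanTemplate(tpl, idx, cfgL, "t"), tpl, cfgL)
  expect_false(any(S4Vectors::mcols(aL)$wrapsOrigin))
  expect_false(200L %in% S4Vectors::mcols(aL)$length)
})

test_that("extracted sequences match coordinates, wrap the origin, and
           always have the amplicon's length", {
  set.seed(64)
  tpl <- randDNA(1000)
  dbl <- paste0(tpl, tpl)
  pF <- substr(dbl, 901, 920)
  pR <- reverseComplementSeq(substr(dbl, 1081, 1100))
  idx <- buildKmerIndex(c(F1 = pF, R1 = pR))
  cfg <- searchConfig(topology = "circular", extractSequences = TRUE)
  a <- pairHits(scanTemplate(tpl, idx, cfg, "t"), tpl, cfg)
  mc <- S4Vectors::mcols(a)
  expect_identical(nchar(mc$sequence), mc$length)
  w <- which(mc$wrapsOrigin)
  expect_identical(as.character(mc$sequence[w]),
                   paste0(substr(tpl, 901, 1000), substr(tpl, 1, 100)))
  expect_error(extractAmpliconSeq(substr(tpl, 1, 50), a), "out of range")
})

test_that("single-primer inverted repeats yield exactly the inter-repeat
           products within bounds", {
  inst <- plantSites(6000, nSites = 5, mode = "invertedRepeat",
                     sizeBounds = c(50, 2000), seed = 65)
  cfg <- searchConfig(minLen = 50, maxLen = 2000)
  h <- scanTemplate(inst@template, buildKmerIndex(inst@primers), cfg,
                    inst@templateId)
  a <- pairHits(h, inst@template, cfg)
  expect_identical(
    sprintf("%d|%d", GenomicRanges::start(a), GenomicRanges::end(a)),
    sprintf("%d|%d", inst@truthAmplicons$start, inst@truthAmplicons$end))
})

test_that("locus dedup collapses coordinate-identical primer pairs but
           lists all of them; toggle restores one row per pair", {
  set.seed(66)
  tpl <- randDNA(1500)
  pF <- substr(tpl, 201, 220)
  pR <- reverseComplementSeq(substr(tpl, 581, 600))
  # duplicate primer sequences under different ids (panel with repeats)
  idx <- buildKmerIndex(c(A = pF, B = pF, C = pR))
  cfg <- searchConfig()
  a <- pairHits(scanTemplate(tpl, idx, cfg, "t"), tpl, cfg)
  expect_identical(length(a), 1L)
  expect_identical(S4Vectors::mcols(a)$allPairs, "A>C;B>C")
  cfgAll <- searchConfig(dedupByLocus = FALSE)
  a2 <- pairHits(scanTemplate(tpl, idx, cfgAll, "t"), tpl, cfgAll)
  expect_identical(length(a2), 2L)
})

test_that("nested amplicons are all reported", {
  set.seed(67)
  tpl <- randDNA(2000)
  pF1 <- substr(tpl, 101, 120)
  pF2 <- substr(tpl, 201, 220)
  pR1 <- reverseComplementSeq(substr(tpl, 881, 900))
  pR2 <- reverseComplementSeq(substr(tpl, 781, 800))
  idx <- buildKmerIndex(c(F1 = pF1, F2 = pF2, R1 = pR1, R2 = pR2))
  cfg <- searchConfig()
  a <- pairHits(scanTemplate(tpl, idx, cfg, "t"), tpl, cfg)
  expect_identical(length(a), 4L)  # outer, inner and both crossed pairs
})

test_that("probe mode reports per-hit rows and no amplicons", {
  set.seed(68)
  tpl <- randDNA(1500)
  probe <- substr(tpl, 301, 330)
  ch <- strsplit(tpl, "", TRUE)[[1L]]
  ch[701:730] <- strsplit(reverseComplementSeq(probe), "", TRUE)[[1L]]
  tpl <- paste(ch, collapse = "")
  cfg <- searchConfig(probeMode = TRUE)
  h <- scanTemplate(tpl, buildKmerIndex(c(B1 = probe), roles = "probe"),
                    cfg, "t")
  rows <- probeReport(h)
  expect_identical(nrow(rows), 2L)
  expect_setequal(rows$strand, c("+", "-"))
  expect_identical(rows$mismatches, c(0L, 0L))
  expect_identical(length(pairHits(h, tpl, cfg)), 0L)
  # a probe with no hits still yields a well-formed empty report
  h0 <- scanTemplate(randDNA(500), buildKmerIndex(c(B2 = "ACGTTGCAACGGTCAT")),
                     cfg, "t0")
  expect_identical(nrow(probeReport(h0)), 0L)
})

test_that("the per-template amplicon cap truncates with a warning", {
  set.seed(69)
  unit <- randDNA(60)
  p <- substr(unit, 1, 15)
  block <- paste0(unit, reverseComplementSeq(unit))
  tpl <- paste(rep(block, 8), collapse = "")  # many inverted repeats
  cfg <- searchConfig(minLen = 30, maxLen = 2000,
                      maxAmpliconsPerTemplate = 5)
  h <- scanTemplate(tpl, buildKmerIndex(c(P = p), k = 9), cfg, "t")
  expect_warning(a <- pairHits(h, tpl, cfg), "truncated")
  expect_identical(length(a), 5L)
})
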