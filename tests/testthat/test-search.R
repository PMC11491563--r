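test_that("an exact embedded primer copy gives exactly one plus hit", {
  set.seed(51)
  tpl <- randDNA(2000)
  p <- substr(tpl, 101, 120)
  h <- scanTemplate(tpl, buildKmerIndex(c(P = p)), searchConfig(), "t")
  hp <- h[S4Vectors::mcols(h)$primer == "P" &
            as.character(GenomicRanges::strand(h)) == "+"]
  expect_identical(GenomicRanges::start(hp), 101L)
  expect_identical(GenomicRanges::end(hp), 120L)
  expect_identical(S4Vectors::mcols(hp)$nMismatches, 0L)
})

test_that("a reverse-complement copy gives exactly one minus hit", {
  set.seed(52)
  tpl <- randDNA(2000)
  p <- reverseComplementSeq(substr(tpl, 501, 520))
  h <- scanTemplate(tpl, buildKmerIndex(c(P = p)), searchConfig(), "t")
  expect_identical(as.character(GenomicRanges::strand(h)), "-")
  expect_identical(GenomicRanges::start(h), 501L)
})

test_that("3'-terminal mismatch is rejected at number3Errors=0, kept at 1", {
  set.seed(53)
  tpl0 <- randDNA(1000)
  p <- substr(tpl0, 301, 320)
  ch <- strsplit(tpl0, "", TRUE)[[1L]]
  ch[320] <- setdiff(c("A", "C", "G", "T"), ch[320])[1L]  # 3'-terminal base
  tpl <- paste(ch, collapse = "")
  idx <- buildKmerIndex(c(P = p))
  h0 <- scanTemplate(tpl, idx, searchConfig(number3Errors = 0), "t")
  h1 <- scanTemplate(tpl, idx, searchConfig(number3Errors = 1), "t")
  expect_false(301L %in% GenomicRanges::start(h0))
  expect_true(301L %in% GenomicRanges::start(h1))
  expect_identical(S4Vectors::mcols(h1[GenomicRanges::start(h1) == 301L])$n3Prime, 1L)
  # probe mode ignores the 3' rule entirely
  hp <- scanTemplate(tpl, idx, searchConfig(number3Errors = 0, probeMode = TRUE), "t")
  expect_true(301L %in% GenomicRanges::start(hp))
})

test_that("stable guanine mismatches are half-weight outside the 3' window", {
  # primer with two G mismatches (duplex G:T and G:G) still passes
  # maxMismatches = 1 because each counts 0.5; a third plain mismatch kills it
  set.seed(54)
  tpl0 <- randDNA(600)
  ch <- strsplit(tpl0, "", TRUE)[[1L]]
  p <- strsplit(substr(tpl0, 201, 220), "", TRUE)[[1L]]
  p[3] <- "G"; ch[203] <- "A"   # duplex G:T
  p[8] <- "G"; ch[208] <- "C"   # duplex G:G
  tpl <- paste(ch, collapse = "")
  primer <- paste(p, collapse = "")
  h <- scanTemplate(tpl, buildKmerIndex(c(P = primer)),
                    searchConfig(maxMismatches = 1), "t")
  expect_true(201L %in% GenomicRanges::start(h))
  hit <- h[GenomicRanges::start(h) == 201L]
  expect_identical(S4Vectors::mcols(hit)$nMismatches, 2L)
  expect_equal(S4Vectors::mcols(hit)$weightedMismatches, 1.0)
  # same two substitutions but with a non-guanine mismatch added: rejected
  ch[212] <- setdiff(c("A", "C", "G", "T"), c(ch[212], "C"))[1L]
  h2 <- scanTemplate(paste(ch, collapse = ""), buildKmerIndex(c(P = primer)),
                     searchConfig(maxMismatches = 1), "t")
  expect_false(201L %in% GenomicRanges::start(h2))
})

test_that("G mismatches keep full weight inside the 3' window", {
  set.seed(55)
  tpl0 <- randDNA(600)
  ch <- strsplit(tpl0, "", TRUE)[[1L]]
  p <- strsplit(substr(tpl0, 201, 220), "", TRUE)[[1L]]
  p[17] <- "G"; ch[217] <- "A"  # stable duplex, but inside the last 7
  tpl <- paste(ch, collapse = "")
  h <- scanTemplate(tpl, buildKmerIndex(c(P = paste(p, collapse = ""))),
                    searchConfig(), "t")
  hit <- h[GenomicRanges::start(h) == 201L]
  expect_equal(S4Vectors::mcols(hit)$weightedMismatches, 1.0)
  expect_identical(S4Vectors::mcols(hit)$n3Prime, 1L)
})

test_that("mismatch budget is monotone in both thresholds", {
  set.seed(56)
  for (i in 1:10) {
    inst <- genInstance(5600 + i)
    idx <- buildKmerIndex(inst$primers)
    keysByMM <- lapply(1:3, function(mm)
      pkgHitKeys(scanTemplate(inst$template, idx,
                              searchConfig(maxMismatches = mm,
                                           number3Errors = 1), "t")))
    # raising maxMismatches never removes a hit locus
    startsOf <- function(keys) unique(vapply(strsplit(keys, "|", fixed = TRUE),
                                             function(x) paste(x[1:3], collapse = "|"), ""))
    expect_true(all(startsOf(keysByMM[[1]]) %in% startsOf(keysByMM[[2]])))
    expect_true(all(startsOf(keysByMM[[2]]) %in% startsOf(keysByMM[[3]])))
  }
})

test_that("scanning is strand-symmetric under template reverse complement", {
  set.seed(57)
  for (i in 1:10) {
    inst <- genInstance(5700 + i, minN = 400L, maxN = 800L)
    idx <- buildKmerIndex(inst$primers)
    cfg <- searchConfig()
    n <- nchar(inst$template)
    h <- scanTemplate(inst$template, idx, cfg, "t")
    hr <- scanTemplate(reverseComplementSeq(inst$template), idx, cfg, "t")
    mirror <- function(gr) {
      if (!length(gr)) return(character())
      sort(sprintf("%s|%s|%d|%d",
                   S4Vectors::mcols(gr)$primer,
                   chartr("+-", "-+", as.character(GenomicRanges::strand(gr))),
                   n - GenomicRanges::end(gr) + 1L,
                   S4Vectors::mcols(gr)$nMismatches))
    }
    direct <- function(gr) {
      if (!length(gr)) return(character())
      sort(sprintf("%s|%s|%d|%d",
                   S4Vectors::mcols(gr)$primer,
                   as.character(GenomicRanges::strand(gr)),
                   GenomicRanges::start(gr),
                   S4Vectors::mcols(gr)$nMismatches))
    }
    expect_identical(mirror(hr), direct(h))
  }
})

test_that("circular hits equal doubled-linear hits with starts inside L", {
  set.seed(58)
  for (i in 1:8) {
    tpl <- randDNA(900)
    p <- substr(paste0(tpl, tpl), 880, 899)  # site spanning the origin
    idx <- buildKmerIndex(c(P = p))
    hC <- scanTemplate(tpl, idx, searchConfig(topology = "circular"), "t")
    hD <- scanTemplate(paste0(tpl, tpl), idx, searchConfig(), "t")
    hD <- hD[GenomicRanges::start(hD) <= 900L]
    expect_identical(pkgHitKeys(hC), pkgHitKeys(hD))
    expect_true(880L %in% GenomicRanges::start(hC))
  }
})

test_that("templates shorter than k warn and return no hits", {
  idx <- buildKmerIndex(c(P = "ACGTACGTACGTACGTACGT"))
  expect_warning(h <- scanTemplate("ACGT", idx, searchConfig(), "tiny"),
                 "shorter than k")
  expect_identical(length(h), 0L)
})

test_that("template N matches everything at half weight, never counted 3'", {
  set.seed(59)
  tpl0 <- randDNA(600)
  ch <- strsplit(tpl0, "", TRUE)[[1L]]
  p <- substr(tpl0, 201, 220)
  ch[c(203, 206, 210, 213)] <- "N"   # 4 N = weight 2.0, at the budget
  h <- scanTemplate(paste(ch, collapse = ""), buildKmerIndex(c(P = p)),
                    searchConfig(number3Errors = 0), "t")
  hit <- h[GenomicRanges::start(h) == 201L &
             as.character(GenomicRanges::strand(h)) == "+"]
  expect_identical(length(hit), 1L)
  expect_identical(S4Vectors::mcols(hit)$nMismatches, 0L)
  expect_equal(S4Vectors::mcols(hit)$weightedMismatches, 2.0)
  ch[216] <- "N"                     # 5th N exceeds the budget
  h2 <- scanTemplate(paste(ch, collapse = ""), buildKmerIndex(c(P = p)),
                     searchConfig(number3Errors = 0), "t")
  expect_false(any(GenomicRanges::start(h2) == 201L &
                     as.character(GenomicRanges::strand(h2)) == "+"))
})
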