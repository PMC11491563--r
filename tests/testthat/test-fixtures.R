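test_that("instances regenerate byte-identically from their seed", {
  a <- plantSites(5000, nPairs = 3, mismatches = 2, threePrimeMismatches = 1,
                  seed = 81)
  b <- plantSites(5000, nPairs = 3, mismatches = 2, threePrimeMismatches = 1,
                  seed = 81)
  expect_identical(a@template, b@template)
  expect_identical(as.character(a@primers), as.character(b@primers))
  expect_identical(a@truthAmplicons, b@truthAmplicons)
  c <- plantSites(5000, nPairs = 3, mismatches = 2, threePrimeMismatches = 1,
                  seed = 82)
  expect_false(identical(a@template, c@template))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(83)
  x1 <- runif(1)
  set.seed(83)
  invisible(plantSites(2000, nPairs = 1, seed = 99))
  expect_identical(runif(1), x1)
})

test_that("planted mismatch counts and 3'-window placements are honored", {
  inst <- plantSites(6000, nPairs = 3, mismatches = 2,
                     threePrimeMismatches = 1, seed = 84)
  th <- inst@truthHits
  expect_true(all(th$nMismatches == 2L))
  expect_true(all(th$n3Prime == 1L))
  # the scan agrees position by position
  h <- scanTemplate(inst@template, buildKmerIndex(inst@primers),
                    searchConfig(), inst@templateId)
  mc <- S4Vectors::mcols(h)
  got <- mc[order(GenomicRanges::start(h)), ]
  th <- th[order(th$start), ]
  expect_identical(got$nMismatches, th$nMismatches)
  expect_identical(got$n3Prime, th$n3Prime)
  expect_equal(got$weightedMismatches, th$weightedMismatches)
})

test_that("requested stable-G substitutions carry half weight", {
  inst <- plantSites(6000, nPairs = 2, mismatches = 2, gType = TRUE,
                     seed = 85)
  expect_true(all(inst@truthHits$weightedMismatches == 1.0))
  h <- scanTemplate(inst@template, buildKmerIndex(inst@primers),
                    searchConfig(maxMismatches = 1), inst@templateId)
  expect_identical(length(h), nrow(inst@truthHits))
})

test_that("infeasible packings are refused", {
  expect_error(plantSites(300, nPairs = 5, seed = 86), "infeasible packing")
})

test_that("degenerate stress truth is recovered, including 3'-terminal N", {
  for (seed in c(87, 88, 89)) {
    d <- degenerateStress(seed)
    h <- scanTemplate(d@template, buildKmerIndex(d@primers),
                      searchConfig(number3Errors = 0), d@templateId)
    mc <- S4Vectors::mcols(h)
    got <- sprintf("%s|%d|%d", mc$primer, GenomicRanges::start(h),
                   mc$nMismatches)
    want <- sprintf("%s|%d|%d", d@truthHits$primer, d@truthHits$start,
                    d@truthHits$nMismatches)
    expect_identical(sort(got), sort(want))
  }
})

test_that("bisulfite planting commutes with conversion", {
  inst <- plantSites(5000, nPairs = 2, mode = "bisulfite", seed = 90)
  cfg <- searchConfig(bisulfite = TRUE)
  h <- scanTemplate(inst@template, buildKmerIndex(inst@primers), cfg,
                    inst@templateId)
  a <- pairHits(h, inst@template, cfg)
  expect_identical(GenomicRanges::start(a), inst@truthAmplicons$start)
  expect_identical(GenomicRanges::end(a), inst@truthAmplicons$end)
  expect_true(all(S4Vectors::mcols(a)$image == "plus"))
  # without bisulfite mode the converted primers do not match the template
  cfg0 <- searchConfig()
  a0 <- pairHits(scanTemplate(inst@template, buildKmerIndex(inst@primers),
                              cfg0, inst@templateId), inst@template, cfg0)
  expect_identical(length(a0), 0L)
})

test_that("zero-site instances produce zero amplicons at default stringency", {
  set.seed(91)
  for (i in 1:10) {
    tpl <- randDNA(50000)
    primers <- vapply(1:20, function(j) randDNA(18), "")
    names(primers) <- paste0("P", 1:20)
    cfg <- searchConfig()
    h <- scanTemplate(tpl, buildKmerIndex(primers), cfg, "bg")
    expect_identical(length(pairHits(h, tpl, cfg)), 0L)
  }
})
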