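## Template scan: configuration constructor and the R-facing wrapper
## around the compiled seed-and-extend core.

#' Create a search configuration
#'
#' @param k k-mer length for the seeding index (9 or 12); `NA` picks 12
#'   when the shortest primer has at least 16 nt, else 9.
#' @param maxMismatches Weighted mismatch budget over the whole primer
#'   (default 2, the usual in silico PCR convention).  Stable guanine
#'   mismatches (G:G, G:T, G:A duplexes) weigh 0.5 outside the 3' window;
#'   template N weighs 0.5; all other mismatches weigh 1.
#' @param threePrimeWindow Size of the 3'-terminal window (default 7).
#' @param number3Errors Mismatches allowed inside the 3' window (default
#'   1; set 0 to demand a perfectly matched 3' end).
#' @param minLen,maxLen Product size bounds, both primer footprints
#'   included (defaults 50 and 5000).
#' @param topology `"linear"` or `"circular"` templates.
#' @param bisulfite Search the two bisulfite-converted strand images of
#'   each template.
#' @param probeMode Report hybridisation sites without pairing; disables
#'   the 3'-end rule and the size filter.
#' @param extractSequences Attach amplified sequences to amplicons.
#' @param primerConcNM,monovalentMM Conditions for Tm calculation.
#' @param dedupByLocus One amplicon per coordinate pair even when several
#'   primer pairs produce it (default TRUE).
#' @param maxAmpliconsPerTemplate Truncation guard (default 100000).
#' @return A [SearchConfig-class].
#' @examples
#' searchConfig(number3Errors = 0, minLen = 30, maxLen = 200)
#' @export
searchConfig <- function(k = NA, maxMismatches = 2,
                         threePrimeWindow = 7, number3Errors = 1,
                         minLen = 50, maxLen = 5000,
                         topology = c("linear", "circular"),
                         bisulfite = FALSE, probeMode = FALSE,
                         extractSequences = FALSE,
                         primerConcNM = 400, monovalentMM = 50,
                         dedupByLocus = TRUE,
                         maxAmpliconsPerTemplate = 100000) {
  topology <- match.arg(topology)
  new("SearchConfig", k = as.integer(k),
      maxMismatches = as.numeric(maxMismatches),
      threePrimeWindow = as.integer(threePrimeWindow),
      number3Errors = as.integer(number3Errors),
      minLen = as.integer(minLen), maxLen = as.integer(maxLen),
      topology = topology, bisulfite = bisulfite, probeMode = probeMode,
      extractSequences = extractSequences,
      primerConcNM = as.numeric(primerConcNM),
      monovalentMM = as.numeric(monovalentMM),
      dedupByLocus = dedupByLocus,
      maxAmpliconsPerTemplate = as.integer(maxAmpliconsPerTemplate))
}

## can the half-word pigeonhole cover the whole-primer budget for this
## primer?  floor(L/k) disjoint windows hold at most 2*floor(L/k)-1 raw
## mismatches while still leaving one window with <= 1; an acceptable hit
## carries at most floor(2*maxMismatches) raw mismatches (all stable-G).
.indexGuaranteed <- function(primerLen, k, maxMismatches) {
  (primerLen %/% k) * 2L - 1L >= floor(2 * maxMismatches)
}

#' Scan one template for primer binding sites
#'
#' Slides over the template at one-nucleotide intervals, seeds candidate
#' footprints from the k-mer index (both primer orientations are stored in
#' the index, so one pass finds both strands) and verifies each candidate
#' by gap-free extension under the weighted mismatch rules and the 3'-end
#' rule.  For primers whose length cannot guarantee the seed sensitivity
#' across the full mismatch budget, every position is verified directly;
#' either way the result equals an exhaustive scan.  Circular templates
#' are scanned as the doubled sequence, keeping only footprints starting
#' in the first copy; in bisulfite mode both converted strand images are
#' scanned and each hit records which image matched.
#'
#' @param template A single sequence: character string,
#'   [Biostrings::DNAString-class], or length-1 DNAStringSet.
#' @param index A [KmerIndex-class] built with the same `k` as `cfg`.
#' @param cfg A [SearchConfig-class].
#' @param templateId Identifier for the output ranges (defaults to the
#'   template's name or `"template"`).
#' @return A [GenomicRanges::GRanges-class], one range per accepted hit
#'   (1-based inclusive footprint; `end` may exceed the template length
#'   for footprints wrapping a circular origin), with metadata columns
#'   `primer`, `nMismatches`, `weightedMismatches`, `n3Prime`,
#'   `mismatchPositions` (1-based, 5' to 3'), `tm`, `image`.
#' @export
scanTemplate <- function(template, index, cfg = searchConfig(),
                         templateId = NULL) {
  stopifnot(is(index, "KmerIndex"), is(cfg, "SearchConfig"))
  if (is(template, "DNAStringSet")) {
    if (is.null(templateId) && !is.null(names(template)))
      templateId <- names(template)[1L]
    template <- as.character(template[[1L]])
  } else if (is(template, "DNAString")) {
    template <- as.character(template)
  }
  if (is.null(templateId)) templateId <- "template"
  tpl <- normalizeSeq(template, sprintf("template '%s'", templateId),
                      onInvalid = "N")
  L <- nchar(tpl)
  emptyHits <- function() {
    gr <- GenomicRanges::GRanges(seqnames = character(), strand = character(),
                                 ranges = IRanges::IRanges())
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      primer = character(), nMismatches = integer(),
      weightedMismatches = numeric(), n3Prime = integer(),
      mismatchPositions = character(), tm = numeric(), image = character())
    gr
  }
  if (L < index@k) {
    warning(sprintf("template '%s' (%d nt) is shorter than k = %d; no hits",
                    templateId, L, index@k), call. = FALSE)
    return(emptyHits())
  }
  if (cfg@threePrimeWindow > min(Biostrings::width(index@primers)))
    stop("threePrimeWindow exceeds the shortest primer length", call. = FALSE)

  images <- if (cfg@bisulfite) {
    c(plus = bisulfiteConvert(tpl, "plus"), minus = bisulfiteConvert(tpl, "minus"))
  } else c(native = tpl)

  prPlus <- as.character(index@primers)
  prMinus <- reverseComplementSeq(index@primers)
  useIndex <- vapply(Biostrings::width(index@primers), .indexGuaranteed,
                     logical(1L), k = index@k,
                     maxMismatches = cfg@maxMismatches)
  post <- index@postings

  out <- list()
  for (img in names(images)) {
    seqText <- images[[img]]
    if (cfg@topology == "circular") seqText <- paste0(seqText, seqText)
    df <- .scanCore(seqText, prPlus, prMinus, index@k, index@half1,
                    post$key, post$primer, post$offset,
                    as.integer(post$orient == "-"),
                    cfg@maxMismatches, cfg@threePrimeWindow,
                    cfg@number3Errors, cfg@probeMode,
                    reportLimit = L, useIndex = useIndex)
    if (!nrow(df)) next
    widths <- Biostrings::width(index@primers)[df$primer]
    ## Tm of each accepted duplex: primer vs the site text in primer
    ## orientation (reverse complement of the window for minus hits)
    siteText <- substring(seqText, df$start0 + 1L, df$start0 + widths)
    tmCache <- new.env(parent = emptyenv())
    tmv <- vapply(seq_len(nrow(df)), function(i) {
      s <- siteText[i]
      if (df$strand[i] == "-") s <- reverseComplementSeq(s)
      key <- paste0(df$primer[i], "|", s)
      val <- tmCache[[key]]
      if (is.null(val)) {
        val <- nnTm(as.character(index@primers[[df$primer[i]]]), s,
                    primerConcNM = cfg@primerConcNM,
                    monovalentMM = cfg@monovalentMM)
        tmCache[[key]] <- val
      }
      val
    }, numeric(1L))
    gr <- GenomicRanges::GRanges(
      seqnames = templateId,
      ranges = IRanges::IRanges(start = df$start0 + 1L,
                                width = widths),
      strand = df$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      primer = names(index@primers)[df$primer],
      nMismatches = df$nMismatches,
      weightedMismatches = df$weightedMismatches,
      n3Prime = df$n3Prime,
      mismatchPositions = df$mismatchPositions,
      tm = tmv, image = img)
    out[[img]] <- gr
  }
  if (!length(out)) return(emptyHits())
  res <- suppressWarnings(do.call(c, unname(out)))
  res[order(GenomicRanges::start(res),
            as.character(GenomicRanges::strand(res)),
            S4Vectors::mcols(res)$primer)]
}
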