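## Pairing accepted hits into predicted PCR products; probe reporting;
## amplicon sequence extraction.

#' Pair primer hits into predicted amplicons
#'
#' Every (plus-strand, minus-strand) hit pair in convergent orientation
#' whose span falls within the configured size bounds yields one product;
#' any primer may act as forward or reverse, so multiplex panels and
#' single-primer inter-repeat fingerprinting (IRAP/ISSR/RAPD) fall out of
#' the same rule.  On circular templates pairs spanning the origin are
#' additionally enumerated (inverse PCR); such products carry
#' `wrapsOrigin = TRUE` and an `end` beyond the template length.  Product
#' length runs from the forward primer's 5' end to the reverse primer's
#' 5' end inclusive - the gel-observable size, both footprints included.
#' The annealing temperature of each product is the lower of the two hit
#' Tm values plus the natural logarithm of the product length.
#'
#' @param hitsGR Hits from [scanTemplate] for one template.
#' @param template The template sequence searched (used for its length
#'   and, when `cfg@extractSequences` is set, for sequence extraction).
#' @param cfg The [SearchConfig-class] used for the scan.
#' @return A [GenomicRanges::GRanges-class] of products sorted by start,
#'   end and primer ids, with metadata `fwdPrimer`, `revPrimer`, `length`,
#'   `fwdMismatches`, `revMismatches`, `fwdTm`, `revTm`, `ta`,
#'   `wrapsOrigin`, `image`, `allPairs` and optionally `sequence`.  When
#'   `cfg@dedupByLocus` is TRUE (default), coordinate-identical products
#'   from different primer pairs collapse to one row whose `allPairs`
#'   lists every contributing pair.
#' @export
pairHits <- function(hitsGR, template, cfg = searchConfig()) {
  if (is(template, "DNAStringSet")) template <- as.character(template[[1L]])
  if (is(template, "DNAString")) template <- as.character(template)
  template <- toupper(template)
  L <- nchar(template)
  templateId <- if (length(hitsGR)) as.character(GenomicRanges::seqnames(hitsGR))[1L]
                else "template"

  emptyAmp <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      fwdPrimer = character(), revPrimer = character(), length = integer(),
      fwdMismatches = integer(), revMismatches = integer(),
      fwdTm = numeric(), revTm = numeric(), ta = numeric(),
      wrapsOrigin = logical(), image = character(), allPairs = character())
    gr
  }
  if (!length(hitsGR) || cfg@probeMode) return(emptyAmp())

  mc <- S4Vectors::mcols(hitsGR)
  rows <- list()
  for (img in unique(mc$image)) {
    sel <- mc$image == img
    str <- as.character(GenomicRanges::strand(hitsGR))
    fwd <- which(sel & str == "+")
    rev <- which(sel & str == "-")
    if (!length(fwd) || !length(rev)) next
    fs0 <- GenomicRanges::start(hitsGR)[fwd] - 1L
    fe0 <- GenomicRanges::end(hitsGR)[fwd]
    rs0 <- GenomicRanges::start(hitsGR)[rev] - 1L
    re0 <- GenomicRanges::end(hitsGR)[rev]
    ridx <- rev
    if (cfg@topology == "circular") {
      rs0 <- c(rs0, rs0 + L)
      re0 <- c(re0, re0 + L)
      ridx <- c(rev, rev)
    }
    g <- expand.grid(f = seq_along(fwd), r = seq_along(ridx))
    len <- re0[g$r] - fs0[g$f]
    ok <- rs0[g$r] >= fs0[g$f] & re0[g$r] >= fe0[g$f] &
      len >= cfg@minLen & len <= cfg@maxLen
    if (cfg@topology == "circular") ok <- ok & len <= L
    g <- g[ok, , drop = FALSE]
    if (!nrow(g)) next
    fi <- fwd[g$f]; rI <- ridx[g$r]
    rows[[img]] <- data.frame(
      start1 = fs0[g$f] + 1L,
      end1 = re0[g$r],
      length = as.integer(re0[g$r] - fs0[g$f]),
      fwdPrimer = mc$primer[fi], revPrimer = mc$primer[rI],
      fwdMismatches = mc$nMismatches[fi], revMismatches = mc$nMismatches[rI],
      fwdTm = mc$tm[fi], revTm = mc$tm[rI],
      wrapsOrigin = re0[g$r] > L,
      image = img, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(emptyAmp())
  amp <- do.call(rbind, unname(rows))
  amp$ta <- annealingTemperature(pmin(amp$fwdTm, amp$revTm), amp$length)
  amp <- amp[order(amp$start1, amp$end1, amp$fwdPrimer, amp$revPrimer), ,
             drop = FALSE]

  pairLab <- paste0(amp$fwdPrimer, ">", amp$revPrimer)
  locus <- paste(amp$start1, amp$end1, amp$image, sep = "|")
  if (cfg@dedupByLocus) {
    allPairs <- vapply(split(pairLab, locus), function(x)
      paste(sort(unique(x)), collapse = ";"), "")
    keep <- !duplicated(locus)
    amp <- amp[keep, , drop = FALSE]
    amp$allPairs <- unname(allPairs[paste(amp$start1, amp$end1, amp$image,
                                          sep = "|")])
  } else {
    amp$allPairs <- pairLab
  }

  if (nrow(amp) > cfg@maxAmpliconsPerTemplate) {
    warning(sprintf(
      "template '%s': %d amplicons exceed the cap of %d; output truncated",
      templateId, nrow(amp), cfg@maxAmpliconsPerTemplate), call. = FALSE)
    amp <- amp[seq_len(cfg@maxAmpliconsPerTemplate), , drop = FALSE]
  }

  gr <- GenomicRanges::GRanges(
    seqnames = templateId,
    ranges = IRanges::IRanges(start = amp$start1, end = amp$end1),
    strand = "*")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    fwdPrimer = amp$fwdPrimer, revPrimer = amp$revPrimer,
    length = amp$length,
    fwdMismatches = amp$fwdMismatches, revMismatches = amp$revMismatches,
    fwdTm = amp$fwdTm, revTm = amp$revTm, ta = amp$ta,
    wrapsOrigin = amp$wrapsOrigin, image = amp$image,
    allPairs = amp$allPairs)
  if (cfg@extractSequences && length(gr))
    S4Vectors::mcols(gr)$sequence <- extractAmpliconSeq(template, gr)
  gr
}

#' Extract the amplified sequence of each product
#'
#' Returns the plus-strand residues spanned by an amplicon, concatenating
#' across the origin for products that wrap a circular template.  The
#' returned string always has exactly the amplicon's length.
#'
#' @param template Template sequence (plus strand, as searched).
#' @param ampliconsGR Products from [pairHits] on this template.
#' @return Character vector of sequences.
#' @export
extractAmpliconSeq <- function(template, ampliconsGR) {
  if (is(template, "DNAStringSet")) template <- as.character(template[[1L]])
  if (is(template, "DNAString")) template <- as.character(template)
  template <- toupper(template)
  L <- nchar(template)
  if (!length(ampliconsGR)) return(character())
  s <- GenomicRanges::start(ampliconsGR)
  e <- GenomicRanges::end(ampliconsGR)
  if (any(s < 1L | s > L | e < s | e > 2L * L))
    stop("amplicon coordinates out of range for this template (internal error)")
  doubled <- paste0(template, template)
  out <- substring(doubled, s, e)
  if (any(nchar(out) != S4Vectors::mcols(ampliconsGR)$length))
    stop("extracted length disagrees with amplicon length (internal error)")
  out
}

#' Per-hit probe report
#'
#' In probe mode hits are reported individually - no pairing, no size
#' filter: one row per hybridisation site with 1-based coordinates,
#' mismatch count and duplex Tm.
#'
#' @param hitsGR Hits from [scanTemplate].
#' @return data.frame with columns `probe`, `template`, `strand`, `start`,
#'   `end`, `mismatches`, `tm` (and `image` in bisulfite mode).
#' @export
probeReport <- function(hitsGR) {
  mc <- S4Vectors::mcols(hitsGR)
  data.frame(
    probe = as.character(mc$primer),
    template = as.character(GenomicRanges::seqnames(hitsGR)),
    strand = as.character(GenomicRanges::strand(hitsGR)),
    start = GenomicRanges::start(hitsGR),
    end = GenomicRanges::end(hitsGR),
    mismatches = mc$nMismatches,
    tm = mc$tm,
    image = as.character(mc$image),
    stringsAsFactors = FALSE)
}
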