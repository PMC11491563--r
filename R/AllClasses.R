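## Central S4 classes: SearchConfig, KmerIndex, PCRReport, PlantedInstance.

#' SearchConfig: tunables of an in silico PCR run
#'
#' Holds every knob of the search with PCR-realistic defaults: up to 2
#' weighted mismatches over the whole primer, at most 1 mismatch in the
#' last 7 bases (the 3' window), products of 50-5,000 bp, linear topology.
#'
#' @slot k k-mer length of the seeding index (9 or 12; `NA` = choose from
#'   the primer set: 12 when the shortest primer has >= 16 nt, else 9).
#' @slot maxMismatches Weighted mismatch budget over the whole primer.
#'   Stable guanine mismatches (G:G, G:T, G:A duplexes) count 0.5 outside
#'   the 3' window; template N counts 0.5; everything else counts 1.
#' @slot threePrimeWindow Length of the 3'-terminal window with its own
#'   stringency rule.
#' @slot number3Errors Mismatches permitted inside the 3' window (all at
#'   full weight there).
#' @slot minLen,maxLen Product size bounds in bp, both primer footprints
#'   included.
#' @slot topology `"linear"` or `"circular"`.
#' @slot bisulfite Search both bisulfite-converted strand images of the
#'   template instead of the native sequence.
#' @slot probeMode Report hybridisation sites only: no pairing, no size
#'   filter, 3'-end rule disabled (probes such as molecular beacons need
#'   not match at their 3' ends).
#' @slot extractSequences Attach the amplified sequence to each amplicon.
#' @slot primerConcNM,monovalentMM Primer concentration (nM) and
#'   monovalent salt (mM) for melting temperatures.
#' @slot dedupByLocus Count one amplicon per locus when several primer
#'   pairs produce identical coordinates (all contributing pairs are still
#'   listed).
#' @slot maxAmpliconsPerTemplate Safety cap against repeat-by-repeat
#'   blowups; exceeding it truncates with a warning.
#' @export
setClass("SearchConfig", representation(
  k = "integer",
  maxMismatches = "numeric",
  threePrimeWindow = "integer",
  number3Errors = "integer",
  minLen = "integer",
  maxLen = "integer",
  topology = "character",
  bisulfite = "logical",
  probeMode = "logical",
  extractSequences = "logical",
  primerConcNM = "numeric",
  monovalentMM = "numeric",
  dedupByLocus = "logical",
  maxAmpliconsPerTemplate = "integer"
))

setValidity("SearchConfig", function(object) {
  msg <- character()
  if (!is.na(object@k) && !object@k %in% c(9L, 12L))
    msg <- c(msg, "k must be 9 or 12")
  if (object@maxMismatches < 0)
    msg <- c(msg, "maxMismatches must be >= 0")
  if (object@number3Errors < 0L)
    msg <- c(msg, "number3Errors must be >= 0")
  if (object@number3Errors > object@maxMismatches)
    msg <- c(msg, "number3Errors must not exceed maxMismatches")
  if (object@minLen > object@maxLen)
    msg <- c(msg, "minLen must not exceed maxLen")
  if (!object@topology %in% c("linear", "circular"))
    msg <- c(msg, "topology must be 'linear' or 'circular'")
  if (object@threePrimeWindow < 0L)
    msg <- c(msg, "threePrimeWindow must be >= 0")
  if (length(msg)) msg else TRUE
})

#' KmerIndex: hash table of primer k-mers
#'
#' Every overlapping k-mer of every primer and of every primer's reverse
#' complement is indexed.  To tolerate one mismatch per k-mer at query
#' time, each window is split into two halves (pigeonhole: a word within
#' Hamming distance 1 of the window matches at least one half exactly) and
#' each half is stored, expanded over its degenerate positions, as a
#' concrete key.
#'
#' @slot k Window length (9 or 12).
#' @slot half1 Length of the first half (`ceiling(k/2)`).
#' @slot primers The primer set as a named [Biostrings::DNAStringSet-class]
#'   (duplicate names and duplicate sequences are allowed).
#' @slot roles `"primer"` or `"probe"` per entry.
#' @slot postings data.frame with columns `key` (half tag + concrete half
#'   word), `primer` (index into `primers`), `offset` (0-based window start
#'   within the oriented primer), `orient` (`"+"` stored as-is, `"-"`
#'   reverse complement).
#' @export
setClass("KmerIndex", representation(
  k = "integer",
  half1 = "integer",
  primers = "DNAStringSet",
  roles = "character",
  postings = "data.frame"
))

setValidity("KmerIndex", function(object) {
  msg <- character()
  if (!object@k %in% c(9L, 12L)) msg <- c(msg, "k must be 9 or 12")
  if (length(object@primers) == 0L) msg <- c(msg, "empty primer set")
  if (any(Biostrings::width(object@primers) < object@k))
    msg <- c(msg, "k exceeds the length of at least one primer")
  need <- c("key", "primer", "offset", "orient")
  if (!all(need %in% names(object@postings)))
    msg <- c(msg, "postings must have columns key/primer/offset/orient")
  if (length(msg)) msg else TRUE
})

#' PCRReport: the result of an in silico PCR run
#'
#' @slot hits [GenomicRanges::GRanges-class] of primer binding sites
#'   (1-based inclusive footprints; metadata: primer, mismatch profile,
#'   Tm, bisulfite image).
#' @slot amplicons [GenomicRanges::GRanges-class] of predicted products
#'   (empty in probe mode).
#' @slot summary Per-template-file data.frame: file, records, bases,
#'   hits, amplicons, seconds.
#' @slot config The [SearchConfig-class] used.
#' @slot templateLengths Named integer vector of template lengths.
#' @export
setClass("PCRReport", representation(
  hits = "GRanges",
  amplicons = "GRanges",
  summary = "data.frame",
  config = "SearchConfig",
  templateLengths = "integer"
))

#' PlantedInstance: a synthetic template with known ground truth
#'
#' @slot template Template sequence (plus strand, unconverted).
#' @slot templateId Identifier used in truth coordinates.
#' @slot primers Named [Biostrings::DNAStringSet-class].
#' @slot truthHits data.frame of expected binding sites (primer, strand,
#'   1-based start/end, mismatches).
#' @slot truthAmplicons data.frame of expected products (1-based start,
#'   end, length, fwdPrimer, revPrimer, wrapsOrigin).
#' @slot topology,bisulfite Template topology and whether the instance is
#'   meant to be searched in bisulfite mode.
#' @slot seed The seed that regenerates the instance byte-identically.
#' @export
setClass("PlantedInstance", representation(
  template = "character",
  templateId = "character",
  primers = "DNAStringSet",
  truthHits = "data.frame",
  truthAmplicons = "data.frame",
  topology = "character",
  bisulfite = "logical",
  seed = "integer"
))

setMethod("show", "SearchConfig", function(object) {
  cat("SearchConfig:",
      sprintf("k=%s maxMismatches=%g 3'window=%d number3Errors=%d",
              ifelse(is.na(object@k), "auto", object@k),
              object@maxMismatches, object@threePrimeWindow,
              object@number3Errors),
      sprintf("product=%d-%d bp topology=%s bisulfite=%s probeMode=%s",
              object@minLen, object@maxLen, object@topology,
              object@bisulfite, object@probeMode), sep = "\n  ")
  cat("\n")
})

setMethod("show", "KmerIndex", function(object) {
  cat(sprintf("KmerIndex: %d primer(s), k=%d (halves %d+%d), %d postings, %d keys\n",
              length(object@primers), object@k, object@half1,
              object@k - object@half1, nrow(object@postings),
              length(unique(object@postings$key))))
})

setMethod("show", "PCRReport", function(object) {
  cat(sprintf("PCRReport: %d template(s), %d primer hit(s), %d amplicon(s)%s\n",
              length(object@templateLengths), length(object@hits),
              length(object@amplicons),
              if (object@config@probeMode) " [probe mode]" else ""))
})

#' @describeIn PCRReport-class Primer/probe binding sites.
#' @param x,object A `PCRReport`.
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' @rdname PCRReport-class
#' @export
setMethod("hits", "PCRReport", function(x) x@hits)

#' @describeIn PCRReport-class Predicted products.
#' @export
setGeneric("amplicons", function(x) standardGeneric("amplicons"))

#' @rdname PCRReport-class
#' @export
setMethod("amplicons", "PCRReport", function(x) x@amplicons)

#' @describeIn PCRReport-class Per-file summary counts.
#' @export
setGeneric("runSummary", function(x) standardGeneric("runSummary"))

#' @rdname PCRReport-class
#' @export
setMethod("runSummary", "PCRReport", function(x) x@summary)
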