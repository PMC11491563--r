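## Alphabet, degeneracy, strand and bisulfite primitives.
##
## Every base (concrete or degenerate) is represented internally as a 4-bit
## mask over {A=1, C=2, G=4, T=8}; two codes "match" when their masks
## intersect.  U is normalised to T so that one alphabet serves DNA and RNA
## inputs alike.

#' @importFrom methods new validObject is setClass setGeneric setMethod slot
#' @importFrom stats runif
#' @importFrom utils write.table head
NULL

## named integer masks for the 15 IUPAC codes (plus U as an alias of T)
.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  M = 3L,  # A/C
  R = 5L,  # A/G
  W = 9L,  # A/T
  S = 6L,  # G/C
  Y = 10L, # C/T
  K = 12L, # G/T
  V = 7L,  # A/C/G
  H = 11L, # A/C/T
  D = 13L, # A/G/T
  B = 14L, # C/G/T
  N = 15L  # A/C/G/T
)

## complement of a mask: A<->T, C<->G bit swap
.maskComplement <- function(m) {
  bitwOr(bitwOr(ifelse(bitwAnd(m, 1L) > 0L, 8L, 0L),
                ifelse(bitwAnd(m, 8L) > 0L, 1L, 0L)),
         bitwOr(ifelse(bitwAnd(m, 2L) > 0L, 4L, 0L),
                ifelse(bitwAnd(m, 4L) > 0L, 2L, 0L)))
}

## mask -> canonical symbol (U never produced on output)
.MASK_SYMBOL <- character(15L)
for (.s in setdiff(names(.IUPAC_MASK), "U")) .MASK_SYMBOL[.IUPAC_MASK[[.s]]] <- .s
rm(.s)

## concrete bases denoted by each mask
.maskBases <- function(m) {
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

.charToMask <- function(chars, onInvalid = c("error", "N"), what = "sequence") {
  onInvalid <- match.arg(onInvalid)
  m <- .IUPAC_MASK[chars]
  bad <- which(is.na(m))
  if (length(bad)) {
    if (onInvalid == "error") {
      stop(sprintf("invalid character '%s' at position %d in %s",
                   chars[bad[1L]], bad[1L], what), call. = FALSE)
    }
    warning(sprintf("%d non-IUPAC character(s) in %s replaced by N (first: '%s' at position %d)",
                    length(bad), what, chars[bad[1L]], bad[1L]), call. = FALSE)
    m[bad] <- 15L
  }
  unname(m)
}

#' Normalise a nucleotide string
#'
#' Uppercases, maps U to T and either rejects non-IUPAC characters
#' (primers) or replaces them with N with a warning (templates, where
#' assemblies occasionally carry stray characters or gaps).
#'
#' @param x A single character string.
#' @param what Label used in error messages (e.g. a primer id).
#' @param onInvalid `"error"` to reject invalid characters, `"N"` to
#'   substitute them.
#' @return The normalised uppercase string.
#' @export
normalizeSeq <- function(x, what = "sequence", onInvalid = c("error", "N")) {
  onInvalid <- match.arg(onInvalid)
  x <- toupper(as.character(x))
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (!length(chars)) stop(sprintf("%s is empty", what), call. = FALSE)
  m <- .charToMask(chars, onInvalid = onInvalid, what = what)
  paste(.MASK_SYMBOL[m], collapse = "")
}

#' Do two IUPAC codes match?
#'
#' Two codes match when the base subsets they denote intersect, e.g. A
#' matches R (= A/G) but Y (= C/T) does not match R.  Vectorised over both
#' arguments; the relation is symmetric and reflexive, and N matches
#' everything.
#'
#' @param a,b Character vectors of single IUPAC symbols (case-insensitive;
#'   U is treated as T).
#' @return Logical vector.
#' @examples
#' iupacMatch("A", "R")  # TRUE
#' iupacMatch("Y", "R")  # FALSE
#' @export
iupacMatch <- function(a, b) {
  ma <- .charToMask(toupper(a), onInvalid = "error", what = "argument 'a'")
  mb <- .charToMask(toupper(b), onInvalid = "error", what = "argument 'b'")
  bitwAnd(ma, mb) > 0L
}

#' Is a duplex mismatch a stable guanine mismatch?
#'
#' The duplex pairs G:G, G:T and G:A destabilise a primer-template duplex
#' far less than other mismatches and are therefore down-weighted during
#' hit scoring.  The two arguments are the bases that face each other in
#' the duplex: the primer base and the template-strand base it is paired
#' against (for a forward hit that is the complement of the plus-strand
#' text).  Only concrete (non-degenerate) bases qualify; the pair is read
#' unordered, so (T, G) is stable just like (G, T).
#'
#' @param primerBase,templateBase Single concrete bases (A/C/G/T),
#'   vectorised.
#' @return Logical vector; `FALSE` whenever either base is degenerate or
#'   the two bases form a Watson-Crick pair.
#' @examples
#' isStableGuanineMismatch("G", "G")  # TRUE
#' isStableGuanineMismatch("A", "C")  # FALSE
#' @export
isStableGuanineMismatch <- function(primerBase, templateBase) {
  ma <- .charToMask(toupper(primerBase), "error", "primerBase")
  mb <- .charToMask(toupper(templateBase), "error", "templateBase")
  concrete <- ma %in% c(1L, 2L, 4L, 8L) & mb %in% c(1L, 2L, 4L, 8L)
  ## Watson-Crick opposition (A:T, G:C) is a match, not a mismatch
  wc <- bitwAnd(ma, .maskComplement(mb)) > 0L
  hasG <- ma == 4L | mb == 4L
  hasC <- ma == 2L | mb == 2L
  concrete & !wc & hasG & !hasC
}

#' Reverse complement of a (possibly degenerate) sequence
#'
#' Degenerate codes are complemented by subset complement (R to Y, M to K,
#' S and W to themselves, N to N); the operation is an involution.
#'
#' @param x Character vector of sequences, or a
#'   [Biostrings::DNAStringSet-class].
#' @return Character vector of reverse complements.
#' @export
reverseComplementSeq <- function(x) {
  if (is(x, "DNAStringSet") || is(x, "DNAString")) {
    return(as.character(Biostrings::reverseComplement(x)))
  }
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(vapply(x, normalizeSeq, "", what = "sequence",
                                    USE.NAMES = FALSE))))
  names(out) <- names(x)
  out
}

#' Bisulfite conversion of one template strand
#'
#' Models fully converted, CpG-methylated DNA: on the plus strand every
#' cytosine not immediately followed by G is read as T; the minus-strand
#' image (expressed in plus-strand coordinates) converts every G not
#' immediately preceded by C to A.  Output length equals input length.
#'
#' @param x A single sequence string.
#' @param strand `"plus"` or `"minus"` - which strand underwent
#'   conversion.
#' @return The converted sequence (plus-strand representation).
#' @examples
#' bisulfiteConvert("ACTC", "plus")    # "ATTT"
#' bisulfiteConvert("ACGTCG", "plus")  # unchanged, all C are CpG
#' @export
bisulfiteConvert <- function(x, strand = c("plus", "minus")) {
  strand <- match.arg(strand)
  x <- toupper(as.character(x))
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (!n) return(x)
  if (strand == "plus") {
    isC <- ch == "C"
    nextG <- c(ch[-1L] == "G", FALSE)
    ch[isC & !nextG] <- "T"
  } else {
    isG <- ch == "G"
    prevC <- c(FALSE, ch[-n] == "C")
    ch[isG & !prevC] <- "A"
  }
  paste(ch, collapse = "")
}

## expand a degenerate string into all concrete strings it denotes
.expandDegenerate <- function(x, cap = 4096L) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  masks <- .charToMask(chars, "error", x)
  sets <- lapply(masks, .maskBases)
  total <- prod(lengths(sets))
  if (total > cap) return(NULL)
  out <- ""
  for (s in sets) {
    out <- as.vector(outer(out, s, paste0))
  }
  out
}

## degeneracy (product of subset sizes) of a string
.degeneracy <- function(x) {
  prod(lengths(lapply(.charToMask(strsplit(x, "", fixed = TRUE)[[1L]],
                                  "error", x), .maskBases)))
}
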