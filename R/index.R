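## k-mer hash index over a primer set: build and query.

.halfLengths <- function(k) {
  h1 <- as.integer(ceiling(k / 2))
  c(h1, k - h1)
}

#' Choose a default k-mer length for a primer set
#'
#' 12 when the shortest primer is at least 16 nt (no sensitivity is lost
#' because queries tolerate one mismatch per k-mer), otherwise 9 so that
#' short primers (down to the 12-nt minimum) remain seedable.
#'
#' @param primers Character vector or [Biostrings::DNAStringSet-class].
#' @return 9L or 12L.
#' @export
defaultK <- function(primers) {
  w <- if (is(primers, "DNAStringSet")) Biostrings::width(primers)
       else nchar(as.character(primers))
  if (min(w) >= 16L) 12L else 9L
}

#' Build the k-mer hash index of a primer set
#'
#' Indexes every overlapping k-mer window of every primer and of every
#' primer's reverse complement, so a single pass over the template finds
#' binding sites on both strands.  Each window is stored as two half-word
#' keys (pigeonhole split): a template word within Hamming distance 1 of
#' the window matches at least one half exactly, which is how one mismatch
#' per k-mer is tolerated without enumerating mutated neighbors.
#' Degenerate half-words are expanded into all concrete keys they denote;
#' windows whose total degeneracy exceeds `4^6` expansions are indexed
#' under their less degenerate half only (with a warning) to guard against
#' unbounded blowup.  Identical windows across primers share keys, which
#' is also how repeated or near-identical sequences within the primer
#' panel are recognised.
#'
#' @param primers Named character vector, or
#'   [Biostrings::DNAStringSet-class]; unnamed entries get ids P1..Pn.
#'   Lengths must be within 12..500.
#' @param k Window length, 9 or 12 (default: [defaultK]).
#' @param roles `"primer"` or `"probe"` per entry (recycled).
#' @return A [KmerIndex-class].
#' @examples
#' idx <- buildKmerIndex(c(RTf = "CARATGGAYGTNAARAC"), k = 12)
#' idx
#' @export
buildKmerIndex <- function(primers, k = NULL, roles = "primer") {
  ids <- names(primers)
  seqs <- unname(as.character(primers))
  if (is.null(ids)) ids <- paste0("P", seq_along(seqs))
  ids[!nzchar(ids)] <- paste0("P", which(!nzchar(ids)))
  seqs <- vapply(seq_along(seqs), function(i)
    normalizeSeq(seqs[i], what = sprintf("primer '%s'", ids[i])), "")
  w <- nchar(seqs)
  if (any(w < 12L | w > 500L)) {
    bad <- which(w < 12L | w > 500L)[1L]
    stop(sprintf("primer '%s' has length %d; allowed range is 12..500",
                 ids[bad], w[bad]), call. = FALSE)
  }
  if (is.null(k)) k <- defaultK(seqs)
  k <- as.integer(k)
  if (!k %in% c(9L, 12L)) stop("k must be 9 or 12", call. = FALSE)
  if (k > min(w))
    stop(sprintf("k = %d exceeds the shortest primer length (%d)", k, min(w)),
         call. = FALSE)
  hl <- .halfLengths(k)

  keyL <- list(); primL <- integer(); offL <- integer(); oriL <- character()
  n <- 0L
  for (i in seq_along(seqs)) {
    for (ori in c("+", "-")) {
      s <- if (ori == "+") seqs[i] else reverseComplementSeq(seqs[i])
      for (o in 0:(w[i] - k)) {
        win <- substr(s, o + 1L, o + k)
        h1 <- substr(win, 1L, hl[1L])
        h2 <- substr(win, hl[1L] + 1L, k)
        halves <- list(h1, h2)
        if (.degeneracy(win) > 4096) {
          warning(sprintf(
            "primer '%s': window at offset %d exceeds 4^6 expansions; indexing its less degenerate half only",
            ids[i], o), call. = FALSE)
          keep <- which.min(c(.degeneracy(h1), .degeneracy(h2)))
          halves[[setdiff(1:2, keep)]] <- NA_character_
        }
        for (h in 1:2) {
          if (is.na(halves[[h]])) next
          exp <- .expandDegenerate(halves[[h]])
          if (is.null(exp)) next  # unreachable for halves <= 6 nt; belt and braces
          n <- n + 1L
          keyL[[n]] <- paste0(h, ":", exp)
          primL <- c(primL, rep.int(i, length(exp)))
          offL <- c(offL, rep.int(o, length(exp)))
          oriL <- c(oriL, rep.int(ori, length(exp)))
        }
      }
    }
  }
  postings <- data.frame(key = unlist(keyL), primer = primL,
                         offset = offL, orient = oriL,
                         stringsAsFactors = FALSE)
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  new("KmerIndex", k = k, half1 = hl[1L], primers = dss,
      roles = rep_len(roles, length(seqs)), postings = postings)
}

#' Query the index with a concrete template word
#'
#' Returns every posting whose stored primer window lies within Hamming
#' distance 1 of `word` under IUPAC subset-match semantics, each
#' (primer, offset, orientation) at most once.  Candidates are gathered by
#' exact lookup of the word's two halves and then verified against the
#' full (possibly degenerate) primer window.
#'
#' @param index A [KmerIndex-class].
#' @param word Concrete k-mer (A/C/G/T only) from the template.
#' @return data.frame with columns `primer` (id), `primerIndex`, `offset`,
#'   `orient`.
#' @export
queryKmerIndex <- function(index, word) {
  word <- normalizeSeq(word, "word")
  k <- index@k
  if (nchar(word) != k) stop(sprintf("word must have length k = %d", k))
  if (grepl("[^ACGT]", word)) stop("word must be concrete (A/C/G/T only)")
  h1 <- substr(word, 1L, index@half1)
  h2 <- substr(word, index@half1 + 1L, k)
  p <- index@postings
  cand <- p[p$key %in% c(paste0("1:", h1), paste0("2:", h2)), , drop = FALSE]
  cand <- unique(cand[, c("primer", "offset", "orient")])
  if (!nrow(cand)) {
    return(data.frame(primer = character(), primerIndex = integer(),
                      offset = integer(), orient = character(),
                      stringsAsFactors = FALSE))
  }
  wordChars <- strsplit(word, "", TRUE)[[1L]]
  keep <- vapply(seq_len(nrow(cand)), function(j) {
    s <- as.character(index@primers[[cand$primer[j]]])
    if (cand$orient[j] == "-") s <- reverseComplementSeq(s)
    win <- substr(s, cand$offset[j] + 1L, cand$offset[j] + k)
    sum(!iupacMatch(strsplit(win, "", TRUE)[[1L]], wordChars)) <= 1L
  }, logical(1L))
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$primer, cand$offset, cand$orient), , drop = FALSE]
  rownames(cand) <- NULL
  data.frame(primer = names(index@primers)[cand$primer],
             primerIndex = cand$primer, offset = cand$offset,
             orient = cand$orient, stringsAsFactors = FALSE)
}
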