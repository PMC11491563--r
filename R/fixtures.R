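## Seeded synthetic template/primer generator with planted ground truth.
##
## Every surface of the search (strand, topology, bisulfite images,
## mismatch placement including the 3' window and stable-G substitutions)
## can be exercised against coordinates that are known by construction,
## with no external data.  All randomness sits behind one seed; the draw
## order is: background template, per-site primers, placements, mismatch
## offsets, substitution bases.

## pick a template base realising a planted mismatch against primer base
## `p` at a site of the given strand.  wantStable selects a stable guanine
## duplex mismatch (the caller has set p so that one exists).
.mismatchBase <- function(p, strand, wantStable) {
  orientChar <- if (strand == "+") p else .MASK_SYMBOL[.maskComplement(.IUPAC_MASK[[p]])]
  cand <- c("A", "C", "G", "T")
  isMm <- !iupacMatch(rep(orientChar, 4L), cand)
  ## duplex-opposed pair: plus (p, comp(t)); minus (p, t)
  dup2 <- if (strand == "+") .MASK_SYMBOL[.maskComplement(.IUPAC_MASK[cand])] else cand
  st <- isStableGuanineMismatch(rep(p, 4L), dup2) & isMm
  pool <- if (wantStable) cand[st] else cand[isMm & !st]
  if (!length(pool)) stop("no substitution base available (internal)")
  sample(pool, 1L)
}

## plant one oriented footprint into a template character vector (modulo
## its length, for sites wrapping a circular origin); returns the updated
## primer, the planted mismatch bookkeeping and the mutated chars
.plantFootprint <- function(chars, L, start1, primer, strand,
                            nMismatch, n3Mismatch, gType, w3) {
  Lp <- nchar(primer)
  pch <- strsplit(primer, "", TRUE)[[1L]]
  mmPos <- integer(0)
  if (nMismatch > 0L) {
    pos3 <- (Lp - w3 + 1L):Lp
    pos5 <- 1L:(Lp - w3)
    if (n3Mismatch > length(pos3) || nMismatch - n3Mismatch > length(pos5))
      stop("more planted mismatches than available positions")
    mmPos <- c(if (n3Mismatch > 0L) sample(pos3, n3Mismatch),
               if (nMismatch - n3Mismatch > 0L)
                 sample(pos5, nMismatch - n3Mismatch))
    mmPos <- sort(mmPos)
    ## force primer bases so the requested mismatch class exists
    for (m in mmPos) pch[m] <- if (gType) "G" else sample(c("A", "T"), 1L)
  }
  primer <- paste(pch, collapse = "")
  siteText <- if (strand == "+") primer else reverseComplementSeq(primer)
  sch <- strsplit(siteText, "", TRUE)[[1L]]
  for (m in mmPos) {
    j <- if (strand == "+") m else Lp - m + 1L  # window index of primer pos m
    sch[j] <- .mismatchBase(pch[m], strand, gType)
  }
  idx <- ((start1 - 1L):(start1 + Lp - 2L)) %% L + 1L
  chars[idx] <- sch
  w <- sum(ifelse(mmPos > Lp - w3, 1, ifelse(gType, 0.5, 1)))
  list(chars = chars, primer = primer, mmPos = mmPos, weighted = w,
       n3 = sum(mmPos > Lp - w3))
}

#' Generate a planted-truth template
#'
#' Builds a uniform-random background and inserts primer binding sites at
#' recorded positions, with mismatches injected at recorded offsets.
#' Three modes:
#' \describe{
#'   \item{`pairs`}{`nPairs` convergent forward/reverse pairs (distinct
#'     primers per pair); with circular topology the last pair spans the
#'     origin.}
#'   \item{`invertedRepeat`}{one primer planted in both orientations at
#'     `nSites` positions - the single-primer inter-repeat (IRAP-style)
#'     scenario; expected products are enumerated by brute force over all
#'     convergent site pairs within `sizeBounds`.}
#'   \item{`bisulfite`}{convergent pairs whose primers are derived from
#'     the bisulfite-converted plus-strand image of the planted loci, for
#'     searching with `bisulfite = TRUE`.}
#' }
#' Regeneration with the same arguments and seed is byte-identical.
#'
#' @param templateLength Background length in bp.
#' @param nPairs Convergent pairs to plant (`pairs`/`bisulfite` modes).
#' @param nSites Sites to plant in `invertedRepeat` mode.
#' @param primerLength Planted primer length.
#' @param mismatches Mismatches per planted footprint.
#' @param threePrimeMismatches How many of them inside the 3' window.
#' @param gType Plant stable guanine mismatches (G:G/G:T/G:A duplexes)
#'   instead of ordinary ones.
#' @param topology `"linear"` or `"circular"`.
#' @param mode Planting mode, see above.
#' @param productRange Planted product length range (bp).
#' @param sizeBounds Size window used to enumerate expected
#'   inter-repeat products in `invertedRepeat` mode.
#' @param threePrimeWindow 3'-window size assumed for mismatch placement.
#' @param seed Integer seed; the instance is a pure function of it.
#' @return A [PlantedInstance-class].
#' @examples
#' inst <- plantSites(templateLength = 5000, nPairs = 3, seed = 1)
#' inst@truthAmplicons
#' @export
plantSites <- function(templateLength = 10000, nPairs = 3, nSites = 4,
                       primerLength = 20, mismatches = 0,
                       threePrimeMismatches = 0, gType = FALSE,
                       topology = c("linear", "circular"),
                       mode = c("pairs", "invertedRepeat", "bisulfite"),
                       productRange = c(120, 400),
                       sizeBounds = c(50, 5000),
                       threePrimeWindow = 7, seed) {
  topology <- match.arg(topology)
  mode <- match.arg(mode)
  if (missing(seed)) stop("a seed is required: instances are functions of it")
  stopifnot(primerLength >= 12, threePrimeMismatches <= mismatches)
  L <- as.integer(templateLength)
  w3 <- as.integer(threePrimeWindow)
  primerLength <- as.integer(primerLength)
  nPairs <- as.integer(nPairs)
  nSites <- as.integer(nSites)
  mismatches <- as.integer(mismatches)
  threePrimeMismatches <- as.integer(threePrimeMismatches)
  productRange <- as.integer(productRange)
  sizeBounds <- as.integer(sizeBounds)

  .withSeed(seed, {
    chars <- strsplit(.randomDNA(L), "", TRUE)[[1L]]
    primers <- character(0)
    hitRows <- list()
    ampRows <- list()

    if (mode %in% c("pairs", "bisulfite")) {
      wrapLast <- topology == "circular" && mode == "pairs"
      nLinear <- nPairs - as.integer(wrapLast)
      ## reserve the template head for the wrapped tail of a circular pair
      cursor <- if (wrapLast) 60L + primerLength else 1L
      place <- list()
      for (i in seq_len(nLinear)) {
        gap <- sample(30:120, 1L)
        prodLen <- sample(productRange[1L]:productRange[2L], 1L)
        a <- cursor + gap
        b <- a + prodLen - 1L
        if (b > L - (if (wrapLast) 2L * primerLength + 60L else 0L))
          stop("infeasible packing: planted sites do not fit the template")
        place[[i]] <- c(a = a, b = b)
        cursor <- b + 1L
      }
      if (wrapLast) {
        a <- L - primerLength - 40L
        tail <- sample(10:25, 1L)
        b <- L + tail + primerLength  # wrapped end
        if (nLinear > 0L && b - L >= place[[1L]][["a"]] - primerLength)
          stop("infeasible packing: wrap-around pair collides with first site")
        place[[nPairs]] <- c(a = a, b = b)
      }
      for (i in seq_len(nPairs)) {
        a <- place[[i]][["a"]]; b <- place[[i]][["b"]]
        fid <- sprintf("F%d", i); rid <- sprintf("R%d", i)
        if (mode == "pairs") {
          pf <- .plantFootprint(chars, L, a, .randomDNA(primerLength), "+",
                                mismatches, threePrimeMismatches, gType, w3)
          chars <- pf$chars
          pr <- .plantFootprint(chars, L, b - primerLength + 1L,
                                .randomDNA(primerLength), "-",
                                mismatches, threePrimeMismatches, gType, w3)
          chars <- pr$chars
          primers[fid] <- pf$primer
          primers[rid] <- pr$primer
          img <- "native"
          ## a wrap-around reverse site starting past the origin is
          ## reported at its mod-L coordinates
          rs1 <- b - primerLength + 1L; re1 <- b
          if (rs1 > L) { rs1 <- rs1 - L; re1 <- re1 - L }
          hitRows[[length(hitRows) + 1L]] <- data.frame(
            primer = c(fid, rid), strand = c("+", "-"),
            start = c(a, rs1),
            end = c(a + primerLength - 1L, re1),
            nMismatches = c(length(pf$mmPos), length(pr$mmPos)),
            weightedMismatches = c(pf$weighted, pr$weighted),
            n3Prime = c(pf$n3, pr$n3), image = img,
            stringsAsFactors = FALSE)
        } else {
          ## bisulfite: background already in place; primers are read off
          ## the converted plus image after all planting (done below)
          hitRows[[length(hitRows) + 1L]] <- data.frame(
            primer = c(fid, rid), strand = c("+", "-"),
            start = c(a, b - primerLength + 1L),
            end = c(a + primerLength - 1L, b),
            nMismatches = 0L, weightedMismatches = 0,
            n3Prime = 0L, image = "plus", stringsAsFactors = FALSE)
        }
      }
      ## ground truth products: ALL convergent site combinations within
      ## sizeBounds count, not only the designed pairs - with several
      ## pairs on one template the primer set is a multiplex panel and
      ## cross-pair products are real
      sites <- do.call(rbind, hitRows)
      plus <- sites[sites$strand == "+", , drop = FALSE]
      minus <- sites[sites$strand == "-", , drop = FALSE]
      for (i in seq_len(nrow(plus))) {
        for (j in seq_len(nrow(minus))) {
          ss <- plus$start[i]; se <- plus$end[i]
          rs <- minus$start[j]; re <- minus$end[j]
          cands <- list(c(rs, re))
          if (topology == "circular") cands <- c(cands, list(c(rs + L, re + L)))
          for (cc in cands) {
            len <- cc[2L] - ss + 1L
            if (cc[1L] >= ss && cc[2L] >= se &&
                len >= sizeBounds[1L] && len <= sizeBounds[2L] &&
                (topology == "linear" || len <= L)) {
              ampRows[[length(ampRows) + 1L]] <- data.frame(
                start = ss, end = cc[2L], length = len,
                fwdPrimer = plus$primer[i], revPrimer = minus$primer[j],
                wrapsOrigin = cc[2L] > L, stringsAsFactors = FALSE)
            }
          }
        }
      }
      if (mode == "bisulfite") {
        conv <- bisulfiteConvert(paste(chars, collapse = ""), "plus")
        for (i in seq_len(nPairs)) {
          a <- place[[i]][["a"]]; b <- place[[i]][["b"]]
          primers[sprintf("F%d", i)] <- substr(conv, a, a + primerLength - 1L)
          primers[sprintf("R%d", i)] <-
            reverseComplementSeq(substr(conv, b - primerLength + 1L, b))
        }
      }
    } else {
      ## invertedRepeat: one primer, nSites oriented copies
      primers["P"] <- .randomDNA(primerLength)
      strands <- c("+", "-", sample(c("+", "-"), max(0L, nSites - 2L),
                                    replace = TRUE))[seq_len(nSites)]
      cursor <- 1L
      starts <- integer(nSites)
      for (i in seq_len(nSites)) {
        gap <- sample(40:200, 1L)
        a <- cursor + gap
        if (a + primerLength - 1L > L)
          stop("infeasible packing: planted sites do not fit the template")
        starts[i] <- a
        pf <- .plantFootprint(chars, L, a, primers[["P"]], strands[i],
                              0L, 0L, FALSE, w3)
        chars <- pf$chars
        cursor <- a + primerLength - 1L
      }
      hitRows[[1L]] <- data.frame(
        primer = "P", strand = strands, start = starts,
        end = starts + primerLength - 1L, nMismatches = 0L,
        weightedMismatches = 0, n3Prime = 0L, image = "native",
        stringsAsFactors = FALSE)
      ## expected inter-repeat products: brute-force pair enumeration
      for (i in which(strands == "+")) {
        for (j in which(strands == "-")) {
          len <- (starts[j] + primerLength - 1L) - starts[i] + 1L
          if (starts[j] >= starts[i] && len >= sizeBounds[1L] &&
              len <= sizeBounds[2L]) {
            ampRows[[length(ampRows) + 1L]] <- data.frame(
              start = starts[i], end = starts[j] + primerLength - 1L,
              length = len, fwdPrimer = "P", revPrimer = "P",
              wrapsOrigin = FALSE, stringsAsFactors = FALSE)
          }
        }
      }
    }

    truthHits <- do.call(rbind, hitRows)
    truthAmp <- if (length(ampRows)) do.call(rbind, ampRows)
                else data.frame(start = integer(), end = integer(),
                                length = integer(), fwdPrimer = character(),
                                revPrimer = character(),
                                wrapsOrigin = logical(),
                                stringsAsFactors = FALSE)
    truthAmp <- truthAmp[order(truthAmp$start, truthAmp$end), , drop = FALSE]
    rownames(truthAmp) <- NULL
    dss <- Biostrings::DNAStringSet(primers)
    names(dss) <- names(primers)
    new("PlantedInstance",
        template = paste(chars, collapse = ""),
        templateId = sprintf("planted_seed%d", as.integer(seed)),
        primers = dss, truthHits = truthHits, truthAmplicons = truthAmp,
        topology = topology, bisulfite = mode == "bisulfite",
        seed = as.integer(seed))
  })
}

#' Degenerate-code stress instance
#'
#' A template with planted sites that exercise IUPAC degeneracy in the
#' primer set: a primer with R and Y positions planted once as a member
#' expansion (0 mismatches expected) and once with a non-member base at
#' the R site (1 mismatch expected), and a primer carrying N at its 3'
#' terminus planted over an arbitrary base (still 0 mismatches: N matches
#' everything, so it survives `number3Errors = 0`).
#'
#' @param seed Integer seed.
#' @param templateLength Background length.
#' @return A [PlantedInstance-class]; `truthHits` carries the expected
#'   mismatch counts, `truthAmplicons` is empty.
#' @export
degenerateStress <- function(seed, templateLength = 3000) {
  L <- as.integer(templateLength)
  .withSeed(seed, {
    chars <- strsplit(.randomDNA(L), "", TRUE)[[1L]]
    base <- strsplit(.randomDNA(18L), "", TRUE)[[1L]]
    p1 <- base; p1[6L] <- "R"; p1[12L] <- "Y"
    p2 <- strsplit(.randomDNA(18L), "", TRUE)[[1L]]
    p2[18L] <- "N"

    ## site 1: member expansion of p1 (R->A, Y->C): 0 mismatches
    s1 <- p1; s1[6L] <- "A"; s1[12L] <- "C"
    ## site 2: non-member base at the R position (R = A/G, plant C)
    s2 <- p1; s2[6L] <- "C"; s2[12L] <- "T"
    ## site 3: p2 with an arbitrary concrete base under the 3'-terminal N
    s3 <- p2; s3[18L] <- sample(c("A", "C", "G", "T"), 1L)

    starts <- c(101L, 801L, 1601L)
    for (i in seq_along(starts)) {
      sch <- list(s1, s2, s3)[[i]]
      chars[starts[i]:(starts[i] + 17L)] <- sch
    }
    primers <- Biostrings::DNAStringSet(c(PRY = paste(p1, collapse = ""),
                                          PN3 = paste(p2, collapse = "")))
    truthHits <- data.frame(
      primer = c("PRY", "PRY", "PN3"), strand = "+",
      start = starts, end = starts + 17L,
      nMismatches = c(0L, 1L, 0L),
      weightedMismatches = c(0, 1, 0),
      n3Prime = 0L, image = "native", stringsAsFactors = FALSE)
    new("PlantedInstance",
        template = paste(chars, collapse = ""),
        templateId = sprintf("degenerate_seed%d", as.integer(seed)),
        primers = primers, truthHits = truthHits,
        truthAmplicons = data.frame(), topology = "linear",
        bisulfite = FALSE, seed = as.integer(seed))
  })
}

#' Write a planted instance to disk
#'
#' Emits `<prefix>_template.fa`, `<prefix>_primers.fa` and
#' `<prefix>_truth.tsv` so end-to-end runs can be replayed through the
#' command-line interface.
#'
#' @param inst A [PlantedInstance-class].
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
writePlantedInstance <- function(inst, prefix) {
  tpl <- Biostrings::DNAStringSet(inst@template)
  names(tpl) <- inst@templateId
  fa <- paste0(prefix, "_template.fa")
  pf <- paste0(prefix, "_primers.fa")
  tf <- paste0(prefix, "_truth.tsv")
  Biostrings::writeXStringSet(tpl, fa)
  Biostrings::writeXStringSet(inst@primers, pf)
  write.table(inst@truthAmplicons, tf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(template = fa, primers = pf, truth = tf))
}
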