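# Independent brute-force reference for the whole search: a naive
# O(n * m) scan over every offset, primer and strand, applying the
# weighted-mismatch, 3'-window, guanine, topology and pairing rules from
# first principles.  Deliberately shares no code with the package (its
# own alphabet tables, its own reverse complement) so the two can
# disagree.

ORA_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L, M = 3L, R = 5L,
              W = 9L, S = 6L, Y = 10L, K = 12L, V = 7L, H = 11L, D = 13L,
              B = 14L, N = 15L)
ORA_SYM <- c("A", "C", "M", "G", "R", "S", "V", "T", "W", "Y", "H", "K",
             "D", "B", "N")

oraMasks <- function(s) unname(ORA_MASK[strsplit(toupper(s), "", TRUE)[[1L]]])

oraComp <- function(m) {
  bitwOr(bitwOr(ifelse(bitwAnd(m, 1L) > 0L, 8L, 0L),
                ifelse(bitwAnd(m, 8L) > 0L, 1L, 0L)),
         bitwOr(ifelse(bitwAnd(m, 2L) > 0L, 4L, 0L),
                ifelse(bitwAnd(m, 4L) > 0L, 2L, 0L)))
}

oraRC <- function(s) paste(ORA_SYM[rev(oraComp(oraMasks(s)))], collapse = "")

oraBisulfite <- function(s, strand) {
  ch <- strsplit(toupper(s), "", TRUE)[[1L]]
  n <- length(ch)
  if (strand == "plus") {
    conv <- ch == "C" & c(ch[-1L] != "G", TRUE)
    ch[conv] <- "T"
  } else {
    conv <- ch == "G" & c(TRUE, ch[-n] != "C")
    ch[conv] <- "A"
  }
  paste(ch, collapse = "")
}

# default-shaped config list for the oracle
oraCfg <- function(maxMM = 2, w3 = 7L, n3max = 1L, probe = FALSE,
                   minLen = 50L, maxLen = 5000L, topology = "linear",
                   bisulfite = FALSE) {
  list(maxMM = maxMM, w3 = w3, n3max = n3max, probe = probe,
       minLen = minLen, maxLen = maxLen, topology = topology,
       bisulfite = bisulfite)
}

# hits of one primer on one image text; start0 is 0-based on the
# (possibly doubled) image, limited to starts < reportLimit
oraScanPrimer <- function(imageText, primerText, cfg, reportLimit) {
  tm <- oraMasks(imageText)
  n <- length(tm)
  out <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") toupper(primerText) else oraRC(primerText)
    qm <- oraMasks(qs)
    L <- length(qm)
    nOff <- min(n - L + 1L, reportLimit)
    if (nOff < 1L) next
    w <- numeric(nOff); nmm <- integer(nOff); n3 <- integer(nOff)
    for (j in seq_len(L)) {
      tj <- tm[j:(j + nOff - 1L)]
      q <- qm[j]
      inter <- bitwAnd(tj, q) > 0L
      isN <- tj == 15L
      ppos <- if (strand == "+") j else L + 1L - j
      in3 <- !cfg$probe && ppos > L - cfg$w3
      qc <- q %in% c(1L, 2L, 4L, 8L)
      tc <- tj %in% c(1L, 2L, 4L, 8L)
      a <- if (strand == "+") rep.int(q, nOff) else rep.int(oraComp(q), nOff)
      b <- if (strand == "+") oraComp(tj) else tj
      stable <- qc & tc & (a == 4L | b == 4L) & !(a == 2L | b == 2L)
      mmw <- if (in3) rep.int(1, nOff) else ifelse(stable, 0.5, 1)
      w <- w + ifelse(inter, ifelse(isN, 0.5, 0), mmw)
      nmm <- nmm + as.integer(!inter)
      n3 <- n3 + as.integer(!inter & in3)
    }
    ok <- w <= cfg$maxMM + 1e-9 & (cfg$probe | n3 <= cfg$n3max)
    if (any(ok)) {
      s0 <- which(ok) - 1L
      out[[strand]] <- data.frame(strand = strand, start0 = s0,
                                  end0 = s0 + L, nmm = nmm[ok], wmm = w[ok],
                                  n3 = n3[ok], stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, unname(out)) else
    data.frame(strand = character(), start0 = integer(), end0 = integer(),
               nmm = integer(), wmm = numeric(), n3 = integer(),
               stringsAsFactors = FALSE)
}

# full oracle: hits (all primers/images) + paired amplicons (locus-dedup)
oraRun <- function(templateText, primers, cfg) {
  templateText <- gsub("[^ACGTUMRWSYKVHDBN]", "N", toupper(templateText))
  L <- nchar(templateText)
  images <- if (cfg$bisulfite) {
    c(plus = oraBisulfite(templateText, "plus"),
      minus = oraBisulfite(templateText, "minus"))
  } else c(native = templateText)
  hitRows <- list()
  for (img in names(images)) {
    txt <- images[[img]]
    if (cfg$topology == "circular") txt <- paste0(txt, txt)
    for (pid in names(primers)) {
      h <- oraScanPrimer(txt, primers[[pid]], cfg, reportLimit = L)
      if (nrow(h)) {
        h$primer <- pid
        h$image <- img
        hitRows[[length(hitRows) + 1L]] <- h
      }
    }
  }
  hits <- if (length(hitRows)) do.call(rbind, hitRows) else
    data.frame(strand = character(), start0 = integer(), end0 = integer(),
               nmm = integer(), wmm = numeric(), n3 = integer(),
               primer = character(), image = character(),
               stringsAsFactors = FALSE)

  amps <- list()
  if (!cfg$probe && nrow(hits)) {
    for (img in unique(hits$image)) {
      fw <- hits[hits$image == img & hits$strand == "+", , drop = FALSE]
      rv <- hits[hits$image == img & hits$strand == "-", , drop = FALSE]
      if (!nrow(fw) || !nrow(rv)) next
      for (i in seq_len(nrow(fw))) for (j in seq_len(nrow(rv))) {
        shifts <- if (cfg$topology == "circular") c(0L, L) else 0L
        for (sh in shifts) {
          rs <- rv$start0[j] + sh; re <- rv$end0[j] + sh
          len <- re - fw$start0[i]
          if (rs >= fw$start0[i] && re >= fw$end0[i] &&
              len >= cfg$minLen && len <= cfg$maxLen &&
              (cfg$topology == "linear" || len <= L)) {
            amps[[length(amps) + 1L]] <- data.frame(
              start1 = fw$start0[i] + 1L, end1 = re, length = len,
              image = img, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  amp <- if (length(amps)) unique(do.call(rbind, amps)) else
    data.frame(start1 = integer(), end1 = integer(), length = integer(),
               image = character(), stringsAsFactors = FALSE)
  list(hits = hits, amplicons = amp)
}

# canonical string forms for set comparison against package output
oraHitKeys <- function(hits) {
  sort(sprintf("%s|%s|%d|%d|%.1f|%d|%s", hits$primer, hits$strand,
               hits$start0 + 1L, hits$nmm, hits$wmm, hits$n3, hits$image))
}

pkgHitKeys <- function(gr) {
  if (!length(gr)) return(character())
  mc <- S4Vectors::mcols(gr)
  sort(sprintf("%s|%s|%d|%d|%.1f|%d|%s", mc$primer,
               as.character(GenomicRanges::strand(gr)),
               GenomicRanges::start(gr), mc$nMismatches,
               mc$weightedMismatches, mc$n3Prime, mc$image))
}

oraAmpKeys <- function(amp) {
  sort(sprintf("%d|%d|%s", amp$start1, amp$end1, amp$image))
}

pkgAmpKeys <- function(gr) {
  if (!length(gr)) return(character())
  mc <- S4Vectors::mcols(gr)
  sort(sprintf("%d|%d|%s", GenomicRanges::start(gr),
               GenomicRanges::end(gr), mc$image))
}
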