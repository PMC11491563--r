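# Randomized instance generator for oracle-equivalence testing: random
# backgrounds with primer copies (mutated, either strand, possibly
# overlapping) written in at random offsets, degenerate positions in
# primers, stray degenerate characters in templates.  No ground truth is
# recorded - the brute-force oracle is the referee.

DEGEN_CODES <- c("M", "R", "W", "S", "Y", "K", "V", "H", "D", "B", "N")

randDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# sample one concrete expansion of a degenerate primer
concretize <- function(s) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", M = c("A", "C"),
               R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
               Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
               H = c("A", "C", "T"), D = c("A", "G", "T"),
               B = c("C", "G", "T"), N = c("A", "C", "G", "T"))
  ch <- strsplit(s, "", TRUE)[[1L]]
  paste(vapply(ch, function(c) sample(sets[[c]], 1L), ""), collapse = "")
}

genInstance <- function(seed, minN = 500L, maxN = 1500L) {
  set.seed(seed)
  n <- sample(minN:maxN, 1L)
  tpl <- strsplit(randDNA(n), "", TRUE)[[1L]]
  np <- sample(2:4, 1L)
  primers <- character(np)
  for (i in seq_len(np)) {
    Lp <- sample(c(12:24, 27:36), 1L)
    p <- strsplit(randDNA(Lp), "", TRUE)[[1L]]
    if (runif(1) < 0.3) {
      k <- sample(1:3, 1L)
      pos <- sample(Lp, min(k, Lp))
      p[pos] <- sample(DEGEN_CODES, length(pos), TRUE)
    }
    primers[i] <- paste(p, collapse = "")
  }
  names(primers) <- paste0("P", seq_len(np))
  # plant mutated copies
  for (i in seq_len(np)) {
    if (runif(1) >= 0.7) next
    for (cp in seq_len(sample(1:2, 1L))) {
      site <- concretize(primers[[i]])
      nm <- sample(0:3, 1L)
      if (nm > 0L) {
        ch <- strsplit(site, "", TRUE)[[1L]]
        pos <- sample(length(ch), nm)
        ch[pos] <- sample(c("A", "C", "G", "T"), nm, TRUE)
        site <- paste(ch, collapse = "")
      }
      if (runif(1) < 0.5) site <- paste(rev(strsplit(chartr("ACGT", "TGCA", site),
                                                     "", TRUE)[[1L]]), collapse = "")
      a <- sample(n - nchar(site), 1L)
      tpl[a:(a + nchar(site) - 1L)] <- strsplit(site, "", TRUE)[[1L]]
    }
  }
  # stray degenerate characters in the template
  if (runif(1) < 0.3) {
    pos <- sample(n, sample(1:5, 1L))
    tpl[pos] <- sample(c("N", "R", "Y", "S"), length(pos), TRUE)
  }
  list(template = paste(tpl, collapse = ""), primers = primers, n = n)
}
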