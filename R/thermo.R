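## Nearest-neighbor duplex thermodynamics and the annealing-temperature rule.
##
## Unified nearest-neighbor parameter set (10 Watson-Crick stacks,
## initiation terms split by terminal A/T vs G/C, symmetry correction for
## self-complementary oligos).  dH in kcal/mol, dS in cal/(mol K).

.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, AC = -8.4, AG = -7.8, TC = -8.2, TG = -8.5,
            CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, AC = -22.4, AG = -21.0, TC = -22.2, TG = -22.7,
            CC = -19.9)
.NN_INIT_AT <- c(dH = 2.3, dS = 4.1)
.NN_INIT_GC <- c(dH = 0.1, dS = -2.8)
.GAS_CONSTANT <- 1.987  # cal/(mol K)

## mean init contribution over concrete expansions of a terminal base
.initTerm <- function(baseMask) {
  bases <- .maskBases(baseMask)
  at <- bases %in% c("A", "T")
  c(dH = mean(ifelse(at, .NN_INIT_AT["dH"], .NN_INIT_GC["dH"])),
    dS = mean(ifelse(at, .NN_INIT_AT["dS"], .NN_INIT_GC["dS"])))
}

#' Nearest-neighbor melting temperature of a primer-site duplex
#'
#' Sums unified nearest-neighbor enthalpy/entropy over all dinucleotide
#' stacks of the duplex formed by `primer` annealed to a template site.
#' `site` is given in the primer's orientation: the text a perfectly
#' matching primer would be identical to (for a minus-strand hit, the
#' reverse complement of the plus-strand window).  Stacks in which either
#' position is mismatched contribute dH = dS = 0 (pure destabilisation by
#' lost pairing); positions where primer or site carry degenerate codes
#' contribute the arithmetic mean of dH and dS over their concrete
#' expansions at that stack.  Entropy is salt-corrected by
#' `0.368 * (L - 1) * ln[Na+]` and the duplex is scored at primer excess,
#' `Tm = dH / (dS + R ln C)` with `C` the primer concentration.
#'
#' @param primer Primer sequence (IUPAC codes allowed).
#' @param site Template site in primer orientation; defaults to `primer`
#'   (perfect duplex).
#' @param primerConcNM Primer concentration in nM (default 400, a typical
#'   PCR recipe).
#' @param monovalentMM Monovalent salt in mM (default 50).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' nnTm("AGCGTTGACCTAGGCATTCA")
#' @export
nnTm <- function(primer, site = primer, primerConcNM = 400,
                 monovalentMM = 50) {
  primer <- normalizeSeq(primer, "primer")
  site <- normalizeSeq(site, "site")
  L <- nchar(primer)
  if (nchar(site) != L) stop("primer and site must have equal length")
  if (L < 8L) stop("duplex shorter than 8 nt: nearest-neighbor model not valid")
  pm <- .charToMask(strsplit(primer, "", TRUE)[[1L]], "error", "primer")
  sm <- .charToMask(strsplit(site, "", TRUE)[[1L]], "error", "site")

  concreteStack <- pm %in% c(1L, 2L, 4L, 8L) & sm %in% c(1L, 2L, 4L, 8L)
  dH <- 0; dS <- 0
  for (i in seq_len(L - 1L)) {
    if (concreteStack[i] && concreteStack[i + 1L]) {
      # fast path: fully concrete stack
      if (pm[i] == sm[i] && pm[i + 1L] == sm[i + 1L]) {
        stack <- paste0(.MASK_SYMBOL[pm[i]], .MASK_SYMBOL[pm[i + 1L]])
        dH <- dH + .NN_DH[[stack]]
        dS <- dS + .NN_DS[[stack]]
      }
      next
    }
    p1 <- .maskBases(pm[i]);  p2 <- .maskBases(pm[i + 1L])
    s1 <- .maskBases(sm[i]);  s2 <- .maskBases(sm[i + 1L])
    combos <- expand.grid(p1 = p1, p2 = p2, s1 = s1, s2 = s2,
                          stringsAsFactors = FALSE)
    matched <- combos$p1 == combos$s1 & combos$p2 == combos$s2
    stack <- paste0(combos$p1, combos$p2)
    dH <- dH + mean(ifelse(matched, .NN_DH[stack], 0))
    dS <- dS + mean(ifelse(matched, .NN_DS[stack], 0))
  }
  iniL <- .initTerm(pm[1L]); iniR <- .initTerm(pm[L])
  dH <- dH + iniL[["dH"]] + iniR[["dH"]]
  dS <- dS + iniL[["dS"]] + iniR[["dS"]]
  ## symmetry correction for self-complementary oligos
  if (primer == reverseComplementSeq(primer)) dS <- dS - 1.4

  dS <- dS + 0.368 * (L - 1L) * log(monovalentMM / 1000)
  conc <- primerConcNM * 1e-9
  dH * 1000 / (dS + .GAS_CONSTANT * log(conc)) - 273.15
}

#' PCR annealing temperature
#'
#' The annealing temperature of a product is taken as the melting
#' temperature of the less stable primer plus the natural logarithm of
#' the product length: `Ta = min(Tm) + ln(L)`.
#'
#' @param tmMin Lowest primer Tm of the pair, in Celsius.
#' @param productLength Product length in bp (>= 1).
#' @return Annealing temperature in Celsius.
#' @examples
#' annealingTemperature(60, 1)    # 60
#' annealingTemperature(55, 500)  # 61.21
#' @export
annealingTemperature <- function(tmMin, productLength) {
  if (any(productLength < 1)) stop("productLength must be >= 1")
  tmMin + log(productLength)
}
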