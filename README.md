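# insilicoPCR

In silico PCR for genome-scale primer and probe analysis: given one or
more DNA templates (up to whole genomes, as multi-record FASTA) and a
panel of primers or probes, the package predicts every PCR product the
panel can form — for standard two-primer PCR, multiplex panels, inverse
PCR on circular templates, bisulfite PCR, and single-primer inter-repeat
fingerprinting (IRAP/ISSR/RAPD), where one oligo complementary to a
dispersed repeat amplifies the stretches between neighboring inverted
copies. It is written for people who validate primers against genomes,
mine repeats (MITEs, LTR retrotransposons) with conserved-motif primers,
or simulate fingerprinting gels before running them.

## Method

**Binding-site search.** Primer binding sites are found by a k-mer hash
seed-and-extend scan. All overlapping k-mers (k = 9 or 12) of every
primer *and* of every primer's reverse complement are stored in a hash
table, each k-mer split into two half-words (pigeonhole: a template word
within Hamming distance 1 of a stored k-mer matches at least one half
exactly, so one mismatch per k-mer is tolerated without enumerating
neighbors). The template is traversed at one-nucleotide intervals —
no template index is ever built, so memory scales with the primer panel —
and every seeded candidate is verified by gap-free extension of the full
primer footprint. For primers too short for the seed guarantee to cover
the whole-primer mismatch budget, every position is verified directly;
either way the reported hit set is exactly the exhaustive-scan semantics.

**Mismatch model.** A hit is accepted when its weighted mismatch count is
at most `maxMismatches` (default 2) and the number of mismatches in the
3′-terminal window (default: last 7 nt) is at most `number3Errors`
(default 1) — 3′ mismatches are what actually stop polymerase extension,
and a run with `number3Errors = 0` demands a perfectly matched 3′ end.
Stable guanine mismatches (duplexes G·G, G·T, G·A) weigh only 0.5 outside
the 3′ window; template `N` matches everything at weight 0.5; IUPAC
degenerate codes in primer *or* template match by subset intersection
(R matches A or G, etc.). Probe mode reports hybridization sites without
pairing and disables the 3′ rule (molecular beacons are not complementary
at their termini).

**Products and temperatures.** Every convergent (plus-hit, minus-hit)
pair within the size bounds (default 50–5,000 bp, both primer footprints
included — the gel-observable size) is an amplicon; on circular templates
pairs spanning the origin are enumerated too. Per-duplex melting
temperatures come from unified nearest-neighbor thermodynamics
(ΔH°/ΔS° sums with initiation terms, entropic salt correction, primer
excess at 400 nM, 50 mM monovalent salt; degenerate positions average
over their expansions, mismatched stacks contribute no stacking energy),
and each product's annealing temperature is

```
Ta = min(Tm_fwd, Tm_rev) + ln(product length)
```

## Worked example

A synthetic template with two planted primer pairs (the generator records
ground truth, so you can check every coordinate):

```r
library(insilicoPCR)
inst <- plantSites(templateLength = 8000, nPairs = 2, seed = 12)
cfg  <- searchConfig(minLen = 100, maxLen = 1000)
rep  <- inSilicoPCR(stats::setNames(inst@template, "toy_contig"),
                    as.character(inst@primers), cfg)
rep
#> PCRReport: 1 template(s), 4 primer hit(s), 3 amplicon(s)
as.data.frame(amplicons(rep))[, c("start", "end", "fwdPrimer", "revPrimer",
                                  "length", "fwdTm", "revTm", "ta")]
#>   start end fwdPrimer revPrimer length fwdTm revTm    ta
#> 1    59 441        F1        R1    383 57.63 51.21 57.16
#> 2    59 757        F1        R2    699 57.63 49.96 56.51
#> 3   540 757        F2        R2    218 65.30 49.96 55.35
```

Three products, not two: with both pairs in one reaction the panel is a
multiplex, and F1 with R2 also forms a 699-bp product. Each row carries
the duplex Tm of both primers at their sites and the product's annealing
temperature (e.g. 51.21 + ln 383 = 57.16 °C for the first row).
`writeReportTsv()`, `writeReportText()` and `writeAmpliconFasta()`
serialize a report; `nnTm("AGCGTTGACCTAGGCATTCA")` returns 58.38 °C, the
package's fixed thermodynamic reference.

The same engine is scriptable from a shell:

```sh
ISPCR=$(Rscript -e 'cat(system.file("scripts/ispcr.R", package="insilicoPCR"))')
Rscript $ISPCR fixtures make --seed 5 --length 8000 --pairs 3 --out fx
Rscript $ISPCR search --primers fx_primers.fa --templates fx_template.fa \
        --number3errors 1 --minlen 50 --maxlen 5000 --sequence-extract --out run1
```

`--type probe`, `--circular` and `--bisulfite` switch modes;
`scripts/genome_counts.R` batches whole-genome directories against a
panel (e.g. the degenerate copia reverse-transcriptase pair shipped in
`inst/extdata/rt_primers.fa` with `--number3errors 1 --minlen 200
--maxlen 500`, or a terminal-inverted-repeat panel with `--number3errors
0 --minlen 30 --maxlen 200`). Genome assemblies are not bundled; point
the script at directories you downloaded.

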