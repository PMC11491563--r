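---
title: "In silico PCR: the search model, its parameters, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico PCR: the search model, its parameters, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insilicoPCR)
```

## The problem

PCR succeeds when two oligonucleotides hybridize to opposite strands of
a template, in convergent orientation, at a distance a polymerase can
bridge. Predicting where that happens in a genome — including imperfect,
mismatched sites, degenerate primers, repeated targets, circular
plasmids and bisulfite-converted DNA — is what this package computes.
The applications range from routine primer validation (does this pair
amplify exactly one locus?) to repeat mining (how many MITE copies does
this terminal-inverted-repeat panel pull out of a cereal genome?) and
virtual fingerprinting (which bands will a single LTR primer produce?).

## The search model

### Seeding

The primer set is indexed, not the template. Every overlapping k-mer of
every primer and of its reverse complement goes into a hash table, so a
single left-to-right pass over each template record finds both strands.
`k` is 9 or 12; by default 12 when the shortest primer has at least
16 nt and 9 otherwise, which keeps 12-nt primers (the minimum length)
seedable while giving long primers the more selective key.

One mismatch per k-mer is tolerated at query time via a pigeonhole
split: each k-mer is stored as two half-words (lengths
$\lceil k/2\rceil$ and $\lfloor k/2\rfloor$); a template word within
Hamming distance 1 of the stored k-mer must match one half exactly.
Degenerate half-words are expanded into the concrete keys they denote.
Because a half-word has at most 6 positions its expansion can never
exceed $4^6$; a whole *window* whose degeneracy product exceeds $4^6$
is nevertheless indexed under its less degenerate half only, with a
warning, as a guard against pathological all-N primers. Template
degeneracy is handled symmetrically, by expanding the queried half-words
(never more than $4^6$ lookups per half).

### Why there are two scan paths

The pigeonhole split guarantees detection of sites with **at most one
mismatch in some k-window**. The acceptance rule, however, admits up to
`maxMismatches` *weighted* mismatches over the whole primer — and since
stable guanine mismatches weigh 0.5, an acceptable site can carry up to
$2\cdot$`maxMismatches` raw mismatches. With $W = \lfloor L/k\rfloor$
disjoint windows in a primer of length $L$, any placement of $M$
mismatches leaves one window with $\le 1$ of them whenever
$M \le 2W - 1$. So the seed is provably complete only when
$\lfloor L/k \rfloor \ge \texttt{maxMismatches} + 1$ — e.g. a 36-mer at
k = 12 with the default budget of 2. For shorter primers the scanner
verifies every template position directly instead (same scoring code,
compiled, and still fast because verification abandons a site as soon as
the budget is exceeded). The result is that `scanTemplate()` returns
**exactly** the exhaustive-scan hit set for every input — the k-mer
index is an accelerator where it is sound, never an approximation. The
oracle-equivalence test (below) checks precisely this property against
an independent naive implementation.

### Scoring a candidate site

A candidate footprint is aligned gap-free (no bulges: primer-template
indels are outside the model) and scored position by position:

* match (IUPAC subsets intersect): weight 0, except template `N`,
  which "matches" everything but contributes 0.5 — otherwise assembly
  N-runs would light up wall to wall. Template `N` is never counted as
  a mismatch (in particular not against the 3′-window count).
* mismatch inside the 3′ window (`threePrimeWindow`, default 7): weight
  1 and one count against `number3Errors`. Mismatches at the 3′ end are
  what block extension, so they get no guanine discount.
* mismatch outside the 3′ window: weight 0.5 if the duplex pair is a
  stable guanine mismatch (G·G, G·T or G·A — read on the physical
  duplex, i.e. the primer base against the complement of the plus-strand
  text for a forward hit, and treated as unordered, so a T·G wobble
  counts whichever strand carries the G), else weight 1. The guanine
  rule applies only when both opposed bases are concrete; degenerate
  mismatches always weigh 1.

Accept when weighted total ≤ `maxMismatches` *and* 3′ count ≤
`number3Errors`. In probe mode the 3′ window has no special role at all
(hybridization probes need no extendable terminus): no 3′ count, and
guanine mismatches keep weight 0.5 wherever they sit.

`maxMismatches` defaults to 2, the usual electronic-PCR convention; the
ceiling is deliberately a tunable rather than a constant because
repeat-panel screens are sometimes run tighter (e.g. `number3Errors = 0`
for terminal-inverted-repeat panels) and gene-validation runs looser.

### Topologies, bisulfite, pairing

Circular templates are scanned as the doubled sequence with footprint
starts restricted to the first copy; pairing additionally considers
origin-shifted reverse hits, so inverse-PCR products that span the
origin are enumerated exactly once (product length is capped at the
template length — a product cannot wrap more than the full circle).
Coordinates are 0-based half-open internally and 1-based inclusive in
all reports; an origin-wrapping product keeps `end > L` plus a
`wrapsOrigin` flag, and sequence extraction concatenates across the
origin.

In bisulfite mode the search runs over both fully-converted strand
images of the template (plus: C→T outside CpG; minus, expressed in
plus-strand coordinates: G→A outside CpG). This models complete
conversion with methylated CpG retained; partial methylation (Y at CpG)
is not modelled. Hits and products record which image they came from and
pairs are formed within one image, as in a real bisulfite reaction where
each converted strand is its own template.

Any plus-strand hit may pair with any minus-strand hit 3′-ward of it:
multiplex panels, single-primer inter-repeat amplification and ordinary
two-primer PCR are all the same rule. All nested and overlapping
products within the size bounds are reported (fingerprinting visualizes
every band; no sub-product suppression). Coordinate-identical products
from different primer pairs collapse by default to one row listing all
contributing pairs (`dedupByLocus`), because panel screens over
near-identical repeats would otherwise count one locus dozens of times;
the toggle restores one row per pair. A configurable cap (default
100,000 products per template) guards repeat-by-repeat blowups and
truncates with a warning.

## Thermodynamics

Duplex melting temperatures use the unified nearest-neighbor parameter
set (ten Watson–Crick stacks; initiation terms split by terminal A/T vs
G/C; −1.4 cal/(mol·K) symmetry correction for self-complementary
oligos), with

$$T_m = \frac{\Delta H^\circ}{\Delta S^\circ + 0.368\,(L-1)\ln[\mathrm{Na}^+] + R \ln C_p} - 273.15$$

at primer excess, $C_p$ = 400 nM (a typical PCR recipe) and 50 mM
monovalent salt by default. Two modelling decisions are worth stating
plainly:

* **Mismatched stacks contribute ΔH = ΔS = 0.** No single-mismatch
  nearest-neighbor tables are included; a mismatch destabilizes purely
  by its lost stacking. This is conservative and strictly monotone
  (every added mismatch lowers Tm), which is the property the search
  relies on; absolute Tm values at mismatched sites will read a few
  degrees differently than mismatch-parameterized models.
* **Degenerate positions average.** Each stack containing degenerate
  primer or site bases contributes the arithmetic mean of ΔH and ΔS over
  its concrete expansions — an averaged-parameter treatment, not a
  min/max bound.

The model is refused below 8 nt, where nearest-neighbor sums are not
meaningful. Reports round temperatures to one decimal. The annealing
temperature of a product is the lower of its two primer Tm values plus
$\ln$(product length): `annealingTemperature(55, 500)` = 61.21 °C.

## The synthetic-data generator

`plantSites()` builds uniform-random A/C/G/T backgrounds and writes
primer footprints in at recorded positions: convergent pairs (products
120–400 bp by default, gaps of 30–120 bp between cassettes), an
origin-spanning pair on circular templates, single-primer inverted
repeats with brute-force-enumerated expected products, and bisulfite
instances whose primers are read off the converted plus image of the
planted loci. Mismatches are injected at recorded offsets with exact
control over 3′-window placement and guanine-type substitutions (the
generator forces a G at the primer position when a stable mismatch is
requested, and avoids template C when a plain one is). Ground truth
enumerates *all* convergent site combinations within the size bounds —
with several pairs on one template the panel is a multiplex and
cross-pair products are real. All randomness sits behind a single seed
(draw order: background, primers, placements, mismatch offsets,
substitution bases), so instances regenerate byte-identically and the
generator never perturbs the caller's RNG stream.

What the generator does **not** emulate: base composition bias, real
repeat families, tandem arrays, assembly gaps, sequencing error.
Passing planted-truth tests therefore demonstrates the search semantics
(coordinates, strands, weights, toggles) — not retrieval performance on
genomes whose repeats are more self-similar than uniform noise. On
random backgrounds an 18–24-nt primer has essentially no chance sites
at default stringency, which is what the zero-planted-site control
checks; short degenerate primers (e.g. a 15-mer with degeneracy 64) do
pick up occasional legitimate chance sites within a 2-mismatch budget,
and the test suite treats those as correct output, not noise.

## Numerical and engineering choices

* Weighted-budget comparisons use a $10^{-9}$ slack so 0.5-weight sums
  never fail on floating-point representation.
* Hit deduplication is by (primer, strand, start, image); overlapping
  hits of one primer are all kept (repeats are the point of
  fingerprinting).
* Output ordering is fully specified (template, start, end, primer ids),
  so repeated runs are byte-identical; there is no unseeded randomness
  anywhere in the engine.
* Templates are streamed record by record from an indexed FASTA
  (gzip supported); memory holds one record plus the primer index.
  Whole-record residence is the one concession — records themselves are
  not chunked, matching the common case of chromosome-sized FASTA.
* Lowercase (soft-masked) template text is searched identically to
  uppercase; primers reject non-IUPAC characters outright, while
  templates replace them with N under a warning.
* U is normalized to T on input, so RNA-style probe sequences work
  against DNA semantics.

## Test scales

The suite verifies oracle equivalence on 1,000 randomized instances
(templates 0.4–1.2 kb, panels of 2–4 primers of 12–36 nt including
degenerate codes, mixed linear/circular/bisulfite/probe configurations)
against a brute-force reference implemented independently inside the
test helpers; planted-truth recovery on ~60 generator instances across
all modes; and the fixed thermodynamic ledger. The acceptance script
replays a 300-instance oracle run, 30 planted instances, the degenerate
copia-RT cassette workflow on a 20-kb synthetic template, and a
byte-determinism check — about a minute end to end. These sizes were
chosen so the whole suite exercises every code path many times while
remaining quick enough to run on every change; the engine itself has
been run on multi-megabase inputs, where the compiled scan is the
bottleneck and scales linearly with template length times panel size.

## Known limitations

* No primer–template indels: a bulged site is invisible, by design.
* No primer *design* and no oligo quality control (hairpins,
  self-dimers, cross-dimers are out of scope; this tool searches).
* Tm at mismatched sites is conservative (see above); no
  divalent-cation or dNTP corrections.
* Genome-scale repeat counts depend on two conventions the model makes
  explicit — the whole-primer weighted mismatch ceiling and
  locus-level deduplication — and counts from tools with different
  conventions will differ accordingly; both knobs are exposed
  (`maxMismatches`, `dedupByLocus`).
* Amplification efficiency, competition and concatemer formation are
  not modelled; a predicted product is a geometric statement, not a
  band intensity.
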