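---
title: "Probe design for multiplexed FISH: models, parameters and design choices"
author: "ProbeTiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe design for multiplexed FISH: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProbeTiler)
```

# Scope

ProbeTiler designs oligonucleotide probe libraries for three families of
multiplexed FISH experiments that share a two-stage hybridization scheme:
chromatin tracing (sequential DNA FISH over many loci), RNA MERFISH
(transcripts identified by error-robust binary barcodes) and sequential
single-molecule RNA FISH. A primary probe consists of a 30-nt targeting
region plus readout overhangs; dye-labeled secondary probes bind the
readouts in successive imaging rounds. This vignette explains the models
the package implements, the parameters that matter, and the choices made
where the design space was genuinely open. It states no empirical result
that the package's own tests and acceptance script do not compute.

# Oligo generation

## The sliding-window scan

Each target is scanned from its 5' end with a window of
`windowLength` (default 30) nt. An accepted window advances the scan by a
full window length, so accepted probes tile the target without overlap;
a rejected window advances by 1 nt. Scanned oligos lie on the *same
strand as the input*; the functional probe is the reverse complement,
applied at assembly (template oligos are reverse-complemented during
probe amplification, primary-probe output is reverse-complemented
computationally).

Windows are tested in a fixed cheap-to-expensive order — alphabet (no N),
GC bounds, homopolymer run, minimum duplex Tm, hairpin stem Tm,
cross-hybridization Tm — short-circuiting at the first failure. The order
cannot change which windows pass, only which rule is reported.

## Thermodynamics

Melting temperatures follow the unified nearest-neighbor model
(SantaLucia-style dinucleotide stacks with terminal initiation terms):

$$T_m = \frac{\Delta H}{\Delta S + R\,\ln(C_T/x)} - 273.15$$

with $R = 1.987$ cal mol⁻¹ K⁻¹, $C_T$ the total probe concentration and
$x = 4$ for non-self-complementary duplexes ($x = 1$, plus the −1.4 cal
mol⁻¹ K⁻¹ symmetry entropy term, for self-complementary ones). The
defaults fix the reference condition at 1 mol/L Na⁺ — the state at which
the nearest-neighbor parameters are tabulated — so **no salt correction
is applied**, and $C_T = 10^{-6}$ mol/L. The test suite pins the
implementation against an independent summation oracle (agreement to
10⁻⁶ °C on 1000 random 20–40-mers) and against externally computed
reference values.

Default thresholds, all editable via `designParameters()` or a
name/value parameter sheet (`readParameterTable()`):

| parameter | default | meaning |
|---|---|---|
| `windowLength` | 30 nt | targeting-region length |
| `tmMin` | 66 °C | duplex Tm floor (a window at exactly 66 °C passes) |
| `gcMin`, `gcMax` | 30, 90 % | inclusive GC bounds |
| `maxRun` | 5 nt | longest tolerated homopolymer (6 identical bases reject) |
| `stemTmMax` | 76 °C | hairpin stem Tm ceiling |
| `crossHybTmMax` | 72 °C | cross-hybridization Tm ceiling |
| `naConc`, `probeConc` | 1 M, 1 µM | thermodynamic reference conditions |

## Secondary structure: a perfect-stem model

The hairpin filter enumerates every *perfect stem* — a pair of
substrings, at least 4 nt long, that are exact reverse complements and
are separated by a loop of at least 3 nt — and thresholds the maximum
duplex Tm over the stem sequences. This is a deliberate simplification
of free-energy folding: it is deterministic, has no tunable energy model
beyond the nearest-neighbor table itself, and is verifiable against a
brute-force enumeration oracle (which the test suite does). Stems with
bulges or internal mismatches are not modeled; users who need full
secondary-structure screening should tighten `stemTmMax` or pre-filter
with a dedicated folding tool.

## Cross-hybridization

A candidate is aligned locally (match +5, mismatch −4, gap opening 8,
gap extension 6, as positive costs) against every previously accepted
oligo *and* its reverse complement — probe-probe hybridization happens
between complementary strands, so checking both orientations is the
conservative choice. The exactly-matching aligned columns are
concatenated and the duplex Tm of that concatenation is thresholded.
Accepted oligos join the pool immediately, so later windows — including
windows of later targets in the same run — are screened against the whole
growing library; targets are processed in input order, which makes runs
reproducible.

Two performance notes. The alignment scoring is not part of any
published parameterization of this filter; the values are ordinary
nucleotide local-alignment defaults and are recorded in
`DesignParameters` so they can be changed. And pool members that share
no exact 8-mer with the candidate in the tested orientation are skipped
(`prescreenK`): a matched region composed entirely of sub-8-nt exact
runs sits far below the 72 °C ceiling in practice. Setting
`prescreenK = NA` forces the full alignment; the test oracle exercises
that path.

# Specificity screening

## The k-mer engine

`buildSpecificityIndex()` records every k-mer (default k = 12) of a
database; `findHits()` extends seeds from the oligo and its reverse
complement along each candidate diagonal without gaps, tolerating up to
`maxMismatch = 2` internal mismatches, and reports alignments with at
least `minMatched = 18` matching bases, merging overlapping alignments
at one locus to the best. A hit is therefore: *a diagonal carrying an
exact run of ≥ k matches whose best ≤ 2-mismatch window matches ≥ 18
bases*. The suite checks this definition exhaustively against a
position-by-position scan oracle on planted fixture databases.

These three knobs stand in for the word size/e-value/identity settings
of a BLAST-based screen, which are not part of the package's contract;
an optional BLAST+ backend (`blastn -task blastn-short -evalue 10 -dust
no`, hits filtered by the same `minMatched`) is provided for parity with
BLAST-based workflows, and a contract test asserts both backends make
identical retain/reject decisions on planted data. Note `minMatched`
also governs how near-duplicate a genomic locus must be to disqualify a
chromatin-tracing oligo (e.g. a 28/30 copy elsewhere).

## Rule sets per probe type

*Chromatin tracing.* Oligos must have **exactly one** genome alignment,
both orientations combined (the self-locus; zero hits indicates a
genome/target mismatch and is an error). With `antisenseOnly` — for
experiments that retain RNA — survivors are screened against the
*unspliced* transcriptome (strand-corrected genomic transcript spans):
no hits → keep; plus/plus hits only → keep the *reverse complement* (the
probe then targets the antisense strand and cannot bind the transcript);
plus/minus only → keep unchanged; both orientations → reject. With
`avoidExons`, any alignment to the *spliced* transcriptome (either
orientation — the conservative reading, protecting combined DNA+RNA
imaging) rejects the oligo.

*RNA FISH (MERFISH and sequential smFISH).* Oligos are screened against
the spliced transcriptome and kept only if every plus/plus hit falls on
a transcript of their own gene — plus/plus is the orientation in which
the probe (the oligo's reverse complement) binds RNA, so plus/minus
overlaps with other genes are harmless and do not disqualify. Both RNA
modes share this rule.

Input transcript ids are matched after stripping version suffixes on
both sides, and chromatin targets are 1-based inclusive coordinates
(spreadsheet style); internal arithmetic is 0-based half-open. Lowercase
(soft-masked) bases are uppercased and treated as ordinary sequence.
Targets are accepted on the plus strand only; ambiguity codes other than
N are rejected at load time because the thermodynamic tables are defined
only on A/C/G/T.

# MERFISH barcoding

## The MHD4 codebook

Barcodes are the weight-4 shell of the extended Hamming [16,11,4] code:
140 binary words, 16 bits, exactly four on-bits, minimum pairwise
Hamming distance 4 — the maximum constant-weight (16, 4, 4) code. The
construction (systematic Hamming encoding of all 2¹¹ messages, overall
parity bit, weight-4 selection, ordered by integer value) is
deterministic, and `verifyCodebook()` re-checks length, weight and all
pairwise distances exhaustively in well under a second. Capacity is
therefore 140 input genes per library. Blank/control codewords and other
code families are out of scope.

## Expression-aware rearrangement

The stated goal of rearranging codes is to reduce bit sharing among
highly expressed genes; the objective and algorithm here are the
package's own choices, since no published parameterization exists.
The objective is the sum over the 16 bit positions of the squared
expression load,
$\mathrm{cost} = \sum_b \left(\sum_{g:\,b \in cw(g)} e_g\right)^2$,
whose cross terms $2 e_g e_h$ appear exactly when two genes share a bit.
Assignment is greedy: genes in decreasing expression order (ties by gene
id) each take the unused codeword whose on-bits carry the least
accumulated load (ties by codeword index). Greedy is near-optimal, not
optimal: on a deliberately cramped 8-word sub-codebook the suite bounds
it at ≤ 1.25× the exhaustively enumerated optimum (observed ~1.11 under
equal expression), and on the full 140-word book it never exceeds the
input-order baseline across 100 random expression vectors.

## Readout triplets

Each probe of a transcript carries three of the four readouts assigned
to it — one upstream of the targeting region, two downstream. Probe $i$
(0-based, offset order) omits on-bit $i \bmod 4$ (ascending bit order),
so the four leave-one-out triplets cycle and every readout sits on three
of any four consecutive probes. Which triplet element goes upstream is
not dictated by any contract; the first (lowest remaining bit) is used,
deterministically.

# Assembly and outputs

Template oligos are `forward primer · upstream readout(s) · targeting
region · downstream readout(s) · revcomp(reverse primer)`; regions are
concatenated directly (no spacer bases — a spacer can be inserted by
editing the readout table). Primary probes are the reverse complement of
the primer-less core, and `outputMode = "primary"` omits primers
entirely. One primer pair per probe type allows separately designed
template libraries to be pooled in one oligo order and amplified
selectively. Both primers are stored 5'→3' as synthesized; the reverse
primer appears reverse-complemented in the template, the standard
template-amplification convention.

Chromatin and smFISH targets take readouts by input order (target *i* →
library entry *i*, never reused within a run; exceeding the library size
is an error that asks for additional readout sequences). The shipped
libraries — 50 chromatin readouts, 16 RNA readouts, 3 primer pairs — are
**synthetic placeholders**: deterministic sequences generated once with
a fixed seed under orthogonality constraints (no shared 12-mer in any
orientation between any two oligos in the combined set, GC 40–60%,
homopolymers ≤ 4 nt). They preserve the counts and contracts of
validated readout sets without shipping anyone's experimental sequences;
replace them via the `readouts`/`primers` paths of `runConfig()`.

`selectProbes()` subsamples evenly by offset — indices
$\mathrm{round}(i\,(m-1)/(n-1))$ over the $m$ offset-sorted candidates
($n = 1$ keeps the middle probe; requesting more than exist returns all
with a warning). Outputs are FASTA (headers
`label|offset|probe_type|readout_ids`), a per-probe CSV carrying full
provenance including both template and primary sequences, a MERFISH
codebook CSV, and a run report of per-target counts at each stage.
Tables are CSV; XLSX input is accepted through readxl where installed.

# The synthetic fixture generator

`generateFixture()` builds the data every test runs on: contigs sampled
base-wise at a target GC (default 50%), planted gene models (spliced =
strand-corrected exon concatenation, unspliced = strand-corrected
genomic span), and planted duplications copied verbatim after gene
placement. Overlaps between distinct planted features are errors;
isoforms of one gene may overlap. A truth table records every planted
feature so tests assert against the construction, not the generator's
internals, and a fixed seed reproduces a fixture byte-identically
without touching the caller's RNG stream.

What the fixtures deliberately do *not* model: repeat families,
segmental-duplication divergence, GC isochores, realistic intron/exon
statistics, or polymorphism. Passing tests therefore demonstrate that
the algorithms implement their stated rules exactly — uniqueness
screening against planted duplicates, orientation logic on planted
genes — not that any particular probe yield will be achieved on a real
genome, where repeat content dominates the uniqueness filter's behavior.
Problem sizes in the suite (mini-genomes of 2–20 kb, targets of
0.25–1.2 kb, 500-oligo oracle comparisons, a 100-kb contig for the GC
concentration check) were chosen as the smallest instances that still
exercise every rule with planted positives and negatives on both
strands.

# Numerical and degenerate-input choices

* Tm thresholds are closed on the passing side: Tm exactly `tmMin`
  passes; stem or cross-hyb Tm exactly at its ceiling passes.
* A sequence with no stem, or an empty cross-hybridization pool, scores
  −∞ and passes those filters.
* Windows containing N are rejected (the scan advances 1 nt);
  thermodynamics are undefined on N.
* Matched regions shorter than 2 nt have no defined duplex Tm and are
  treated as no cross-hybridization.
* Targets shorter than the window yield zero probes — a warning at the
  pipeline level, not an error, unless no target yields any probe.
* `round()` (banker's rounding) fixes the subsampling indices and is
  part of the documented behavior.
* Greedy codeword assignment and triplet cycling break all ties by
  index, making every pipeline stage deterministic; `runDesign()` on an
  identical configuration reproduces outputs byte for byte.

# Known limitations

* The hairpin model ignores bulged and mismatched stems (see above).
* The built-in specificity engine is ungapped; an indel-containing
  near-duplicate locus can evade it (the BLAST+ backend is gapped).
* No formamide or Mg²⁺ corrections, and no RNA:DNA hybrid
  thermodynamics — all Tm values are DNA:DNA at 1 M Na⁺.
* Whether the cross-hybridization pool should span the whole library or
  only the current target is not externally specified; the whole library
  is used, matching the growing-pool reading. Likewise no minimum gap
  beyond non-overlap is enforced between adjacent probes.
* Genome downloads, GTF feature types beyond transcript spans, and
  coordinate liftover between assemblies are out of scope.
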