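# ProbeTiler

Probe design for highly multiplexed fluorescence in situ hybridization
(FISH): chromatin tracing, RNA MERFISH, and sequential single-molecule
RNA FISH.

Multiplexed FISH experiments image hundreds of genomic loci or
transcripts by hybridizing a library of *primary probes* — each a
targeting region flanked by *readout* overhangs — and then reading the
sample out over sequential rounds with dye-labeled secondary probes.
Designing such a library means solving four problems at once, and
ProbeTiler does all of them in one pipeline:

1. **Oligo generation.** Each target sequence is tiled with a sliding
   window (default 30 nt). A window is accepted when it passes all
   physical filters; the scan then jumps one full window (adjacent,
   non-overlapping probes), otherwise it slides 1 nt. Filters: GC content
   in [30, 90]%, no homopolymer run longer than 5 nt, duplex melting
   temperature `Tm >= 66 °C`, hairpin stem `Tm <= 76 °C`, and
   cross-hybridization `Tm <= 72 °C` against every oligo already accepted
   in the library. Tm follows the unified nearest-neighbor model,

   `Tm = ΔH / (ΔS + R ln(CT / x)) − 273.15`,

   with stack and initiation ΔH, ΔS summed over the duplex, R = 1.987
   cal/(mol·K), CT = 1 µM probe, x = 4 (x = 1 with the symmetry entropy
   correction for self-complementary duplexes), at the 1 M Na⁺ reference
   state.
2. **Specificity.** A strand-aware k-mer seed-and-extend search (seed 12,
   ≤ 2 internal mismatches, ≥ 18 matched bases; all configurable) screens
   oligos against genome and transcriptome databases. Chromatin-tracing
   oligos must align exactly once in the genome; optional rules restrict
   probes to the antisense strand of genes (for RNase-free experiments)
   and reject exon overlaps (for combined DNA + RNA imaging). RNA probes
   must bind only transcript isoforms of their own gene. An optional
   BLAST+ backend (`backend = "blast"`) reproduces the same decisions
   with `blastn`.
3. **Barcoding (MERFISH).** `generateMHD4Codebook()` constructs the
   140-word MHD4 code — all weight-4 codewords of the extended Hamming
   [16,11,4] code — and `assignCodewords()` rearranges codewords by bulk
   expression so highly expressed genes share as few bits as possible.
   Each probe carries three of its transcript's four readouts, cycling
   deterministically.
4. **Assembly and export.** Template oligos
   (`forward primer + readouts + targeting region + readouts +
   revcomp(reverse primer)`) for pooled synthesis, or primer-less primary
   probes (reverse complements, ordered directly), written as FASTA plus
   a CSV provenance table and, for MERFISH, a codebook CSV.

The shipped readout and primer sets are deterministic synthetic
placeholders (50 chromatin readouts, 16 RNA readouts, 3 primer pairs;
mutually orthogonal, GC 40–60%) — substitute your validated sequences via
the editable CSV tables in `inst/extdata/`.

## Worked example

Design chromatin-tracing probes for three 800-bp loci of a synthetic
6-kb chromosome, 12 probes per locus:

```r
library(ProbeTiler)

fx <- generateFixture(seed = 42, contigLengths = c(chr19 = 6000L))
paths <- writeFixture(fx, "demo")
write.csv(data.frame(contig = "chr19",
                     start = c(501, 2501, 4501), end = c(1300, 3300, 5300),
                     label = c("TAD1", "TAD2", "TAD3")),
          "demo/targets.csv", row.names = FALSE)

cfg <- runConfig(probeType = "chromatin", genome = paths[["genome"]],
                 targets = "demo/targets.csv", outDir = "demo/probes",
                 probesPerTarget = 12, outputMode = "template")
res <- runDesign(cfg)
res$report
#>   target scanned specific selected assembled
#> 1   TAD1      26       26       12        12
#> 2   TAD2      25       25       12        12
#> 3   TAD3      26       26       12        12
```

The report counts probes per target at each stage: windows accepted by
the physical filters (`scanned`), survivors of the genome-uniqueness
screen (`specific` — here all, since the fixture genome is single-copy),
and the even-spaced subsample (`selected`). The first template oligo:

```r
res$records[1, c("target_label", "offset", "readout_ids")]
#>   target_label offset readout_ids
#> 1         TAD1      0        DR01
nchar(res$records$template_sequence[1])
#> [1] 110
```

110 nt = 20 (forward primer) + 20 (readout) + 30 (targeting region) +
20 (readout) + 20 (reverse-complemented reverse primer). All probes of a
target share one readout (`DR01` for the first target), so each locus
lights up in its own imaging round. The FASTA header carries
`label|offset|probe_type|readout`:

```
>TAD1|0|chromatin|DR01
TTGCATCCCAGATCACCTCGAACGGACGATGCGTGTATGGCCTACATCAGCACGTGCGGT...
```

For RNA designs, supply transcript targets instead
(`probeType = "merfish"` with an `expression` column, or `"smfish"`);
MERFISH runs additionally write `codebook.csv` mapping each gene to its
16-bit barcode and readout set.

A command-line wrapper with the same options ships in
`inst/scripts/design-probes.R`.

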