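---
title: "Inferring alternative genetic codes in phage genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring alternative genetic codes in phage genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagecode)
```

## The problem

Bacteria of the Candidate Phyla Radiation that use genetic code 25 read the
codon TGA as glycine; only TAA and TAG terminate translation. A phage that
infects such a host is under pressure to adopt the same code, and its genome
then carries a distinctive computational signature: open reading frames
(ORFs) called under the standard bacterial code 11 are truncated wherever an
in-frame TGA occurs, while calling under code 25 restores full-length genes.
`phagecode` turns that signature into a reproducible statistic and embeds it
in the small set of analyses that accompany it in practice: suppressor-tRNA
classification, phage/host codon-usage compatibility, CRISPR
spacer-to-protospacer matching, terminal-repeat and GC-skew checks for
genome completeness, and single-copy-marker QC for the host bins.

## ORF model

An ORF is the *maximal* open reading frame of a stop-bounded segment: from
the first in-frame start codon after the previous in-frame stop, through
the terminating stop codon. The stop codon is included in the interval and
the length; the protein excludes it. One ORF per segment — nested later
starts are not reported, so each genome yields a single well-defined ORF
count. Both strands are always scanned. Defaults follow common prokaryotic
gene-caller conventions: start codons {ATG, GTG, TTG}, minimum length 150
nt. Codons containing an ambiguous base translate to `X` and never
terminate an ORF, so ambiguity cannot create or destroy genes silently.

Circular replicons are stored linearised with a topology flag. Calling on a
circular genome of length $L$ scans the sequence **tripled** and keeps
candidates whose start falls in the middle copy: each such candidate has at
least $L$ nt of genuine sequence on both sides, so the first-start rule and
the terminating stop are decided with full circular context for any ORF of
length $\le L$, and every circular codon position maps to exactly one
middle-copy position (no deduplication step is needed, even when
$L \bmod 3 \ne 0$ and reading frames precess around the circle). Two
consequences are deliberate: ORFs longer than $L$ (a frame with no stop all
the way round) are dropped, and a candidate with no observed upstream stop
within its look-back window is dropped — both arise only in near-stop-free
sequences where "the first start after the previous stop" stops being
well defined. Origin-wrapping ORFs are reported once, at their canonical
start in $[0, L)$, with `end > L` and `wraps_origin = TRUE` (the common
convention for circular contigs, also used in the GFF3 output).

The test suite holds this implementation against an independent brute-force
oracle — enumeration over every start position with modular forward and
backward codon walks — on 200 random sequences up to 2 kb, for both tables
and both topologies, plus strand-symmetry and rotation-invariance suites.

## Code assignment

For ORFs called under table 25, the disruption statistic is
$(n, k, k/n)$: ORF count, ORFs with $\ge 1$ internal (non-terminal) TGA,
and their fraction. `assess_codes()` assigns table 25 when

* $k/n \ge$ `threshold_fraction` (default 0.10), **and**
* $\Delta = \text{density}_{25} - \text{density}_{11} \ge$ `density_margin`
  (default 0.05),

where coding density is the union length of ORF intervals divided by genome
length. Otherwise table 11 is assigned; with no TGA anywhere the two ORF
sets coincide and the lower table id wins the tie. The rationale string
always records both raw quantities, so the thresholds are a reporting
convenience, not a black box. Profile-based confirmation (predictability of
signature proteins under one code only) is out of scope here; the numeric
rule captures the same logic — code 25 "rescues" genes that code 11
truncates — in a self-contained form.

A structural property worth knowing when applying the rule: calling a
genuine code-11 genome under code 25 reads through its TGA stop codons and
opens spurious frames, but everything it can add to the coding-density
union is bounded by the genome's non-coding fraction. The density-margin
criterion therefore discriminates exactly in the compact-genome regime
(non-coding fraction below the margin) that phage genomes occupy — and that
the synthetic generator emulates. On sparse genomes the margin should be
raised or the assignment read from the raw statistics.

## The synthetic-data generator

`generate_genome()` emits a phage-like replicon with exact ground truth:
`n_orfs` forward-strand ORFs under the generating table, of which exactly
`n_orfs_with_internal_tga` carry internal TGA codons, separated by
intergenic spacers that host no ORF of their own. The contract is strict
set equality: calling ORFs on the emitted genome with the generating table
at the generator minimum (150 nt) recovers precisely the truth intervals,
on both strands, and intergenic regions contain no ORF under either
candidate table.

Design choices, in the order they matter:

* **Defaults are the study conditions.** ORF lengths 300–1200 nt (uniform
  over multiples of 3), intergenic lengths 24–48 nt, GC 0.30, circular
  topology. The intergenic default keeps the genome ~95% coding — the
  compactness typical of tailed phages, and, per the structural point
  above, the regime in which the density-margin rule is designed to
  operate. GC targeting applies to intergenic bases and codon wobble
  positions only (coding constraints dominate the first two positions), so
  low-GC targets are approximate: the realised coding GC floor is about
  1/3.
* **Flagged ORFs** receive `max(1, Binomial(n_internal, 0.03))` TGA codons
  at uniformly chosen internal positions — never the first or last codon,
  so "internal" is unambiguous — emulating code-25 genes in which a
  fraction of glycines are TGA-encoded. Unflagged ORFs are TGA-free.
* **Guard motifs.** Every intergenic region is framed by two fixed 12-mers:
  `TTATTTATTTAT` (reverse-strand stops in all three frames) at its 5' end
  and `ATAAATAAATAA` (forward stops in all three frames, the last TAA flush
  against the next ORF's ATG) at its 3' end. The guards pin the ORF
  boundaries: no reading frame can run through an intergenic region, and
  the first-start rule cannot move a truth ORF's start upstream.
* **Repair loop.** Random coding sequence still opens occasional spurious
  frames (reverse-strand or off-frame forward stretches without a stop).
  The generator calls its own ORF finder, and for each spurious ORF writes
  a stop into the offending frame via a reserved codon pair (e.g. `ATA+AGC`
  places TAA at frame offset +1 without touching the host frame's amino
  -acid validity, TGA bookkeeping, or creating new starts), choosing the
  site randomly (seeded) near the middle of the offender — a fixed site can
  oscillate when two overlapping spurious frames keep overwriting each
  other's repair stops. Purely intergenic offenders are resampled. The
  loop re-validates until the call equals the truth exactly; a spec that
  fails to validate within the iteration budget raises an infeasibility
  error rather than emitting a genome that violates its contract.
* **Determinism.** All randomness flows from `spec$seed` through R's RNG
  (saved and restored around the call); identical specs yield
  byte-identical FASTA.
* **DTRs.** With `dtr_length > 0` the circular core is emitted with its
  first `dtr_length` nt duplicated at the end, as assemblers emit
  DTR-bearing contigs; truth and round-trip contracts are defined on the
  core (trim the duplicated end before circular calling).

What the generator does **not** emulate: sequencing error, assembly
artefacts, amplification bias, real codon-usage bias beyond the wobble-GC
knob, overlapping genes, or any protein-level functional content. Passing
tests on these genomes therefore demonstrate the correctness of the
*inference machinery* — calling, counting, matching, arithmetic — not the
field behaviour of the assignment rule on noisy real assemblies.

## CRISPR arrays and spacer matching

Arrays are reconstructed from a *supplied* repeat (de novo repeat discovery
belongs to dedicated external tools): all non-overlapping occurrences
within a Hamming tolerance are found greedily left-to-right, and the
inter-repeat segments are the spacers ($R$ repeats $\Rightarrow R-1$
spacers; fewer than 2 occurrences reject the array; spacer lengths outside
15–60 nt are flagged, not dropped). At tolerance 0 a degenerate repeat copy
is unrecognised and its two flanking spacers fuse — the tests pin this
behaviour — so a tolerance of 1–2 is advisable for real arrays.

Spacer-to-protospacer matching aligns each spacer locally against both
strands of each target with BLASTn-like scoring (match 2, mismatch −3, gap
open 5, gap extend 2; masked regions, e.g. the spacer's own source array,
are N-ed out and N scores −6). Percent identity is matches over alignment
columns (gap columns included, the BLAST convention); percent coverage is
aligned spacer positions over spacer length. A hit is retained iff identity
≥ 95% and coverage ≥ 95%; ties break deterministically by target id,
leftmost coordinate, then + strand. On gap-free cases — all synthetic
fixtures — the aligner is held against a sliding-window Hamming oracle.
One subtlety is handled at the *generator* side: `implant_protospacer()`
draws substitution sites from interior spacer positions (≥ 5 nt from the
ends), because an end mutation would simply be trimmed by any local
aligner (BLAST included), changing a 1-mismatch hit from 29/30 identity
into a 29/30-coverage hit and muddying the arithmetic the retention rule
is exercised against.

## tRNAs, markers, and the remaining tracks

tRNA genes are consumed from tRNAscan-SE-like tables, not predicted. The
decoded codon is the reverse complement of the anticodon; a record is a
suppressor under a table iff its decoded codon is in that table's stop set
(so anticodon TCA: suppressor under table 11, ordinary Gly-tRNA under
table 25). Isotype labels that disagree with the decoded codon's standard
meaning are reported, never corrected. Codon-usage compatibility counts
each decoded codon in all phage and host ORFs (annotated-gene-only counting
would need annotations this package deliberately does not produce).

Marker QC is arithmetic over a named copy-count table:
$100\,|\{c\ge1\}|/m$ and $100\,|\{c\ge2\}|/m$, rounded to two decimals.
The shipped 43-name list is an explicit placeholder (standard bacterial
single-copy genes); the curated CPR-adapted list it stands in for is not
printed in public sources, and the arithmetic depends only on the set size.

GC skew is $(G-C)/(G+C)$ per window with a cumulative track; windows with
$G+C=0$ are missing (`NA`), never 0, and skip the cumulative sum. Windows
wrap on circular genomes. The window/step for a published skew figure is
rarely stated; the pipeline default (window = genome/100, step = window/2)
is an explicit free choice. Terminal-repeat detection reports the longest
exact prefix/suffix (DTR) or prefix/reverse-complement-suffix (ITR)
identity ≥ 20 nt, DTR preferred on ties.

## Numerical and interface choices

* Coordinates are 0-based half-open internally; GFF3 output converts to
  1-based inclusive. Sequences are uppercase `{A,C,G,T,N}` on read;
  IUPAC ambiguity codes collapse to N (counted, warned).
* ORF tables are plain data.frames sorted by `(start, strand)`; reports
  are JSON written via `jsonlite` with a structural validator against the
  shipped schema.
* The pipeline subcommands (`simulate`, `orfs`, `infer-code`, `trna`,
  `crispr`, `markers`, `run`) are a thin dispatcher over the exported
  functions; YAML config values override defaults and flags override
  config.
* Test problem sizes are chosen for tight feedback: oracle comparisons on
  sequences ≤ 2 kb, recovery simulations on 10-ORF genomes (100 per
  generating table), the headline disruption check on the full 65-ORF
  genome. The suite completes in about a minute on one CPU.

## Known limitations

* Only the TGA→Gly reassignment (table 25 vs 11) is modelled; other
  recodings (e.g. TAG reassignments) would need their tables added and the
  disruption statistic pointed at the right codon.
* The assignment rule is a two-threshold heuristic; on genomes with low
  coding density or very few ORFs the raw statistics should be inspected
  rather than the binary call trusted.
* `detect_terminal_repeats` finds exact repeats only; a DTR with a single
  sequencing error reports the longest exact flank instead.
* Spacer matching reports the single best hit per spacer-target pair;
  multi-copy protospacers within one target are not enumerated.
* The ORF finder is an enumerator, not a gene caller: no coding-potential
  scoring, no RBS model, no start refinement beyond the first-start rule.
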