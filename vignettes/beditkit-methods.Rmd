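---
title: "Methods: insertion-screen mapping and base-editor off-target analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: insertion-screen mapping and base-editor off-target analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beditkit)
```

## Scope and model

`beditkit` implements the desk-side analyses of a deaminase-embedding
base-editor workflow: (1) mapping random transposon insertions of a
deaminase cargo into a circular screen plasmid and locating them at
amino-acid resolution on a Cas9-nickase coding sequence; (2) quantifying
on-target base editing and indels from amplicon deep sequencing; (3)
filtering candidate transcriptome (RNA) off-target edits; (4) calling
gRNA-independent genomic off-target SNVs by three-caller consensus against
a paired control, with substitution-class summaries and fold-change
arithmetic; and (5) predicting gRNA-dependent off-target sites by
protospacer-mismatch scanning under a PAM constraint.

Raw sequencing data from such experiments is large and external; instead a
seeded generator (`make_screen_plasmid()`, `simulate_insertion_library()`,
`simulate_reads()`, `simulate_amplicon_reads()`,
`simulate_caller_outputs()`) produces every input format the pipeline
consumes along with ground truth, so each analysis stage is validated by
recovery of known simulated signal, and the worked fold-change numbers are
recomputed from the counts the source experiments report.

## Coordinates and codon logic

Nucleotide coordinates are 0-based half-open internally; amino acids and
VCF positions are reported 1-based, matching the conventions of the
formats involved. The plasmid is circular: features may span the origin
(`end > length`), and all positions are normalized to `[0, length)` via
modulo arithmetic on a virtual doubled sequence.

The selection logic of the screen rests on one codon: an
ampicillin-resistance gene is disabled by a C>T change creating a TAA
premature stop, and adenine editing of the bottom strand (A>G, i.e. T>C on
the coding strand) reverts it to CAA (glutamine).
`predict_edit_consequence()` encodes exactly this: a strand-aware
single-base change applied to one codon and translated with the standard
genetic code. Protospacer numbering is fixed with position 1 PAM-distal,
the standard base-editing convention, so "A5" means the adenine five bases
from the 5' end of the protospacer.

## The synthetic screen and what it does (not) emulate

`make_screen_plasmid()` lays out a ~3.2-kb circular plasmid with a random
nCas9-like CDS (default 300 codons), AmpR-like and KanR-like CDSs, and an
f1-like origin interval, separated by spacers; CDS bodies are drawn from
sense codons so the engineered premature stop (codon 118 of the AmpR-like
gene) is unique in its frame. `simulate_insertion_library()` draws
insertion positions uniformly (the transposition model is the unbiased
limit; a hotspot-weighted variant can be emulated by post-filtering
events), flips a fair coin for cargo orientation, and duplicates
`tsd_len = 5` bases at the insertion point — the target-site duplication
characteristic of MuA transposition; the canonical position recorded in
truth is the leftmost duplicated base. `simulate_selection()` models
ampicillin survival as: inside the CDS, in frame (insertion offset and
cargo length both multiples of 3), and accepted with probability given by
a per-residue tolerance map, standing in for the unknown biology of which
embedding sites preserve nickase function.

The read model is deliberately simple: uniform start positions,
independent substitution errors, and a two-state quality scheme (Q37 for
correct bases, Q14 for errors) — exactly enough to exercise the base
quality ≥ 30 pileup filter. PCR duplicates, quality drift along the read,
indel sequencing errors, and coverage bias are not modelled, so passing
recovery tests demonstrates correctness of the analysis logic, not
robustness to every artefact of real libraries.

Default generator sizes used in the tests and the acceptance script:
200 insertion events (recovery), 8,000 events (CDS residue-coverage
saturation), 10,000 amplicon read pairs, 200 true SNVs with 20 consensus
replicates, and a 20-kb scan genome. These are chosen as the smallest
sizes at which the binomial tolerances quoted below are meaningfully
tight.

## Insertion-site mapping

Reads are mapped to the backbone with a minimal exact-k-mer seed-and-extend
mapper (`align_to_backbone()`, default `k = 21`): the longest ungapped
exact extension of the best unique seed becomes the M block and unmatched
read ends become soft clips; ties are reported unmapped ("multi-mapping")
rather than guessed. Junction reads of an insertion therefore carry the
cargo as a terminal soft clip. `extract_softclips()` keeps terminal clips
of length ≥ 20 (left clips anchor at the alignment start, right clips at
the end of the reference span), and `call_breakpoints()` accepts a clip as
insertion evidence when its junction-proximal 15 bases exactly match a
cargo terminus in either orientation.

Two numerical details matter:

* **TSD-aware merging.** The two junctions of one event anchor `tsd_len`
  bases apart; both are normalized to the leftmost-duplicated-base
  coordinate before merging, otherwise every event would be double-counted
  as two nearby sites.
* **Junction microhomology.** When the cargo terminus happens to share its
  first bases with the backbone at the insertion point (probability 1/4
  per extra base), exact extension absorbs those bases into the M block
  and shifts the observed clip boundary outward. The cargo-end comparison
  therefore slides into the cargo by up to 10 bases, taking the smallest
  shift that matches and correcting the anchor by it. Without this,
  roughly 40% of events would be called one or more bases away from their
  true position.

With error-free junction reads these rules recover 100% of simulated
canonical positions with zero false calls, and equal an exhaustive
junction-substring search oracle; with 15 exact bases required against a
≤ 10-kb backbone, random false assignment is negligible (and asserted
empirically across seeds).

## Amplicon editing quantification

Read pairs overlapping by ≥ 11 bases are combined into a consensus read
(`merge_read_pairs()`); at disagreeing positions the higher-quality base
wins and receives quality `max − min`, so a disagreement between a Q37 and
a Q14 call yields Q23 — below the pileup threshold, which is how most
residual sequencing errors are excluded. Merged reads are aligned to the
amplicon (ungapped fast path for full-length substitution-only molecules;
Biostrings `pairwiseAlignment` for anything carrying an indel), and
`build_pileup()` counts a base only if read mapping quality ≥ 20 and base
quality ≥ 30, mirroring a `bam-readcount -q 20 -b 30` workflow. Editing is
reported per position (`conversion_rate()`, `protospacer_profile()`), not
per haplotype; co-occurrence of edits within a read is out of scope. A
depth-0 column reports `NA`, never 0, so window averages are not deflated
by missing data. For a minus-strand site the reference is walked 3'→5' with
bases complemented, making profiles strand-invariant (tested). Indel
frequency is read-level — a read counts if any I/D CIGAR operation
overlaps the protospacer interval (insertions by their insertion point,
strictly inside; deletions by reference footprint) — and ignores base
quality, since the statistic is defined on reads, while the mapping-quality
filter still applies. Both the per-position maximum and the full
per-position table are emitted; neither is privileged as "the" site rate.

## RNA off-target filtering and consensus SNV calling

`filter_rna_edits()` keeps a candidate iff depth ≥ 10, the wild-type
control supports the reference allele at ≥ 99%, and the substitution
expressed on the transcribed (annotated gene) strand is A>G (ABE mode) or
C>T (CBE mode); candidates are complemented before the test when the gene
is on the minus strand. Positions with ambiguous or overlapping gene
annotation should be dropped upstream; the filter trusts the given strand.

`goti_consensus()` intersects the per-caller variant sets on the identity
key (chrom, pos, ref, alt) — depth and quality metadata are deliberately
ignored, because callers disagree on metadata for the same event — then
subtracts the paired control sample. `classify_snvs()` collapses the 12
substitutions into 6 strand-symmetric classes; the C:G>T:A proportion is
the cytosine-deaminase signature and is reported `NA` for an empty set
(with no SNVs the proportion cannot be quantified). `fold_reduction()` is
plain count arithmetic with an infinite-reduction sentinel for a zero
denominator.

## Off-target site scanning

`predict_guide_dependent_sites()` scans both strands for 23-nt windows
whose last three bases match the PAM (N = any, R ∈ {A, G}) and whose first
20 bases match the protospacer within budget, in two modes: a total budget
(≤ 3 mismatches over the protospacer, Cas-OFFinder-style) and a seed-aware
budget (≤ 2 in the PAM-proximal seed and ≤ 3 in the remainder,
CasOT-style). The seed length is not standardized across tools; the
default of 12 PAM-proximal bases is the package's documented choice and is
exposed as a parameter. Reported positions are 0-based starts of the
23-mer in forward-genome coordinates with the strand alongside. The
scanner is validated against per-window brute-force enumeration; note the
two modes are not nested in general (a window with 0 seed and 4 non-seed
mismatches passes neither, one with 2 and 3 passes only seed-aware), so
the tests assert the defining predicate per window rather than any subset
relation.

## Reproducibility

Every generator is a pure function of its parameters and one integer seed
(`.Random.seed` is saved and restored around each call), truth objects are
serialized next to outputs, and every tabular output of `run_pipeline()`
starts with `#` header lines naming the package version, an MD5 hash of
the resolved configuration, and the seed; reruns with the same
configuration are byte-identical. The command-line front end
(`inst/cli/beditkit`) is a thin argument-parsing wrapper over
`run_pipeline()` and adds no logic of its own.

## Known limitations

* The backbone mapper is exact-match seed-and-extend: adequate for the
  synthetic error models used here, but not a general-purpose aligner
  (no gapped backbone alignment, no base-quality-aware scoring).
* Insertion calling requires junction-spanning reads with ≥ 15 exact
  cargo bases; heavily degraded junctions are reported unmapped rather
  than rescued.
* The per-residue tolerance map of the selection simulator is a free
  parameter, not an estimate of nickase-domain biology.
* Consensus calling emulates caller outputs at the set level; it does not
  reimplement any variant-calling model, and caller-specific error modes
  (alignment artefacts, strand bias) are outside the generator.
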