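# beditkit

Analysis toolkit for deaminase-embedding base-editor screens and
off-target profiling.

## The problem

Base editors couple a deaminase to a Cas9 nickase (nCas9) to install A•T→G•C
(ABE) or C•G→T•A (CBE) changes without double-strand breaks, but the free
deaminase moiety also edits RNA and, for CBEs, the genome, independent of
the guide. One route to suppressing these off-target effects is to *embed*
the deaminase inside nCas9 at insertion-tolerant sites found with a
transposon screen: a plasmid carries nCas9, a kanamycin marker, and an
ampicillin-resistance gene broken by a premature stop codon (TAA, created
from CAA by C>T); cargo is inserted at random by MuA transposition (leaving
a 5-bp target-site duplication), and only cells whose insertion preserves
editing activity can revert the stop (T>C on the coding strand, i.e. A>G on
the bottom strand) and survive ampicillin.

`beditkit` implements the computational stages of that workflow for
analysts who need them reusable and testable:

* **refmodel** — circular plasmid coordinates, features, protospacer
  numbering (position 1 = PAM-distal), codon-consequence logic
  (`translate_cds()`, `aa_position_of()`, `predict_edit_consequence()`).
* **simkit** — a seeded synthetic-data generator for every input the
  pipeline consumes (plasmid, insertion libraries, FASTQ reads, amplicon
  reads with programmed edit rates, emulated caller VCFs), always with
  ground truth.
* **insmap** — backbone mapping with soft-clip extraction and cargo
  breakpoint calling at amino-acid resolution
  (`map_insertions()`, `summarize_profile()`).
* **editquant** — amplicon editing quantification: pair merging (≥ 11-bp
  overlap), quality-filtered pileups (mapq ≥ 20, base quality ≥ 30),
  per-protospacer-position conversion rates, read-level indel frequency
  (`quantify_editing()`, `window_summary()`).
* **offtarget** — RNA edit filtering (depth ≥ 10, control reference
  fraction ≥ 0.99, transcribed-strand A>G/C>T), three-caller consensus
  SNV calling minus a paired control, substitution-class summaries,
  fold-change arithmetic, and protospacer-mismatch off-target scanning
  with an NRG/NGG PAM constraint (`filter_rna_edits()`,
  `goti_consensus()`, `classify_snvs()`, `fold_reduction()`,
  `predict_guide_dependent_sites()`).
* **cli** — `run_pipeline()` plus a thin `Rscript` front end
  (`inst/cli/beditkit`) with subcommands `simulate-library`,
  `simulate-amplicon`, `map-insertions`, `quantify-editing`,
  `filter-rna-edits`, `goti-consensus`, `predict-offtargets`, `report`.

See `vignettes/beditkit-methods.Rmd` for the models, defaults, and design
choices.

## Worked example

Simulate a small insertion screen, map the junction reads back, and call
breakpoints:

```r
library(beditkit)

plasmid <- make_screen_plasmid(seed = 42)           # ~3.2-kb circular plasmid
cargo   <- strrep("ACGGTTCA", 150)                  # 1200-nt cargo stand-in
lib     <- simulate_insertion_library(plasmid, cargo, n = 25, tsd_len = 5,
                                      seed = 7)
reads   <- simulate_junction_reads(plasmid, lib$truth, cargo, seed = 8)
calls   <- map_insertions(reads, plasmid, cargo)
head(calls, 4)
#>   position support orientations      sides aa_position in_frame
#> 1      133       2            + left,right           5    FALSE
#> 2      206       2            - left,right          29    FALSE
#> 3      267       2            - left,right          50     TRUE
#> 4      281       2            + left,right          54    FALSE
```

Each row is one insertion site: the canonical 0-based plasmid position
(leftmost base of the 5-bp duplication), the number of junction reads
supporting it, the cargo orientation(s) observed, which junction sides were
seen, and — for insertions inside the nCas9-like CDS — the 1-based residue
hit and whether the insertion is in frame. All 25 simulated positions are
recovered exactly, each from its two junction reads.

```r
summarize_profile(calls, plasmid)
#> <insertion_profile> 50 calls, 2.7% of ncas9 residues hit
#>      ncas9       ampR       kanR         f1 intergenic
#>         16         10         10          8          6
```

The selection readout of the screen is one codon:

```r
predict_edit_consequence("TAA", 1, "T>C")
#> $codon
#> [1] "CAA"
#>
#> $residue
#> [1] "Q"
```

and the off-target bottom line is count arithmetic — e.g. transcriptome
SNVs falling from 20,739 with the N-terminal ABE fusion to 88 with the
embedded editor:

```r
fold_reduction(20739, 88)
#> $ratio
#> [1] 235.6705
#>
#> $rounded
#> [1] 236
```

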