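# Synthetic screen plasmid and transposon insertion library. The generator
# emulates the all-in-one selection plasmid of an embedding screen: a
# nickase-Cas9-like CDS, a kanamycin marker, an ampicillin marker disabled by
# a C>T premature stop, and an f1-like origin region, on one circular
# molecule.

#' Build a synthetic screen plasmid
#'
#' Generates a circular plasmid carrying a random nCas9-like CDS of
#' `cds_len_aa` codons, an AmpR-like CDS whose codon 118 is a TAA premature
#' stop created by a C>T change from CAA (so reverting the first base to C
#' restores Gln), a KanR-like CDS, and an f1-like origin interval. CDS bodies
#' are drawn from sense codons only, so the premature stop is the unique stop
#' in its frame. Features are pairwise disjoint, separated by random spacers.
#'
#' @param seed Integer seed; the plasmid is a pure function of the arguments.
#' @param cds_len_aa Number of codons of the nCas9-like CDS (>= 10).
#' @param gc GC fraction for non-coding sequence.
#' @return A `plasmid_map` with features `ncas9`, `ampR`, `kanR`, `f1` and
#'   `premature_stop = list(feature = "ampR", codon = 118)`.
#' @export
make_screen_plasmid <- function(seed, cds_len_aa = 300L, gc = 0.5) {
  if (cds_len_aa < 10L) stop("cds_len_aa must be >= 10", call. = FALSE)
  with_seed(seed, {
    sense <- sense_codons()
    rand_cds <- function(n_codons) {
      paste(sample(sense, n_codons, replace = TRUE), collapse = "")
    }
    ncas9 <- rand_cds(cds_len_aa)
    ampR <- rand_cds(240L)
    # premature stop at codon 118: CAA (Gln) disabled by C>T -> TAA
    substr(ampR, 352L, 354L) <- "TAA"
    kanR <- rand_cds(200L)
    f1 <- rand_dna(400L, gc)
    spacer <- function(n) rand_dna(n, gc)
    parts <- list(spacer(120L), ncas9, spacer(100L), ampR, spacer(100L),
                  kanR, spacer(100L), f1, spacer(150L))
    widths <- vapply(parts, nchar, integer(1))
    starts <- cumsum(c(0L, widths[-length(widths)]))
    seq <- paste(unlist(parts), collapse = "")
    feats <- rbind(
      gene_feature("ncas9", starts[2L], starts[2L] + widths[2L], "+", "CDS"),
      gene_feature("ampR",  starts[4L], starts[4L] + widths[4L], "+", "CDS"),
      gene_feature("kanR",  starts[6L], starts[6L] + widths[6L], "+", "CDS"),
      gene_feature("f1",    starts[8L], starts[8L] + widths[8L], "+", "origin"))
    plasmid_map(seq, feats,
                premature_stop = list(feature = "ampR", codon = 118L))
  })
}

#' Simulate a random transposon insertion library
#'
#' Draws insertion positions uniformly over the circular plasmid. Each event
#' duplicates `tsd_len` bases flanking the insertion point (the
#' target-site duplication of MuA transposition) and inserts the cargo in a
#' random orientation. The canonical position recorded in the truth is the
#' 0-based leftmost duplicated base. Mutated molecules are returned
#' linearized starting at the first TSD copy, so each has length
#' `plasmid + cargo + tsd_len`.
#'
#' @param plasmid A `plasmid_map`.
#' @param cargo Cargo DNA string (non-empty).
#' @param n Number of insertion events (>= 1).
#' @param tsd_len Target-site duplication length (5 for MuA).
#' @param seed Integer seed.
#' @param sequences If FALSE, skip building mutated sequences (positions and
#'   truth only; useful for large statistical checks).
#' @return `list(sequences = character vector or NULL, truth = list(...))`
#'   where `truth$true_insertions` is a data.frame (position, orientation).
#' @export
simulate_insertion_library <- function(plasmid, cargo, n, tsd_len = 5L,
                                       seed = NULL, sequences = TRUE) {
  assert_dna(cargo, "cargo")
  if (nchar(cargo) == 0L) stop("cargo must be non-empty", call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  L <- plasmid$sequence$length
  with_seed(seed, {
    pos <- sample.int(L, n, replace = TRUE) - 1L
    orient <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- NULL
    if (sequences) {
      rc <- revcomp(cargo)
      seqs <- vapply(seq_len(n), function(i) {
        ins <- if (orient[i] == "+") cargo else rc
        paste0(circ_substr(plasmid$sequence, pos[i], tsd_len), ins,
               circ_substr(plasmid$sequence, pos[i], L))
      }, character(1))
    }
    truth <- list(true_insertions = data.frame(position = pos,
                                               orientation = orient,
                                               stringsAsFactors = FALSE),
                  tsd_len = as.integer(tsd_len),
                  cargo_len = nchar(cargo),
                  seed = seed)
    list(sequences = seqs, truth = truth)
  })
}

#' Simulate ampicillin selection of the insertion library
#'
#' A colony survives selection only if its insertion can still repair the
#' premature stop, modelled as: the insertion lies inside the designated CDS,
#' is in frame (nucleotide offset within the CDS and the cargo length both
#' multiples of 3), and the per-residue tolerance at its amino-acid position
#' admits activity. Events are drawn with replacement, surviving with
#' probability `tolerance[aa]`, until `n_colonies` survivors are collected.
#'
#' @param truth Truth list from [simulate_insertion_library()].
#' @param plasmid The `plasmid_map` the library was built on.
#' @param tolerance Numeric vector in `[0,1]` indexed by amino-acid position
#'   of the CDS (a per-site editing-activity tolerance map).
#' @param cargo_len Cargo length in nt.
#' @param n_colonies Number of surviving colonies to sample.
#' @param seed Integer seed.
#' @param cds_name Feature name of the CDS under selection.
#' @return data.frame of survivors (position, orientation, aa_position).
#' @export
simulate_selection <- function(truth, plasmid, tolerance, cargo_len,
                               n_colonies, seed = NULL, cds_name = "ncas9") {
  ins <- truth$true_insertions
  if (nrow(ins) == 0L) stop("no insertion events available", call. = FALSE)
  if (any(tolerance < 0) || any(tolerance > 1)) {
    stop("tolerance values must lie in [0,1]", call. = FALSE)
  }
  cds <- get_feature(plasmid, cds_name)
  L <- plasmid$sequence$length
  off <- vapply(ins$position, cds_offset, integer(1), cds = cds,
                plasmid_len = L)
  aa <- ifelse(is.na(off), NA_integer_, off %/% 3L + 1L)
  in_frame <- !is.na(off) & off %% 3L == 0L & cargo_len %% 3L == 0L
  p <- rep(0, nrow(ins))
  ok <- in_frame & !is.na(aa) & aa <= length(tolerance)
  p[ok] <- tolerance[aa[ok]]
  if (all(p == 0)) stop("no survivors: all survival probabilities are zero",
                        call. = FALSE)
  with_seed(seed, {
    survivors <- integer(0)
    while (length(survivors) < n_colonies) {
      draw <- sample.int(nrow(ins), n_colonies, replace = TRUE)
      keep <- draw[stats::runif(n_colonies) < p[draw]]
      survivors <- c(survivors, keep)
    }
    survivors <- survivors[seq_len(n_colonies)]
    data.frame(position = ins$position[survivors],
               orientation = ins$orientation[survivors],
               aa_position = aa[survivors],
               stringsAsFactors = FALSE)
  })
}
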