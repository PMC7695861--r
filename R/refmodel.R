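# Core coordinate, sequence and codon-consequence model shared by all
# pipeline stages. Nucleotide coordinates are 0-based half-open throughout;
# amino-acid positions and VCF positions are reported 1-based.

#' Circular DNA sequence
#'
#' A plasmid-style circular sequence. Indexing is modulo length; features
#' spanning the origin are handled by extraction from a virtual doubled
#' sequence with positions normalized back to `[0, length)`.
#'
#' @param seq Single string over {A,C,G,T}.
#' @return An object of class `circular_sequence` with elements `seq` and
#'   `length`.
#' @export
circular_sequence <- function(seq) {
  assert_dna(seq)
  if (nchar(seq) == 0L) stop("circular sequence must be non-empty", call. = FALSE)
  structure(list(seq = seq, length = nchar(seq)), class = "circular_sequence")
}

#' @export
print.circular_sequence <- function(x, ...) {
  cat(sprintf("<circular_sequence> %d bp\n", x$length))
  invisible(x)
}

#' Extract a subsequence from a circular sequence
#'
#' @param x A `circular_sequence` (or plain string, treated as circular).
#' @param start 0-based start position (any integer; reduced modulo length).
#' @param width Number of bases to extract, at most one full circle plus the
#'   wrap needed by origin-spanning features.
#' @return Character string of length `width`.
#' @export
circ_substr <- function(x, start, width) {
  s <- if (inherits(x, "circular_sequence")) x$seq else x
  L <- nchar(s)
  if (width < 0L || width > 2L * L) stop("invalid width", call. = FALSE)
  start <- ((start %% L) + L) %% L
  doubled <- paste0(s, s, s)
  substr(doubled, start + 1L, start + width)
}

#' Normalize a position to the canonical circular frame
#' @param pos Integer position(s).
#' @param len Sequence length.
#' @return Positions in `[0, len)`.
#' @export
normalize_pos <- function(pos, len) ((pos %% len) + len) %% len

#' Gene feature on a plasmid
#'
#' @param name Feature name (unique within a plasmid map).
#' @param start,end 0-based half-open interval on the plasmid. For features
#'   spanning the circular origin, `end` may exceed the plasmid length.
#' @param strand "+" or "-".
#' @param kind One of "CDS", "marker", "origin", "other".
#' @return A one-row data.frame.
#' @export
gene_feature <- function(name, start, end, strand = "+", kind = "CDS") {
  stopifnot(is.character(name), length(name) == 1L,
            strand %in% c("+", "-"),
            kind %in% c("CDS", "marker", "origin", "other"))
  if (start < 0L || end <= start) stop("need 0 <= start < end", call. = FALSE)
  data.frame(name = name, start = as.integer(start), end = as.integer(end),
             strand = strand, kind = kind, stringsAsFactors = FALSE)
}

feature_width <- function(feature) feature$end - feature$start

#' Plasmid map: circular sequence plus typed features
#'
#' The coordinate frame for the insertion screen. Validates that feature
#' names are unique, intervals fit the (circular) sequence, CDS lengths are
#' multiples of 3, and that the recorded premature stop, if any, really is a
#' stop codon in its feature's reading frame.
#'
#' @param sequence A `circular_sequence` or plain DNA string.
#' @param features data.frame with columns name, start, end, strand, kind
#'   (rows as produced by [gene_feature()]).
#' @param premature_stop NULL, or `list(feature = <name>, codon = <1-based
#'   codon index>)` naming a stop codon inside a CDS-frame feature.
#' @return An object of class `plasmid_map`.
#' @export
plasmid_map <- function(sequence, features, premature_stop = NULL) {
  if (!inherits(sequence, "circular_sequence")) {
    sequence <- circular_sequence(sequence)
  }
  L <- sequence$length
  stopifnot(is.data.frame(features),
            all(c("name", "start", "end", "strand", "kind") %in% names(features)))
  if (anyDuplicated(features$name)) {
    stop("feature names must be unique", call. = FALSE)
  }
  if (any(features$start < 0L) || any(features$start >= L) ||
      any(features$end <= features$start) || any(features$end > 2L * L)) {
    stop("feature intervals must satisfy 0 <= start < end <= 2*length",
         call. = FALSE)
  }
  cds <- features$kind == "CDS"
  if (any((features$end[cds] - features$start[cds]) %% 3L != 0L)) {
    stop("CDS feature length must be a multiple of 3", call. = FALSE)
  }
  obj <- structure(list(sequence = sequence, features = features,
                        premature_stop = premature_stop),
                   class = "plasmid_map")
  if (!is.null(premature_stop)) {
    codon <- feature_codon(obj, premature_stop$feature, premature_stop$codon)
    if (translate_cds(codon) != "*") {
      stop("premature_stop does not point at a stop codon", call. = FALSE)
    }
  }
  obj
}

#' @export
print.plasmid_map <- function(x, ...) {
  cat(sprintf("<plasmid_map> %d bp, %d features\n",
              x$sequence$length, nrow(x$features)))
  print(x$features)
  invisible(x)
}

get_feature <- function(plasmid, name) {
  i <- match(name, plasmid$features$name)
  if (is.na(i)) stop("no feature named '", name, "'", call. = FALSE)
  plasmid$features[i, , drop = FALSE]
}

#' Extract the spliced sequence of a feature in translation orientation
#' @param plasmid A `plasmid_map`.
#' @param name Feature name.
#' @return DNA string, reverse-complemented for minus-strand features.
#' @export
feature_seq <- function(plasmid, name) {
  f <- get_feature(plasmid, name)
  s <- circ_substr(plasmid$sequence, f$start, f$end - f$start)
  if (f$strand == "-") revcomp(s) else s
}

#' Extract one codon of a CDS-frame feature
#' @keywords internal
feature_codon <- function(plasmid, name, codon_index) {
  s <- feature_seq(plasmid, name)
  if (3L * codon_index > nchar(s)) stop("codon index beyond feature", call. = FALSE)
  substr(s, 3L * (codon_index - 1L) + 1L, 3L * codon_index)
}

#' Target site for a Cas9 base editor
#'
#' Protospacer coordinate 1 is the PAM-distal (5') base; coordinate 20 abuts
#' the PAM (the standard base-editing convention behind labels like "A5").
#'
#' @param protospacer 20-nt DNA string (protospacer-strand sequence).
#' @param pam PAM pattern, "NGG" or "NRG".
#' @param ref_name Name of the reference the site sits on.
#' @param position 0-based start of the protospacer on the reference
#'   (+ strand coordinates).
#' @param strand Strand of the protospacer on the reference.
#' @return An object of class `target_site`.
#' @export
target_site <- function(protospacer, pam = "NGG", ref_name = "amplicon",
                        position = 0L, strand = "+") {
  assert_dna(protospacer, "protospacer")
  if (nchar(protospacer) != 20L) {
    stop("protospacer must be exactly 20 nt", call. = FALSE)
  }
  stopifnot(pam %in% c("NGG", "NRG"), strand %in% c("+", "-"), position >= 0L)
  structure(list(protospacer = protospacer, pam = pam, ref_name = ref_name,
                 position = as.integer(position), strand = strand),
            class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("<target_site> %s:%d(%s) %s-%s\n", x$ref_name, x$position,
              x$strand, x$protospacer, x$pam))
  invisible(x)
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds DNA string whose length is a multiple of 3.
#' @return Protein string, one letter per codon, `*` for stop.
#' @export
#' @examples
#' translate_cds("CAA")     # "Q"
#' translate_cds("TAATAA")  # "**"
translate_cds <- function(cds) {
  assert_dna(cds, "cds")
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("cds length must be a multiple of 3", call. = FALSE)
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Amino-acid position of a plasmid breakpoint within a CDS
#'
#' Maps a 0-based nucleotide breakpoint to the 1-based amino-acid index of
#' the codon it interrupts, in the feature's translation orientation; used to
#' report insertion sites in "1048Thr" style.
#'
#' @param breakpoint 0-based plasmid position.
#' @param cds A one-row feature data.frame (kind "CDS" frame assumed).
#' @param plasmid_len Plasmid length, needed for origin-spanning features.
#' @return 1-based amino-acid index, or NA if the breakpoint is outside the
#'   CDS.
#' @export
aa_position_of <- function(breakpoint, cds, plasmid_len) {
  off <- cds_offset(breakpoint, cds, plasmid_len)
  if (is.na(off)) return(NA_integer_)
  off %/% 3L + 1L
}

#' Nucleotide offset of a breakpoint from a CDS start (translation frame)
#'
#' @inheritParams aa_position_of
#' @return 0-based offset within the CDS, or NA if outside.
#' @export
cds_offset <- function(breakpoint, cds, plasmid_len) {
  w <- cds$end - cds$start
  if (cds$strand == "+") {
    off <- normalize_pos(breakpoint - cds$start, plasmid_len)
  } else {
    off <- normalize_pos(cds$end - 1L - breakpoint, plasmid_len)
  }
  if (off >= w) return(NA_integer_)
  as.integer(off)
}

#' Predict the coding consequence of a single base edit
#'
#' Applies a top-strand single-base change to one codon and translates the
#' result; this is the selection logic of the AmpR(A118X) screen, where a TAA
#' premature stop is reverted to CAA (Gln) by A>G editing of the bottom
#' strand, i.e. a T>C change on the top strand.
#'
#' @param codon 3-nt DNA string (top/coding strand).
#' @param codon_position Position of the edited base within the codon (1-3).
#'   Values outside 1-3 mean the edit falls outside this codon and the codon
#'   is returned unchanged.
#' @param change Substitution such as `"T>C"`, expressed on the strand given
#'   by `strand`.
#' @param strand `"+"` if `change` is stated on the coding (top) strand,
#'   `"-"` if on the bottom strand (it is complemented before applying, so an
#'   A>G bottom-strand edit becomes T>C on top).
#' @return `list(codon = <edited codon>, residue = <one-letter translation>)`.
#' @export
#' @examples
#' predict_edit_consequence("TAA", 1, "T>C")            # CAA -> "Q"
#' predict_edit_consequence("CAA", 1, "C>T")            # TAA -> "*"
#' predict_edit_consequence("TAA", 1, "A>G", strand = "-")  # same as T>C
predict_edit_consequence <- function(codon, codon_position, change,
                                     strand = "+") {
  assert_dna(codon, "codon")
  if (nchar(codon) != 3L) stop("codon must be 3 nt", call. = FALSE)
  stopifnot(strand %in% c("+", "-"))
  ch <- parse_change(change)
  if (strand == "-") {
    ch <- list(from = complement_base(ch$from), to = complement_base(ch$to))
  }
  if (!(codon_position %in% 1:3)) {
    return(list(codon = codon, residue = translate_cds(codon)))
  }
  ref <- substr(codon, codon_position, codon_position)
  if (ref != ch$from) {
    stop(sprintf("codon has %s at position %d, not %s", ref, codon_position,
                 ch$from), call. = FALSE)
  }
  new_codon <- codon
  substr(new_codon, codon_position, codon_position) <- ch$to
  list(codon = new_codon, residue = translate_cds(new_codon))
}

#' Parse a substitution string like "A>G"
#' @keywords internal
parse_change <- function(change) {
  if (!grepl("^[ACGT]>[ACGT]$", change)) {
    stop("change must look like 'A>G'", call. = FALSE)
  }
  list(from = substr(change, 1L, 1L), to = substr(change, 3L, 3L))
}
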