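# Breakpoint calling and insertion-landscape summaries. A soft-clip segment
# supports an insertion when its junction-proximal bases exactly match a
# cargo terminus; left- and right-junction anchors of the same event differ
# by the target-site duplication length and are normalized to one canonical
# coordinate (the leftmost duplicated base) before merging.

# Which cargo end does a clip match, and in which orientation?
# Right clips start at the junction, so their leading bases are compared;
# left clips end at the junction, so their trailing bases are compared.
# When the cargo terminus shares its first bases with the backbone at the
# junction (microhomology), the exact-extension aligner absorbs those bases
# into the M block, shifting the observed clip boundary outward; the
# comparison therefore slides into the cargo by up to `max_shift` bases and
# reports the shift so the anchor can be corrected. The smallest shift that
# matches wins (maximum parsimony).
classify_clip <- function(seq, side, cargo, rc, m, max_shift = 10L) {
  clen <- nchar(cargo)
  for (s in 0:max_shift) {
    if (nchar(seq) < m || s + m > clen) break
    if (side == "right") {
      lead <- substr(seq, 1L, m)
      fwd <- lead == substr(cargo, s + 1L, s + m)
      rev <- lead == substr(rc, s + 1L, s + m)
    } else {
      trail <- substr(seq, nchar(seq) - m + 1L, nchar(seq))
      fwd <- trail == substr(cargo, clen - s - m + 1L, clen - s)
      rev <- trail == substr(rc, clen - s - m + 1L, clen - s)
    }
    if (fwd && rev) return(list(orient = "ambiguous", shift = s))
    if (fwd) return(list(orient = "+", shift = s))
    if (rev) return(list(orient = "-", shift = s))
  }
  NULL
}

#' Call cargo insertion breakpoints from soft-clip segments
#'
#' A segment supports an insertion iff its junction-proximal
#' `min_cargo_match` bases exactly match a cargo terminus (forward or
#' reverse-complement). Right-junction anchors sit `tsd_len` bases
#' downstream of left-junction anchors of the same event; both are
#' normalized to the canonical leftmost-TSD-base coordinate and merged, with
#' support summed and orientation taken from which cargo end matched
#' ("ambiguous" when both do, e.g. palindromic cargo).
#'
#' @param segments data.frame from [extract_softclips()].
#' @param cargo Cargo DNA string.
#' @param plasmid The backbone `plasmid_map` (for circular normalization and
#'   amino-acid annotation).
#' @param tsd_len Target-site duplication length used by the library.
#' @param min_cargo_match Exact bases a clip must share with a cargo end.
#' @param cds_name CDS feature used for amino-acid annotation.
#' @return data.frame with columns position, support, orientations, sides,
#'   aa_position, in_frame — one row per called insertion site, sorted by
#'   position.
#' @export
call_breakpoints <- function(segments, cargo, plasmid, tsd_len = 5L,
                             min_cargo_match = 15L, cds_name = "ncas9") {
  assert_dna(cargo, "cargo")
  if (nchar(cargo) < min_cargo_match) {
    stop("cargo shorter than min_cargo_match", call. = FALSE)
  }
  L <- plasmid$sequence$length
  m <- min_cargo_match
  rc <- revcomp(cargo)

  empty <- data.frame(position = integer(), support = integer(),
                      orientations = character(), sides = character(),
                      aa_position = integer(), in_frame = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(segments) == 0L) return(empty)

  hits <- list()
  for (i in seq_len(nrow(segments))) {
    cl <- classify_clip(segments$seq[i], segments$side[i], cargo, rc, m)
    if (is.null(cl)) next
    # An event at canonical position p produces a right clip anchored at
    # p + tsd_len (read runs off the left flank into the cargo 5' end) and a
    # left clip anchored at p (cargo 3' end precedes the right flank);
    # microhomology shifts the observed anchor outward by cl$shift.
    if (segments$side[i] == "right") {
      pos <- normalize_pos(segments$anchor[i] - cl$shift - tsd_len, L)
    } else {
      pos <- normalize_pos(segments$anchor[i] + cl$shift, L)
    }
    hits[[length(hits) + 1L]] <- data.frame(
      position = pos, side = segments$side[i], orientation = cl$orient,
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(empty)
  h <- do.call(rbind, hits)
  cds <- get_feature(plasmid, cds_name)
  out <- do.call(rbind, lapply(split(h, h$position), function(g) {
    pos <- g$position[1L]
    off <- cds_offset(pos, cds, L)
    data.frame(position = pos, support = nrow(g),
               orientations = paste(sort(unique(g$orientation)),
                                    collapse = ","),
               sides = paste(sort(unique(g$side)), collapse = ","),
               aa_position = if (is.na(off)) NA_integer_ else off %/% 3L + 1L,
               in_frame = if (is.na(off)) NA else off %% 3L == 0L,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize the insertion landscape of a plasmid
#'
#' @param calls data.frame from [call_breakpoints()].
#' @param plasmid The `plasmid_map`.
#' @param cds_name CDS whose amino-acid coverage is summarized.
#' @return An `insertion_profile`: list with `per_position` (counts over the
#'   plasmid, weighted by support), `per_feature` (totals by feature interval
#'   membership, plus "intergenic"), `per_aa` (support per amino-acid
#'   position of the CDS), and `fraction_aa_covered`.
#' @export
summarize_profile <- function(calls, plasmid, cds_name = "ncas9") {
  L <- plasmid$sequence$length
  per_position <- integer(L)
  if (nrow(calls) > 0L) {
    per_position[calls$position + 1L] <-
      per_position[calls$position + 1L] + calls$support
  }
  feats <- plasmid$features
  in_feature <- function(pos, f) {
    normalize_pos(pos - f$start, L) < (f$end - f$start)
  }
  per_feature <- integer(nrow(feats) + 1L)
  names(per_feature) <- c(feats$name, "intergenic")
  for (i in seq_len(nrow(calls))) {
    hit <- vapply(seq_len(nrow(feats)), function(j) {
      in_feature(calls$position[i], feats[j, , drop = FALSE])
    }, logical(1))
    if (any(hit)) {
      per_feature[which(hit)] <- per_feature[which(hit)] + calls$support[i]
    } else {
      per_feature["intergenic"] <- per_feature["intergenic"] + calls$support[i]
    }
  }
  cds <- get_feature(plasmid, cds_name)
  n_aa <- (cds$end - cds$start) %/% 3L
  per_aa <- integer(n_aa)
  if (nrow(calls) > 0L) {
    aa <- calls$aa_position[!is.na(calls$aa_position)]
    sup <- calls$support[!is.na(calls$aa_position)]
    for (i in seq_along(aa)) per_aa[aa[i]] <- per_aa[aa[i]] + sup[i]
  }
  structure(list(per_position = per_position, per_feature = per_feature,
                 per_aa = per_aa,
                 fraction_aa_covered = mean(per_aa > 0L),
                 cds_name = cds_name),
            class = "insertion_profile")
}

#' @export
print.insertion_profile <- function(x, ...) {
  cat(sprintf("<insertion_profile> %d calls, %.1f%% of %s residues hit\n",
              sum(x$per_position), 100 * x$fraction_aa_covered, x$cds_name))
  print(x$per_feature)
  invisible(x)
}

#' Map an insertion-read set end to end
#'
#' Convenience wrapper: align reads to the backbone, extract soft clips, and
#' call breakpoints.
#'
#' @param reads data.frame with columns id, seq (FASTQ-style), or an aligned
#'   data.frame from [read_sam()] (detected by a `cigar` column, in which
#'   case alignment is skipped).
#' @param plasmid The backbone `plasmid_map`.
#' @param cargo Cargo DNA string.
#' @param k Seed k-mer length for the mapper.
#' @param min_anchor Minimum backbone match block.
#' @param min_clip_len Minimum soft-clip length to consider.
#' @param tsd_len Target-site duplication length.
#' @param min_cargo_match Exact bases required against a cargo terminus.
#' @param cds_name CDS for amino-acid annotation.
#' @return data.frame of insertion calls (see [call_breakpoints()]).
#' @export
map_insertions <- function(reads, plasmid, cargo, k = 21L, min_anchor = 30L,
                           min_clip_len = 20L, tsd_len = 5L,
                           min_cargo_match = 15L, cds_name = "ncas9") {
  aligned <- if ("cigar" %in% names(reads)) reads else {
    align_to_backbone(reads, backbone_index(plasmid, k),
                      min_anchor = min_anchor)
  }
  segs <- extract_softclips(aligned, min_clip_len = min_clip_len,
                            backbone_len = plasmid$sequence$length)
  call_breakpoints(segs, cargo, plasmid, tsd_len = tsd_len,
                   min_cargo_match = min_cargo_match, cds_name = cds_name)
}
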