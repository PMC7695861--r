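# Amplicon editing quantification: paired-read merging, quality-filtered
# pileups (mapq >= 20, base quality >= 30 by default, mirroring a
# bam-readcount -q 20 -b 30 workflow), per-protospacer-position conversion
# rates, read-level indel frequency, and cross-site window summaries.

phred_int <- function(qual) utf8ToInt(qual) - 33L

# Best ungapped overlap of r1 suffix with r2rc prefix. Returns overlap
# length and mismatch count, or NULL. An exact-prefix seed shortcuts the
# offset scan for the common error-free case; the full scan is the fallback.
best_overlap <- function(s1, s2rc, min_overlap) {
  n1 <- nchar(s1)
  n2 <- nchar(s2rc)
  if (min(n1, n2) < min_overlap) return(NULL)
  a <- utf8ToInt(s1)
  b <- utf8ToInt(s2rc)
  score_at <- function(o) {
    mism <- sum(a[(n1 - o + 1L):n1] != b[1:o])
    list(o = o, mism = mism, score = (o - mism) - 4L * mism)
  }
  pick <- function(cands) {
    best <- NULL
    for (o in cands) {
      s <- score_at(o)
      if (is.null(best) || s$score > best$score) best <- s
    }
    if (is.null(best) || best$score <= 0L || best$mism > 0.25 * best$o) {
      return(NULL)
    }
    best
  }
  seedlen <- min(16L, n2, min_overlap)
  hits <- gregexpr(substr(s2rc, 1L, seedlen), s1, fixed = TRUE)[[1L]]
  if (hits[1L] != -1L) {
    cand <- n1 - hits + 1L
    cand <- cand[cand >= min_overlap & cand <= min(n1, n2)]
    best <- pick(cand)
    if (!is.null(best)) return(best)
  }
  pick(seq.int(min(n1, n2), min_overlap))
}

#' Merge a read pair into a consensus read
#'
#' Reverse-complements mate 2 and searches for the best ungapped overlap; if
#' the best overlap spans at least `min_overlap` bases the pair is combined
#' into one consensus read. At disagreeing overlap positions the
#' higher-quality base wins and receives quality `max - min`; agreeing
#' positions keep the higher of the two qualities.
#'
#' @param seq1,qual1 Mate 1 sequence and Phred+33 quality.
#' @param seq2,qual2 Mate 2 sequence and quality (as sequenced).
#' @param min_overlap Minimum acceptable overlap (bases).
#' @return `list(merged = TRUE, seq =, qual =)` or `list(merged = FALSE)`
#'   (both reads are then kept unmerged by callers).
#' @export
merge_read_pairs <- function(seq1, qual1, seq2, qual2, min_overlap = 11L) {
  s2 <- revcomp(seq2)
  q2 <- str_rev(qual2)
  ov <- best_overlap(seq1, s2, min_overlap)
  if (is.null(ov)) return(list(merged = FALSE))
  o <- ov$o
  n1 <- nchar(seq1)
  left_s <- substr(seq1, 1L, n1 - o)
  left_q <- substr(qual1, 1L, n1 - o)
  a_s <- str_chars(substr(seq1, n1 - o + 1L, n1))
  a_q <- phred_int(substr(qual1, n1 - o + 1L, n1))
  b_s <- str_chars(substr(s2, 1L, o))
  b_q <- phred_int(substr(q2, 1L, o))
  take_a <- a_q >= b_q
  cons_s <- ifelse(take_a, a_s, b_s)
  agree <- a_s == b_s
  cons_q <- ifelse(agree, pmax(a_q, b_q), pmax(a_q, b_q) - pmin(a_q, b_q))
  right_s <- substr(s2, o + 1L, nchar(s2))
  right_q <- substr(q2, o + 1L, nchar(q2))
  list(merged = TRUE,
       seq = paste0(left_s, paste(cons_s, collapse = ""), right_s),
       qual = paste0(left_q, intToUtf8(cons_q + 33L), right_q))
}

#' Merge all pairs in a reads data.frame
#'
#' @param reads data.frame with columns id, mate, seq, qual.
#' @param min_overlap Minimum overlap passed to [merge_read_pairs()].
#' @return data.frame (id, seq, qual) of merged consensus reads plus any
#'   unmerged mates kept as-is (mate 2 reverse-complemented back is NOT
#'   applied; unmerged reads keep sequencing orientation).
#' @export
merge_all_pairs <- function(reads, min_overlap = 11L) {
  r1 <- reads[reads$mate == 1L, , drop = FALSE]
  r2 <- reads[reads$mate == 2L, , drop = FALSE]
  r2 <- r2[match(r1$id, r2$id), , drop = FALSE]
  # collapse duplicate molecules before the quadratic overlap search
  key <- paste(r1$seq, r1$qual, r2$seq, r2$qual, sep = "|")
  ukey <- unique(key)
  merged <- lapply(match(ukey, key), function(i) {
    merge_read_pairs(r1$seq[i], r1$qual[i], r2$seq[i], r2$qual[i],
                     min_overlap = min_overlap)
  })
  idx <- match(key, ukey)
  ok <- vapply(merged, `[[`, logical(1), "merged")[idx]
  mseq <- vapply(merged, function(m) if (m$merged) m$seq else "",
                 character(1))[idx]
  mqual <- vapply(merged, function(m) if (m$merged) m$qual else "",
                  character(1))[idx]
  rbind(
    data.frame(id = r1$id[ok], seq = mseq[ok], qual = mqual[ok],
               stringsAsFactors = FALSE),
    data.frame(id = rep(r1$id[!ok], 2L),
               seq = c(r1$seq[!ok], r2$seq[!ok]),
               qual = c(r1$qual[!ok], r2$qual[!ok]),
               stringsAsFactors = FALSE))
}

#' Align reads to an amplicon reference (gapped)
#'
#' Global-local pairwise alignment of each distinct read sequence against
#' the amplicon (Biostrings), producing 0-based start coordinates and
#' M/I/D CIGARs; identical sequences are aligned once and the result reused.
#'
#' @param reads data.frame with columns id, seq, qual.
#' @param amplicon Amplicon reference string.
#' @param mapq Mapping quality to assign (the toy model has no repeats).
#' @return data.frame with columns id, seq, qual, ref_start, cigar, mapq.
#' @export
align_to_amplicon <- function(reads, amplicon, mapq = 60L) {
  useq <- unique(reads$seq)
  n <- length(useq)
  cigars <- character(n)
  starts <- integer(n)
  # fast path: a full-length molecule differing by substitutions only needs
  # no gapped alignment
  aint <- utf8ToInt(amplicon)
  alen <- length(aint)
  gapped <- logical(n)
  for (i in seq_len(n)) {
    if (nchar(useq[i]) == alen &&
        sum(utf8ToInt(useq[i]) != aint) <= 0.2 * alen) {
      cigars[i] <- paste0(alen, "M")
      starts[i] <- 0L
    } else {
      gapped[i] <- TRUE
    }
  }
  if (any(gapped)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(useq[gapped]), Biostrings::DNAString(amplicon),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    pstr <- as.character(Biostrings::alignedPattern(aln))
    sstr <- as.character(Biostrings::alignedSubject(aln))
    cigars[gapped] <- vapply(seq_along(pstr), function(i) {
      p <- str_chars(pstr[i])
      s <- str_chars(sstr[i])
      op <- ifelse(s == "-", "I", ifelse(p == "-", "D", "M"))
      r <- rle(op)
      paste0(r$lengths, r$values, collapse = "")
    }, character(1))
    starts[gapped] <- Biostrings::start(Biostrings::subject(aln)) - 1L
  }
  idx <- match(reads$seq, useq)
  data.frame(id = reads$id, seq = reads$seq, qual = reads$qual,
             ref_start = starts[idx], cigar = cigars[idx],
             mapq = mapq, stringsAsFactors = FALSE)
}

#' Build a quality-filtered pileup over a region
#'
#' A base contributes to a column iff its read's mapping quality is at least
#' `min_mapq` and its base quality at least `min_baseq`; deletions never
#' contribute to counts. Columns are emitted for every position of the
#' region.
#'
#' @param aligned data.frame with columns seq, qual, ref_start, cigar, mapq.
#' @param region `c(start, end)` 0-based half-open reference interval
#'   (non-empty).
#' @param ref Reference string (for the ref_base column).
#' @param min_mapq Minimum mapping quality (bam-readcount -q).
#' @param min_baseq Minimum base quality (bam-readcount -b).
#' @return data.frame with columns ref_pos, ref_base, A, C, G, T, depth.
#' @export
build_pileup <- function(aligned, region, ref, min_mapq = 20L,
                         min_baseq = 30L) {
  if (region[2L] <= region[1L]) stop("empty region", call. = FALSE)
  W <- region[2L] - region[1L]
  counts <- matrix(0L, nrow = 4L, ncol = W,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  # identical read records contribute identically: collapse with weights
  key <- paste(aligned$seq, aligned$qual, aligned$ref_start, aligned$cigar,
               aligned$mapq, sep = "|")
  w <- as.integer(table(key)[key])
  first <- !duplicated(key)
  keep <- first & aligned$mapq >= min_mapq
  for (i in which(keep)) {
    cg <- parse_cigar(aligned$cigar[i])
    qp <- 0L
    rp <- aligned$ref_start[i]
    sint <- utf8ToInt(aligned$seq[i])
    qint <- utf8ToInt(aligned$qual[i]) - 33L
    for (j in seq_len(nrow(cg))) {
      l <- cg$len[j]
      switch(cg$op[j],
        M = {
          rpos <- rp + seq_len(l) - 1L
          qpos <- qp + seq_len(l)
          ok <- rpos >= region[1L] & rpos < region[2L] &
                qint[qpos] >= min_baseq
          if (any(ok)) {
            bi <- match(sint[qpos[ok]], c(65L, 67L, 71L, 84L))
            ci <- rpos[ok] - region[1L] + 1L
            val <- !is.na(bi)
            idx <- cbind(bi[val], ci[val])
            counts[idx] <- counts[idx] + w[i]
          }
          qp <- qp + l; rp <- rp + l
        },
        I = { qp <- qp + l },
        D = { rp <- rp + l },
        S = { qp <- qp + l })
    }
  }
  ref_pos <- seq.int(region[1L], region[2L] - 1L)
  data.frame(ref_pos = ref_pos,
             ref_base = substring(ref, ref_pos + 1L, ref_pos + 1L),
             A = counts["A", ], C = counts["C", ], G = counts["G", ],
             T = counts["T", ], depth = colSums(counts),
             stringsAsFactors = FALSE)
}

#' Conversion rate at one pileup column
#'
#' @param column One row of a pileup data.frame.
#' @param from_base Reference base expected at the column.
#' @param to_base Converted base.
#' @return `counts[to_base] / depth`, or NA when depth is 0 (missing, never
#'   0: a depth-0 column carries no information).
#' @export
conversion_rate <- function(column, from_base, to_base) {
  if (column$ref_base != from_base) {
    stop(sprintf("column reference base is %s, not %s", column$ref_base,
                 from_base), call. = FALSE)
  }
  if (column$depth == 0L) return(NA_real_)
  column[[to_base]] / column$depth
}

#' Per-protospacer-position editing profile
#'
#' Walks protospacer positions 1-20 (PAM-distal = 1). For a minus-strand
#' site, reference positions are walked 3'->5' and bases complemented, so
#' the profile is expressed on the protospacer strand regardless of how the
#' site is annotated. Only positions whose protospacer base is the editable
#' base (A for A>G, C for C>T) appear; depth-0 positions are reported NA.
#'
#' @param pileup Pileup data.frame from [build_pileup()].
#' @param site A `target_site` within the pileup region.
#' @param edit_type "A>G" or "C>T" on the protospacer strand.
#' @return An `editing_profile`: list with `site`, `edit_type`, `rate`
#'   (named numeric over editable positions), `depth` (same names).
#' @export
protospacer_profile <- function(pileup, site, edit_type = c("A>G", "C>T")) {
  edit_type <- match.arg(edit_type)
  ch <- parse_change(edit_type)
  map <- protospacer_ref_positions(site)
  if (any(!(map %in% pileup$ref_pos))) {
    stop("site lies outside the pileup region", call. = FALSE)
  }
  proto <- str_chars(site$protospacer)
  editable <- which(proto == ch$from)
  rate <- depth <- stats::setNames(numeric(0), character(0))
  for (p in editable) {
    col <- pileup[pileup$ref_pos == map[p], , drop = FALSE]
    to_top <- if (site$strand == "+") ch$to else complement_base(ch$to)
    d <- col$depth
    rate[as.character(p)] <- if (d == 0L) NA_real_ else col[[to_top]] / d
    depth[as.character(p)] <- d
  }
  structure(list(site = site, edit_type = edit_type, rate = rate,
                 depth = depth),
            class = "editing_profile")
}

#' @export
print.editing_profile <- function(x, ...) {
  cat(sprintf("<editing_profile> %s %s, %d editable positions\n",
              x$site$ref_name, x$edit_type, length(x$rate)))
  print(round(x$rate, 4))
  invisible(x)
}

#' Read-level indel frequency over the protospacer
#'
#' A read counts as indel-containing iff any I or D CIGAR op overlaps the
#' protospacer interval: a deletion if its reference footprint intersects
#' the interval, an insertion if its insertion point falls strictly inside
#' it. Indel ops count irrespective of base quality (the statistic is
#' read-level); the mapping-quality filter still applies.
#'
#' @param aligned data.frame with columns cigar, ref_start, mapq.
#' @param interval `c(start, end)` 0-based half-open protospacer interval.
#' @param min_mapq Minimum mapping quality.
#' @return `list(indel_reads, total_reads, frequency)`.
#' @export
indel_frequency <- function(aligned, interval, min_mapq = 20L) {
  key <- paste(aligned$ref_start, aligned$cigar, aligned$mapq, sep = "|")
  w <- as.integer(table(key)[key])
  first <- !duplicated(key)
  pass <- aligned$mapq >= min_mapq
  total <- sum(pass)
  keep <- first & pass
  n_indel <- 0L
  for (i in which(keep)) {
    cg <- parse_cigar(aligned$cigar[i])
    rp <- aligned$ref_start[i]
    hit <- FALSE
    for (j in seq_len(nrow(cg))) {
      l <- cg$len[j]
      if (cg$op[j] == "D") {
        if (rp < interval[2L] && rp + l > interval[1L]) hit <- TRUE
        rp <- rp + l
      } else if (cg$op[j] == "I") {
        if (rp > interval[1L] && rp < interval[2L]) hit <- TRUE
      } else if (cg$op[j] == "M") {
        rp <- rp + l
      }
    }
    if (hit) n_indel <- n_indel + w[i]
  }
  list(indel_reads = n_indel, total_reads = total,
       frequency = if (total == 0L) NA_real_ else n_indel / total)
}

#' Mean and standard error of editing rates across sites
#'
#' @param profiles List of `editing_profile` objects.
#' @return data.frame with columns position, mean, se, n_sites; positions
#'   present in no profile are absent, and a site lacking the editable base
#'   at a position (or with no depth there) is excluded from that position's
#'   average.
#' @export
window_summary <- function(profiles) {
  rates <- lapply(profiles, function(p) p$rate[!is.na(p$rate)])
  pos <- sort(unique(as.integer(unlist(lapply(rates, names)))))
  out <- do.call(rbind, lapply(pos, function(p) {
    v <- unlist(lapply(rates, function(r) r[as.character(p)]))
    v <- v[!is.na(v)]
    data.frame(position = p, mean = mean(v),
               se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0,
               n_sites = length(v))
  }))
  if (is.null(out)) {
    out <- data.frame(position = integer(), mean = numeric(),
                      se = numeric(), n_sites = integer())
  }
  out
}

#' Quantify editing for one amplicon from raw read pairs
#'
#' End-to-end wrapper: merge pairs, align to the amplicon, build the
#' quality-filtered pileup, and derive the per-position editing profile and
#' protospacer indel frequency.
#'
#' @param reads data.frame with columns id, mate, seq, qual.
#' @param amplicon Amplicon reference string.
#' @param site `target_site` on the amplicon.
#' @param edit_type "A>G" or "C>T".
#' @param min_overlap Pair-merging overlap threshold.
#' @param min_mapq,min_baseq Pileup filters.
#' @return list with `profile` (editing_profile), `indels`, `pileup`.
#' @export
quantify_editing <- function(reads, amplicon, site, edit_type = "A>G",
                             min_overlap = 11L, min_mapq = 20L,
                             min_baseq = 30L) {
  merged <- if (!is.null(reads$mate) && any(reads$mate == 2L)) {
    merge_all_pairs(reads, min_overlap = min_overlap)
  } else reads
  aligned <- align_to_amplicon(merged, amplicon)
  pile <- build_pileup(aligned, c(0L, nchar(amplicon)), amplicon,
                       min_mapq = min_mapq, min_baseq = min_baseq)
  map <- protospacer_ref_positions(site)
  list(profile = protospacer_profile(pile, site, edit_type),
       indels = indel_frequency(aligned, c(min(map), max(map) + 1L),
                                min_mapq = min_mapq),
       pileup = pile)
}
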