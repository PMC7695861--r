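# Minimal exact-k-mer seed-and-extend mapper for the circular backbone.
# Junction reads of a cargo insertion map with one ungapped match block
# (M) and the cargo portion soft-clipped (S), which is exactly the evidence
# the breakpoint caller consumes. Circularity is handled by seeding against
# a doubled backbone and normalizing positions modulo length.

#' Build a k-mer index of the (circular) backbone
#'
#' @param plasmid A `plasmid_map` or DNA string (treated as circular).
#' @param k Seed k-mer length.
#' @return An opaque index object for [align_to_backbone()].
#' @export
backbone_index <- function(plasmid, k = 21L) {
  s <- if (inherits(plasmid, "plasmid_map")) plasmid$sequence$seq else plasmid
  L <- nchar(s)
  if (L < k) stop("backbone shorter than seed length", call. = FALSE)
  doubled <- paste0(s, s)
  kmers <- substring(doubled, 1:L, k:(L + k - 1L))
  env <- new.env(hash = TRUE, parent = emptyenv(), size = 2L * L)
  sp <- split(0:(L - 1L), kmers)
  list2env(sp, envir = env)
  structure(list(env = env, doubled_int = utf8ToInt(paste0(doubled, s)),
                 length = L, k = k),
            class = "backbone_index")
}

# Best ungapped alignment of one oriented read against the index: returns
# NULL or list(ref_start, q_start, m_len, n_best_ties).
best_ungapped <- function(qint, idx) {
  k <- idx$k
  L <- idx$length
  n <- length(qint)
  if (n < k) return(NULL)
  q <- intToUtf8(qint)
  starts <- 1:(n - k + 1L)
  kmers <- substring(q, starts, starts + k - 1L)
  diags <- integer(0)
  for (i in seq_along(starts)) {
    hits <- idx$env[[kmers[i]]]
    if (!is.null(hits)) diags <- c(diags, (hits - (starts[i] - 1L)) %% L)
  }
  diags <- unique(diags)
  if (length(diags) == 0L) return(NULL)
  best <- NULL
  ties <- 0L
  for (d in diags) {
    ref <- idx$doubled_int[(d + 1L):(d + n)]
    m <- ref == qint
    r <- rle(m)
    lens <- r$lengths
    ends <- cumsum(lens)
    ok <- which(r$values & lens >= k)
    if (length(ok) == 0L) next
    j <- ok[which.max(lens[ok])]
    cand <- list(ref_start = (d + ends[j] - lens[j]) %% L,
                 q_start = ends[j] - lens[j] + 1L, m_len = lens[j])
    if (is.null(best) || cand$m_len > best$m_len) {
      best <- cand
      ties <- 1L
    } else if (cand$m_len == best$m_len &&
               !(cand$ref_start == best$ref_start &&
                 cand$q_start == best$q_start)) {
      ties <- ties + 1L
    }
  }
  if (is.null(best)) return(NULL)
  best$ties <- ties
  best
}

#' Align a read to the circular backbone
#'
#' Seeds with exact k-mers against a doubled backbone, extends the best seed
#' ungapped and exactly in both directions; the longest match block becomes
#' the M segment and the unmatched prefix/suffix become soft clips (S).
#' Minus-strand reads are reverse-complemented, so the stored query is always
#' in reference orientation.
#'
#' @param read Read sequence (string), or a reads data.frame with columns
#'   `id` and `seq` (each row aligned in turn).
#' @param index A `backbone_index`, or a `plasmid_map`/string from which one
#'   is built with seed length `k`.
#' @param k Seed length (used only when `index` is not already an index).
#' @param min_anchor Minimum M-block length to accept a mapping.
#' @return For a single read: a list with `mapped`, and when mapped `query`
#'   (reference-oriented), `ref_start` (0-based, normalized), `cigar`,
#'   `mapq`, `strand`, plus `ambiguous = TRUE` on a best-seed tie. For a
#'   data.frame: a data.frame of mapped reads with columns id, seq,
#'   ref_start, cigar, mapq, strand.
#' @export
align_to_backbone <- function(read, index, k = 21L, min_anchor = 30L) {
  if (!inherits(index, "backbone_index")) index <- backbone_index(index, k)
  if (is.data.frame(read)) {
    res <- lapply(read$seq, align_to_backbone, index = index,
                  min_anchor = min_anchor)
    mapped <- vapply(res, `[[`, logical(1), "mapped")
    res <- res[mapped]
    return(data.frame(id = read$id[mapped],
                      seq = vapply(res, `[[`, character(1), "query"),
                      ref_start = vapply(res, `[[`, integer(1), "ref_start"),
                      cigar = vapply(res, `[[`, character(1), "cigar"),
                      mapq = vapply(res, `[[`, integer(1), "mapq"),
                      strand = vapply(res, `[[`, character(1), "strand"),
                      stringsAsFactors = FALSE))
  }
  if (nchar(read) < index$k) return(list(mapped = FALSE))
  fwd <- utf8ToInt(read)
  rev_seq <- revcomp(read)
  rev <- utf8ToInt(rev_seq)
  hf <- best_ungapped(fwd, index)
  hr <- best_ungapped(rev, index)
  score <- function(h) if (is.null(h)) -1L else h$m_len
  if (score(hf) < min_anchor && score(hr) < min_anchor) {
    return(list(mapped = FALSE))
  }
  if (score(hf) == score(hr)) {
    return(list(mapped = FALSE, ambiguous = TRUE))
  }
  if (score(hf) > score(hr)) {
    h <- hf; strand <- "+"; query <- read
  } else {
    h <- hr; strand <- "-"; query <- rev_seq
  }
  if (h$ties > 1L) return(list(mapped = FALSE, ambiguous = TRUE))
  n <- nchar(query)
  left <- h$q_start - 1L
  right <- n - left - h$m_len
  cigar <- paste0(if (left > 0L) paste0(left, "S"), h$m_len, "M",
                  if (right > 0L) paste0(right, "S"))
  list(mapped = TRUE, query = query,
       ref_start = as.integer(h$ref_start %% index$length),
       cigar = cigar, mapq = 60L, strand = strand)
}

#' Parse a CIGAR string
#' @param cigar CIGAR string over ops M, I, D, S.
#' @return data.frame with columns op, len.
#' @export
parse_cigar <- function(cigar) {
  if (cigar == "*" || !grepl("^([0-9]+[MIDS])+$", cigar)) {
    stop("unsupported CIGAR: ", cigar, call. = FALSE)
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

cigar_ref_span <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D")])
}

#' Extract terminal soft-clip segments from aligned reads
#'
#' One segment per terminal S block of length >= `min_clip_len`. A left clip
#' anchors at `ref_start`; a right clip anchors at `ref_start` plus the
#' reference span of the alignment (both 0-based backbone positions,
#' normalized to the circular frame when `backbone_len` is given).
#'
#' @param aligned data.frame of aligned reads (columns id, seq, ref_start,
#'   cigar; as returned by [align_to_backbone()] or [read_sam()]).
#' @param min_clip_len Minimum clip length to keep.
#' @param backbone_len Backbone length for circular normalization (NULL for
#'   linear references).
#' @return data.frame with columns read_id, side ("left"/"right"), seq,
#'   anchor.
#' @export
extract_softclips <- function(aligned, min_clip_len = 20L,
                              backbone_len = NULL) {
  out <- list()
  for (i in seq_len(nrow(aligned))) {
    cg <- parse_cigar(aligned$cigar[i])
    qlen <- nchar(aligned$seq[i])
    if (cg$op[1L] == "S" && cg$len[1L] >= min_clip_len) {
      anchor <- aligned$ref_start[i]
      if (!is.null(backbone_len)) anchor <- normalize_pos(anchor, backbone_len)
      out[[length(out) + 1L]] <- data.frame(
        read_id = aligned$id[i], side = "left",
        seq = substr(aligned$seq[i], 1L, cg$len[1L]),
        anchor = anchor, stringsAsFactors = FALSE)
    }
    last <- nrow(cg)
    if (last > 1L && cg$op[last] == "S" && cg$len[last] >= min_clip_len) {
      anchor <- aligned$ref_start[i] + cigar_ref_span(aligned$cigar[i])
      if (!is.null(backbone_len)) anchor <- normalize_pos(anchor, backbone_len)
      out[[length(out) + 1L]] <- data.frame(
        read_id = aligned$id[i], side = "right",
        seq = substr(aligned$seq[i], qlen - cg$len[last] + 1L, qlen),
        anchor = anchor, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(read_id = character(), side = character(),
                      seq = character(), anchor = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
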