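# Read simulators: shotgun reads off (circular) templates, targeted junction
# reads for insertion events, and amplicon reads with position-specific base
# conversions and indels. Quality model is two-state: Q37 ('F') for correct
# bases, Q14 ('/') for simulated errors, which is enough to exercise a
# base-quality >= 30 pileup filter.

QUAL_HIGH <- "F"  # Phred 37
QUAL_LOW <- "/"   # Phred 14

# Substitution errors at `rate`; returns list(seq, qual) character vectors.
apply_error_model <- function(seqs, rate) {
  quals <- strrep(QUAL_HIGH, nchar(seqs))
  if (rate > 0) {
    bases <- c("A", "C", "G", "T")
    for (i in seq_along(seqs)) {
      n <- nchar(seqs[i])
      hit <- which(stats::runif(n) < rate)
      if (length(hit) == 0L) next
      s <- str_chars(seqs[i])
      q <- str_chars(quals[i])
      for (j in hit) {
        s[j] <- sample(setdiff(bases, s[j]), 1L)
        q[j] <- QUAL_LOW
      }
      seqs[i] <- paste(s, collapse = "")
      quals[i] <- paste(q, collapse = "")
    }
  }
  list(seq = seqs, qual = quals)
}

#' Simulate shotgun sequencing reads from a template
#'
#' Start positions are uniform over the template (wrapping if circular);
#' substitution errors occur independently at `error_rate` and are assigned
#' low base quality (Q14), correct bases Q37. Paired mode emulates a 2x150
#' fragment protocol: mate 1 from the fragment start, mate 2 the reverse
#' complement of the fragment end.
#'
#' @param template DNA string (or character vector of templates, sampled
#'   uniformly).
#' @param n_reads Number of reads (fragments in paired mode).
#' @param read_len Read length.
#' @param paired Generate read pairs?
#' @param insert_size Fragment length in paired mode (>= read_len).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @param circular Treat templates as circular (start positions wrap)?
#' @return data.frame with columns id, mate, seq, qual.
#' @export
simulate_reads <- function(template, n_reads, read_len = 150L, paired = FALSE,
                           insert_size = 400L, error_rate = 0.001,
                           seed = NULL, circular = FALSE) {
  span <- if (paired) insert_size else read_len
  if (paired && insert_size < read_len) {
    stop("insert_size must be >= read_len", call. = FALSE)
  }
  if (!circular && any(nchar(template) < span)) {
    stop("template shorter than the read/fragment span", call. = FALSE)
  }
  with_seed(seed, {
    tpl_idx <- if (length(template) > 1L) {
      sample.int(length(template), n_reads, replace = TRUE)
    } else rep(1L, n_reads)
    frags <- vapply(seq_len(n_reads), function(i) {
      tpl <- template[tpl_idx[i]]
      L <- nchar(tpl)
      if (circular) {
        start <- sample.int(L, 1L) - 1L
        circ_substr(tpl, start, span)
      } else {
        start <- sample.int(L - span + 1L, 1L)
        substr(tpl, start, start + span - 1L)
      }
    }, character(1))
    if (paired) {
      r1 <- apply_error_model(substr(frags, 1L, read_len), error_rate)
      r2 <- apply_error_model(revcomp(substr(frags, span - read_len + 1L, span)),
                              error_rate)
      ids <- sprintf("read%06d", seq_len(n_reads))
      data.frame(id = rep(ids, 2L), mate = rep(1:2, each = n_reads),
                 seq = c(r1$seq, r2$seq), qual = c(r1$qual, r2$qual),
                 stringsAsFactors = FALSE)
    } else {
      r <- apply_error_model(frags, error_rate)
      data.frame(id = sprintf("read%06d", seq_len(n_reads)), mate = 1L,
                 seq = r$seq, qual = r$qual, stringsAsFactors = FALSE)
    }
  })
}

#' Simulate junction-spanning reads for insertion events
#'
#' For each true insertion, emits one read across the left backbone/cargo
#' junction and one across the right cargo/backbone junction, each with
#' `flank` backbone bases, so every event is guaranteed the soft-clip
#' evidence the breakpoint caller needs. Reads are emitted on a random
#' sequencing strand.
#'
#' @param plasmid The backbone `plasmid_map`.
#' @param truth Truth list from [simulate_insertion_library()].
#' @param cargo Cargo DNA string.
#' @param read_len Read length.
#' @param flank Backbone bases retained on the anchored side (the rest of the
#'   read is cargo).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return data.frame with columns id, mate, seq, qual.
#' @export
simulate_junction_reads <- function(plasmid, truth, cargo, read_len = 150L,
                                    flank = 70L, error_rate = 0,
                                    seed = NULL) {
  ins <- truth$true_insertions
  t <- truth$tsd_len
  clen <- nchar(cargo)
  if (clen < read_len - flank) {
    stop("cargo shorter than the cargo side of a junction read", call. = FALSE)
  }
  with_seed(seed, {
    reads <- character(2L * nrow(ins))
    for (i in seq_len(nrow(ins))) {
      p <- ins$position[i]
      cg <- if (ins$orientation[i] == "+") cargo else revcomp(cargo)
      # left junction: backbone [.. p+t) then cargo 5' end
      left <- paste0(circ_substr(plasmid$sequence, p + t - flank, flank),
                     substr(cg, 1L, read_len - flank))
      # right junction: cargo 3' end then backbone [p ..)
      right <- paste0(substr(cg, clen - (read_len - flank) + 1L, clen),
                      circ_substr(plasmid$sequence, p, flank))
      flip <- stats::runif(2L) < 0.5
      reads[2L * i - 1L] <- if (flip[1L]) revcomp(left) else left
      reads[2L * i] <- if (flip[2L]) revcomp(right) else right
    }
    r <- apply_error_model(reads, error_rate)
    data.frame(id = sprintf("jx%05d_%s", rep(seq_len(nrow(ins)), each = 2L),
                            rep(c("L", "R"), nrow(ins))),
               mate = 1L, seq = r$seq, qual = r$qual, stringsAsFactors = FALSE)
  })
}

#' Simulate amplicon deep-sequencing reads with programmed editing
#'
#' Each simulated molecule independently converts the editable base at
#' protospacer position `p` with probability `per_position_rates[[p]]`
#' (strand-aware: for a minus-strand site the conversion is applied as its
#' complement on the amplicon top strand), and with probability `indel_rate`
#' carries a 1-bp insertion or deletion inside the protospacer. Molecules are
#' then sequenced as 2x`read_len` pairs (or single full-length reads).
#'
#' @param amplicon Amplicon reference DNA string.
#' @param site A `target_site` lying inside the amplicon.
#' @param per_position_rates Named numeric vector; names are protospacer
#'   positions (1-20, PAM-distal = 1) whose protospacer base is the editable
#'   base, values are conversion fractions.
#' @param indel_rate Per-molecule probability of a 1-bp indel in the
#'   protospacer.
#' @param n_reads Number of molecules (read pairs).
#' @param edit_type "A>G" (ABE) or "C>T" (CBE), on the protospacer strand.
#' @param error_rate Sequencing substitution error probability.
#' @param paired Emit read pairs (TRUE) or single full-length reads.
#' @param read_len Read length in paired mode.
#' @param seed Integer seed.
#' @return `list(reads = data.frame(id, mate, seq, qual), truth = list(...))`.
#' @export
simulate_amplicon_reads <- function(amplicon, site, per_position_rates,
                                    indel_rate = 0, n_reads = 1000L,
                                    edit_type = c("A>G", "C>T"),
                                    error_rate = 0, paired = TRUE,
                                    read_len = 150L, seed = NULL) {
  edit_type <- match.arg(edit_type)
  assert_dna(amplicon, "amplicon")
  L <- nchar(amplicon)
  if (site$position < 0L || site$position + 20L > L) {
    stop("site must lie inside the amplicon", call. = FALSE)
  }
  ch <- parse_change(edit_type)
  pp <- as.integer(names(per_position_rates))
  if (any(is.na(pp)) || any(pp < 1L | pp > 20L)) {
    stop("per_position_rates must be named by protospacer positions 1-20",
         call. = FALSE)
  }
  map <- protospacer_ref_positions(site)   # 0-based amplicon positions
  ref_pos <- map[pp]
  exp_top <- if (site$strand == "+") ch$from else complement_base(ch$from)
  new_top <- if (site$strand == "+") ch$to else complement_base(ch$to)
  found <- substring(amplicon, ref_pos + 1L, ref_pos + 1L)
  if (any(found != exp_top)) {
    stop("per_position_rates given at positions whose reference base is not ",
         "the editable base", call. = FALSE)
  }
  proto_iv <- c(min(map), max(map) + 1L)   # protospacer footprint, half-open
  with_seed(seed, {
    molecules <- character(n_reads)
    base <- str_chars(amplicon)
    for (i in seq_len(n_reads)) {
      s <- base
      hit <- stats::runif(length(pp)) < per_position_rates
      s[ref_pos[hit] + 1L] <- new_top
      if (indel_rate > 0 && stats::runif(1L) < indel_rate) {
        # interior positions only, so the event stays attributable to the
        # protospacer even after gap placement by the aligner
        at <- sample(seq.int(proto_iv[1L] + 2L, proto_iv[2L] - 1L), 1L)
        if (stats::runif(1L) < 0.5) {
          s <- s[-at]                                   # 1-bp deletion
        } else {
          s <- append(s, sample(c("A", "C", "G", "T"), 1L), after = at)
        }
      }
      molecules[i] <- paste(s, collapse = "")
    }
    reads <- if (paired) {
      r1 <- apply_error_model(substr(molecules, 1L, read_len), error_rate)
      r2 <- apply_error_model(
        revcomp(substr(molecules, nchar(molecules) - read_len + 1L,
                       nchar(molecules))), error_rate)
      ids <- sprintf("amp%06d", seq_len(n_reads))
      data.frame(id = rep(ids, 2L), mate = rep(1:2, each = n_reads),
                 seq = c(r1$seq, r2$seq), qual = c(r1$qual, r2$qual),
                 stringsAsFactors = FALSE)
    } else {
      r <- apply_error_model(molecules, error_rate)
      data.frame(id = sprintf("amp%06d", seq_len(n_reads)), mate = 1L,
                 seq = r$seq, qual = r$qual, stringsAsFactors = FALSE)
    }
    truth <- list(true_edit_rates = as.list(per_position_rates),
                  indel_rate = indel_rate, edit_type = edit_type,
                  seed = seed)
    list(reads = reads, truth = truth)
  })
}

#' Map protospacer positions 1-20 to 0-based reference positions
#'
#' Position 1 is PAM-distal; for a minus-strand site the walk runs 3'->5'
#' along the top strand.
#'
#' @param site A `target_site`.
#' @return Integer vector of length 20 (0-based reference positions), named
#'   by protospacer position.
#' @export
protospacer_ref_positions <- function(site) {
  p <- 1:20
  out <- if (site$strand == "+") site$position + p - 1L
         else site$position + 20L - p
  names(out) <- p
  out
}
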