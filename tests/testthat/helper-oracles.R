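# Shared fixtures and independent oracles used across the suite. The
# oracles deliberately avoid the package's own code paths: the off-target
# oracle tests every window with a per-window predicate, and the breakpoint
# oracle finds insertion sites by exhaustive junction-substring search.

# Build a 200-bp amplicon with a plus-strand protospacer at 0-based
# position 60, an AGG PAM, and editable bases planted at the given
# protospacer positions.
make_test_amplicon <- function(seed, editable_at = 4:9, edit_type = "A>G") {
  from <- substr(edit_type, 1L, 1L)
  amp <- beditkit:::with_seed(seed, beditkit:::rand_dna(200L, 0.5))
  substr(amp, 81L, 83L) <- "AGG"
  proto <- substr(amp, 61L, 80L)
  for (p in editable_at) substr(proto, p, p) <- from
  substr(amp, 61L, 80L) <- proto
  site <- target_site(proto, pam = "NGG", ref_name = "site1",
                      position = 60L, strand = "+")
  list(amplicon = amp, site = site, protospacer = proto)
}

# Editable protospacer positions of a site for one edit type.
editable_positions <- function(site, edit_type = "A>G") {
  which(strsplit(site$protospacer, "")[[1]] == substr(edit_type, 1L, 1L))
}

# Oracle: every protospacer+PAM window on both strands, tested one window
# at a time with plain substring extraction.
oracle_offtarget_scan <- function(genome, proto, mode, max_mm = 3L,
                                  seed_len = 12L, seed_max_mm = 2L,
                                  nonseed_max_mm = 3L, pam = "NRG") {
  L <- nchar(genome)
  pp <- strsplit(proto, "")[[1]]
  seed_idx <- (20L - seed_len + 1L):20L
  rows <- list()
  for (strand in c("+", "-")) {
    for (s in 0:(L - 23L)) {
      win <- if (strand == "+") substr(genome, s + 1L, s + 23L)
             else revcomp(substr(genome, L - s - 22L, L - s))
      p2 <- substr(win, 22L, 22L)
      p3 <- substr(win, 23L, 23L)
      pam_ok <- if (pam == "NRG") p2 %in% c("A", "G") && p3 == "G"
                else p2 == "G" && p3 == "G"
      if (!pam_ok) next
      wp <- strsplit(substr(win, 1L, 20L), "")[[1]]
      mm <- sum(wp != pp)
      mm_seed <- sum(wp[seed_idx] != pp[seed_idx])
      keep <- if (mode == "total_mm") mm <= max_mm
              else mm_seed <= seed_max_mm &&
                   (mm - mm_seed) <= nonseed_max_mm
      if (keep) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = if (strand == "+") s else L - s - 23L,
          strand = strand, mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Plant a protospacer+PAM copy with a given number of mismatches into a
# genome at a 0-based window start.
plant_offtarget <- function(genome, proto, n_mm, at, strand) {
  p <- strsplit(proto, "")[[1]]
  if (n_mm > 0L) {
    for (i in sample(20L, n_mm)) {
      p[i] <- sample(setdiff(c("A", "C", "G", "T"), p[i]), 1L)
    }
  }
  w <- paste0(paste(p, collapse = ""), "TGG")
  if (strand == "-") w <- revcomp(w)
  substr(genome, at + 1L, at + 23L) <- w
  genome
}

# Oracle: recover insertion positions by exhaustive junction-substring
# search. For every plasmid position p and cargo orientation, build the two
# 40-nt junction strings an insertion with TSD t would create and look for
# them verbatim in the read set (either strand).
oracle_junction_search <- function(reads_seq, plasmid, cargo, tsd_len) {
  L <- plasmid$sequence$length
  haystack <- paste(c(reads_seq, revcomp(reads_seq)), collapse = "#")
  found <- integer(0)
  for (orient in c("+", "-")) {
    cg <- if (orient == "+") cargo else revcomp(cargo)
    clen <- nchar(cg)
    for (p in 0:(L - 1L)) {
      jl <- paste0(circ_substr(plasmid$sequence, p + tsd_len - 20L, 20L),
                   substr(cg, 1L, 20L))
      jr <- paste0(substr(cg, clen - 19L, clen),
                   circ_substr(plasmid$sequence, p, 20L))
      if (grepl(jl, haystack, fixed = TRUE) ||
          grepl(jr, haystack, fixed = TRUE)) {
        found <- c(found, p)
      }
    }
  }
  sort(unique(found))
}

# Random variant set keyed for set-algebra comparisons.
random_variant_df <- function(n, max_pos = 1000L) {
  pos <- sample.int(max_pos, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1), USE.NAMES = FALSE)
  data.frame(chrom = rep("chr1", n), pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

vkey <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
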