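# Off-target analysis: transcriptome edit filtering, three-caller consensus
# SNV calling with a paired control (GOTI-style), substitution-class
# summaries, fold-change arithmetic, and a protospacer-mismatch scanner with
# PAM constraint for guide-dependent site prediction.

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Filter candidate RNA edits
#'
#' Keeps a candidate iff (1) its depth is at least `min_depth`, (2) the
#' wild-type control supports the reference allele at a fraction of at least
#' `min_control_ref_fraction`, and (3) the substitution, expressed on the
#' transcribed (gene) strand, is A>G in ABE mode or C>T in CBE mode.
#' Candidates on a minus-strand gene are complemented before the
#' substitution test (so T>C on the sequenced strand passes in ABE mode).
#'
#' @param candidates data.frame with columns chrom, pos, ref, alt, depth,
#'   gene_strand, control_ref_fraction.
#' @param mode "ABE" or "CBE".
#' @param min_depth Minimum sequencing depth.
#' @param min_control_ref_fraction Minimum reference-allele fraction in the
#'   wild-type samples.
#' @return The subset of `candidates` passing all three rules.
#' @export
filter_rna_edits <- function(candidates, mode = c("ABE", "CBE"),
                             min_depth = 10L,
                             min_control_ref_fraction = 0.99) {
  mode <- match.arg(mode)
  want <- if (mode == "ABE") c(from = "A", to = "G") else c(from = "C", to = "T")
  if (nrow(candidates) == 0L) return(candidates)
  stopifnot(all(candidates$gene_strand %in% c("+", "-")))
  ts_ref <- ifelse(candidates$gene_strand == "+", candidates$ref,
                   complement_base(candidates$ref))
  ts_alt <- ifelse(candidates$gene_strand == "+", candidates$alt,
                   complement_base(candidates$alt))
  keep <- candidates$depth >= min_depth &
    candidates$control_ref_fraction >= min_control_ref_fraction &
    ts_ref == want["from"] & ts_alt == want["to"]
  candidates[keep, , drop = FALSE]
}

#' Consensus SNV set from three callers minus a paired control
#'
#' The variants reported by all callers (matching on chrom, pos, ref, alt —
#' depth and quality metadata are ignored, since callers disagree on those
#' for the same event), with any variant also present in the paired control
#' sample removed.
#'
#' @param caller_sets List of per-caller variant data.frames (chrom, pos,
#'   ref, alt, ...).
#' @param control_set Variant data.frame of the paired control sample.
#' @return A `consensus_set`: list with `variants` (data.frame), `n_input`
#'   (per-caller sizes), `n_intersection`, `n_consensus`
#'   (control-subtracted count).
#' @export
goti_consensus <- function(caller_sets, control_set = NULL) {
  stopifnot(is.list(caller_sets), length(caller_sets) >= 1L)
  keys <- lapply(caller_sets, variant_key)
  inter <- Reduce(intersect, keys)
  if (is.null(control_set)) {
    control_keys <- character(0)
  } else {
    control_keys <- variant_key(control_set)
  }
  final <- setdiff(inter, control_keys)
  first <- caller_sets[[1L]]
  variants <- first[variant_key(first) %in% final,
                    c("chrom", "pos", "ref", "alt"), drop = FALSE]
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(variants = variants,
                 n_input = vapply(caller_sets, nrow, integer(1)),
                 n_intersection = length(inter),
                 n_consensus = length(final)),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("<consensus_set> inputs %s -> intersection %d -> %d after control subtraction\n",
              paste(x$n_input, collapse = "/"), x$n_intersection,
              x$n_consensus))
  invisible(x)
}

#' Classify consensus SNVs into strand-symmetric substitution classes
#'
#' The 12 substitutions collapse to 6 classes by pairing each change with
#' its complement (C>T with G>A, and so on). `proportion_CG_to_TA` is the
#' fraction of SNVs in the C:G>T:A class, the signature of
#' cytosine-deaminase off-target activity; it is NA for an empty set (with
#' no SNVs the proportion cannot be quantified).
#'
#' @param variants data.frame with columns ref, alt (or a `consensus_set`).
#' @return A `snv_class_summary`: list with `counts` (named by class),
#'   `total`, `proportion_CG_to_TA`.
#' @export
classify_snvs <- function(variants) {
  if (inherits(variants, "consensus_set")) variants <- variants$variants
  classes <- c("C:G>T:A", "C:G>A:T", "C:G>G:C",
               "T:A>A:T", "T:A>C:G", "T:A>G:C")
  counts <- stats::setNames(integer(length(classes)), classes)
  n <- nrow(variants)
  if (n > 0L) {
    ref <- ifelse(variants$ref %in% c("C", "T"), variants$ref,
                  complement_base(variants$ref))
    alt <- ifelse(variants$ref %in% c("C", "T"), variants$alt,
                  complement_base(variants$alt))
    cls <- paste0(ref, ":", complement_base(ref), ">",
                  alt, ":", complement_base(alt))
    tab <- table(factor(cls, levels = classes))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, total = n,
                 proportion_CG_to_TA = if (n == 0L) NA_real_
                                       else unname(counts["C:G>T:A"]) / n),
            class = "snv_class_summary")
}

#' @export
print.snv_class_summary <- function(x, ...) {
  cat(sprintf("<snv_class_summary> %d SNVs, C:G>T:A proportion %s\n",
              x$total,
              if (is.na(x$proportion_CG_to_TA)) "NA"
              else sprintf("%.2f", x$proportion_CG_to_TA)))
  print(x$counts)
  invisible(x)
}

#' Fold change between two off-target SNV counts
#'
#' @param n_reference_editor SNV count of the reference editor.
#' @param n_test_editor SNV count of the editor under test (denominator).
#' @return `list(ratio, rounded)`; a zero denominator yields `Inf` (an
#'   "infinite reduction" sentinel), never an error.
#' @export
#' @examples
#' fold_reduction(20739, 88)$rounded  # 236
#' fold_reduction(773, 18)$rounded    # 43
fold_reduction <- function(n_reference_editor, n_test_editor) {
  stopifnot(n_reference_editor >= 0, n_test_editor >= 0)
  if (n_test_editor == 0) {
    return(list(ratio = Inf, rounded = Inf))
  }
  r <- n_reference_editor / n_test_editor
  list(ratio = r, rounded = round(r))
}

pam_matches <- function(p1, p2, p3, pam) {
  if (pam == "NGG") p2 == "G" & p3 == "G"
  else p2 %in% c("A", "G") & p3 == "G"   # NRG
}

#' Predict guide-dependent off-target sites by mismatch scanning
#'
#' Scans both strands of a genome for 23-nt windows whose last 3 nt match
#' the PAM pattern (N = any base, R = A or G) and whose first 20 nt match
#' the protospacer within the mismatch budget. `total_mm` mode keeps
#' windows with at most `max_mm` protospacer mismatches (Cas-OFFinder-style
#' setting); `seed_aware` mode keeps windows with at most `seed_max_mm`
#' mismatches in the PAM-proximal `seed_len` bases AND at most
#' `nonseed_max_mm` in the remainder (CasOT-style setting).
#'
#' @param genome DNA string.
#' @param site `target_site` providing the 20-nt protospacer.
#' @param mode "total_mm" or "seed_aware".
#' @param max_mm Total mismatch budget (total_mm mode).
#' @param seed_len PAM-proximal seed length (seed_aware mode).
#' @param seed_max_mm,nonseed_max_mm Seed / non-seed budgets (seed_aware
#'   mode).
#' @param pam PAM pattern, "NGG" or "NRG".
#' @return data.frame with columns position (0-based start of the 23-nt
#'   protospacer+PAM window in forward-genome coordinates), strand,
#'   mismatches (and seed_mismatches in seed_aware mode), sorted by
#'   position.
#' @export
predict_guide_dependent_sites <- function(genome, site,
                                          mode = c("total_mm", "seed_aware"),
                                          max_mm = 3L, seed_len = 12L,
                                          seed_max_mm = 2L,
                                          nonseed_max_mm = 3L,
                                          pam = c("NRG", "NGG")) {
  mode <- match.arg(mode)
  pam <- match.arg(pam)
  assert_dna(genome, "genome")
  empty <- data.frame(position = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  L <- nchar(genome)
  if (L < 23L) return(empty)
  proto <- str_chars(site$protospacer)
  seed_pos <- (20L - seed_len + 1L):20L   # PAM-proximal
  scan_strand <- function(s) {
    g <- str_chars(s)
    nw <- nchar(s) - 22L
    w0 <- seq_len(nw)                     # 1-based window starts
    mm_total <- integer(nw)
    mm_seed <- integer(nw)
    for (p in 1:20) {
      neq <- g[w0 + p - 1L] != proto[p]
      mm_total <- mm_total + neq
      if (p %in% seed_pos) mm_seed <- mm_seed + neq
    }
    pam_ok <- pam_matches(g[w0 + 20L], g[w0 + 21L], g[w0 + 22L], pam)
    keep <- if (mode == "total_mm") {
      pam_ok & mm_total <= max_mm
    } else {
      pam_ok & mm_seed <= seed_max_mm &
        (mm_total - mm_seed) <= nonseed_max_mm
    }
    data.frame(start0 = w0[keep] - 1L, mismatches = mm_total[keep],
               seed_mismatches = mm_seed[keep], stringsAsFactors = FALSE)
  }
  fwd <- scan_strand(genome)
  fwd$strand <- if (nrow(fwd)) "+" else character(0)
  fwd$position <- fwd$start0
  rev <- scan_strand(revcomp(genome))
  rev$strand <- if (nrow(rev)) "-" else character(0)
  rev$position <- L - rev$start0 - 23L    # forward-genome start of the window
  out <- rbind(fwd, rev)
  cols <- c("position", "strand", "mismatches")
  if (mode == "seed_aware") cols <- c(cols, "seed_mismatches")
  out <- out[order(out$position, out$strand), cols, drop = FALSE]
  rownames(out) <- NULL
  out
}
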