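# Emulated somatic-caller outputs for the consensus-calling stage: each
# caller reports each true SNV with its own sensitivity plus caller-private
# false positives, on top of germline-like variants shared by every caller
# and by the paired control sample.

random_snvs <- function(n, genome_len, chrom = "chr1", exclude_pos = integer(0)) {
  bases <- c("A", "C", "G", "T")
  pos <- integer(0)
  while (length(pos) < n) {
    cand <- sample.int(genome_len, n - length(pos))
    pos <- unique(c(pos, setdiff(cand, exclude_pos)))
  }
  pos <- pos[seq_len(n)]
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1),
                USE.NAMES = FALSE)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Simulate random true SNVs on a toy genome
#'
#' @param n Number of SNVs.
#' @param genome_len Genome length (positions are 1-based, unique).
#' @param seed Integer seed.
#' @param chrom Chromosome label.
#' @return data.frame with columns chrom, pos, ref, alt.
#' @export
simulate_true_snvs <- function(n, genome_len, seed = NULL, chrom = "chr1") {
  with_seed(seed, random_snvs(n, genome_len, chrom))
}

#' Emulate per-caller SNV call sets for an edited and a control sample
#'
#' Each of `n_callers` callers reports every true SNV independently with its
#' own sensitivity, plus `Poisson(fp_rate * genome_len)` caller-private false
#' positives. Germline-like variants are shared across all callers and both
#' samples; the control sample consists of exactly these, so subtracting the
#' paired control removes them from any downstream consensus.
#'
#' @param true_snvs data.frame (chrom, pos, ref, alt) of edited-sample-only
#'   true variants.
#' @param n_callers Number of callers to emulate.
#' @param sensitivity Per-caller detection probability (recycled to
#'   `n_callers`).
#' @param fp_rate Per-base false-positive rate per caller.
#' @param genome_len Toy genome length.
#' @param n_germline Number of shared germline-like variants.
#' @param seed Integer seed.
#' @return `list(edited = list of per-caller data.frames, control =
#'   data.frame, truth = true_snvs)`.
#' @export
simulate_caller_outputs <- function(true_snvs, n_callers = 3L,
                                    sensitivity = 1, fp_rate = 0,
                                    genome_len = 1e6L, n_germline = 0L,
                                    seed = NULL) {
  sensitivity <- rep_len(sensitivity, n_callers)
  with_seed(seed, {
    germline <- if (n_germline > 0L) {
      random_snvs(n_germline, genome_len, unique(true_snvs$chrom)[1],
                  exclude_pos = true_snvs$pos)
    } else true_snvs[0L, c("chrom", "pos", "ref", "alt")]
    taken <- c(true_snvs$pos, germline$pos)
    edited <- lapply(seq_len(n_callers), function(i) {
      det <- true_snvs[stats::runif(nrow(true_snvs)) < sensitivity[i], ,
                       drop = FALSE]
      n_fp <- stats::rpois(1L, fp_rate * genome_len)
      fp <- if (n_fp > 0L) {
        random_snvs(n_fp, genome_len, unique(true_snvs$chrom)[1],
                    exclude_pos = taken)
      } else true_snvs[0L, c("chrom", "pos", "ref", "alt")]
      taken <<- c(taken, fp$pos)
      out <- rbind(det[, c("chrom", "pos", "ref", "alt")], germline, fp)
      out[order(out$pos), , drop = FALSE]
    })
    list(edited = edited, control = germline, truth = true_snvs)
  })
}
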