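# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so generators are pure functions of
#' (parameters, seed) and never perturb the caller's RNG stream.
#'
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

#' Reverse a string
#' @keywords internal
str_rev <- function(x) {
  vapply(x, function(s) rawToChar(rev(charToRaw(s))), character(1),
         USE.NAMES = FALSE)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector over the DNA alphabet.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")   # "ACGT"
#' revcomp("AAAC")   # "GTTT"
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", str_rev(x))
}

#' Complement (no reversal)
#' @keywords internal
complement_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Check DNA alphabet
#' @keywords internal
is_dna <- function(x) grepl("^[ACGT]*$", x)

assert_dna <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !is_dna(x)) {
    stop(what, " must be a single string over {A,C,G,T}", call. = FALSE)
  }
  invisible(x)
}

#' Split a string into single characters
#' @keywords internal
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Sample random DNA of given length and GC content
#' @keywords internal
rand_dna <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Sense (non-stop) codons of the standard genetic code.
sense_codons <- function() {
  codons <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                  paste0), c("T", "C", "A", "G"), paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
}
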