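# Format plumbing: FASTA/FASTQ via Biostrings, feature/site tables as TSV,
# ground truth as JSON, minimal per-caller VCFs, and a light SAM reader for
# pre-aligned input. TSV files may start with '#' metadata lines, which all
# readers here skip.

#' Read a single-sequence FASTA file
#' @param path FASTA file.
#' @return Named character vector of sequences (upper case).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (and optionally
#'   `mate`; mate number is appended to the id as `/1`, `/2`).
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  ids <- reads$id
  if (!is.null(reads$mate)) ids <- paste0(ids, "/", reads$mate)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Read a FASTQ file into a reads data.frame
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path, call. = FALSE)
  i <- seq(1L, length(lines), 4L)
  data.frame(id = sub("^@", "", lines[i]),
             seq = toupper(lines[i + 1L]),
             qual = lines[i + 3L],
             stringsAsFactors = FALSE)
}

#' Write plasmid features as a BED-like TSV
#' @param features Feature data.frame (name, start, end, strand, kind).
#' @param path Output file.
#' @param header Optional character vector of '#'-prefixed metadata lines.
#' @export
write_features <- function(features, path, header = NULL) {
  write_tsv(features, path, header = header)
}

#' Read plasmid features from TSV
#' @param path File written by [write_features()].
#' @return Feature data.frame.
#' @export
read_features <- function(path) {
  read_tsv(path, colClasses = c(start = "integer", end = "integer"))
}

#' Write target sites as TSV
#' @param sites List of `target_site` objects or a data.frame.
#' @param path Output file.
#' @param header Optional metadata lines.
#' @export
write_sites <- function(sites, path, header = NULL) {
  if (!is.data.frame(sites)) {
    sites <- do.call(rbind, lapply(sites, function(s) {
      data.frame(name = s$ref_name, protospacer = s$protospacer, pam = s$pam,
                 position = s$position, strand = s$strand,
                 stringsAsFactors = FALSE)
    }))
  }
  write_tsv(sites, path, header = header)
}

#' Read target sites from TSV
#' @param path File written by [write_sites()].
#' @return List of `target_site` objects.
#' @export
read_sites <- function(path) {
  df <- read_tsv(path, colClasses = c(position = "integer"))
  lapply(seq_len(nrow(df)), function(i) {
    target_site(df$protospacer[i], pam = df$pam[i], ref_name = df$name[i],
                position = df$position[i], strand = df$strand[i])
  })
}

#' Write a TSV with optional '#' metadata header lines
#' @keywords internal
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV, skipping '#' metadata lines
#' @keywords internal
read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = colClasses)
}

#' Serialize synthetic ground truth to JSON
#' @param truth A truth list from a simkit generator.
#' @param path Output file.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read synthetic ground truth from JSON
#' @param path File written by [write_truth()].
#' @return Truth list; data.frame components restored.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in intersect(names(x), c("true_insertions", "true_snvs"))) {
    x[[nm]] <- as.data.frame(x[[nm]], stringsAsFactors = FALSE)
  }
  x
}

#' Write a minimal VCF v4.2 for one caller/sample
#'
#' Emits CHROM, POS, REF, ALT plus a single sample column with AD
#' (ref,alt depths) and DP, which is all the consensus and filter logic
#' consumes.
#'
#' @param variants data.frame with columns chrom, pos (1-based), ref, alt and
#'   optionally depth, alt_count.
#' @param path Output file.
#' @param sample Sample name for the genotype column.
#' @export
write_caller_vcf <- function(variants, path, sample = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample, sep = "\t")), con)
  if (nrow(variants) > 0L) {
    depth <- if (is.null(variants$depth)) rep(30L, nrow(variants)) else variants$depth
    altc <- if (is.null(variants$alt_count)) pmax(1L, depth %/% 2L) else variants$alt_count
    writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                     variants$alt, ".", "PASS", ".", "AD:DP",
                     paste0(depth - altc, ",", altc, ":", depth),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal per-caller VCF
#' @param path VCF file with single-base REF/ALT records.
#' @return data.frame with columns chrom, pos, ref, alt, depth, alt_count.
#' @export
read_caller_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(),
                      alt_count = integer(), stringsAsFactors = FALSE)
  if (length(body) == 0L) return(empty)
  f <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(f)
  if (any(nfield < 8L)) stop("malformed VCF record in ", path, call. = FALSE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  out <- data.frame(chrom = get(1L), pos = as.integer(get(2L)),
                    ref = get(4L), alt = get(5L),
                    depth = NA_integer_, alt_count = NA_integer_,
                    stringsAsFactors = FALSE)
  if (all(nfield >= 10L)) {
    fmt <- strsplit(get(9L), ":", fixed = TRUE)
    val <- strsplit(get(10L), ":", fixed = TRUE)
    for (i in seq_len(nrow(out))) {
      dp <- match("DP", fmt[[i]])
      ad <- match("AD", fmt[[i]])
      if (!is.na(dp)) out$depth[i] <- as.integer(val[[i]][dp])
      if (!is.na(ad)) {
        out$alt_count[i] <- as.integer(strsplit(val[[i]][ad], ",")[[1]][2L])
      }
    }
  }
  out
}

#' Read aligned reads from a SAM file
#'
#' Accepts the plain-text SAM subset insmap consumes: QNAME, FLAG, RNAME,
#' POS, MAPQ, CIGAR, SEQ (other fields ignored). The CIGAR is trusted, so
#' [align_to_backbone()] is skipped for these reads.
#'
#' @param path SAM file.
#' @return data.frame with columns id, seq, ref_start (0-based), cigar,
#'   mapq, strand; unmapped records (FLAG 0x4 or CIGAR "*") are dropped.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      ref_start = integer(), cigar = character(),
                      mapq = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 10L)) stop("malformed SAM record in ", path, call. = FALSE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2L))
  out <- data.frame(id = get(1L), seq = toupper(get(10L)),
                    ref_start = as.integer(get(4L)) - 1L, cigar = get(6L),
                    mapq = as.integer(get(5L)),
                    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    stringsAsFactors = FALSE)
  out[!(bitwAnd(flag, 4L) > 0L | out$cigar == "*"), , drop = FALSE]
}
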