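# Reproducible runs tying the stages together. Each subcommand reads
# standard-format inputs, runs the corresponding module functions with the
# configured thresholds, and writes TSV/VCF/FASTQ outputs whose '#' headers
# record tool version, a hash of the resolved configuration, and the seed.

pkg_version <- function() {
  as.character(utils::packageVersion("beditkit"))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[order(names(config))],
                              auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

run_header <- function(config) {
  c(sprintf("beditkit %s", pkg_version()),
    sprintf("config_hash=%s", config_hash(config)),
    sprintf("seed=%s", if (is.null(config$seed)) "NA" else config$seed))
}

default_config <- function() {
  list(
    seed = 1L,
    # simulate-library
    cds_len_aa = 300L, gc = 0.5, n_insertions = 100L, tsd_len = 5L,
    cargo_len = 1200L, read_len = 150L, flank = 70L, error_rate = 0,
    # map-insertions
    k = 21L, min_anchor = 30L, min_clip_len = 20L, min_cargo_match = 15L,
    cds_name = "ncas9",
    # simulate-amplicon / quantify-editing
    n_reads = 2000L, edit_type = "A>G", indel_rate = 0,
    min_overlap = 11L, min_mapq = 20L, min_baseq = 30L,
    # filter-rna-edits
    mode = "ABE", min_depth = 10L, min_control_ref_fraction = 0.99,
    # predict-offtargets
    scan_mode = "total_mm", max_mm = 3L, seed_len = 12L, seed_max_mm = 2L,
    nonseed_max_mm = 3L, pam = "NRG")
}

resolve_config <- function(config) {
  base <- default_config()
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  base
}

#' Read a YAML run configuration
#' @param path YAML file of subcommand parameters.
#' @return Named list merged over the package defaults.
#' @export
read_config <- function(path) resolve_config(yaml::read_yaml(path))

#' Run one pipeline subcommand
#'
#' Subcommands: `simulate-library`, `simulate-amplicon`, `map-insertions`,
#' `quantify-editing`, `filter-rna-edits`, `goti-consensus`,
#' `predict-offtargets`, `report`. All thresholds default to the package's
#' documented values; every tabular output starts with '#' header lines
#' naming the tool version, the hash of the resolved configuration, and the
#' seed, and reruns with the same config are byte-identical.
#'
#' @param subcommand Subcommand name.
#' @param config Named list of parameters and input/output paths (see the
#'   per-module functions for semantics); missing entries take defaults.
#' @param out_dir Directory for outputs (created if needed).
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(subcommand, config = list(), out_dir = ".") {
  config <- resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- run_header(config)
  p <- function(name) file.path(out_dir, name)
  out <- switch(
    subcommand,
    "simulate-library" = {
      plasmid <- make_screen_plasmid(config$seed, config$cds_len_aa,
                                     config$gc)
      cargo <- with_seed(config$seed + 1L, rand_dna(config$cargo_len, 0.5))
      lib <- simulate_insertion_library(plasmid, cargo, config$n_insertions,
                                        tsd_len = config$tsd_len,
                                        seed = config$seed + 2L)
      reads <- simulate_junction_reads(plasmid, lib$truth, cargo,
                                       read_len = config$read_len,
                                       flank = config$flank,
                                       error_rate = config$error_rate,
                                       seed = config$seed + 3L)
      write_fasta(c(backbone = plasmid$sequence$seq), p("backbone.fasta"))
      write_fasta(c(cargo = cargo), p("cargo.fasta"))
      write_features(plasmid$features, p("features.tsv"), header = hdr)
      write_fastq(reads, p("reads.fastq"))
      write_truth(lib$truth, p("truth.json"))
      list(backbone = p("backbone.fasta"), cargo = p("cargo.fasta"),
           features = p("features.tsv"), reads = p("reads.fastq"),
           truth = p("truth.json"))
    },
    "map-insertions" = {
      plasmid <- load_plasmid(config$backbone, config$features)
      cargo <- unname(read_fasta(config$cargo)[1L])
      reads <- if (grepl("\\.sam$", config$reads)) read_sam(config$reads)
               else read_fastq(config$reads)
      calls <- map_insertions(reads, plasmid, cargo, k = config$k,
                              min_anchor = config$min_anchor,
                              min_clip_len = config$min_clip_len,
                              tsd_len = config$tsd_len,
                              min_cargo_match = config$min_cargo_match,
                              cds_name = config$cds_name)
      prof <- summarize_profile(calls, plasmid, cds_name = config$cds_name)
      write_tsv(calls, p("insertion_calls.tsv"), header = hdr)
      write_tsv(data.frame(position = seq_along(prof$per_position) - 1L,
                           count = prof$per_position),
                p("insertion_histogram.tsv"), header = hdr)
      write_tsv(data.frame(feature = names(prof$per_feature),
                           count = as.integer(prof$per_feature)),
                p("feature_totals.tsv"),
                header = c(hdr, sprintf("fraction_aa_covered=%.6f",
                                        prof$fraction_aa_covered)))
      list(calls = p("insertion_calls.tsv"),
           histogram = p("insertion_histogram.tsv"),
           features = p("feature_totals.tsv"))
    },
    "simulate-amplicon" = {
      amp <- with_seed(config$seed, rand_dna(200L, 0.5))
      site <- place_protospacer(amp, config$edit_type, seed = config$seed + 1L)
      rates <- default_rate_profile(site$site, config$edit_type)
      sim <- simulate_amplicon_reads(site$amplicon, site$site, rates,
                                     indel_rate = config$indel_rate,
                                     n_reads = config$n_reads,
                                     edit_type = config$edit_type,
                                     error_rate = config$error_rate,
                                     seed = config$seed + 2L)
      write_fasta(c(amplicon = site$amplicon), p("amplicon.fasta"))
      write_sites(list(site$site), p("sites.tsv"), header = hdr)
      write_fastq(sim$reads, p("amplicon_reads.fastq"))
      write_truth(sim$truth, p("amplicon_truth.json"))
      list(amplicon = p("amplicon.fasta"), sites = p("sites.tsv"),
           reads = p("amplicon_reads.fastq"),
           truth = p("amplicon_truth.json"))
    },
    "quantify-editing" = {
      amp <- unname(read_fasta(config$amplicon)[1L])
      site <- read_sites(config$sites)[[1L]]
      reads <- read_fastq(config$reads)
      reads$mate <- as.integer(sub("^.*/", "", reads$id))
      reads$id <- sub("/[12]$", "", reads$id)
      q <- quantify_editing(reads, amp, site, edit_type = config$edit_type,
                            min_overlap = config$min_overlap,
                            min_mapq = config$min_mapq,
                            min_baseq = config$min_baseq)
      write_tsv(data.frame(position = as.integer(names(q$profile$rate)),
                           ref_base = substr(config$edit_type, 1L, 1L),
                           depth = as.integer(q$profile$depth),
                           rate = as.numeric(q$profile$rate)),
                p("editing_rates.tsv"), header = hdr)
      write_tsv(data.frame(indel_reads = q$indels$indel_reads,
                           total_reads = q$indels$total_reads,
                           frequency = q$indels$frequency),
                p("indels.tsv"), header = hdr)
      list(rates = p("editing_rates.tsv"), indels = p("indels.tsv"))
    },
    "filter-rna-edits" = {
      cand <- read_tsv(config$candidates)
      filt <- filter_rna_edits(cand, mode = config$mode,
                               min_depth = config$min_depth,
                               min_control_ref_fraction =
                                 config$min_control_ref_fraction)
      write_tsv(filt, p("rna_edits_filtered.tsv"), header = hdr)
      list(filtered = p("rna_edits_filtered.tsv"))
    },
    "goti-consensus" = {
      sets <- lapply(config$caller_vcfs, read_caller_vcf)
      control <- if (is.null(config$control_vcf)) NULL
                 else read_caller_vcf(config$control_vcf)
      cons <- goti_consensus(sets, control)
      cls <- classify_snvs(cons)
      write_caller_vcf(cons$variants, p("consensus.vcf"),
                       sample = "consensus")
      write_tsv(data.frame(class = names(cls$counts),
                           count = as.integer(cls$counts)),
                p("snv_classes.tsv"),
                header = c(hdr,
                           sprintf("total=%d", cls$total),
                           sprintf("proportion_CG_to_TA=%s",
                                   format(cls$proportion_CG_to_TA))))
      list(consensus = p("consensus.vcf"), classes = p("snv_classes.tsv"))
    },
    "predict-offtargets" = {
      genome <- unname(read_fasta(config$genome)[1L])
      site <- read_sites(config$sites)[[1L]]
      hits <- predict_guide_dependent_sites(
        genome, site, mode = config$scan_mode, max_mm = config$max_mm,
        seed_len = config$seed_len, seed_max_mm = config$seed_max_mm,
        nonseed_max_mm = config$nonseed_max_mm, pam = config$pam)
      hits <- cbind(chrom = rep(names(read_fasta(config$genome))[1L],
                                nrow(hits)),
                    hits, mode = rep(config$scan_mode, nrow(hits)))
      write_tsv(hits, p("offtarget_sites.tsv"), header = hdr)
      list(sites = p("offtarget_sites.tsv"))
    },
    "report" = {
      pieces <- list()
      if (!is.null(config$calls)) {
        calls <- read_tsv(config$calls)
        pieces$n_insertion_sites <- nrow(calls)
        pieces$total_support <- sum(calls$support)
      }
      if (!is.null(config$rates)) {
        rates <- read_tsv(config$rates)
        pieces$mean_editing_rate <- mean(rates$rate, na.rm = TRUE)
        pieces$max_editing_rate <- max(rates$rate, na.rm = TRUE)
      }
      if (!is.null(config$classes)) {
        cls <- read_tsv(config$classes)
        pieces$total_snvs <- sum(cls$count)
      }
      df <- data.frame(metric = names(pieces),
                       value = unlist(pieces, use.names = FALSE))
      write_tsv(df, p("report.tsv"), header = hdr)
      list(report = p("report.tsv"))
    },
    stop("unknown subcommand: ", subcommand, call. = FALSE))
  invisible(out)
}

#' Load a plasmid map from FASTA + feature TSV
#' @param fasta_path Backbone FASTA.
#' @param features_path Feature TSV from [write_features()].
#' @return A `plasmid_map` (premature-stop annotation not restored).
#' @export
load_plasmid <- function(fasta_path, features_path) {
  seq <- unname(read_fasta(fasta_path)[1L])
  plasmid_map(seq, read_features(features_path))
}

# Find a 20-nt window followed by a suitable PAM that contains editable
# bases in the editing window, patching in a PAM if none exists naturally.
place_protospacer <- function(amplicon, edit_type, seed = NULL) {
  with_seed(seed, {
    start <- 60L
    substr(amplicon, start + 21L, start + 23L) <- "AGG"
    proto <- substr(amplicon, start + 1L, start + 20L)
    ch <- parse_change(edit_type)
    # guarantee editable bases at canonical window positions 4-8
    for (p in c(5L, 6L, 7L)) substr(proto, p, p) <- ch$from
    substr(amplicon, start + 1L, start + 20L) <- proto
    list(amplicon = amplicon,
         site = target_site(proto, pam = "NGG", ref_name = "site1",
                            position = start, strand = "+"))
  })
}

default_rate_profile <- function(site, edit_type) {
  ch <- parse_change(edit_type)
  proto <- str_chars(site$protospacer)
  editable <- which(proto == ch$from)
  # bell-shaped activity centred on the canonical editing window (pos ~6)
  rates <- 0.7 * exp(-((editable - 6)^2) / 8)
  stats::setNames(round(rates, 4), editable)
}
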