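test_that("screen plasmid generation is deterministic and well-formed", {
  p1 <- make_screen_plasmid(42L)
  p2 <- make_screen_plasmid(42L)
  expect_identical(p1$sequence$seq, p2$sequence$seq)
  expect_identical(p1$features, p2$features)
  # features pairwise disjoint
  f <- p1$features
  for (i in seq_len(nrow(f) - 1L)) {
    expect_lte(f$end[i], f$start[i + 1L])
  }
  # premature stop is a stop and reverts to Gln by the T>C (bottom-strand
  # A>G) edit
  stop_codon <- beditkit:::feature_codon(p1, "ampR", 118L)
  expect_identical(translate_cds(stop_codon), "*")
  expect_identical(predict_edit_consequence(stop_codon, 1L, "T>C")$residue,
                   "Q")
  # CDS bodies carry no other stop codon
  aa <- translate_cds(feature_seq(p1, "ampR"))
  expect_identical(gregexpr("*", aa, fixed = TRUE)[[1]][1], 118L)
  expect_error(make_screen_plasmid(1L, cds_len_aa = 5L), ">= 10")
})

test_that("insertion events conserve length and record canonical positions", {
  pl <- make_screen_plasmid(7L)
  L <- pl$sequence$length
  lib0 <- simulate_insertion_library(pl, "ACGTACGTAA", 3L, tsd_len = 0L,
                                     seed = 1L)
  expect_true(all(nchar(lib0$sequences) == L + 10L))
  lib5 <- simulate_insertion_library(pl, "ACGTACGTAA", 3L, tsd_len = 5L,
                                     seed = 1L)
  expect_true(all(nchar(lib5$sequences) == L + 10L + 5L))
  # the TSD flanks the cargo: bases [pos, pos+5) appear before and after it
  tr <- lib5$truth$true_insertions
  for (i in seq_len(nrow(tr))) {
    tsd <- circ_substr(pl$sequence, tr$position[i], 5L)
    expect_identical(substr(lib5$sequences[i], 1L, 5L), tsd)
    cargo_obs <- substr(lib5$sequences[i], 6L, 15L)
    expect_true(cargo_obs %in% c("ACGTACGTAA", revcomp("ACGTACGTAA")))
    expect_identical(substr(lib5$sequences[i], 16L, 20L), tsd)
  }
  expect_error(simulate_insertion_library(pl, "", 1L), "non-empty")
})

test_that("insertion positions are uniform over the plasmid", {
  pl <- make_screen_plasmid(7L)
  L <- pl$sequence$length
  lib <- simulate_insertion_library(pl, "ACGT", 10000L, seed = 3L,
                                    sequences = FALSE)
  bins <- cut(lib$truth$true_insertions$position, breaks = 20L)
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
  expect_true(all(lib$truth$true_insertions$position >= 0L &
                    lib$truth$true_insertions$position < L))
})

test_that("selection keeps only in-frame CDS insertions, weighted by tolerance", {
  pl <- make_screen_plasmid(11L)
  cds <- pl$features[pl$features$name == "ncas9", ]
  n_aa <- (cds$end - cds$start) %/% 3L
  # constructed events: in-frame at aa 150, out-of-frame next to it, and
  # one outside the CDS entirely
  truth <- list(true_insertions = data.frame(
    position = c(cds$start + 149L * 3L, cds$start + 149L * 3L + 1L, 10L),
    orientation = "+", stringsAsFactors = FALSE))
  tol <- rep(0, n_aa)
  tol[150L] <- 1
  surv <- simulate_selection(truth, pl, tol, cargo_len = 300L,
                             n_colonies = 40L, seed = 6L)
  expect_identical(nrow(surv), 40L)
  expect_true(all(surv$aa_position == 150L))
  expect_true(all((surv$position - cds$start) %% 3L == 0L))
  # out-of-frame cargo never survives, nor does an all-zero tolerance
  expect_error(simulate_selection(truth, pl, tol, cargo_len = 301L,
                                  n_colonies = 5L, seed = 6L),
               "no survivors")
  expect_error(simulate_selection(truth, pl, rep(0, n_aa),
                                  cargo_len = 300L, n_colonies = 5L,
                                  seed = 6L),
               "no survivors")
  # survivor frequencies proportional to tolerance for equally common events
  truth2 <- list(true_insertions = data.frame(
    position = rep(cds$start + c(99L, 199L) * 3L, each = 50L),
    orientation = "+", stringsAsFactors = FALSE))
  tol2 <- rep(0, n_aa)
  tol2[c(100L, 200L)] <- c(0.2, 0.8)
  surv2 <- simulate_selection(truth2, pl, tol2, cargo_len = 300L,
                              n_colonies = 500L, seed = 8L)
  share <- mean(surv2$aa_position == 200L)
  se <- sqrt(0.8 * 0.2 / 500L)
  expect_lt(abs(share - 0.8), 3 * se)
})

test_that("read simulator honors counts, error rate, and perfect-substring reads", {
  tpl <- beditkit:::with_seed(2L, beditkit:::rand_dna(3000L, 0.5))
  r0 <- simulate_reads(tpl, 50L, error_rate = 0, seed = 4L)
  expect_identical(nrow(r0), 50L)
  expect_true(all(vapply(r0$seq, grepl, logical(1), x = tpl,
                         fixed = TRUE)))
  expect_true(all(r0$qual == strrep("F", 150L)))
  # circular wrap: reads from a circular template may span the origin
  rc <- simulate_reads(tpl, 200L, error_rate = 0, seed = 5L, circular = TRUE)
  doubled <- paste0(tpl, tpl)
  expect_true(all(vapply(rc$seq, grepl, logical(1), x = doubled,
                         fixed = TRUE)))
  # paired mode: mate 2 is the reverse complement of the fragment end
  rp <- simulate_reads(tpl, 30L, paired = TRUE, insert_size = 300L,
                       error_rate = 0, seed = 6L)
  expect_identical(nrow(rp), 60L)
  for (id in unique(rp$id)[1:5]) {
    m1 <- rp$seq[rp$id == id & rp$mate == 1L]
    m2 <- revcomp(rp$seq[rp$id == id & rp$mate == 2L])
    frag_start <- regexpr(m1, tpl, fixed = TRUE)[1]
    expect_identical(substr(tpl, frag_start + 150L, frag_start + 299L), m2)
  }
  # observed mismatch fraction close to the error rate
  rate <- 0.01
  re <- simulate_reads(tpl, 400L, error_rate = rate, seed = 7L)
  n_err <- sum(vapply(re$qual, function(q) {
    sum(strsplit(q, "")[[1]] == "/")
  }, numeric(1)))
  n_tot <- 400L * 150L
  expect_lt(abs(n_err / n_tot - rate), 3 * sqrt(rate * (1 - rate) / n_tot))
  expect_error(simulate_reads("ACGT", 1L), "shorter")
})

test_that("amplicon simulator plants edits at the stated rates and positions", {
  fx <- make_test_amplicon(31L)
  ed <- editable_positions(fx$site)
  rates <- stats::setNames(rep(0, length(ed)), ed)
  sim <- simulate_amplicon_reads(fx$amplicon, fx$site, rates, n_reads = 50L,
                                 seed = 1L, paired = FALSE)
  expect_true(all(sim$reads$seq == fx$amplicon))  # all rates 0 -> reference
  rates["5"] <- 1
  sim1 <- simulate_amplicon_reads(fx$amplicon, fx$site, rates, n_reads = 50L,
                                  seed = 1L, paired = FALSE)
  expect_true(all(substr(sim1$reads$seq, 65L, 65L) == "G"))  # rate 1 -> all
  non_editable <- setdiff(1:20, editable_positions(fx$site))[1L]
  expect_error(
    simulate_amplicon_reads(fx$amplicon, fx$site,
                            stats::setNames(0.5, non_editable), n_reads = 5L,
                            seed = 1L),
    "editable base")
})

test_that("caller emulation reduces to truth at perfect sensitivity", {
  truth <- simulate_true_snvs(50L, 1e6L, seed = 2L)
  out <- simulate_caller_outputs(truth, sensitivity = 1, fp_rate = 0,
                                 seed = 3L)
  for (s in out$edited) {
    expect_setequal(vkey(s), vkey(truth))
  }
  out0 <- simulate_caller_outputs(truth, sensitivity = 0, fp_rate = 0,
                                  seed = 3L)
  expect_identical(goti_consensus(out0$edited, out0$control)$n_consensus, 0L)
  # expected three-way intersection ~ s1*s2*s3 per true SNV
  sens <- c(0.9, 0.8, 0.7)
  hits <- vapply(1:15, function(i) {
    o <- simulate_caller_outputs(truth, sensitivity = sens, fp_rate = 0,
                                 seed = 1000L + i)
    goti_consensus(o$edited, o$control)$n_consensus
  }, integer(1))
  expected <- nrow(truth) * prod(sens)
  se <- sqrt(nrow(truth) * prod(sens) * (1 - prod(sens)) / 15L)
  expect_lt(abs(mean(hits) - expected), 3 * se)
})
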