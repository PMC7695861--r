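test_that("RNA edit filtering applies depth, control, and strand rules exactly", {
  cand <- data.frame(
    chrom = "chr1", pos = 1:8,
    ref = c("A", "A", "A", "A", "T", "C", "A", "T"),
    alt = c("G", "G", "G", "G", "C", "T", "C", "C"),
    depth = c(10L, 9L, 10L, 10L, 10L, 10L, 10L, 9L),
    gene_strand = c("+", "+", "+", "+", "-", "+", "+", "+"),
    control_ref_fraction = c(0.99, 0.99, 0.989, 0.99, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  kept <- filter_rna_edits(cand, "ABE")
  # row 1 passes; row 2 fails depth (9 < 10); row 3 fails control (0.989);
  # row 4 passes; row 5 is T>C on a minus-strand gene = A>G transcribed ->
  # passes; row 6 is C>T (CBE-type) -> fails in ABE mode; row 7 is A>C ->
  # fails; row 8 fails depth
  expect_identical(kept$pos, c(1L, 4L, 5L))
  # CBE mode keeps the C>T candidate instead
  expect_identical(filter_rna_edits(cand, "CBE")$pos, 6L)
  # output is a subset of input, and tightening thresholds never grows it
  k2 <- filter_rna_edits(cand, "ABE", min_depth = 20L)
  expect_true(all(k2$pos %in% kept$pos))
  k3 <- filter_rna_edits(cand, "ABE", min_control_ref_fraction = 0.999)
  expect_true(all(k3$pos %in% kept$pos))
  expect_error(filter_rna_edits(cand, "XBE"))
})

test_that("consensus equals naive set algebra on random caller sets", {
  set.seed(71)
  for (i in 1:20) {
    s1 <- random_variant_df(sample(5:40, 1L))
    s2 <- random_variant_df(sample(5:40, 1L))
    s3 <- random_variant_df(sample(5:40, 1L))
    ctrl <- random_variant_df(sample(0:10, 1L))
    cs <- goti_consensus(list(s1, s2, s3), ctrl)
    expected <- setdiff(Reduce(intersect, list(vkey(s1), vkey(s2), vkey(s3))),
                        vkey(ctrl))
    expect_setequal(vkey(cs$variants), expected)
    # consensus is contained in every caller set and excludes the control
    expect_true(all(vkey(cs$variants) %in% vkey(s1)))
    expect_true(all(vkey(cs$variants) %in% vkey(s2)))
    expect_true(all(vkey(cs$variants) %in% vkey(s3)))
    expect_false(any(vkey(cs$variants) %in% vkey(ctrl)))
  }
  # worked examples
  v <- function(pos) data.frame(chrom = rep("c", length(pos)), pos = pos,
                                ref = rep("A", length(pos)),
                                alt = rep("G", length(pos)),
                                stringsAsFactors = FALSE)
  expect_identical(goti_consensus(list(v(1:2), v(1:2), v(1:2)),
                                  v(integer(0)))$n_consensus, 2L)
  expect_identical(goti_consensus(list(v(c(1, 2)), v(c(1, 3)), v(1)),
                                  v(integer(0)))$variants$pos, 1)
  expect_identical(goti_consensus(list(v(1), v(1), v(1)), v(1))$n_consensus,
                   0L)
})

test_that("SNV classes collapse strand-symmetrically with the C:G>T:A proportion", {
  v <- data.frame(ref = c(rep("C", 15L), rep("G", 8L), rep("A", 2L)),
                  alt = c(rep("T", 15L), rep("A", 8L), rep("G", 2L)),
                  stringsAsFactors = FALSE)
  cls <- classify_snvs(v)
  expect_identical(unname(cls$counts["C:G>T:A"]), 23L)
  expect_identical(unname(cls$counts["T:A>C:G"]), 2L)
  expect_identical(cls$proportion_CG_to_TA, 0.92)
  expect_identical(sum(cls$counts), cls$total)
  # all A>G -> proportion 0; empty set -> missing, not 0
  expect_identical(classify_snvs(data.frame(ref = "A", alt = "G"))$proportion_CG_to_TA, 0)
  expect_true(is.na(classify_snvs(v[0L, ])$proportion_CG_to_TA))
})

test_that("fold-change arithmetic matches the worked examples", {
  r <- fold_reduction(20739, 88)
  expect_equal(r$ratio, 235.67, tolerance = 1e-4)
  expect_identical(r$rounded, 236)
  r <- fold_reduction(773, 18)
  expect_equal(r$ratio, 42.944, tolerance = 1e-4)
  expect_identical(r$rounded, 43)
  expect_identical(fold_reduction(10, 10)$rounded, 1)
  expect_identical(fold_reduction(5, 0)$ratio, Inf)
})

test_that("mismatch scanner equals brute-force enumeration with planted sites", {
  set.seed(82)
  proto <- beditkit:::rand_dna(20L, 0.5)
  site <- target_site(proto, pam = "NRG", position = 0L)
  g <- beditkit:::rand_dna(4000L, 0.5)
  for (i in 0:4) {
    g <- plant_offtarget(g, proto, i, 300L + i * 700L,
                         if (i %% 2L == 0L) "+" else "-")
  }
  for (mode in c("total_mm", "seed_aware")) {
    mine <- predict_guide_dependent_sites(g, site, mode = mode)
    oracle <- oracle_offtarget_scan(g, proto, mode)
    expect_identical(mine[, c("position", "strand", "mismatches")], oracle)
  }
  # the planted perfect site is reported with zero mismatches in both modes
  perfect <- predict_guide_dependent_sites(g, site, mode = "total_mm")
  expect_true(any(perfect$position == 300L & perfect$mismatches == 0L))
  # a 4-mismatch plant is absent under a total budget of 3
  expect_false(any(predict_guide_dependent_sites(g, site,
                                                 mode = "total_mm")$position ==
                     300L + 4L * 700L))
  # NGG is stricter than NRG
  nrg <- predict_guide_dependent_sites(g, site, pam = "NRG")
  ngg <- predict_guide_dependent_sites(g, site, pam = "NGG")
  expect_true(all(ngg$position %in% nrg$position))
  # genomes shorter than one window yield an empty result
  expect_identical(nrow(predict_guide_dependent_sites("ACGT", site)), 0L)
})

test_that("caller-recovery pipeline: perfect callers return truth, s^3 otherwise", {
  truth <- simulate_true_snvs(150L, 5e5L, seed = 91L)
  o <- simulate_caller_outputs(truth, sensitivity = 1, fp_rate = 0,
                               n_germline = 20L, seed = 92L)
  cs <- goti_consensus(o$edited, o$control)
  expect_setequal(vkey(cs$variants), vkey(truth))
  recalls <- vapply(1:20, function(i) {
    o <- simulate_caller_outputs(truth, sensitivity = 0.8, fp_rate = 0,
                                 n_germline = 20L, seed = 200L + i)
    goti_consensus(o$edited, o$control)$n_consensus / nrow(truth)
  }, numeric(1))
  p <- 0.8^3
  se <- sqrt(p * (1 - p) / (150L * 20L))
  expect_lt(abs(mean(recalls) - p), 3 * se)
})
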