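test_that("pair merging applies the overlap threshold and quality rules", {
  tpl <- beditkit:::with_seed(12L, beditkit:::rand_dna(80L, 0.5))
  q <- strrep("F", 80L)
  # identical fully-overlapping mates merge into themselves
  m <- merge_read_pairs(tpl, q, revcomp(tpl), q)
  expect_true(m$merged)
  expect_identical(m$seq, tpl)
  # true overlap of 10 is below an 11-base threshold
  left <- beditkit:::with_seed(13L, beditkit:::rand_dna(50L, 0.5))
  right <- beditkit:::with_seed(14L, beditkit:::rand_dna(50L, 0.5))
  ov <- substr(tpl, 1L, 10L)
  r1 <- paste0(left, ov)
  r2 <- revcomp(paste0(ov, right))
  expect_false(merge_read_pairs(r1, strrep("F", 60L), r2,
                                strrep("F", 60L),
                                min_overlap = 11L)$merged)
  expect_true(merge_read_pairs(r1, strrep("F", 60L), r2, strrep("F", 60L),
                               min_overlap = 10L)$merged)
  # disagreeing position: higher-quality base wins, quality max - min
  frag <- paste0(left, ov, right)[1]     # 110 nt
  r1 <- substr(frag, 1L, 60L)
  r2 <- revcomp(substr(frag, 41L, 100L))  # overlap 20 (positions 41-60)
  r2d <- r2
  substr(r2d, 60L, 60L) <- if (substr(r2, 60L, 60L) == "A") "C" else "A"
  # the altered base is mate 2's last sequenced base = fragment position 41;
  # give it Q14 against mate 1's Q37
  q2 <- paste0(strrep("F", 59L), "/")
  m <- merge_read_pairs(r1, strrep("F", 60L), r2d, q2)
  expect_true(m$merged)
  expect_identical(nchar(m$seq), 100L)
  expect_identical(substr(m$seq, 41L, 41L), substr(frag, 41L, 41L))
  expect_identical(utf8ToInt(substr(m$qual, 41L, 41L)) - 33L, 37L - 14L)
})

test_that("pileup counts only bases passing mapq and base-quality filters", {
  amp <- strrep("C", 30L)
  hi <- data.frame(id = "a", seq = strrep("C", 30L), qual = strrep("F", 30L),
                   ref_start = 0L, cigar = "30M", mapq = 60L,
                   stringsAsFactors = FALSE)
  lo <- transform(hi, qual = strrep("/", 30L))
  badmap <- transform(hi, mapq = 10L)
  p <- build_pileup(rbind(hi, hi, hi), c(0L, 30L), amp)
  expect_true(all(p$depth == 3L))
  expect_true(all(p$C == 3L))
  # Q14 bases vanish under a -b 30 filter; mapq 10 under -q 20
  expect_true(all(build_pileup(lo, c(0L, 30L), amp)$depth == 0L))
  expect_true(all(build_pileup(badmap, c(0L, 30L), amp)$depth == 0L))
  # lowering min_baseq never decreases depth
  p14 <- build_pileup(rbind(hi, lo), c(0L, 30L), amp, min_baseq = 14L)
  p30 <- build_pileup(rbind(hi, lo), c(0L, 30L), amp, min_baseq = 30L)
  expect_true(all(p14$depth >= p30$depth))
  # mixed column: 60 of 100 reads carry T at a C position
  reads <- rbind(hi[rep(1L, 40L), ],
                 transform(hi, seq = paste0(strrep("C", 10L), "T",
                                            strrep("C", 19L)))[rep(1L, 60L), ])
  pm <- build_pileup(reads, c(0L, 30L), amp)
  col <- pm[pm$ref_pos == 10L, ]
  expect_identical(col$T, 60L)
  expect_identical(conversion_rate(col, "C", "T"), 0.6)
  expect_error(build_pileup(hi, c(5L, 5L), amp), "empty region")
})

test_that("conversion rate distinguishes zero from missing", {
  col <- data.frame(ref_pos = 0L, ref_base = "C", A = 0L, C = 100L, G = 0L,
                    T = 0L, depth = 100L)
  expect_identical(conversion_rate(col, "C", "T"), 0)
  col0 <- transform(col, C = 0L, depth = 0L)
  expect_true(is.na(conversion_rate(col0, "C", "T")))
  expect_error(conversion_rate(col, "A", "G"), "reference base")
})

test_that("protospacer profiles are strand-invariant and editable-base-only", {
  fx <- make_test_amplicon(51L, editable_at = c(5L, 7L))
  ed <- editable_positions(fx$site)
  rates <- stats::setNames(rep(0, length(ed)), ed)
  rates[c("5", "7")] <- c(0.5, 0.2)
  sim <- simulate_amplicon_reads(fx$amplicon, fx$site, rates,
                                 n_reads = 3000L, seed = 52L)
  q <- quantify_editing(sim$reads, fx$amplicon, fx$site)
  expect_setequal(names(q$profile$rate), as.character(ed))
  tol <- 3 * sqrt(rates * (1 - rates) / 3000L)
  expect_true(all(abs(q$profile$rate[names(rates)] - rates) <=
                    pmax(tol, 0.005)))
  # same molecules, site annotated on the minus strand of the flipped
  # amplicon -> identical profile
  amp2 <- revcomp(fx$amplicon)
  site2 <- target_site(fx$site$protospacer, pam = "NGG", ref_name = "site1",
                       position = nchar(amp2) - fx$site$position - 20L,
                       strand = "-")
  sim2 <- simulate_amplicon_reads(amp2, site2, rates, n_reads = 3000L,
                                  seed = 52L)
  q2 <- quantify_editing(sim2$reads, amp2, site2)
  expect_identical(q$profile$rate, q2$profile$rate)
  # a protospacer without the editable base yields an empty profile
  proto_nc <- gsub("C", "T", gsub("A", "G", fx$site$protospacer))
  pile <- data.frame(ref_pos = 0:199,
                     ref_base = strsplit(strrep("G", 200L), "")[[1]],
                     A = 0L, C = 0L, G = 10L, T = 0L, depth = 10L,
                     stringsAsFactors = FALSE)
  site_nc <- target_site(proto_nc, pam = "NGG", position = 60L)
  expect_length(protospacer_profile(pile, site_nc, "A>G")$rate, 0L)
})

test_that("indel frequency counts reads with I/D ops over the protospacer only", {
  base <- data.frame(id = "r", seq = strrep("A", 50L), qual = strrep("F", 50L),
                     ref_start = 0L, mapq = 60L, stringsAsFactors = FALSE)
  clean <- transform(base, cigar = "50M")
  del_in <- transform(base, cigar = "25M1D25M")     # D at ref pos 25
  del_out <- transform(base, cigar = "5M1D45M")     # D at ref pos 5
  ins_in <- transform(base, cigar = "25M1I24M")     # I at ref pos 25
  reads <- rbind(clean[rep(1L, 45L), ], del_in[rep(1L, 5L), ])
  st <- indel_frequency(reads, c(20L, 40L))
  expect_identical(st$indel_reads, 5L)
  expect_identical(st$total_reads, 50L)
  expect_identical(st$frequency, 0.1)
  expect_identical(indel_frequency(del_out, c(20L, 40L))$indel_reads, 0L)
  expect_identical(indel_frequency(ins_in, c(20L, 40L))$indel_reads, 1L)
  expect_identical(indel_frequency(clean, c(20L, 40L))$frequency, 0)
})

test_that("window summaries average only sites carrying each position", {
  mk <- function(rates) {
    structure(list(site = NULL, edit_type = "A>G", rate = rates,
                   depth = rates * 0 + 100), class = "editing_profile")
  }
  p1 <- mk(c("5" = 0.2, "6" = 0.1))
  p2 <- mk(c("6" = 0.4))
  ws <- window_summary(list(p1, p2))
  expect_identical(ws$mean[ws$position == 6L], 0.25)
  expect_identical(ws$n_sites[ws$position == 5L], 1L)
  expect_identical(ws$se[ws$position == 5L], 0)
  expect_false(7L %in% ws$position)
  single <- window_summary(list(p1))
  expect_identical(single$mean, unname(p1$rate[c("5", "6")]))
})
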