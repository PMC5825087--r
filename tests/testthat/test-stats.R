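test_that("an empty stream yields an all-zero profile", {
  def <- parse_fsld(FSLD_5MER)
  p <- profile_reads(character(0), def)
  expect_identical(p$total_reads, 0L)
  expect_identical(p$valid_reads, 0L)
  expect_length(p$dna_counts, 0)
  expect_true(all(p$base_pos_counts == 0))
  expect_true(all(p$residue_pos_counts == 0))
})

test_that("repeated windows accumulate into every counter", {
  def <- parse_fsld(FSLD_5MER)
  recs <- records_for_windows(rep("AAATTTGGGCCCATG", 3), def)
  p <- profile_reads(recs, def)
  expect_identical(p$valid_reads, 3L)
  expect_identical(p$dna_counts, c(AAATTTGGGCCCATG = 3))
  expect_identical(p$peptide_counts, c(KFGPM = 3))
  expect_equal(p$base_pos_counts["A", 1], 3)
  expect_equal(p$residue_pos_counts["K", 1], 3)
})

test_that("exhaustive enumeration fills every positional cell equally", {
  def <- parse_fsld(FSLD_2COD)
  p <- profile_reads(enumerate_exhaustive(def), def)
  expect_identical(p$valid_reads, 4096L)
  expect_length(p$dna_counts, 4096L)
  # each base appears in 4^5 of the 4^6 windows at every position
  expect_true(all(p$base_pos_counts == 4^5))
})

test_that("profile column sums are conserved under arbitrary input", {
  def <- parse_fsld("CCGATTNNKVNNTAGCAT")
  set.seed(23)
  # mix of valid constructions and junk reads
  wins <- vapply(seq_len(300), function(i) {
    paste0(vapply(def$random_patterns, sample, character(1), size = 1),
           collapse = "")
  }, character(1))
  recs <- records_for_windows(wins, def)
  junk <- data.frame(read_id = sprintf("j%d", 1:100),
                     sequence = random_dna(100, 40),
                     quality = strrep("I", 40), stringsAsFactors = FALSE)
  p <- profile_reads(rbind(recs, junk), def)
  expect_equal(sum(p$dna_counts), p$valid_reads)
  expect_equal(sum(p$peptide_counts), p$valid_reads)
  expect_equal(unname(colSums(p$base_pos_counts)),
               rep(p$valid_reads, def$n_random_bases))
  expect_equal(unname(colSums(p$residue_pos_counts)),
               rep(p$valid_reads, def$n_residues))
  expect_equal(sum(p$strand_counts), p$valid_reads)
})

test_that("merging profiles equals profiling the concatenated stream", {
  def <- parse_fsld(FSLD_2COD)
  set.seed(31)
  recs <- records_for_windows(random_dna(500, 6), def)
  flip <- runif(500) < 0.4
  recs$sequence[flip] <- reverse_complement(recs$sequence[flip])
  whole <- profile_reads(recs, def)
  a <- profile_reads(recs[1:200, ], def)
  b <- profile_reads(recs[201:500, ], def)
  merged <- merge_profiles(a, b)
  expect_equal(merged$total_reads, whole$total_reads)
  expect_equal(merged$valid_reads, whole$valid_reads)
  expect_equal(merged$strand_counts, whole$strand_counts)
  expect_equal(merged$dna_counts[order(names(merged$dna_counts))],
               whole$dna_counts[order(names(whole$dna_counts))])
  expect_equal(merged$base_pos_counts, whole$base_pos_counts)
  expect_equal(merged$residue_pos_counts, whole$residue_pos_counts)
  expect_error(merge_profiles(a, profile_reads(character(0), parse_fsld(FSLD_5MER))),
               "different library definitions")
})

test_that("coverage statistics reproduce the worked percentages", {
  expect_equal(coverage_percent(972372, 4^15), 0.09)
  expect_equal(coverage_percent(644214, 20^5), 20.13)
  def <- parse_fsld(FSLD_2COD)
  p <- profile_reads(records_for_windows(c("AAAAAA", "AAAAAA", "CCCGGG"), def), def)
  cov <- coverage_stats(p)
  expect_identical(cov$unique_dna, 2L)
  expect_equal(cov$theoretical_dna, 4096)
  expect_equal(cov$dna_not_found, 4094)
  expect_equal(cov$dna_coverage_pct, round(100 * 2 / 4096, 2))
  # stop-containing peptides are counted unless explicitly dropped
  pstop <- profile_reads(records_for_windows(c("TAGAAA", "AAAAAA"), def), def)
  expect_identical(coverage_stats(pstop)$unique_pep, 2L)
  expect_identical(coverage_stats(pstop, drop_stop_peptides = TRUE)$unique_pep, 1L)
  # empty profile: zero coverage, everything missing
  cov0 <- coverage_stats(profile_reads(character(0), def))
  expect_equal(cov0$dna_coverage_pct, 0)
  expect_equal(cov0$dna_not_found, cov0$theoretical_dna)
})

test_that("frequency-of-frequencies sums to the unique and read totals", {
  cc <- count_of_counts(c(A = 2, B = 1))
  expect_equal(cc$times_seen, c(1, 2))
  expect_equal(cc$n_sequences, c(1, 1))
  expect_equal(nrow(count_of_counts(numeric(0))), 0L)
  set.seed(41)
  counts <- table(sample(letters, 5000, replace = TRUE, prob = runif(26)))
  counts <- structure(as.numeric(counts), names = names(counts))
  cc <- count_of_counts(counts)
  expect_equal(sum(cc$times_seen * cc$n_sequences), sum(counts))
  expect_equal(sum(cc$n_sequences), length(counts))
  expect_equal(cc$cum_frac_unique[nrow(cc)], 1)
  expect_equal(cc$cum_frac_reads[nrow(cc)], 1)
})

test_that("occupancy of a saturating library matches multinomial expectation", {
  # low-complexity design (8 windows) sequenced far past saturation
  def <- parse_fsld("AAASSWTTT")
  k <- theoretical_dna_complexity(def)
  expect_equal(k, 8)
  set.seed(53)
  n <- 8000
  recs <- records_for_windows(
    vapply(seq_len(n), function(i) {
      paste0(vapply(def$random_patterns, sample, character(1), size = 1),
             collapse = "")
    }, character(1)), def)
  p <- profile_reads(recs, def)
  expect_identical(length(p$dna_counts), 8L)
  # per-window counts are Binomial(n, 1/8): all within 4 sigma of n/8
  expect_true(all(abs(p$dna_counts - n / 8) < 4 * sqrt(n * (1 / 8) * (7 / 8))))
})

test_that("top sequences rank by count with lexicographic tie-break", {
  top <- top_sequences(c(GGG = 1, CCC = 5, AAA = 5), k = 2)
  expect_identical(top$sequence, c("AAA", "CCC"))
  expect_identical(top$count, c(5, 5))
  expect_identical(nrow(top_sequences(c(A = 1), k = 100)), 1L)
  expect_identical(nrow(top_sequences(numeric(0))), 0L)
})

test_that("enrichment is exactly 1.0 on exhaustive input and errors on empty", {
  def <- parse_fsld(FSLD_2COD)
  p <- profile_reads(enumerate_exhaustive(def), def)
  re <- residue_enrichment(p)
  be <- base_enrichment(p)
  expect_true(all(re$enrichment[re$defined] == 1))
  expect_true(all(be$enrichment[be$defined] == 1))
  expect_false(any(re$contamination))
  expect_true(all(is.na(re$enrichment[!re$defined])))
  # a residue never observed but expected > 0 scores 0
  p1 <- profile_reads(records_for_windows("AAAAAA", def), def)
  re1 <- residue_enrichment(p1)
  expect_equal(re1$enrichment["W", 1], 0)
  expect_error(residue_enrichment(profile_reads(character(0), def)),
               "no valid reads")
})

test_that("expected-weighted enrichment sums to 1 at every position", {
  def <- parse_fsld("CCGATTNNKVNNTAGCAT")
  set.seed(61)
  wins <- vapply(seq_len(500), function(i) {
    paste0(vapply(def$random_patterns, sample, character(1), size = 1),
           collapse = "")
  }, character(1))
  p <- profile_reads(records_for_windows(wins, def), def)
  re <- residue_enrichment(p)
  be <- base_enrichment(p)
  sums_r <- colSums(re$expected_freq * ifelse(re$defined, re$enrichment, 0))
  sums_b <- colSums(be$expected_freq * ifelse(be$defined, be$enrichment, 0))
  expect_equal(unname(sums_r), rep(1, ncol(re$enrichment)), tolerance = 1e-9)
  expect_equal(unname(sums_b), rep(1, ncol(be$enrichment)), tolerance = 1e-9)
})
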