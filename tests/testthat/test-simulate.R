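test_that("simulation is byte-identical under a fixed seed", {
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  for (f in c(f1, f2)) {
    simulate_dataset(FSLD_2COD, 500, f, seed = 9,
                     truth_path = paste0(f, ".tsv"))
  }
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(paste0(f1, ".tsv")), readLines(paste0(f2, ".tsv")))
  # and a different seed changes the data
  f3 <- tempfile(fileext = ".fastq")
  simulate_dataset(FSLD_2COD, 500, f3, seed = 10, truth_path = NULL)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("clean simulations are fully recovered by the profiler", {
  def <- parse_fsld(FSLD_2COD)
  f <- tempfile(fileext = ".fastq.gz")
  truth_path <- tempfile(fileext = ".tsv")
  simulate_dataset(def, 1000, f, seed = 13,
                   corruption_rates = c(frameshift = 0, marker_mutation = 0,
                                        ambiguous_base = 0),
                   truth_path = truth_path)
  p <- profile_fastq(f, def)
  expect_identical(p$total_reads, 1000L)
  expect_identical(p$valid_reads, 1000L)
  # recovered windows match the ground-truth sidecar exactly
  truth <- read.delim(truth_path, header = TRUE, stringsAsFactors = FALSE)
  expect_identical(nrow(truth), 1000L)
  expect_true(all(truth$intended_valid))
  expect_equal(p$dna_counts[sort(unique(truth$window))],
               structure(as.numeric(table(truth$window)),
                         names = sort(unique(truth$window))))
  expect_equal(unname(p$strand_counts[c("forward", "reverse")]),
               unname(as.numeric(table(factor(truth$strand,
                                              c("forward", "reverse"))))))
})

test_that("strand mixing follows fraction_reverse", {
  def <- parse_fsld(FSLD_2COD)
  f <- tempfile(fileext = ".fastq")
  simulate_dataset(def, 400, f, seed = 19, fraction_reverse = 1,
                   corruption_rates = c(frameshift = 0, marker_mutation = 0,
                                        ambiguous_base = 0),
                   truth_path = NULL)
  p <- profile_fastq(f, def)
  expect_identical(p$strand_counts[["forward"]], 0L)
  expect_identical(p$strand_counts[["reverse"]], 400L)
})

test_that("corrupted reads are rejected at close to the injected rate", {
  def <- parse_fsld(FSLD_2COD)
  f <- tempfile(fileext = ".fastq")
  truth_path <- tempfile(fileext = ".tsv")
  simulate_dataset(def, 4000, f, seed = 29,
                   corruption_rates = c(frameshift = 0.1,
                                        marker_mutation = 0.1,
                                        ambiguous_base = 0.05),
                   truth_path = truth_path)
  truth <- read.delim(truth_path, header = TRUE, stringsAsFactors = FALSE)
  p <- profile_fastq(f, def)
  n_clean <- sum(truth$intended_valid)
  # every clean read is recovered; corrupted reads can sporadically still
  # contain a valid site by chance, so allow a small excess
  expect_gte(p$valid_reads, n_clean)
  expect_lte(p$valid_reads - n_clean, 0.02 * nrow(truth))
  expect_true(all(c("frameshift", "marker_mutation", "ambiguous_base") %in%
                    truth$status))
})

test_that("spiked sequences surface at rank one", {
  def <- parse_fsld(FSLD_2COD)
  f <- tempfile(fileext = ".fastq")
  simulate_dataset(def, 20000, f, seed = 37,
                   spike_sequences = c(ACGTAC = 40),
                   corruption_rates = c(frameshift = 0, marker_mutation = 0,
                                        ambiguous_base = 0),
                   truth_path = NULL)
  p <- profile_fastq(f, def)
  top <- top_sequences(p$dna_counts, 1)
  expect_identical(top$sequence, "ACGTAC")
  # weight 40 in a 4096-window library: expected ~ 40/4096 of 20000 reads
  expect_gt(top$count, 100)
})

test_that("injected base skew is recovered within binomial sampling error", {
  def <- parse_fsld(FSLD_2COD)
  w <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  w[, 1] <- c(0.4, 0.2, 0.2, 0.2)
  f <- tempfile(fileext = ".fastq.gz")
  n <- 50000
  simulate_dataset(def, n, f, seed = 43, base_weights = w,
                   corruption_rates = c(frameshift = 0, marker_mutation = 0,
                                        ambiguous_base = 0),
                   truth_path = NULL)
  p <- profile_fastq(f, def)
  be <- base_enrichment(p)
  # enrichment at the skewed position: 3 sigma band of the binomial rate
  for (b in c("A", "C", "G", "T")) {
    sd_rate <- sqrt(w[b, 1] * (1 - w[b, 1]) / n)
    expect_lt(abs(be$enrichment[b, 1] - w[b, 1] / 0.25), 3 * sd_rate / 0.25)
  }
  # unskewed positions stay near 1.0
  expect_true(all(abs(be$enrichment[, 2:6] - 1) < 3 * sqrt(0.25 * 0.75 / n) / 0.25))
})

test_that("simulation validates its configuration", {
  expect_error(simulate_dataset(FSLD_2COD, 10, tempfile(), seed = 1,
                                base_weights = matrix(1, 4, 2)),
               "base_weights")
  w <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  defk <- parse_fsld("AAANNKNNKTTT")
  wk <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(simulate_dataset(defk, 10, tempfile(), seed = 1,
                                base_weights = wk),
               "disallowed base")
  expect_error(simulate_dataset(FSLD_2COD, 10, tempfile(), seed = 1,
                                corruption_rates = c(frameshift = 0.8,
                                                     marker_mutation = 0.5)),
               "sum to at most 1")
  expect_error(simulate_dataset(FSLD_2COD, 10, tempfile(), seed = 1,
                                spike_sequences = c(ACGTAC = 1e9)),
               "probability mass")
})

test_that("exhaustive enumeration is deterministic and guarded", {
  recs1 <- enumerate_exhaustive(FSLD_2COD)
  recs2 <- enumerate_exhaustive(FSLD_2COD)
  expect_identical(recs1, recs2)
  expect_identical(nrow(recs1), 4096L)
  expect_identical(anyDuplicated(recs1$sequence), 0L)
  expect_identical(nrow(enumerate_exhaustive("AAANNKTTT")), 32L)
  expect_error(enumerate_exhaustive(FSLD_5MER), "guard")
})
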