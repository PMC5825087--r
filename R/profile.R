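# Accumulation of the library profile over reads and every derived statistic:
# coverage, frequency-of-frequencies, most-common sequences, and
# observed/expected enrichment tables.

.BASES <- c("A", "C", "G", "T")

.empty_counts <- function() {
  structure(integer(0), names = character(0))
}

.new_profile <- function(libdef, table) {
  structure(
    list(
      libdef = libdef,
      codon_table = table,
      total_reads = 0L,
      valid_reads = 0L,
      strand_counts = c(forward = 0L, reverse = 0L),
      dna_counts = .empty_counts(),
      peptide_counts = .empty_counts(),
      base_pos_counts = matrix(
        0, nrow = 4L, ncol = libdef$n_random_bases,
        dimnames = list(.BASES, paste0("pos", seq_len(libdef$n_random_bases)))),
      residue_pos_counts = matrix(
        0, nrow = length(RESIDUE_ALPHABET), ncol = libdef$n_residues,
        dimnames = list(RESIDUE_ALPHABET, paste0("pos", seq_len(libdef$n_residues))))
    ),
    class = "library_profile"
  )
}

# Sum two named count vectors.
.merge_counts <- function(a, b) {
  if (length(a) == 0L) return(b)
  if (length(b) == 0L) return(a)
  v <- c(a, b)
  m <- rowsum(as.numeric(v), group = names(v))
  out <- as.vector(m)
  names(out) <- rownames(m)
  out
}

#' Profile a set of reads against a library definition
#'
#' Runs the window matcher over every read and accumulates the library
#' profile: total/valid read counts, per-strand counts, unique DNA window and
#' translated peptide occurrence maps, and positional base and residue count
#' matrices. Reads without an acceptable window on either strand are counted
#' in `total_reads` only.
#'
#' @param reads Data.frame of FASTQ records (see [read_fastq()]) or a
#'   character vector of read sequences.
#' @param libdef An [parse_fsld()] library definition.
#' @param table Codon table (default [standard_codon_table()]).
#' @return An object of class `"library_profile"`.
#' @export
profile_reads <- function(reads, libdef, table = standard_codon_table()) {
  stopifnot(inherits(libdef, "fsld"))
  sequences <- if (is.character(reads)) reads else reads$sequence
  prof <- .new_profile(libdef, table)
  prof$total_reads <- length(sequences)
  if (length(sequences) == 0L) return(prof)

  m <- .match_windows(toupper(sequences), libdef)
  ok <- !is.na(m$strand)
  prof$valid_reads <- sum(ok)
  prof$strand_counts <- c(
    forward = sum(m$strand[ok] == "forward"),
    reverse = sum(m$strand[ok] == "reverse")
  )
  windows <- m$window[ok]
  if (length(windows) > 0L) {
    dna_tab <- table(windows)
    prof$dna_counts <- structure(as.numeric(dna_tab), names = names(dna_tab))
    peptides <- translate_dna(windows, table)
    pep_tab <- table(peptides)
    prof$peptide_counts <- structure(as.numeric(pep_tab), names = names(pep_tab))
    for (i in seq_len(libdef$n_random_bases)) {
      prof$base_pos_counts[, i] <-
        as.numeric(table(factor(substr(windows, i, i), levels = .BASES)))
    }
    for (j in seq_len(libdef$n_residues)) {
      prof$residue_pos_counts[, j] <-
        as.numeric(table(factor(substr(peptides, j, j), levels = RESIDUE_ALPHABET)))
    }
  }
  prof
}

#' Profile a FASTQ file in bounded memory
#'
#' Streams the file in chunks, profiles each chunk and merges the partial
#' profiles, so arbitrarily large (plain or Gzip-compressed) datasets are
#' handled in a single pass with bounded memory.
#'
#' @param path FASTQ(.gz) path.
#' @inheritParams profile_reads
#' @param chunk_size Number of reads per chunk.
#' @return A `"library_profile"` with attribute `"malformed"` carrying the
#'   skipped malformed-record count.
#' @export
profile_fastq <- function(path, libdef, table = standard_codon_table(),
                          chunk_size = 250000L) {
  con <- .open_fastq(path)
  on.exit(close(con))
  prof <- .new_profile(libdef, table)
  malformed <- 0L
  any_lines <- FALSE
  repeat {
    lines <- readLines(con, n = 4L * chunk_size, warn = FALSE)
    if (length(lines) == 0L) break
    any_lines <- TRUE
    parsed <- .parse_fastq_lines(lines)
    malformed <- malformed + parsed$malformed
    prof <- merge_profiles(prof, profile_reads(parsed$records, libdef, table))
    if (length(lines) < 4L * chunk_size) break
  }
  if (!any_lines) stop(sprintf("empty FASTQ file '%s'", path), call. = FALSE)
  attr(prof, "malformed") <- malformed
  prof
}

#' Merge two library profiles
#'
#' Associative and commutative combination of profiles built against the same
#' library definition, so chunked or parallel processing yields the same
#' result as profiling the concatenated stream.
#'
#' @param a,b `"library_profile"` objects sharing the same FSLD.
#' @return Combined `"library_profile"`.
#' @export
merge_profiles <- function(a, b) {
  stopifnot(inherits(a, "library_profile"), inherits(b, "library_profile"))
  if (!identical(a$libdef$raw, b$libdef$raw)) {
    stop("profiles were built against different library definitions", call. = FALSE)
  }
  out <- a
  out$total_reads <- a$total_reads + b$total_reads
  out$valid_reads <- a$valid_reads + b$valid_reads
  out$strand_counts <- a$strand_counts + b$strand_counts
  out$dna_counts <- .merge_counts(a$dna_counts, b$dna_counts)
  out$peptide_counts <- .merge_counts(a$peptide_counts, b$peptide_counts)
  out$base_pos_counts <- a$base_pos_counts + b$base_pos_counts
  out$residue_pos_counts <- a$residue_pos_counts + b$residue_pos_counts
  out
}

#' @export
print.library_profile <- function(x, ...) {
  cat("Library profile (", x$libdef$raw, ")\n", sep = "")
  cat(sprintf("  reads: %d total, %d valid (%d forward / %d reverse)\n",
              as.integer(x$total_reads), as.integer(x$valid_reads),
              as.integer(x$strand_counts[["forward"]]),
              as.integer(x$strand_counts[["reverse"]])))
  cat(sprintf("  unique sequences: %d DNA, %d peptide\n",
              length(x$dna_counts), length(x$peptide_counts)))
  invisible(x)
}

#' Coverage percentage of a theoretical library
#'
#' @param n_unique Number of unique sequences observed.
#' @param n_theoretical Theoretical library complexity.
#' @return `100 * n_unique / n_theoretical`, rounded to 2 decimals.
#' @export
coverage_percent <- function(n_unique, n_theoretical) {
  round(100 * n_unique / n_theoretical, 2L)
}

#' Coverage statistics of a profiled library
#'
#' Compares the unique DNA and peptide sequences observed against the
#' theoretical complexity of the library design. Sequence reads are a sample
#' of the library population, so for high-complexity designs the number of
#' sequences not found is expected to be large.
#'
#' @param profile A `"library_profile"`.
#' @param libdef,table Library definition and codon table; default to the
#'   ones stored in the profile.
#' @param drop_stop_peptides If `TRUE`, peptides containing `"*"` are excluded
#'   from the unique-peptide count. By default they are counted (the coverage
#'   denominator always excludes stop-containing designs).
#' @return A list: `unique_dna`, `unique_pep`, `theoretical_dna`,
#'   `theoretical_pep`, `dna_not_found`, `pep_not_found`, `dna_coverage_pct`,
#'   `pep_coverage_pct`.
#' @export
coverage_stats <- function(profile, libdef = profile$libdef,
                           table = profile$codon_table,
                           drop_stop_peptides = FALSE) {
  stopifnot(inherits(profile, "library_profile"))
  unique_dna <- length(profile$dna_counts)
  pep_names <- names(profile$peptide_counts)
  if (drop_stop_peptides && length(pep_names) > 0L) {
    pep_names <- pep_names[!grepl("*", pep_names, fixed = TRUE)]
  }
  unique_pep <- length(pep_names)
  theo_dna <- theoretical_dna_complexity(libdef)
  theo_pep <- theoretical_peptide_complexity(libdef, table)
  list(
    unique_dna = unique_dna,
    unique_pep = unique_pep,
    theoretical_dna = theo_dna,
    theoretical_pep = theo_pep,
    dna_not_found = max(theo_dna - unique_dna, 0),
    pep_not_found = max(theo_pep - unique_pep, 0),
    dna_coverage_pct = coverage_percent(unique_dna, theo_dna),
    pep_coverage_pct = coverage_percent(unique_pep, theo_pep)
  )
}

#' Frequency-of-frequencies (cumulative counts) table
#'
#' Counts how many distinct sequences were observed exactly `k` times. For
#' low-complexity libraries sequenced to high coverage this occupancy
#' distribution concentrates around reads/complexity; for sparse sampling of
#' large libraries most observed sequences appear once.
#'
#' @param counts Named occurrence-count vector (e.g. `profile$dna_counts`).
#' @return Data.frame with columns `times_seen`, `n_sequences`,
#'   `cum_frac_unique` (cumulative fraction of distinct sequences) and
#'   `cum_frac_reads` (cumulative fraction of valid reads).
#' @export
count_of_counts <- function(counts) {
  if (length(counts) == 0L) {
    return(data.frame(times_seen = numeric(0), n_sequences = numeric(0),
                      cum_frac_unique = numeric(0), cum_frac_reads = numeric(0)))
  }
  tab <- table(counts)
  k <- as.numeric(names(tab))
  n_k <- as.numeric(tab)
  o <- order(k)
  k <- k[o]; n_k <- n_k[o]
  data.frame(
    times_seen = k,
    n_sequences = n_k,
    cum_frac_unique = cumsum(n_k) / sum(n_k),
    cum_frac_reads = cumsum(k * n_k) / sum(k * n_k)
  )
}

#' Most common sequences
#'
#' @param counts Named occurrence-count vector.
#' @param k Maximum number of entries to return (default 100).
#' @return Data.frame `(rank, sequence, count)` ranked by count descending,
#'   ties broken lexicographically ascending.
#' @export
top_sequences <- function(counts, k = 100L) {
  if (length(counts) == 0L) {
    return(data.frame(rank = integer(0), sequence = character(0),
                      count = numeric(0)))
  }
  o <- order(-counts, names(counts))
  o <- o[seq_len(min(k, length(o)))]
  data.frame(rank = seq_along(o), sequence = names(counts)[o],
             count = unname(counts[o]), stringsAsFactors = FALSE)
}

#' Observed/expected enrichment table
#'
#' Normalises positional occurrence counts by their expectation under the
#' library design: `enrichment = observed / (valid_reads * expected_freq)`.
#' A value of 1.0 means a symbol was observed at exactly its expected rate;
#' above 1 indicates enrichment, below 1 under-representation. Cells whose
#' expected frequency is zero are undefined (`NA`) when unobserved and
#' flagged as contamination (with the raw count retained) when observed.
#'
#' @param observed Count matrix `[symbols x positions]`.
#' @param expected_freq Matching matrix of expected frequencies.
#' @param valid_reads Number of valid reads the counts were accumulated over;
#'   must be positive (no statistics are possible for an empty profile).
#' @return An object of class `"enrichment_table"`: list with `enrichment`
#'   and `expected_freq` matrices, logical `defined` and `contamination`
#'   matrices, and the `observed` counts.
#' @export
enrichment_table <- function(observed, expected_freq, valid_reads) {
  stopifnot(is.matrix(observed), is.matrix(expected_freq),
            all(dim(observed) == dim(expected_freq)))
  if (valid_reads <= 0) {
    stop("no valid reads: enrichment statistics are undefined", call. = FALSE)
  }
  defined <- expected_freq > 0
  contamination <- !defined & observed > 0
  enr <- matrix(NA_real_, nrow = nrow(observed), ncol = ncol(observed),
                dimnames = dimnames(observed))
  enr[defined] <- observed[defined] / (valid_reads * expected_freq[defined])
  structure(
    list(enrichment = enr, expected_freq = expected_freq, defined = defined,
         contamination = contamination, observed = observed,
         valid_reads = valid_reads),
    class = "enrichment_table"
  )
}

#' Residue enrichment heatmap values for a profile
#'
#' Expected rates come from the codon table actually used in the run, so
#' remapped tables (e.g. amber suppression) and restricted codon sets are
#' reflected in the normalisation.
#'
#' @param profile A `"library_profile"` with at least one valid read.
#' @return An `"enrichment_table"` over residues x positions.
#' @export
residue_enrichment <- function(profile) {
  enrichment_table(profile$residue_pos_counts,
                   expected_residue_freqs(profile$libdef, profile$codon_table),
                   profile$valid_reads)
}

#' DNA base enrichment heatmap values for a profile
#'
#' @param profile A `"library_profile"` with at least one valid read.
#' @return An `"enrichment_table"` over bases x positions.
#' @export
base_enrichment <- function(profile) {
  enrichment_table(profile$base_pos_counts,
                   expected_base_freqs(profile$libdef),
                   profile$valid_reads)
}
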