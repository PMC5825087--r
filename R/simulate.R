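# Synthetic phage-library FASTQ generation with known ground truth. Clean
# reads are random flank + upstream marker + sampled window + downstream
# marker + random flank, emitted forward or reverse-complemented; corrupted
# reads exercise every rejection path of the matcher (frameshift after the
# upstream marker, marker mutation, ambiguous base inside the window), and a
# per-read ground-truth sidecar records intent so invalid-read accounting is
# testable, not just the happy path.

.QUALITY_CHARS <- intToUtf8(33:73, multiple = TRUE)  # '!'..'I', Phred+33

.random_pool <- function(n, alphabet) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Substrings of given lengths cut from a shared random pool: cheap random
# flank/quality strings without per-read sampling.
.pool_substrings <- function(pool, lengths) {
  max_start <- nchar(pool) - max(lengths, 0L)
  starts <- sample.int(max(max_start, 1L), length(lengths), replace = TRUE)
  substr(rep(pool, length(lengths)), starts, starts + lengths - 1L)
}

.mutate_one_base <- function(seqs, pos) {
  cur <- substr(seqs, pos, pos)
  repl <- vapply(cur, function(b) sample(setdiff(.BASES, b), 1L), character(1L),
                 USE.NAMES = FALSE)
  substr(seqs, pos, pos) <- repl
  seqs
}

#' Simulate a phage-library NGS dataset with ground truth
#'
#' Generates `n_reads` FASTQ records for a library design, with optional
#' positional base skew, spiked-in sequences, strand mixing and injected
#' invalid reads, plus a tab-separated ground-truth sidecar recording the
#' intended window, strand and validity of every read. Output is
#' deterministic given `seed`.
#'
#' @param fsld FSLD string or [parse_fsld()] object.
#' @param n_reads Number of reads to emit.
#' @param out_fastq Output FASTQ path; a `.gz` suffix selects Gzip output.
#' @param seed Integer seed; the only source of randomness.
#' @param base_weights Optional `4 x n_random_bases` matrix (rows A,C,G,T) of
#'   sampling weights for window bases; weights on disallowed bases must be
#'   zero. Default: uniform over each position's allowed bases.
#' @param spike_sequences Optional named numeric vector: names are window
#'   sequences, values are relative weights where weight 1 equals the
#'   expected rate of any single window under a uniform library
#'   (i.e. a spike of weight `w` is emitted with probability
#'   `w / theoretical_dna_complexity`).
#' @param fraction_reverse Probability a read is emitted as the reverse
#'   complement (default 0.5, emulating unstranded sequencing).
#' @param flank_range Length-2 integer range for the random context flanking
#'   the insert on each side (default 5 to 15 bases).
#' @param corruption_rates Named numeric vector with elements `frameshift`
#'   (one base inserted directly after the upstream marker),
#'   `marker_mutation` (one upstream-marker base substituted) and
#'   `ambiguous_base` (one window base replaced by N).
#' @param quality `"constant"` (all bases `I`, Phred 40) or `"uniform"`
#'   (uniform over the Sanger/Illumina 1.9 range `!`..`I`). Quality is
#'   carried in the FASTQ but plays no role in profiling.
#' @param truth_path Sidecar TSV path (default: `out_fastq` with a
#'   `.truth.tsv` suffix); `NULL` suppresses the sidecar.
#' @param chunk_size Reads generated per chunk (memory bound).
#' @return Invisibly, a list with `fastq`, `truth` and `n_reads`.
#' @export
simulate_dataset <- function(fsld, n_reads, out_fastq, seed,
                             base_weights = NULL,
                             spike_sequences = NULL,
                             fraction_reverse = 0.5,
                             flank_range = c(5L, 15L),
                             corruption_rates = c(frameshift = 0.01,
                                                  marker_mutation = 0.01,
                                                  ambiguous_base = 0.005),
                             quality = c("constant", "uniform"),
                             truth_path = paste0(
                               sub("\\.(fastq|fq)(\\.gz)?$", "", out_fastq),
                               ".truth.tsv"),
                             chunk_size = 250000L) {
  libdef <- if (inherits(fsld, "fsld")) fsld else parse_fsld(fsld)
  quality <- match.arg(quality)
  stopifnot(n_reads >= 0, length(flank_range) == 2L,
            flank_range[1L] >= 0L, flank_range[2L] >= flank_range[1L],
            fraction_reverse >= 0, fraction_reverse <= 1)
  rates <- c(frameshift = 0, marker_mutation = 0, ambiguous_base = 0)
  if (length(corruption_rates) > 0L) {
    if (is.null(names(corruption_rates)) ||
        !all(names(corruption_rates) %in% names(rates))) {
      stop("corruption_rates must be named frameshift/marker_mutation/ambiguous_base",
           call. = FALSE)
    }
    rates[names(corruption_rates)] <- corruption_rates
  }
  if (any(rates < 0) || sum(rates) > 1) {
    stop("corruption rates must be in [0,1] and sum to at most 1", call. = FALSE)
  }
  n_pos <- libdef$n_random_bases
  if (!is.null(base_weights)) {
    stopifnot(is.matrix(base_weights), nrow(base_weights) == 4L,
              ncol(base_weights) == n_pos)
    if (is.null(rownames(base_weights))) rownames(base_weights) <- .BASES
    for (i in seq_len(n_pos)) {
      disallowed <- setdiff(.BASES, libdef$random_patterns[[i]])
      if (any(base_weights[disallowed, i] > 0)) {
        stop(sprintf("base_weights puts mass on a disallowed base at position %d", i),
             call. = FALSE)
      }
      if (sum(base_weights[, i]) <= 0) {
        stop("base_weights columns must have positive mass", call. = FALSE)
      }
    }
  }
  spike_prob <- numeric(0)
  if (!is.null(spike_sequences)) {
    stopifnot(is.numeric(spike_sequences), !is.null(names(spike_sequences)),
              all(nchar(names(spike_sequences)) == n_pos),
              all(spike_sequences >= 0))
    spike_prob <- spike_sequences / theoretical_dna_complexity(libdef)
    if (sum(spike_prob) > 1) {
      stop("spike weights exceed the library's total probability mass", call. = FALSE)
    }
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  gz <- grepl("\\.gz$", out_fastq)
  # truncate outputs, then append chunk-wise
  write_fastq(data.frame(read_id = character(0), sequence = character(0),
                         quality = character(0)), out_fastq, gzip = gz)
  if (!is.null(truth_path)) {
    cat("read_id\tstrand\twindow\tstatus\tspike\tintended_valid\n",
        file = truth_path)
  }

  up <- libdef$upstream_marker
  down <- libdef$downstream_marker
  emitted <- 0L
  while (emitted < n_reads) {
    m <- min(chunk_size, n_reads - emitted)
    cols <- vector("list", n_pos)
    for (i in seq_len(n_pos)) {
      allowed <- libdef$random_patterns[[i]]
      w <- if (is.null(base_weights)) NULL else base_weights[allowed, i]
      cols[[i]] <- sample(allowed, m, replace = TRUE, prob = w)
    }
    windows <- do.call(paste0, cols)

    is_spike <- rep(FALSE, m)
    if (length(spike_prob) > 0L) {
      u <- stats::runif(m)
      edges <- cumsum(spike_prob)
      pick <- findInterval(u, c(0, edges), left.open = TRUE)
      hit <- pick >= 1L & pick <= length(spike_prob) & u <= edges[length(edges)]
      windows[hit] <- names(spike_prob)[pick[hit]]
      is_spike <- hit
    }

    status <- sample(c("clean", names(rates)), m, replace = TRUE,
                     prob = c(1 - sum(rates), rates))

    ups <- rep(up, m)
    mut <- status == "marker_mutation"
    if (any(mut)) {
      pos <- sample.int(nchar(up), sum(mut), replace = TRUE)
      ups[mut] <- .mutate_one_base(ups[mut], pos)
    }
    emitted_windows <- windows
    amb <- status == "ambiguous_base"
    if (any(amb)) {
      pos <- sample.int(n_pos, sum(amb), replace = TRUE)
      w2 <- emitted_windows[amb]
      substr(w2, pos, pos) <- "N"
      emitted_windows[amb] <- w2
    }
    shift <- status == "frameshift"
    inserted <- rep("", m)
    if (any(shift)) inserted[shift] <- sample(.BASES, sum(shift), replace = TRUE)

    pool <- .random_pool(100000L, .BASES)
    lens5 <- sample(seq.int(flank_range[1L], flank_range[2L]), m, replace = TRUE)
    lens3 <- sample(seq.int(flank_range[1L], flank_range[2L]), m, replace = TRUE)
    left <- .pool_substrings(pool, lens5)
    right <- .pool_substrings(pool, lens3)

    reads <- paste0(left, ups, inserted, emitted_windows, down, right)
    rev_flag <- stats::runif(m) < fraction_reverse
    if (any(rev_flag)) reads[rev_flag] <- reverse_complement(reads[rev_flag])

    quals <- if (quality == "constant") {
      strrep("I", nchar(reads))
    } else {
      qpool <- paste0(sample(.QUALITY_CHARS, 100000L, replace = TRUE),
                      collapse = "")
      .pool_substrings(qpool, nchar(reads))
    }
    ids <- sprintf("sim_%08d", emitted + seq_len(m))
    write_fastq(data.frame(read_id = ids, sequence = reads, quality = quals,
                           stringsAsFactors = FALSE),
                out_fastq, gzip = gz, append = TRUE)
    if (!is.null(truth_path)) {
      truth <- data.frame(
        read_id = ids,
        strand = ifelse(rev_flag, "reverse", "forward"),
        window = windows,
        status = status,
        spike = is_spike,
        intended_valid = status == "clean",
        stringsAsFactors = FALSE
      )
      utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE, append = TRUE)
    }
    emitted <- emitted + m
  }
  invisible(list(fastq = out_fastq, truth = truth_path, n_reads = n_reads))
}

#' Enumerate every allowed library window exactly once
#'
#' Produces one clean forward-strand read per allowed window of the design,
#' in deterministic order with no flanks or corruption. Profiling this
#' dataset makes observed counts identical to their expectation, so every
#' defined enrichment cell equals exactly 1.0 — the exact oracle input for
#' the normalised heatmaps.
#'
#' @param fsld FSLD string or [parse_fsld()] object; the theoretical DNA
#'   complexity must not exceed `max_complexity`.
#' @param path Optional FASTQ output path (a `.gz` suffix selects Gzip).
#' @param max_complexity Enumeration guard (default 1e7).
#' @return Data.frame of FASTQ records (also written to `path` if given).
#' @export
enumerate_exhaustive <- function(fsld, path = NULL, max_complexity = 1e7) {
  libdef <- if (inherits(fsld, "fsld")) fsld else parse_fsld(fsld)
  complexity <- theoretical_dna_complexity(libdef)
  if (complexity > max_complexity) {
    stop(sprintf("theoretical DNA complexity %.0f exceeds the enumeration guard (%.0f)",
                 complexity, max_complexity), call. = FALSE)
  }
  g <- expand.grid(rev(libdef$random_patterns), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  windows <- do.call(paste0, rev(g))
  reads <- paste0(libdef$upstream_marker, windows, libdef$downstream_marker)
  records <- data.frame(
    read_id = sprintf("exh_%07d", seq_along(windows)),
    sequence = reads,
    quality = strrep("I", nchar(reads)),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) write_fastq(records, path, gzip = grepl("\\.gz$", path))
  records
}
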