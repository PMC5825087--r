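# Dynamic reading-frame identification: locate the randomized library window
# within a read on either strand.
#
# The accepted-site predicate is: full upstream marker, then n_random_bases
# bases each drawn from the allowed set of its randomized position, then the
# first 3 bases of the downstream marker. Compiling that predicate into a
# single regular expression makes a left-to-right scan find the FIRST site
# satisfying it, which also gives the documented recovery behaviour: a marker
# hit whose candidate window fails (ambiguous base, disallowed base, missing
# downstream 3-mer) is skipped and the scan continues at the next hit.

# Regex for the full accepted site, anchored nowhere. Character classes come
# from the per-position allowed-base sets, so restricted codon sets (NNK and
# friends) are enforced during matching, not post hoc.
.window_regex <- function(libdef) {
  classes <- vapply(libdef$random_patterns, function(set) {
    if (length(set) == 1L) set else paste0("[", paste0(set, collapse = ""), "]")
  }, character(1L))
  paste0(libdef$upstream_marker,
         paste0(classes, collapse = ""),
         substr(libdef$downstream_marker, 1L, 3L))
}

# Vectorised matcher over a character vector of (already uppercased) read
# sequences. Returns a data.frame with one row per read: strand ("forward",
# "reverse" or NA), offset (0-based index of the first randomized base in the
# searched orientation) and window.
.match_windows <- function(sequences, libdef) {
  n <- length(sequences)
  strand <- rep(NA_character_, n)
  offset <- rep(NA_integer_, n)
  window <- rep(NA_character_, n)
  pattern <- .window_regex(libdef)
  up_len <- nchar(libdef$upstream_marker)
  win_len <- libdef$n_random_bases

  hit <- regexpr(pattern, sequences, perl = TRUE)
  fwd <- which(hit > 0L)
  if (length(fwd) > 0L) {
    strand[fwd] <- "forward"
    offset[fwd] <- as.integer(hit[fwd]) - 1L + up_len
    window[fwd] <- substr(sequences[fwd], offset[fwd] + 1L, offset[fwd] + win_len)
  }
  rest <- which(hit <= 0L)
  if (length(rest) > 0L) {
    # Reverse-strand detection: reverse-complement the read and reuse the
    # forward markers, equivalent to scanning with derived backwards markers.
    # Non-IUPAC characters (rare sequencer artefacts) are treated as N so a
    # single bad call never aborts the read.
    rc <- reverse_complement(gsub("[^ACGTRYSWKMBDHVNX]", "N", sequences[rest]))
    hit_rc <- regexpr(pattern, rc, perl = TRUE)
    rev_ok <- hit_rc > 0L
    if (any(rev_ok)) {
      i <- rest[rev_ok]
      strand[i] <- "reverse"
      offset[i] <- as.integer(hit_rc[rev_ok]) - 1L + up_len
      window[i] <- substr(rc[rev_ok], offset[i] + 1L, offset[i] + win_len)
    }
  }
  data.frame(strand = strand, offset = offset, window = window,
             stringsAsFactors = FALSE)
}

#' Locate the randomized library window within a read
#'
#' Scans the read left-to-right for the full upstream marker; at each hit the
#' following `n_random_bases` bases are accepted as the library window iff
#' every base belongs to the allowed set of its randomized position and the
#' next 3 bases equal the first 3 bases of the downstream marker. The first
#' accepted site wins. If the forward scan fails, the identical scan runs on
#' the reverse complement of the read, so reverse-strand reads are detected.
#' Reads containing ambiguous calls (`N`) inside a candidate window are not
#' discarded outright: the scan continues at the next marker occurrence.
#'
#' @param read A single read sequence (character scalar), or a list/data.frame
#'   with a `sequence` element. Case-insensitive.
#' @param libdef An [parse_fsld()] library definition.
#' @return `NULL` if no window is found on either strand (a normal outcome,
#'   tallied as an invalid read); otherwise a list with `strand`
#'   (`"forward"`/`"reverse"`), `offset` (0-based index of the first
#'   randomized base in the searched orientation) and `window`.
#' @export
find_library_window <- function(read, libdef) {
  stopifnot(inherits(libdef, "fsld"))
  seq <- if (is.character(read)) read else read$sequence
  stopifnot(is.character(seq), length(seq) == 1L)
  m <- .match_windows(toupper(seq), libdef)
  if (is.na(m$strand[1L])) return(NULL)
  list(strand = m$strand[1L], offset = m$offset[1L], window = m$window[1L])
}
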