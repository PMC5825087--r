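# IUPAC nucleotide algebra and the forward-strand library definition (FSLD).

# Degeneracy table. 'X' is accepted as a legacy alias for 'N'.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), X = c("A", "C", "G", "T")
)

# Complement partners for every accepted symbol (X complements to X).
.IUPAC_FROM <- "ACGTRYSWKMBDHVNXacgtryswkmbdhvnx"
.IUPAC_TO   <- "TGCAYRSWMKVHDBNXtgcayrswmkvhdbnx"

#' Expand an IUPAC nucleotide code to its set of concrete bases
#'
#' All fifteen IUPAC degeneracy codes are supported, plus the legacy symbol
#' `X` which behaves identically to `N` (any base). Matching is
#' case-insensitive.
#'
#' @param code A single-character IUPAC symbol.
#' @return Character vector of concrete bases in `{A, C, G, T}`.
#' @examples
#' iupac_expand("N")  # A C G T
#' iupac_expand("K")  # G T
#' @export
iupac_expand <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L) {
    stop("'code' must be a single character", call. = FALSE)
  }
  code <- toupper(code)
  set <- .IUPAC_SETS[[code]]
  if (is.null(set)) {
    stop(sprintf("unknown IUPAC nucleotide code '%s'", code), call. = FALSE)
  }
  set
}

#' Reverse complement of a DNA sequence
#'
#' Vectorised over `seq`. Degenerate IUPAC symbols complement to their
#' IUPAC partners (R/Y, K/M, B/V, D/H; S, W, N and X are self-complementary).
#'
#' @param seq Character vector of sequences over the IUPAC alphabet.
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("CGTTGC")  # "GCAACG"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) stop("'seq' must be character", call. = FALSE)
  bad <- grepl(sprintf("[^%s]", .IUPAC_FROM), seq)
  if (any(bad)) {
    stop(sprintf("invalid nucleotide symbol in sequence '%s'",
                 seq[bad][1L]), call. = FALSE)
  }
  stringi::stri_reverse(chartr(.IUPAC_FROM, .IUPAC_TO, seq))
}

#' Parse a forward-strand library definition (FSLD)
#'
#' An FSLD is a single IUPAC string describing, on the forward strand, a fixed
#' upstream marker, a contiguous randomized region, and a fixed downstream
#' marker, e.g. `"CGTTGCXXXXXXXXXXXXXXXTGTGCT"`. The randomized region is the
#' span from the first to the last degenerate (non-ACGT) symbol, inclusive;
#' concrete bases inside that span are kept as single-option randomized
#' positions so that fixed linkers within the insert are supported. Parsing
#' is case-insensitive.
#'
#' Validation enforces the library-definition contract: the markers must be
#' concrete A/C/G/T, of equal length and at least 3 bases each (only the first
#' 3 downstream bases are ever matched, but the full-length downstream marker
#' is needed to derive the reverse-strand markers), and the randomized region
#' must encode whole codons (a positive multiple of 3 bases).
#'
#' @param raw FSLD string over `{A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N,X}`.
#' @return An object of class `"fsld"`: a list with elements `raw`,
#'   `upstream_marker`, `downstream_marker`, `random_patterns` (list of
#'   allowed-base sets, one per randomized position), `n_random_bases`,
#'   `n_residues`, `rc_upstream_marker` and `rc_downstream_marker` (the
#'   markers used when scanning the reverse strand).
#' @examples
#' def <- parse_fsld("CGTTGCXXXXXXXXXXXXXXXTGTGCT")
#' def$n_random_bases  # 15
#' @export
parse_fsld <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || nchar(raw) == 0L) {
    stop("FSLD must be a single nonempty string", call. = FALSE)
  }
  up_raw <- toupper(raw)
  chars <- strsplit(up_raw, NULL)[[1L]]
  known <- chars %in% names(.IUPAC_SETS)
  if (!all(known)) {
    i <- which(!known)[1L]
    stop(sprintf("FSLD parse error: unknown symbol '%s' at position %d",
                 chars[i], i), call. = FALSE)
  }
  degenerate <- !(chars %in% c("A", "C", "G", "T"))
  if (!any(degenerate)) {
    stop("FSLD parse error: no degenerate symbol found; the randomized region is empty",
         call. = FALSE)
  }
  first <- which(degenerate)[1L]
  last <- which(degenerate)[sum(degenerate)]
  upstream <- substr(up_raw, 1L, first - 1L)
  downstream <- substr(up_raw, last + 1L, nchar(up_raw))
  span <- chars[first:last]
  n_random <- length(span)
  if (n_random %% 3L != 0L) {
    stop(sprintf(paste0("FSLD parse error: randomized region length %d is not ",
                        "a multiple of 3 (whole codons required)"), n_random),
         call. = FALSE)
  }
  if (nchar(upstream) != nchar(downstream)) {
    stop(sprintf(paste0("FSLD parse error: downstream marker must have the same ",
                        "length as the upstream marker (%d vs %d)"),
                 nchar(upstream), nchar(downstream)), call. = FALSE)
  }
  if (nchar(upstream) < 3L) {
    stop(sprintf("FSLD parse error: markers must be at least 3 bases (got %d)",
                 nchar(upstream)), call. = FALSE)
  }
  patterns <- lapply(span, iupac_expand)
  structure(
    list(
      raw = up_raw,
      upstream_marker = upstream,
      downstream_marker = downstream,
      random_patterns = patterns,
      n_random_bases = n_random,
      n_residues = n_random %/% 3L,
      rc_upstream_marker = reverse_complement(downstream),
      rc_downstream_marker = reverse_complement(upstream)
    ),
    class = "fsld"
  )
}

#' @export
print.fsld <- function(x, ...) {
  cat("Forward-strand library definition\n")
  cat("  raw:               ", x$raw, "\n", sep = "")
  cat("  upstream marker:   ", x$upstream_marker, "\n", sep = "")
  cat("  downstream marker: ", x$downstream_marker,
      " (first 3 bases matched)\n", sep = "")
  cat("  randomized region: ", x$n_random_bases, " bases / ",
      x$n_residues, " residues\n", sep = "")
  cat("  reverse-strand markers: ", x$rc_upstream_marker, " / ",
      x$rc_downstream_marker, "\n", sep = "")
  invisible(x)
}
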