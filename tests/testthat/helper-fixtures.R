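# Shared fixtures: all inputs are built in code at test time.

# The cyclic 5-mer exemplar design: 6-base markers around 15 fully
# randomized positions.
FSLD_5MER <- "CGTTGCXXXXXXXXXXXXXXXTGTGCT"
# Small all-N design used wherever exhaustive enumeration must stay cheap.
FSLD_2COD <- "CGTTGCNNNNNNTGTGCT"

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste0(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Random valid FSLD: concrete equal-length markers (>= 3) around a randomized
# region of whole codons drawn from the degenerate IUPAC codes.
random_fsld <- function() {
  mlen <- sample(3:8, 1)
  up <- paste0(sample(c("A", "C", "G", "T"), mlen, replace = TRUE), collapse = "")
  down <- paste0(sample(c("A", "C", "G", "T"), mlen, replace = TRUE), collapse = "")
  n_codons <- sample(1:5, 1)
  degenerate <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "X")
  region <- paste0(sample(degenerate, 3 * n_codons, replace = TRUE), collapse = "")
  paste0(up, region, down)
}

# FASTQ records embedding given windows in the exemplar design, with fixed
# flanks so matches are unambiguous.
records_for_windows <- function(windows, libdef, flank5 = "TT", flank3 = "AA") {
  seqs <- paste0(flank5, libdef$upstream_marker, windows,
                 libdef$downstream_marker, flank3)
  data.frame(read_id = sprintf("r%d", seq_along(seqs)),
             sequence = seqs,
             quality = strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE)
}
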