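# Codon table, remapping, translation, and expected-frequency / complexity
# computations derived from the table and a library definition.

#' Residue alphabet used by all count and frequency matrices
#'
#' The 20 amino acids followed by the stop symbol. `"*"` is a first-class
#' symbol in counts and heatmaps; it is excluded only from theoretical
#' peptide complexity.
#' @export
RESIDUE_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                      "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*")

.STANDARD_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  AGT = "S", AGC = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y",
  TAA = "*", TAG = "*", TGA = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  GAA = "E", GAG = "E",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D",
  TGT = "C", TGC = "C", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' The standard DNA codon table
#'
#' Returns the standard 64-entry DNA triplet to amino-acid residue table used
#' for translation and for deriving expected residue frequencies. The three
#' stop codons (TAA, TAG, TGA) map to `"*"`.
#'
#' @return Named character vector of length 64 mapping each triplet over
#'   `{A,C,G,T}` to a single residue letter or `"*"`.
#' @examples
#' tab <- standard_codon_table()
#' tab[["TGT"]]  # "C"
#' @export
standard_codon_table <- function() {
  .STANDARD_CODONS
}

#' Apply codon remappings to a codon table
#'
#' Remap pairs customise the triplet-to-residue table, typically to model
#' nonsense suppression: under amber suppression the TAG stop codon
#' incorporates glutamine, expressed as the pair `c("UAG", "Q")`. `U` is
#' treated as `T`; any number of pairs may be given and later pairs override
#' earlier ones.
#'
#' @param table Codon table as returned by [standard_codon_table()].
#' @param pairs Character vector of alternating triplet/residue tokens (as
#'   they would appear on a command line, e.g. `c("UAG", "Q")`), or a list of
#'   2-element character vectors.
#' @return The remapped 64-entry codon table.
#' @examples
#' tab <- apply_codon_remaps(standard_codon_table(), c("UAG", "Q"))
#' tab[["TAG"]]  # "Q"
#' @export
apply_codon_remaps <- function(table, pairs) {
  stopifnot(is.character(table), length(table) == 64L)
  if (is.list(pairs)) pairs <- unlist(pairs, use.names = FALSE)
  if (length(pairs) == 0L) return(table)
  if (!is.character(pairs) || length(pairs) %% 2L != 0L) {
    stop("codon remaps must be given as (triplet, residue) pairs", call. = FALSE)
  }
  triplets <- toupper(pairs[seq(1L, length(pairs), by = 2L)])
  residues <- toupper(pairs[seq(2L, length(pairs), by = 2L)])
  triplets <- chartr("U", "T", triplets)
  bad_t <- !grepl("^[ACGT]{3}$", triplets)
  if (any(bad_t)) {
    stop(sprintf("malformed codon remap triplet '%s'", triplets[bad_t][1L]),
         call. = FALSE)
  }
  bad_r <- !(residues %in% RESIDUE_ALPHABET)
  if (any(bad_r)) {
    stop(sprintf("malformed codon remap residue '%s'", residues[bad_r][1L]),
         call. = FALSE)
  }
  for (i in seq_along(triplets)) table[[triplets[i]]] <- residues[i]
  table
}

#' Translate DNA to peptide residues
#'
#' Vectorised over `dna`. Stop codons are rendered as `"*"` in the output
#' rather than truncating the peptide.
#'
#' @param dna Character vector of sequences over `{A,C,G,T}`; each must have
#'   length divisible by 3.
#' @param table Codon table (default [standard_codon_table()]).
#' @return Character vector of translated residue strings.
#' @examples
#' translate_dna("AAATTTGGGCCCATG")  # "KFGPM"
#' @export
translate_dna <- function(dna, table = standard_codon_table()) {
  if (!is.character(dna)) stop("'dna' must be character", call. = FALSE)
  if (length(dna) == 0L) return(character(0))
  lens <- nchar(dna)
  if (any(is.na(dna))) stop("'dna' contains NA", call. = FALSE)
  if (any(lens %% 3L != 0L)) {
    stop("sequence length not divisible by 3", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", dna))) {
    stop("'dna' contains a symbol outside {A,C,G,T}", call. = FALSE)
  }
  out <- character(length(dna))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (L == 0L) {
      out[idx] <- ""
      next
    }
    starts <- seq.int(1L, L, by = 3L)
    codon_cols <- lapply(starts, function(s) substr(dna[idx], s, s + 2L))
    residue_cols <- lapply(codon_cols, function(cc) unname(table[cc]))
    out[idx] <- do.call(paste0, residue_cols)
  }
  out
}

# Enumerate the triplets reachable at residue position j of a library
# definition: the Cartesian product of the allowed-base sets of the three
# underlying DNA positions. Returns a character vector of triplets.
.codon_triplets <- function(libdef, j) {
  sets <- libdef$random_patterns[(3L * j - 2L):(3L * j)]
  g <- expand.grid(sets[[1L]], sets[[2L]], sets[[3L]],
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paste0(g[[1L]], g[[2L]], g[[3L]])
}

#' Expected residue frequencies under a library design
#'
#' For each residue position, all triplets reachable from the allowed-base
#' sets of its three DNA positions are enumerated through the codon table;
#' the expected frequency of a residue is the fraction of those triplets
#' mapping to it. Frequencies are exact small-integer ratios, so each column
#' sums to 1 and restricted codon sets or remapped tables (e.g. amber
#' suppression) are captured automatically.
#'
#' @param libdef An [parse_fsld()] library definition.
#' @param table Codon table (default [standard_codon_table()]).
#' @return Numeric matrix `[21 residues x n_residues]` (rows in
#'   [RESIDUE_ALPHABET] order, including the `"*"` row) of probabilities.
#' @export
expected_residue_freqs <- function(libdef, table = standard_codon_table()) {
  stopifnot(inherits(libdef, "fsld"))
  out <- matrix(0, nrow = length(RESIDUE_ALPHABET), ncol = libdef$n_residues,
                dimnames = list(RESIDUE_ALPHABET,
                                paste0("pos", seq_len(libdef$n_residues))))
  for (j in seq_len(libdef$n_residues)) {
    residues <- unname(table[.codon_triplets(libdef, j)])
    counts <- table(factor(residues, levels = RESIDUE_ALPHABET))
    out[, j] <- as.numeric(counts) / length(residues)
  }
  out
}

#' Expected base frequencies under a library design
#'
#' @param libdef An [parse_fsld()] library definition.
#' @return Numeric matrix `[4 bases x n_random_bases]`: `1/k` for each of the
#'   `k` allowed bases at a position, 0 for disallowed bases.
#' @export
expected_base_freqs <- function(libdef) {
  stopifnot(inherits(libdef, "fsld"))
  bases <- c("A", "C", "G", "T")
  out <- matrix(0, nrow = 4L, ncol = libdef$n_random_bases,
                dimnames = list(bases,
                                paste0("pos", seq_len(libdef$n_random_bases))))
  for (i in seq_len(libdef$n_random_bases)) {
    allowed <- libdef$random_patterns[[i]]
    out[allowed, i] <- 1 / length(allowed)
  }
  out
}

#' Theoretical DNA complexity of a library design
#'
#' The number of distinct DNA sequences the randomized region can encode:
#' the product over randomized positions of the number of allowed bases.
#'
#' @param libdef An [parse_fsld()] library definition.
#' @return Numeric scalar (may exceed the 32-bit integer range).
#' @export
theoretical_dna_complexity <- function(libdef) {
  stopifnot(inherits(libdef, "fsld"))
  prod(vapply(libdef$random_patterns, length, integer(1L)))
}

#' Theoretical peptide complexity of a library design
#'
#' The number of distinct stop-free peptide sequences the design can encode:
#' the product over residue positions of the number of distinct non-stop
#' residues reachable there. A fully randomized (NNN) codon reaches all 20
#' amino acids, so a 5-mer library has complexity 20^5 = 3.2 million.
#'
#' @inheritParams expected_residue_freqs
#' @return Numeric scalar.
#' @export
theoretical_peptide_complexity <- function(libdef, table = standard_codon_table()) {
  stopifnot(inherits(libdef, "fsld"))
  per_pos <- vapply(seq_len(libdef$n_residues), function(j) {
    residues <- unique(unname(table[.codon_triplets(libdef, j)]))
    as.numeric(length(setdiff(residues, "*")))
  }, numeric(1L))
  prod(per_pos)
}
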