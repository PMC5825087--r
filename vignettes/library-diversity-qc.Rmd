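---
title: "Methods: diversity quality control of randomized phage display libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity quality control of randomized phage display libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageqc)
```

## The problem

Phage display screens rely on the assumption that the randomized DNA stretch
encoding the displayed peptide is truly random: every allowed base
incorporated at a similar rate at every randomized position. As library
complexity grows, a sequencing run samples the library ever more sparsely,
and positional skew in base incorporation silently concentrates the screen
on one corner of sequence space. `phageqc` quantifies that skew from an NGS
sample of the library, at both the DNA base and the translated residue
level.

## The library definition and the matching model

A library is described by a single forward-strand definition (FSLD): a fixed
upstream marker, a degenerate randomized region over the IUPAC alphabet
(`X` is accepted as a legacy alias for `N`), and a fixed downstream marker,
e.g.

```{r}
def <- parse_fsld("CGTTGCXXXXXXXXXXXXXXXTGTGCT")
def
```

Reads are scanned for the full upstream marker; at each hit the following
`n_random_bases` bases are accepted as the library window iff each base lies
in the allowed set of its randomized position and the next 3 bases equal the
first 3 bases of the downstream marker. Requiring the downstream 3-mer
rejects reads that frame-shifted after the marker, whose miscalled windows
would otherwise contaminate the positional statistics (visible as an excess
of apparent stop codons). Only 3 downstream bases are checked, but the
downstream marker must be given at full (upstream-equal) length because its
reverse complement becomes the upstream marker when scanning reverse-strand
reads: if the forward scan fails, the identical scan runs on the reverse
complement of the read, so both read orientations are handled.

Design choices where the matching semantics were genuinely open:

* The randomized region is the span from the first to the last degenerate
  symbol; concrete bases inside it are kept as single-option randomized
  positions, so designs with fixed linkers inside the insert are accepted.
* Markers must be concrete A/C/G/T — matching semantics for degenerate
  markers are undefined — and at least 3 bases long so the 3-base end rule
  is applicable. A randomized length not divisible by 3 is rejected: every
  window is translated, so whole codons are required.
* The first acceptable site wins, and a failed candidate (e.g. an `N` inside
  the window) does not abort the read: the scan continues at the next marker
  occurrence. This is the permissive reading; it recovers reads whose 5'
  flank happens to contain a spurious marker copy.
* The forward strand is searched before the reverse, and at most one window
  is taken per read, making results deterministic.

The matcher compiles this predicate into one regular expression (marker +
per-position character classes + downstream 3-mer), so "first match of the
regex" is exactly "first marker hit whose candidate validates".

## Translation and expected frequencies

Windows are translated with the standard 64-entry codon table; stop codons
appear as `*` in the peptide rather than truncating it. The table can be
remapped pairwise (`c("UAG", "Q")` models amber suppression, where the UAG
stop incorporates glutamine); `U` is read as `T` and later pairs override
earlier ones.

Expected frequencies — the null against which enrichment is measured — are
derived by exact enumeration, not sampling. For residue position *j* the
Cartesian product of the allowed bases at DNA positions 3j−2..3j is pushed
through the codon table in use; the expected frequency of residue *a* is the
fraction of those triplets mapping to *a*. Because the products are tiny
(≤ 64 triplets) the ratios are exact small-integer fractions: columns sum to
1 to machine precision, and profiling an exhaustively enumerated library
yields enrichment values of exactly 1.0 in every defined cell, a property
the test suite asserts with `==`, not a tolerance. Restricted codon sets
(NNK and friends) and remapped tables are automatically reflected in the
null, e.g. a single NNK codon has stop probability 1/32 (only TAG remains).

`*` is a first-class symbol: it has a row in the count and heatmap matrices,
and stop-containing peptides are counted among unique peptides observed
(`drop_stop_peptides = TRUE` flips this for users who disagree). Theoretical
peptide complexity, by contrast, excludes stops — it counts the distinct
non-stop residues reachable per codon position — which is the convention
that makes a fully randomized 5-mer library 20^5 = 3.2 million sequences.

## Statistics reported

For each run the package reports: basic counts (total, valid, per strand,
unique DNA / peptide sequences, and the complement not found in the
theoretical library, with coverage percentages rounded to 2 decimals);
frequency-of-frequencies tables (how many distinct sequences were seen
exactly *k* times — informative only for low-complexity, high-coverage
libraries); the 100 most common DNA and peptide sequences (ties broken
lexicographically so ranking is deterministic); positional base and residue
count matrices; and the two normalised heatmaps,
`observed / (valid_reads × expected)`, where 1.0 means a symbol occurred at
exactly its expected rate. Cells with zero expected frequency are undefined
(`NA`) when unobserved and flagged as contamination when observed. The
algebraic identity Σ expected × enrichment = 1 per position holds by
construction and is used as an internal consistency check.

Profiles are accumulated in a single streaming pass with bounded memory per
unique sequence, and the merge of two partial profiles equals the profile of
the concatenated stream, so chunked (and in principle parallel) processing
is exact, not approximate.

Two deliberate data-handling policies: quality strings are parsed and
carried but play no role in any statistic — windows are filtered by marker
context and allowed-base membership only — and FASTQ records are strict
4-line blocks (wrapped FASTQ is not supported); malformed blocks are skipped
and counted rather than aborting the run.

## Reports

The HTML report is a standalone document (all styling inlined, no external
assets) whose heatmap cells use a diverging scale centred at 1.0: blue below
(under-representation), white at 1, red above (enrichment), with colour
saturating at a configurable maximum (default 3.0). The text twin is
tab-separated with `#`-prefixed section headers and full-precision numbers,
designed to be trivially parsed by pipelines; both carry numerically
identical statistics, and `parse_report_text()` recovers every cell. The
eight sections are run information, basic statistics, cumulative counts,
most common sequences, protein residue counts, DNA base counts, and the two
normalised heatmaps. Output filenames derive from the input by stripping the
`.fastq[.gz]`/`.fq[.gz]` suffix and appending `.html`/`.txt`.

## The simulator

`simulate_dataset()` emulates a library sequencing run with known ground
truth: each clean read is random flank + upstream marker + sampled window +
downstream marker + random flank, reverse-complemented with probability
`fraction_reverse`, and a per-read TSV sidecar records the intended window,
strand and validity. Defaults were chosen once as a realistic unstranded
short-read run over an amplicon: `fraction_reverse = 0.5`; flanks uniform in
5–15 bases (enough context for spurious-marker edge cases without bloating
files); corruption rates of 1% frameshift (one base inserted after the
upstream marker), 1% marker mutation (one marker base substituted) and 0.5%
ambiguous base (`N` inside the window), chosen to exercise every rejection
path of the matcher at rates typical of a reasonable-quality run; constant
quality `I` (Phred 40, Sanger/Illumina 1.9 encoding), since quality is
deliberately ignored downstream. Spike-in weights are expressed relative to
the expected rate of a single window in a uniform library: weight *w* emits
the spike with probability *w* / DNA complexity, so "a 10× spike" means
exactly ten times the base rate. All randomness flows from one explicit
`seed` through R's default generator — same seed, same bytes.

`enumerate_exhaustive()` emits every allowed window exactly once (forward
strand, no flanks, no corruption), guarded to designs of at most 10^7
windows; it is the oracle input for the exact-1.0 heatmap identity.

What the simulator does *not* emulate: quality-dependent substitution error
profiles, indels inside reads, paired-end structure, or PCR duplication.
Passing tests therefore demonstrate correctness of the accounting and the
normalisation, and robustness to the modelled corruption classes — not
robustness to every artefact of real sequencers.

## Problem sizes and numerical choices

The test suite verifies the exact heatmap identity on the 4096-window
two-codon library, parameter recovery of an injected base skew
(0.4/0.2/0.2/0.2 at one position) within 3 binomial standard deviations at
n = 100,000 reads, and FASTQ accounting on a simulated 2.5-million-read
(10-million-line) file; larger runs only scale these linearly. Expected
frequencies are exact rational ratios; enrichment uses plain double
division (observed and expected share the denominator `valid_reads`, so the
Σ expected × enrichment = 1 identity holds to ≤ 1e−9); percentages are
rounded to 2 decimals only at the reporting layer. Ties in the most-common
tables break lexicographically; degenerate inputs (no valid reads) produce a
complete report with zeros and a prominent warning, but enrichment itself
refuses a zero-read profile, since no rate is estimable.

## Limitations

Single contiguous randomized region only (no multi-insert designs); no
fuzzy or indel-tolerant marker matching; each read is processed
independently (no mate-pair reconciliation); no inter-round biopanning
comparison or diversity indices beyond the outputs above. The text report is
tab-separated by design, as the format intended for machine parsing.
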