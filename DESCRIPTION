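Package: phageqc
Title: Quality Control and Diversity Profiling of Randomized Phage Display Libraries from NGS Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assesses the randomness and diversity of phage display peptide
    libraries from next-generation sequencing reads. A forward-strand library
    definition (an IUPAC string encoding fixed flanking markers around a
    degenerate randomized region) is used to dynamically locate the library
    window within each read on either strand. Accepted windows are accumulated
    into unique DNA and translated peptide counts, positional base and residue
    count matrices, and observed/expected enrichment tables whose null
    frequencies are derived from the codon table in use, including user-supplied
    codon remappings such as amber stop-codon suppression. Reports are emitted
    as a self-contained HTML document and a parsable tab-separated twin. A
    companion simulator generates synthetic FASTQ datasets with ground-truth
    sidecars so every statistic can be verified without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    stringi
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
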