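# FASTQ input/output. Strict 4-line records (Illumina style); Gzip handled
# transparently. Quality strings are carried through but never used in any
# statistic: the method profiles base identity, not base confidence.

# Turn a block of raw FASTQ lines (length divisible into 4-line groups) into
# a data.frame of records plus a malformed count. Malformed groups (header
# not starting '@', separator not starting '+', sequence/quality length
# mismatch) are skipped and counted, never fatal.
.parse_fastq_lines <- function(lines) {
  n_groups <- length(lines) %/% 4L
  n_trailing <- length(lines) - 4L * n_groups
  if (n_groups == 0L) {
    return(list(records = data.frame(read_id = character(0),
                                     sequence = character(0),
                                     quality = character(0),
                                     stringsAsFactors = FALSE),
                malformed = as.integer(n_trailing > 0L)))
  }
  idx <- seq_len(n_groups)
  hdr <- lines[4L * idx - 3L]
  seqs <- toupper(lines[4L * idx - 2L])
  sep <- lines[4L * idx - 1L]
  qual <- lines[4L * idx]
  ok <- startsWith(hdr, "@") & startsWith(sep, "+") &
    nchar(seqs) == nchar(qual) & nchar(seqs) > 0L
  malformed <- sum(!ok) + as.integer(n_trailing > 0L)
  list(
    records = data.frame(
      read_id = sub("^@", "", hdr[ok]),
      sequence = seqs[ok],
      quality = qual[ok],
      stringsAsFactors = FALSE
    ),
    malformed = malformed
  )
}

# Open a FASTQ path for text reading, sniffing the 2-byte Gzip magic header
# (0x1f 0x8b) rather than trusting the file extension.
.open_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)) {
    gzfile(path, open = "rt")
  } else {
    file(path, open = "rt")
  }
}

#' Read a FASTQ file
#'
#' Reads strict 4-line FASTQ records from a plain or Gzip-compressed file
#' (compression is detected from the Gzip magic bytes, not the extension).
#' Malformed 4-line blocks are skipped and counted, not fatal; an unreadable
#' or empty file is an error.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return A data.frame with columns `read_id` (header line without the
#'   leading `@`), `sequence` and `quality`, with attribute `"malformed"`
#'   giving the number of skipped malformed blocks.
#' @export
read_fastq <- function(path) {
  con <- .open_fastq(path)
  on.exit(close(con))
  chunks <- list()
  malformed <- 0L
  carry <- character(0)
  repeat {
    lines <- readLines(con, n = 4000000L, warn = FALSE)
    if (length(lines) == 0L && length(carry) == 0L) break
    lines <- c(carry, lines)
    done <- length(lines) < 4000000L
    if (done) {
      carry <- character(0)
    } else {
      keep <- 4L * (length(lines) %/% 4L)
      carry <- lines[seq_len(length(lines) - keep) + keep]
      lines <- lines[seq_len(keep)]
    }
    parsed <- .parse_fastq_lines(lines)
    chunks[[length(chunks) + 1L]] <- parsed$records
    malformed <- malformed + parsed$malformed
    if (done) break
  }
  if (length(chunks) == 0L) stop(sprintf("empty FASTQ file '%s'", path), call. = FALSE)
  records <- do.call(rbind, chunks)
  if (nrow(records) == 0L && malformed == 0L) {
    stop(sprintf("empty FASTQ file '%s'", path), call. = FALSE)
  }
  rownames(records) <- NULL
  attr(records, "malformed") <- malformed
  records
}

#' Write a FASTQ file
#'
#' Inverse of [read_fastq()]: emits one 4-line block per record, optionally
#' Gzip-compressed. Quality strings are written exactly as provided.
#'
#' @param records Data.frame with columns `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @param gzip Compress the output with Gzip.
#' @param append Append to an existing file instead of truncating.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path, gzip = FALSE, append = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("read_id", "sequence", "quality") %in% names(records)))
  mode <- if (append) "ab" else "wb"
  con <- if (gzip) gzfile(path, open = mode) else file(path, open = mode)
  on.exit(close(con))
  if (nrow(records) > 0L) {
    lines <- character(4L * nrow(records))
    idx <- seq_len(nrow(records))
    lines[4L * idx - 3L] <- paste0("@", records$read_id)
    lines[4L * idx - 2L] <- records$sequence
    lines[4L * idx - 1L] <- "+"
    lines[4L * idx] <- records$quality
    writeLines(lines, con)
  }
  invisible(path)
}
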