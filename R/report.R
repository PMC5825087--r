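# Report rendering: a self-contained HTML document and a parsable
# tab-separated twin carrying identical statistics. Eight sections: run
# information, basic statistics, cumulative counts, most common sequences,
# protein residue counts, DNA base counts, and the two normalised heatmaps.

#' Section headings of the rendered reports, in order
#' @export
REPORT_SECTIONS <- c(
  "Run information", "Basic statistics", "Cumulative counts",
  "Most common sequences", "Protein residue counts", "DNA base counts",
  "Normalized peptide residue heatmap", "Normalized DNA base heatmap"
)

# full precision, round-trippable through as.numeric
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15,
                formatC(x, format = "f", digits = 0),
                formatC(x, format = "g", digits = 17)))
}

#' Derive the report base name from an input FASTQ path
#'
#' Strips a trailing `.fastq.gz`, `.fastq`, `.fq.gz` or `.fq` so the HTML and
#' text reports sit next to the input as `<base>.html` / `<base>.txt`.
#'
#' @param path Input FASTQ path.
#' @return The path without the FASTQ suffix.
#' @export
report_basename <- function(path) {
  sub("\\.(fastq|fq)(\\.gz)?$", "", path)
}

#' Assemble the report bundle for a profiled library
#'
#' Collects every output section into one structure so the HTML and text
#' renderers draw on identical numbers.
#'
#' @param profile A `"library_profile"`.
#' @param input_name Name of the input FASTQ shown in the run information.
#' @param remaps Character vector of codon remap tokens as given on the
#'   command line (e.g. `c("UAG", "Q")`).
#' @param top_k Number of most-common sequences to report (default 100).
#' @return An object of class `"report_bundle"`.
#' @export
build_report_bundle <- function(profile, input_name = "", remaps = character(0),
                                top_k = 100L) {
  stopifnot(inherits(profile, "library_profile"))
  libdef <- profile$libdef
  cov <- coverage_stats(profile)
  malformed <- attr(profile, "malformed")
  if (is.null(malformed)) malformed <- NA_real_
  empty <- profile$valid_reads == 0

  remap_text <- if (length(remaps) == 0L) "none" else {
    t <- chartr("U", "T", toupper(remaps))
    paste(paste0(t[seq(1L, length(t), 2L)], ">",
                 t[seq(2L, length(t), 2L)]), collapse = ";")
  }

  run_info <- data.frame(
    key = c("input", "fsld", "upstream_marker", "downstream_marker",
            "rc_upstream_marker", "rc_downstream_marker",
            "n_randomized_bases", "n_residues", "codon_remaps"),
    value = c(input_name, libdef$raw, libdef$upstream_marker,
              libdef$downstream_marker, libdef$rc_upstream_marker,
              libdef$rc_downstream_marker, libdef$n_random_bases,
              libdef$n_residues, remap_text),
    stringsAsFactors = FALSE
  )

  basic <- data.frame(
    key = c("total_reads", "valid_reads", "forward_reads", "reverse_reads",
            "malformed_records", "unique_dna", "unique_peptide",
            "theoretical_dna", "theoretical_peptide",
            "dna_not_found", "peptide_not_found",
            "dna_coverage_pct", "peptide_coverage_pct"),
    value = c(profile$total_reads, profile$valid_reads,
              profile$strand_counts[["forward"]],
              profile$strand_counts[["reverse"]], malformed,
              cov$unique_dna, cov$unique_pep,
              cov$theoretical_dna, cov$theoretical_pep,
              cov$dna_not_found, cov$pep_not_found,
              cov$dna_coverage_pct, cov$pep_coverage_pct),
    stringsAsFactors = FALSE
  )

  cc_dna <- count_of_counts(profile$dna_counts)
  cc_pep <- count_of_counts(profile$peptide_counts)
  cumulative <- rbind(
    if (nrow(cc_dna)) cbind(molecule = "dna", cc_dna),
    if (nrow(cc_pep)) cbind(molecule = "peptide", cc_pep)
  )
  if (is.null(cumulative)) {
    cumulative <- data.frame(molecule = character(0), times_seen = numeric(0),
                             n_sequences = numeric(0),
                             cum_frac_unique = numeric(0),
                             cum_frac_reads = numeric(0))
  }

  top_dna <- top_sequences(profile$dna_counts, top_k)
  top_pep <- top_sequences(profile$peptide_counts, top_k)
  most_common <- rbind(
    if (nrow(top_dna)) cbind(molecule = "dna", top_dna),
    if (nrow(top_pep)) cbind(molecule = "peptide", top_pep)
  )
  if (is.null(most_common)) {
    most_common <- data.frame(molecule = character(0), rank = integer(0),
                              sequence = character(0), count = numeric(0))
  }

  if (empty) {
    res_heat <- matrix(NA_real_, nrow = nrow(profile$residue_pos_counts),
                       ncol = ncol(profile$residue_pos_counts),
                       dimnames = dimnames(profile$residue_pos_counts))
    base_heat <- matrix(NA_real_, nrow = 4L,
                        ncol = ncol(profile$base_pos_counts),
                        dimnames = dimnames(profile$base_pos_counts))
  } else {
    res_heat <- residue_enrichment(profile)$enrichment
    base_heat <- base_enrichment(profile)$enrichment
  }

  structure(
    list(
      run_information = run_info,
      basic_statistics = basic,
      cumulative_counts = cumulative,
      most_common = most_common,
      residue_counts = profile$residue_pos_counts,
      base_counts = profile$base_pos_counts,
      residue_heatmap = res_heat,
      base_heatmap = base_heat,
      empty = empty
    ),
    class = "report_bundle"
  )
}

.matrix_lines <- function(m, label) {
  header <- paste(c(label, colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], .fmt_num(m[i, ])), collapse = "\t")
  }, character(1L))
  c(header, rows)
}

.df_lines <- function(df) {
  header <- paste(names(df), collapse = "\t")
  if (nrow(df) == 0L) return(header)
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) .fmt_num(col) else as.character(col)
  })
  c(header, do.call(paste, c(cols, sep = "\t")))
}

#' Render the tab-separated text report
#'
#' Sections are delimited by `#`-prefixed headers; numbers are written at
#' full precision so the file round-trips losslessly into downstream
#' pipelines.
#'
#' @param bundle A [build_report_bundle()] result.
#' @param out_path Output path.
#' @return `out_path`, invisibly.
#' @export
render_report_text <- function(bundle, out_path) {
  stopifnot(inherits(bundle, "report_bundle"))
  lines <- c(
    paste0("# ", REPORT_SECTIONS[1L]), .df_lines(bundle$run_information),
    paste0("# ", REPORT_SECTIONS[2L]), .df_lines(bundle$basic_statistics),
    paste0("# ", REPORT_SECTIONS[3L]), .df_lines(bundle$cumulative_counts),
    paste0("# ", REPORT_SECTIONS[4L]), .df_lines(bundle$most_common),
    paste0("# ", REPORT_SECTIONS[5L]), .matrix_lines(bundle$residue_counts, "residue"),
    paste0("# ", REPORT_SECTIONS[6L]), .matrix_lines(bundle$base_counts, "base"),
    paste0("# ", REPORT_SECTIONS[7L]), .matrix_lines(bundle$residue_heatmap, "residue"),
    paste0("# ", REPORT_SECTIONS[8L]), .matrix_lines(bundle$base_heatmap, "base")
  )
  writeLines(lines, out_path)
  invisible(out_path)
}

#' Parse a text report back into data frames
#'
#' Inverse of [render_report_text()]: recovers every section as a data.frame
#' with numeric columns restored.
#'
#' @param path Path to a text report.
#' @return Named list of data.frames, one per section.
#' @export
parse_report_text <- function(path) {
  lines <- readLines(path)
  heads <- which(startsWith(lines, "# "))
  out <- list()
  for (i in seq_along(heads)) {
    name <- sub("^# ", "", lines[heads[i]])
    end <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    body <- lines[(heads[i] + 1L):end]
    body <- body[nzchar(body)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    header <- parts[[1L]]
    if (length(parts) == 1L) {
      df <- as.data.frame(matrix(character(0), ncol = length(header),
                                 dimnames = list(NULL, header)))
    } else {
      mat <- do.call(rbind, parts[-1L])
      colnames(mat) <- header
      df <- utils::type.convert(as.data.frame(mat, stringsAsFactors = FALSE),
                                as.is = TRUE)
    }
    out[[name]] <- df
  }
  out
}

# diverging blue-white-red fill centred at 1.0, intensity clipped at max_scale
.heat_color <- function(v, max_scale = 3) {
  if (is.na(v)) return("#dddddd")
  if (v >= 1) {
    t <- min((v - 1) / (max_scale - 1), 1)
    sprintf("#ff%02x%02x", round(255 * (1 - t)), round(255 * (1 - t)))
  } else {
    t <- min(1 - v, 1)
    sprintf("#%02x%02xff", round(255 * (1 - t)), round(255 * (1 - t)))
  }
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.html_table_df <- function(df, digits = 2L) {
  cells <- lapply(df, function(col) {
    if (is.numeric(col)) {
      ifelse(is.na(col), "NA",
             ifelse(col == floor(col) & abs(col) < 1e15,
                    formatC(col, format = "f", digits = 0),
                    formatC(col, format = "f", digits = digits)))
    } else .html_escape(as.character(col))
  })
  head <- paste0("<tr>", paste0("<th>", .html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  if (nrow(df) == 0L) return(paste0("<table>", head, "</table>"))
  rows <- do.call(paste0, lapply(cells, function(cc) paste0("<td>", cc, "</td>")))
  paste0("<table>", head, paste0("<tr>", rows, "</tr>", collapse = ""),
         "</table>")
}

.html_table_matrix <- function(m, label, heat = FALSE, max_scale = 3) {
  head <- paste0("<tr><th>", label,
                 paste0("<th>", colnames(m), collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    cells <- vapply(seq_len(ncol(m)), function(j) {
      v <- m[i, j]
      txt <- if (is.na(v)) "n/a" else if (heat) {
        formatC(v, format = "f", digits = 2)
      } else formatC(v, format = "f", digits = 0)
      style <- if (heat) sprintf(" style=\"background-color:%s\"",
                                 .heat_color(v, max_scale)) else ""
      sprintf("<td%s>%s</td>", style, txt)
    }, character(1L))
    paste0("<tr><th>", rownames(m)[i], "</th>", paste0(cells, collapse = ""),
           "</tr>")
  }, character(1L))
  paste0("<table>", head, paste0(rows, collapse = ""), "</table>")
}

#' Render the HTML report
#'
#' A standalone HTML5 document with all styling inlined, so it opens offline
#' in any modern browser. Heatmap cells are coloured on a diverging scale
#' centred at 1.0 — blue below 1 (under-representation), white at 1
#' (expected), red above 1 (enrichment) — with colour intensity clipped at
#' `max_scale`.
#'
#' @param bundle A [build_report_bundle()] result.
#' @param out_path Output path.
#' @param max_scale Enrichment value at which heatmap colour saturates
#'   (default 3.0).
#' @return `out_path`, invisibly.
#' @export
render_report_html <- function(bundle, out_path, max_scale = 3) {
  stopifnot(inherits(bundle, "report_bundle"))
  warn <- if (isTRUE(bundle$empty)) {
    "<p class=\"warn\">WARNING: no valid reads were found; all statistics are zero and the heatmaps are undefined.</p>"
  } else ""
  body <- c(
    "<h1>Phage library diversity report</h1>", warn,
    paste0("<h2>", REPORT_SECTIONS[1L], "</h2>"),
    .html_table_df(bundle$run_information),
    paste0("<h2>", REPORT_SECTIONS[2L], "</h2>"),
    .html_table_df(bundle$basic_statistics),
    paste0("<h2>", REPORT_SECTIONS[3L], "</h2>"),
    .html_table_df(bundle$cumulative_counts, digits = 4L),
    paste0("<h2>", REPORT_SECTIONS[4L], "</h2>"),
    .html_table_df(bundle$most_common),
    paste0("<h2>", REPORT_SECTIONS[5L], "</h2>"),
    .html_table_matrix(bundle$residue_counts, "residue"),
    paste0("<h2>", REPORT_SECTIONS[6L], "</h2>"),
    .html_table_matrix(bundle$base_counts, "base"),
    paste0("<h2>", REPORT_SECTIONS[7L], "</h2>"),
    .html_table_matrix(bundle$residue_heatmap, "residue", heat = TRUE,
                       max_scale = max_scale),
    paste0("<h2>", REPORT_SECTIONS[8L], "</h2>"),
    .html_table_matrix(bundle$base_heatmap, "base", heat = TRUE,
                       max_scale = max_scale)
  )
  doc <- c(
    "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
    "<title>Phage library diversity report</title>",
    "<style>",
    "body{font-family:sans-serif;margin:2em;}",
    "table{border-collapse:collapse;margin:1em 0;}",
    "td,th{border:1px solid #999;padding:2px 6px;text-align:right;font-size:12px;}",
    "th{background:#f0f0f0;}",
    ".warn{color:#b00;font-weight:bold;}",
    "</style></head><body>",
    body,
    "</body></html>"
  )
  writeLines(doc, out_path)
  invisible(out_path)
}
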