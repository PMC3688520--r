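#' Read a probe track from bedGraph or fixed-step wiggle
#'
#' bedGraph records carry `chrom start end score` (0-based half-open,
#' whitespace-separated; `#`, `track` and `browser` lines are skipped) and
#' are parsed line-by-line so malformed lines are reported with their line
#' number. Fixed-step wiggle is read through [rtracklayer::import()] and
#' converted to 0-based starts. Unsorted input is sorted; duplicate probe
#' positions are an error (silent averaging would distort the delta null).
#'
#' @param path Path to the track file.
#' @param format `"bedGraph"` or `"wig"` (fixed-step wiggle).
#' @param tile_width Probe tile width in bp (default 35).
#' @return A [probe_track()].
#' @export
read_track <- function(path, format = c("bedGraph", "wig"), tile_width = 35) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("track file not found: %s", path))
  if (format == "bedGraph") {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
    idx <- which(keep)
    if (length(idx) == 0) {
      return(probe_track(tibble(chrom = character(), start = numeric(),
                                score = numeric()), tile_width))
    }
    fields <- strsplit(trimws(lines[idx]), "\\s+")
    nf <- lengths(fields)
    if (any(nf < 4)) {
      abort(sprintf("malformed bedGraph line %d in %s: expected 4 fields, got %d",
                    idx[which(nf < 4)[1]], path, nf[which(nf < 4)[1]]))
    }
    m <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4, byrow = TRUE)
    start <- suppressWarnings(as.numeric(m[, 2]))
    score <- suppressWarnings(as.numeric(m[, 4]))
    bad <- which(is.na(start) | is.na(score))
    if (length(bad) > 0) {
      abort(sprintf("malformed bedGraph line %d in %s: non-numeric start or score",
                    idx[bad[1]], path))
    }
    probe_track(tibble(chrom = m[, 1], start = start, score = score), tile_width)
  } else {
    gr <- rtracklayer::import(path, format = "wig")
    probe_track(tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      score = gr$score
    ), tile_width)
  }
}

#' Write a probe track as bedGraph
#'
#' Scores are written with full precision (`format(..., digits = 17)`), so
#' a read/write cycle round-trips scores bit-identically.
#'
#' @param track A [probe_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  tw <- tile_width(track)
  lines <- sprintf("%s\t%s\t%s\t%s", track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$start + tw, scientific = FALSE, trim = TRUE),
                   format(track$score, digits = 17, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3 or TSV
#'
#' Returns one gene model per annotated transcription unit with a
#' strand-aware TSS: `tss = tx_start` on `+`, `tss = tx_end - 1` on `-`
#' (0-based half-open span). GFF3 (1-based inclusive) is converted on
#' read via [rtracklayer::import()], keeping `gene`-type records when
#' present. The TSV format is 5 columns without header:
#' `gene_id chrom strand start end` (0-based half-open).
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gff3"`.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `tx_start`, `tx_end`.
#' @export
read_genes <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("gene annotation file not found: %s", path))
  if (format == "tsv") {
    df <- readr::read_tsv(path, col_names = c("gene_id", "chrom", "strand",
                                              "tx_start", "tx_end"),
                          col_types = "cccdd", comment = "#", progress = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    }
    ids <- gr$ID %||% gr$gene_id %||% gr$Name
    if (is.null(ids)) abort("GFF3 records carry no ID/gene_id/Name attribute")
    df <- tibble(
      gene_id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      tx_start = GenomicRanges::start(gr) - 1,  # to 0-based half-open
      tx_end = as.numeric(GenomicRanges::end(gr))
    )
  }
  gene_models(df)
}

#' Validate a gene model table and derive the TSS
#'
#' @param df A data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tx_start`, `tx_end` (0-based half-open).
#' @return A tibble with `tss` added (strand-aware).
#' @export
gene_models <- function(df) {
  df <- as_tibble(df)
  check_columns(df, c("gene_id", "chrom", "strand", "tx_start", "tx_end"),
                "gene table")
  if (anyNA(df$strand) || !all(df$strand %in% c("+", "-"))) {
    abort("gene table: strand must be '+' or '-' for every gene")
  }
  bad <- which(df$tx_start >= df$tx_end)
  if (length(bad) > 0) {
    abort(sprintf("gene table: tx_start >= tx_end at row(s) %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  if (anyDuplicated(df$gene_id)) abort("gene table: duplicate gene_id")
  mutate(df,
         tss = ifelse(.data$strand == "+", .data$tx_start, .data$tx_end - 1),
         .after = "strand")
}

#' Write signed intervals as BED6
#'
#' The interval sign is encoded in both the name column
#' (`increase`/`decrease`/`region`) and the strand column (`+`/`-`/`.`);
#' the score column carries the interval's summary score at full
#' precision. Files round-trip through [read_bed()].
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`, optionally
#'   `sign` and `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- as_tibble(intervals)
  if (nrow(intervals) > 0) validate_intervals(intervals, "BED intervals")
  sign_col <- if ("sign" %in% names(intervals)) intervals$sign else rep(0, nrow(intervals))
  score_col <- if ("score" %in% names(intervals)) intervals$score else rep(0, nrow(intervals))
  header <- "# BED6: chrom start end name score strand (0-based half-open)"
  if (nrow(intervals) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  name <- ifelse(sign_col > 0, "increase", ifelse(sign_col < 0, "decrease", "region"))
  strand <- ifelse(sign_col > 0, "+", ifelse(sign_col < 0, "-", "."))
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s", intervals$chrom,
                   format(intervals$start, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE),
                   name, format(score_col, digits = 17, trim = TRUE), strand)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a BED6 interval file written by [write_bed()]
#'
#' @param path Path to a BED file.
#' @return An interval tibble with columns `chrom`, `start`, `end`,
#'   `sign`, `score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  sign = numeric(), score = numeric()))
  }
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  n <- lengths(fields)
  if (any(n < 6)) abort(sprintf("BED line with %d fields; expected BED6", min(n)))
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  out <- tibble(
    chrom = m[, 1],
    start = as.numeric(m[, 2]),
    end = as.numeric(m[, 3]),
    sign = ifelse(m[, 6] == "+", 1, ifelse(m[, 6] == "-", -1, 0)),
    score = as.numeric(m[, 5])
  )
  validate_intervals(out, "BED intervals")
  out
}

#' Read a two-column gene expression table
#'
#' @param path TSV with columns `gene_id` and `expression` (log2 mRNA
#'   units), no header required.
#' @return A tibble with unique `gene_id` and `expression`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("expression file not found: %s", path))
  df <- readr::read_tsv(path, col_names = c("gene_id", "expression"),
                        col_types = "cd", comment = "#", progress = FALSE)
  if (anyDuplicated(df$gene_id)) abort("expression table: duplicate gene_id")
  df
}
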