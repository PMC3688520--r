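# Shared coordinate validation. Every module speaks 0-based half-open
# [start, end); this is the single place the convention is enforced.

check_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(x)
}

#' Validate a genomic interval table
#'
#' Checks the package-wide coordinate contract: columns `chrom`, `start`,
#' `end`; non-negative integers with `start < end` (0-based half-open).
#'
#' @param x A data frame of intervals.
#' @param what Label used in error messages.
#' @return `x`, invisibly, as a tibble.
#' @export
validate_intervals <- function(x, what = "interval table") {
  x <- as_tibble(x)
  check_columns(x, c("chrom", "start", "end"), what)
  if (nrow(x) == 0) return(invisible(x))
  if (!is.numeric(x$start) || !is.numeric(x$end)) {
    abort(sprintf("%s: start/end must be numeric", what))
  }
  if (anyNA(x$start) || anyNA(x$end)) {
    abort(sprintf("%s: start/end contain NA", what))
  }
  if (any(x$start < 0)) {
    abort(sprintf("%s: negative start coordinate", what))
  }
  bad <- which(x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf("%s: start >= end at row(s) %s (coordinates are 0-based half-open)",
                  what, paste(head(bad, 5), collapse = ", ")))
  }
  invisible(x)
}

# Internal: 0-based half-open tibble columns -> GRanges (1-based closed).
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = start + 1, end = end)
  )
}

# Probe tiles of a track as GRanges.
probe_granges <- function(track) {
  tw <- tile_width(track)
  as_granges0(track$chrom, track$start, track$start + tw)
}
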