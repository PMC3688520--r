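#' Construct a probe track
#'
#' A probe track holds per-probe tiling-array enrichment scores (MAT-score
#' semantics: linear in the log2 IP/control ratio). Each probe represents
#' the tile `[start, start + tile_width)`; the default 35 bp tile means
#' three contiguous features span 105 bp.
#'
#' @param x A data frame with columns `chrom`, `start` (0-based bp) and
#'   `score` (enrichment units).
#' @param tile_width Tile width in bp (> 0).
#' @return A `probe_track` tibble sorted by `(chrom, start)`, with the tile
#'   width carried as an attribute (see [tile_width()]).
#' @examples
#' probe_track(tibble::tibble(chrom = "chr2L", start = c(0, 35, 70),
#'                            score = c(1, 2, 3)))
#' @export
probe_track <- function(x, tile_width = 35) {
  x <- as_tibble(x)
  check_columns(x, c("chrom", "start", "score"), "probe track")
  if (!is.numeric(tile_width) || length(tile_width) != 1 || tile_width <= 0) {
    abort("tile_width must be a single positive number")
  }
  if (nrow(x) > 0) {
    if (anyNA(x$start) || anyNA(x$chrom)) abort("probe track: NA in chrom/start")
    if (any(x$start < 0)) abort("probe track: negative probe start")
    if (length(x$score) != length(x$start)) abort("probe track: score/start length mismatch")
    x <- arrange(x, .data$chrom, .data$start)
    dup <- duplicated(x[, c("chrom", "start")])
    if (any(dup)) {
      d <- x[dup, ]
      abort(sprintf(
        "duplicate probe position(s), e.g. %s:%d; duplicates are an error, not averaged",
        d$chrom[1], d$start[1]))
    }
  }
  new_probe_track(x, tile_width)
}

new_probe_track <- function(x, tile_width) {
  attr(x, "tile_width") <- tile_width
  class(x) <- unique(c("probe_track", class(x)))
  x
}

#' Tile width of a probe track
#'
#' @param track A [probe_track()].
#' @return Tile width in bp.
#' @export
tile_width <- function(track) {
  tw <- attr(track, "tile_width", exact = TRUE)
  if (is.null(tw)) abort("object has no tile_width attribute; is it a probe_track?")
  tw
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("# A probe_track: %d probes on %d chromosome(s), tile width %g bp\n",
              nrow(x), length(unique(x$chrom)), tile_width(x)))
  NextMethod()
}

#' Align two probe tracks on their shared probes
#'
#' Returns the scores of both tracks at the intersection of probe positions
#' (same chromosome, same start), ordered by genome coordinate. Probes
#' present in only one track are dropped and counted.
#'
#' @param a,b [probe_track()] objects (or tibbles with `chrom`, `start`,
#'   `score`).
#' @return A tibble with columns `chrom`, `start`, `score_a`, `score_b`,
#'   carrying attributes `dropped_a` and `dropped_b` (counts of unmatched
#'   probes). Warns on an empty intersection.
#' @export
align_tracks <- function(a, b) {
  check_columns(a, c("chrom", "start", "score"), "track a")
  check_columns(b, c("chrom", "start", "score"), "track b")
  out <- inner_join(
    select(as_tibble(a), "chrom", "start", score_a = "score"),
    select(as_tibble(b), "chrom", "start", score_b = "score"),
    by = c("chrom", "start")
  )
  out <- arrange(out, .data$chrom, .data$start)
  attr(out, "dropped_a") <- nrow(a) - nrow(out)
  attr(out, "dropped_b") <- nrow(b) - nrow(out)
  if (nrow(out) == 0) {
    warn("align_tracks: tracks share no probe positions (empty intersection)")
  }
  out
}

#' Per-probe difference track between depleted and control conditions
#'
#' Computes `delta = depleted - control` at every probe shared by the two
#' tracks (the genome-wide array of per-feature differences that the
#' change-interval caller segments).
#'
#' @param control,depleted [probe_track()] objects on the same probe grid.
#' @return A `delta_track` tibble with columns `chrom`, `start`, `delta`,
#'   the tile width of `control`, and attribute `n_dropped` (probes present
#'   in only one track).
#' @export
delta_track <- function(control, depleted) {
  paired <- suppressWarnings(align_tracks(control, depleted))
  if (nrow(paired) == 0) {
    abort("delta_track: no shared probes between control and depleted tracks")
  }
  out <- transmute(paired, .data$chrom, .data$start,
                   delta = .data$score_b - .data$score_a)
  out <- new_probe_track(out, tile_width(control))
  class(out) <- unique(c("delta_track", class(out)))
  attr(out, "n_dropped") <- attr(paired, "dropped_a") + attr(paired, "dropped_b")
  out
}
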