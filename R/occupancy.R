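# Run-length segmentation shared by the binding caller and the
# differential caller. A "run" is a maximal stretch of probes that
# (a) all carry the same non-zero state (+1/-1),
# (b) are adjacent in track order (an intervening probe with state 0
#     breaks the run -- every probe inside an emitted interval satisfies
#     the calling condition), and
# (c) have successive start gaps <= max_start_gap bp (tolerates missing
#     grid positions, e.g. masked probes).
# Runs with >= min_run probes and tile-union span >= min_span are emitted
# as intervals [first_start, last_start + tile_width) carrying the mean
# probe score.
call_runs <- function(chrom, start, score, state, tile_width,
                      max_start_gap, min_run, min_span) {
  stopifnot(length(chrom) == length(start), length(start) == length(state))
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  sign = numeric(), score = numeric(), n_probes = integer())
  if (length(start) == 0) return(empty)
  brk <- c(TRUE,
           chrom[-1] != chrom[-length(chrom)] |
             state[-1] != state[-length(state)] |
             diff(start) > max_start_gap)
  run_id <- cumsum(brk)
  keep <- state != 0
  if (!any(keep)) return(empty)
  d <- tibble(chrom = chrom[keep], start = start[keep], score = score[keep],
              state = state[keep], run_id = run_id[keep])
  out <- d |>
    group_by(.data$run_id) |>
    summarise(chrom = .data$chrom[1],
              end = max(.data$start) + tile_width,
              start = min(.data$start),
              sign = .data$state[1],
              score = mean(.data$score),
              n_probes = dplyr::n(),
              .groups = "drop") |>
    filter(.data$n_probes >= min_run, .data$end - .data$start >= min_span) |>
    arrange(.data$chrom, .data$start) |>
    select("chrom", "start", "end", "sign", "score", "n_probes")
  out
}

#' Binding-call parameters
#'
#' Bundles the run-length thresholding parameters used by
#' [call_bound_intervals()]. The defaults (three probes, 105 bp) mirror
#' the differential caller for symmetry; the score threshold `tau` is the
#' score-space stand-in for a MAT p-value cutoff and must be calibrated by
#' the user for real tracks.
#'
#' @param tau Score threshold (enrichment units); probes with
#'   `score >= tau` are candidate bound probes.
#' @param min_run Minimum number of contiguous probes (default 3).
#' @param min_span Minimum tile-union span in bp (default 105).
#' @param merge_gap Extra gap beyond the tile width across which runs are
#'   still considered contiguous, in bp (default: one tile width, i.e. a
#'   single missing probe is tolerated).
#' @return A list of class `binding_call_params`.
#' @export
binding_call_params <- function(tau, min_run = 3, min_span = 105,
                                merge_gap = NULL) {
  if (!is.finite(tau)) abort("tau must be finite")
  if (min_run < 1) abort("min_run must be >= 1")
  structure(list(tau = tau, min_run = min_run, min_span = min_span,
                 merge_gap = merge_gap),
            class = "binding_call_params")
}

#' Call bound intervals from an enrichment track
#'
#' Emits maximal runs of at least `min_run` contiguous probes with
#' `score >= tau` as tile-union intervals of span at least `min_span` bp.
#' Contiguity tolerates missing grid positions up to
#' `tile_width + merge_gap` bp between successive probe starts; a probe
#' below threshold always breaks a run, so every probe inside an emitted
#' interval satisfies the threshold.
#'
#' @param track A [probe_track()].
#' @param params A [binding_call_params()] object, or `NULL` to pass
#'   `tau`, `min_run`, `min_span`, `merge_gap` directly.
#' @param tau,min_run,min_span,merge_gap See [binding_call_params()];
#'   ignored when `params` is given.
#' @return An interval tibble (`chrom`, `start`, `end`, `sign` = 0,
#'   `score` = mean probe score, `n_probes`), sorted and non-overlapping.
#' @examples
#' tr <- probe_track(tibble::tibble(chrom = "chr2L", start = c(0, 35, 70),
#'                                  score = c(5, 5, 5)))
#' call_bound_intervals(tr, tau = 3)
#' @export
call_bound_intervals <- function(track, params = NULL, tau = NULL,
                                 min_run = 3, min_span = 105,
                                 merge_gap = NULL) {
  if (is.null(params)) {
    if (is.null(tau)) abort("supply either params or tau")
    params <- binding_call_params(tau, min_run, min_span, merge_gap)
  }
  tw <- tile_width(track)
  gap <- params$merge_gap %||% tw
  if (params$min_span < tw) abort("min_span must be >= tile_width")
  state <- ifelse(track$score >= params$tau, 1L, 0L)
  out <- call_runs(track$chrom, track$start, track$score, state, tw,
                   max_start_gap = tw + gap,
                   min_run = params$min_run, min_span = params$min_span)
  mutate(out, sign = 0)
}

#' Mark genes overlapped by intervals
#'
#' A gene is bound (1) iff any interval overlaps its transcription unit
#' `[tx_start, tx_end)` by at least 1 bp; intervals and genes are both
#' 0-based half-open, so abutting features do not overlap. Strand is
#' ignored (ChIP signal is unstranded).
#'
#' @param intervals Interval tibble.
#' @param genes Gene model tibble from [gene_models()].
#' @return A tibble `gene_id`, `bound` (0/1).
#' @export
assign_gene_binding <- function(intervals, genes) {
  genes <- as_tibble(genes)
  check_columns(genes, c("gene_id", "chrom", "tx_start", "tx_end"), "genes")
  if (nrow(intervals) == 0 || nrow(genes) == 0) {
    return(tibble(gene_id = genes$gene_id, bound = rep(0L, nrow(genes))))
  }
  validate_intervals(intervals, "intervals")
  hits <- GenomicRanges::findOverlaps(
    as_granges0(genes$chrom, genes$tx_start, genes$tx_end),
    as_granges0(intervals$chrom, intervals$start, intervals$end),
    minoverlap = 1L
  )
  tibble(gene_id = genes$gene_id,
         bound = as.integer(seq_len(nrow(genes)) %in% queryHits(hits)))
}

#' Assemble a gene-by-factor binding matrix
#'
#' @param genes Gene model tibble.
#' @param interval_sets Named list of interval tibbles, one per factor.
#' @return A tibble with `gene_id` and one 0/1 column per factor.
#' @export
binding_matrix <- function(genes, interval_sets) {
  if (is.null(names(interval_sets)) || any(!nzchar(names(interval_sets)))) {
    abort("interval_sets must be a named list (factor names)")
  }
  out <- tibble(gene_id = genes$gene_id)
  for (f in names(interval_sets)) {
    out[[f]] <- assign_gene_binding(interval_sets[[f]], genes)$bound
  }
  out
}

#' Venn overlap counts over factor combinations
#'
#' Counts genes in every non-empty presence/absence combination of the
#' listed factors. Counts over all combinations sum to the number of genes
#' bound by at least one factor.
#'
#' @param matrix Binding matrix tibble ([binding_matrix()]).
#' @param factors Character vector of factor column names.
#' @return A tibble with one 0/1 column per factor, a `combination` label,
#'   and `n_genes`, sorted by combination.
#' @export
overlap_counts <- function(matrix, factors) {
  missing <- setdiff(factors, names(matrix))
  if (length(missing) > 0) {
    abort(sprintf("unknown factor(s) in binding matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  sub <- matrix[, factors, drop = FALSE]
  if (!all(unlist(sub) %in% c(0, 1))) abort("binding matrix values must be 0/1")
  grid <- expand.grid(rep(list(c(1L, 0L)), length(factors)))
  names(grid) <- factors
  grid <- as_tibble(grid) |> filter(rowSums(pick(everything())) > 0)
  counts <- sub |>
    group_by(across(all_of(factors))) |>
    summarise(n_genes = dplyr::n(), .groups = "drop")
  out <- left_join(grid, counts, by = factors) |>
    mutate(n_genes = as.integer(replace_na(.data$n_genes, 0L)),
           combination = pmap_chr_combo(pick(all_of(factors)), factors)) |>
    relocate("combination") |>
    arrange(desc(rowSums(pick(all_of(factors)))), .data$combination)
  out
}

pmap_chr_combo <- function(df, factors) {
  apply(as.matrix(df), 1, function(r) {
    paste(factors[r == 1], collapse = "&")
  })
}

#' Genome-wide Pearson correlation between two tracks
#'
#' Pearson r over the aligned probe scores of the two tracks (all shared
#' probes genome-wide), as used to compare ChIP enrichment patterns
#' between factors.
#'
#' @param a,b [probe_track()] objects.
#' @return A tibble with `r` and `n_probes`.
#' @export
genomewide_correlation <- function(a, b) {
  paired <- suppressWarnings(align_tracks(a, b))
  if (nrow(paired) < 2) {
    abort("correlation undefined: fewer than 2 shared probes")
  }
  if (sd(paired$score_a) == 0 || sd(paired$score_b) == 0) {
    abort("correlation undefined: zero variance in one of the tracks")
  }
  tibble(r = cor(paired$score_a, paired$score_b), n_probes = nrow(paired))
}
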