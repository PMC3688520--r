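#' State-classification parameters
#'
#' @param restrained_min_overlap Minimum cohesin/H3K27me3 overlap within
#'   the transcription unit, in bp, to call the restrained state
#'   (default 2000; "several kilobases" operationalized conservatively).
#' @param expression_cutoff log2 mRNA cutoff separating low from high
#'   expression; `NULL` (default) uses the cohort median.
#' @param pre_slack Tolerated bp of called-cohesin overhang beyond an
#'   annotated PRE before cohesin counts as present outside the PRE
#'   (default 100 bp, about three tiles of boundary quantization).
#' @return A list of class `state_params`.
#' @export
state_params <- function(restrained_min_overlap = 2000,
                         expression_cutoff = NULL, pre_slack = 100) {
  if (restrained_min_overlap <= 0) abort("restrained_min_overlap must be > 0")
  structure(list(restrained_min_overlap = restrained_min_overlap,
                 expression_cutoff = expression_cutoff,
                 pre_slack = pre_slack),
            class = "state_params")
}

# Internal: per-gene total bp of (intervals_a intersect intervals_b)
# clipped to the transcription unit. Either set may be empty.
pairwise_overlap_span <- function(a, b, genes) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(gene_id = genes$gene_id, overlap_bp = 0))
  }
  gr_a <- as_granges0(a$chrom, a$start, a$end)
  gr_b <- as_granges0(b$chrom, b$start, b$end)
  inter <- GenomicRanges::intersect(GenomicRanges::reduce(gr_a),
                                    GenomicRanges::reduce(gr_b))
  if (length(inter) == 0) {
    return(tibble(gene_id = genes$gene_id, overlap_bp = 0))
  }
  tx <- as_granges0(genes$chrom, genes$tx_start, genes$tx_end)
  hits <- GenomicRanges::findOverlaps(tx, inter)
  if (length(hits) == 0) {
    return(tibble(gene_id = genes$gene_id, overlap_bp = 0))
  }
  clipped <- GenomicRanges::pintersect(tx[queryHits(hits)], inter[subjectHits(hits)])
  tibble(gene_id = genes$gene_id[queryHits(hits)],
         w = GenomicRanges::width(clipped)) |>
    group_by(.data$gene_id) |>
    summarise(overlap_bp = sum(.data$w), .groups = "drop") |>
    right_join(tibble(gene_id = genes$gene_id), by = "gene_id") |>
    mutate(overlap_bp = replace_na(.data$overlap_bp, 0)) |>
    select("gene_id", "overlap_bp")
}

#' Cohesin/H3K27me3 overlap span per gene
#'
#' Total bp of the intersection of cohesin-bound intervals and H3K27me3
#' domains, clipped to each transcription unit. Multi-kilobase overlaps
#' are the signature of the cohesin-PcG restrained state.
#'
#' @param cohesin_intervals,k27_intervals Interval tibbles.
#' @param genes Gene model tibble.
#' @return A tibble `gene_id`, `overlap_bp`.
#' @export
cohesin_k27_overlap_span <- function(cohesin_intervals, k27_intervals, genes) {
  if (nrow(cohesin_intervals) > 0) validate_intervals(cohesin_intervals, "cohesin intervals")
  if (nrow(k27_intervals) > 0) validate_intervals(k27_intervals, "H3K27me3 intervals")
  pairwise_overlap_span(cohesin_intervals, k27_intervals, genes)
}

#' Classify genes into cohesin-PcG chromatin states
#'
#' Assigns every gene exactly one of four states, in decision order:
#'
#' 1. `RESTRAINED`: cohesin bound AND H3K27me3 bound AND their interval
#'    overlap within the transcription unit spans at least
#'    `restrained_min_overlap` bp.
#' 2. `SILENCED`: H3K27me3 bound AND Pc bound AND cohesin absent from the
#'    transcription unit outside annotated PREs AND expression below the
#'    cutoff. Without a PRE annotation the cohesin condition degrades to
#'    "cohesin not bound at gene level" (flagged `pre_fallback`).
#' 3. `ACTIVE`: cohesin bound AND Pc bound AND H3K27me3 absent.
#' 4. `OTHER`: everything else.
#'
#' @param genes Gene model tibble.
#' @param matrix Binding matrix with columns for `cohesin`, `pc`, `k27`.
#' @param cohesin_intervals,k27_intervals Interval tibbles for the two
#'   factors (used for the overlap span and the outside-PRE test).
#' @param expression Expression tibble (`gene_id`, `expression`, log2).
#' @param pre_intervals Optional PRE annotation (interval tibble).
#' @param params A [state_params()] object.
#' @param cohesin,pc,k27 Column names of the three factors in `matrix`.
#' @return A tibble `gene_id`, `state`, plus evidence columns:
#'   `overlap_bp`, `cohesin_bound`, `pc_bound`, `k27_bound`,
#'   `cohesin_outside_pre_bp`, `expression`, `low_expression`,
#'   `pre_fallback`.
#' @export
classify_states <- function(genes, matrix, cohesin_intervals, k27_intervals,
                            expression, pre_intervals = NULL,
                            params = state_params(),
                            cohesin = "Rad21", pc = "Pc", k27 = "H3K27me3") {
  for (f in c(cohesin, pc, k27)) {
    if (!f %in% names(matrix)) {
      abort(sprintf("binding matrix is missing factor column '%s'", f))
    }
  }
  missing_expr <- setdiff(genes$gene_id, expression$gene_id)
  if (length(missing_expr) > 0) {
    abort(sprintf("expression missing for %d gene(s), e.g. %s",
                  length(missing_expr), missing_expr[1]))
  }
  cutoff <- params$expression_cutoff %||%
    median(expression$expression[expression$gene_id %in% genes$gene_id])
  ov <- cohesin_k27_overlap_span(cohesin_intervals, k27_intervals, genes)

  pre_fallback <- is.null(pre_intervals) || nrow(pre_intervals) == 0
  if (!pre_fallback) {
    # bp of cohesin intervals within the transcription unit after
    # subtracting annotated PREs
    pre_gr <- GenomicRanges::reduce(
      as_granges0(pre_intervals$chrom, pre_intervals$start, pre_intervals$end))
    if (nrow(cohesin_intervals) > 0) {
      coh_gr <- GenomicRanges::reduce(
        as_granges0(cohesin_intervals$chrom, cohesin_intervals$start,
                    cohesin_intervals$end))
      outside <- GenomicRanges::setdiff(coh_gr, pre_gr)
      out_tbl <- tibble(chrom = as.character(GenomicRanges::seqnames(outside)),
                        start = GenomicRanges::start(outside) - 1,
                        end = as.numeric(GenomicRanges::end(outside)))
      coh_out <- pairwise_overlap_span(
        out_tbl, tibble(chrom = genes$chrom, start = genes$tx_start,
                        end = genes$tx_end), genes)
    } else {
      coh_out <- tibble(gene_id = genes$gene_id, overlap_bp = 0)
    }
    names(coh_out)[2] <- "cohesin_outside_pre_bp"
  } else {
    coh_out <- tibble(gene_id = genes$gene_id,
                      cohesin_outside_pre_bp = NA_real_)
  }

  evidence <- tibble(gene_id = genes$gene_id) |>
    left_join(select(matrix, "gene_id",
                     cohesin_bound = all_of(cohesin),
                     pc_bound = all_of(pc),
                     k27_bound = all_of(k27)), by = "gene_id") |>
    left_join(ov, by = "gene_id") |>
    left_join(coh_out, by = "gene_id") |>
    left_join(select(expression, "gene_id", "expression"), by = "gene_id") |>
    mutate(low_expression = .data$expression < cutoff,
           pre_fallback = pre_fallback)

  cohesin_free <- if (pre_fallback) {
    evidence$cohesin_bound == 0
  } else {
    evidence$cohesin_outside_pre_bp <= params$pre_slack
  }
  evidence |>
    mutate(
      cohesin_free = cohesin_free,
      state = case_when(
        .data$cohesin_bound == 1 & .data$k27_bound == 1 &
          .data$overlap_bp >= params$restrained_min_overlap ~ "RESTRAINED",
        .data$k27_bound == 1 & .data$pc_bound == 1 & .data$cohesin_free &
          .data$low_expression ~ "SILENCED",
        .data$cohesin_bound == 1 & .data$pc_bound == 1 &
          .data$k27_bound == 0 ~ "ACTIVE",
        TRUE ~ "OTHER")) |>
    select("gene_id", "state", "overlap_bp", "cohesin_bound", "pc_bound",
           "k27_bound", "cohesin_outside_pre_bp", "expression",
           "low_expression", "pre_fallback")
}

#' Active-gene predicate
#'
#' Default operational definition of an "active" gene used for
#' category denominators: not H3K27me3-bound AND (Pol II-bound OR
#' expression at or above the cutoff). Both conditions are exposed so the
#' predicate can be tightened or relaxed.
#'
#' @param matrix Binding matrix.
#' @param expression Expression tibble.
#' @param k27,polii Column names for H3K27me3 and Pol II in `matrix`;
#'   `polii = NULL` drops the Pol II disjunct.
#' @param expression_cutoff log2 cutoff; `NULL` uses the cohort median.
#' @return A tibble `gene_id`, `active` (logical).
#' @export
active_genes <- function(matrix, expression, k27 = "H3K27me3",
                         polii = "Rpb3", expression_cutoff = NULL) {
  if (!k27 %in% names(matrix)) {
    abort(sprintf("binding matrix is missing factor column '%s'", k27))
  }
  cutoff <- expression_cutoff %||% median(expression$expression)
  out <- matrix |>
    left_join(expression, by = "gene_id") |>
    mutate(high_expr = .data$expression >= cutoff)
  polii_bound <- if (!is.null(polii) && polii %in% names(matrix)) {
    out[[polii]] == 1
  } else {
    FALSE
  }
  tibble(gene_id = out$gene_id,
         active = out[[k27]] == 0 & (polii_bound | out$high_expr))
}
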