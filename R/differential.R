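#' Genome-wide null statistics of a delta track
#'
#' Summarises the genome-wide distribution of per-probe differences:
#' median, mean, sample standard deviation and probe count. The
#' change-interval caller thresholds at `median +/- k * sd`. A diagnostic
#' warning is emitted when `|median| > 0.25 * sd`, signalling a shifted
#' delta distribution (the analysis assumes a near-normal null centred
#' close to zero).
#'
#' @param delta A [delta_track()] (or tibble with a `delta` column).
#' @return A `null_stats` object (list with `median`, `mean`, `sd`, `n`).
#'   Supports [tidy()] and [glance()].
#' @export
null_stats <- function(delta) {
  check_columns(delta, "delta", "delta track")
  x <- delta$delta
  if (length(x) < 3) abort("null_stats requires at least 3 probes")
  s <- sd(x)
  if (s == 0) abort("degenerate null: all delta values are equal (sd = 0)")
  m <- median(x)
  if (abs(m) > 0.25 * s) {
    warn(sprintf(paste0("delta distribution looks shifted: |median| = %.3g ",
                        "> 0.25 * sd = %.3g"), abs(m), 0.25 * s))
  }
  structure(list(median = m, mean = mean(x), sd = s, n = length(x)),
            class = "null_stats")
}

#' @export
print.null_stats <- function(x, ...) {
  cat(sprintf(
    "Genome-wide delta null: median %.4g, mean %.4g, sd %.4g (n = %d probes)\n",
    x$median, x$mean, x$sd, x$n))
  invisible(x)
}

#' @rdname null_stats
#' @param x A `null_stats` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.null_stats <- function(x, ...) {
  tibble(median = x$median, mean = x$mean, sd = x$sd, n = x$n)
}

#' @rdname null_stats
#' @exportS3Method generics::glance
glance.null_stats <- function(x, ...) tidy.null_stats(x)

#' Change-call parameters
#'
#' Differential intervals require per-probe deltas at least `k_sd`
#' standard deviations from the genome-wide median delta, sustained over
#' at least `min_run` contiguous probes spanning at least `min_span` bp
#' (defaults: 2 SD, 3 probes, 105 bp).
#'
#' @param k_sd SD multiplier (> 0, default 2).
#' @param min_run Minimum probes per run (default 3).
#' @param min_span Minimum span in bp (default 105).
#' @param max_gap Maximum start-to-start gap between contiguous probes, in
#'   bp; default `NULL` means twice the tile width (tolerates one missing
#'   probe).
#' @return A list of class `change_call_params`.
#' @export
change_call_params <- function(k_sd = 2, min_run = 3, min_span = 105,
                               max_gap = NULL) {
  if (k_sd <= 0) abort("k_sd must be > 0")
  if (min_run < 1) abort("min_run must be >= 1")
  structure(list(k_sd = k_sd, min_run = min_run, min_span = min_span,
                 max_gap = max_gap),
            class = "change_call_params")
}

#' Call signed differential-occupancy intervals
#'
#' Segments a delta track into maximal runs of probes beyond
#' `median + k_sd * sd` (increases, sign +1) or below
#' `median - k_sd * sd` (decreases, sign -1), with the same sign
#' throughout a run. Runs of at least `min_run` probes and tile-union span
#' at least `min_span` bp are emitted; increase and decrease intervals can
#' never overlap because each probe has a single state.
#'
#' @param delta A [delta_track()].
#' @param null A [null_stats()] object (computed from `delta` if `NULL`).
#' @param params A [change_call_params()] object.
#' @return A `change_calls` interval tibble (`chrom`, `start`, `end`,
#'   `sign` +1/-1, `score` = mean delta, `n_probes`), with the thresholds
#'   carried as attributes.
#' @export
call_change_intervals <- function(delta, null = NULL,
                                  params = change_call_params()) {
  check_columns(delta, c("chrom", "start", "delta"), "delta track")
  if (is.null(null)) null <- null_stats(delta)
  tw <- tile_width(delta)
  max_gap <- params$max_gap %||% (2 * tw)
  up_thr <- null$median + params$k_sd * null$sd
  dn_thr <- null$median - params$k_sd * null$sd
  state <- ifelse(delta$delta >= up_thr, 1L,
                  ifelse(delta$delta <= dn_thr, -1L, 0L))
  out <- call_runs(delta$chrom, delta$start, delta$delta, state, tw,
                   max_start_gap = max_gap,
                   min_run = params$min_run, min_span = params$min_span)
  attr(out, "thresholds") <- c(down = dn_thr, up = up_thr)
  attr(out, "params") <- params
  class(out) <- unique(c("change_calls", class(out)))
  out
}

#' @exportS3Method generics::glance
glance.change_calls <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble(n_increase = sum(x$sign > 0), n_decrease = sum(x$sign < 0),
         threshold_down = unname(thr["down"]), threshold_up = unname(thr["up"]))
}

#' Promoter/body partition of gene models
#'
#' The promoter is the window of width `promoter_width` centred on the
#' TSS (strand-aware); the body is the remainder of the transcription
#' unit. Two widths are in routine use: 200 bp for change classification
#' and 400 bp for the pause index.
#'
#' @param genes Gene model tibble ([gene_models()]).
#' @param promoter_width Promoter window width in bp (default 200).
#' @return A tibble with one row per gene region: `gene_id`, `region`
#'   (`"promoter"`/`"body"`), `chrom`, `start`, `end`. Genes whose body is
#'   fully covered by the promoter window contribute no body row.
#' @export
gene_regions <- function(genes, promoter_width = 200) {
  if (promoter_width <= 0) abort("promoter_width must be > 0")
  half <- promoter_width / 2
  prom <- transmute(genes, .data$gene_id, region = "promoter", .data$chrom,
                    start = pmax(0, .data$tss - half),
                    end = .data$tss + half)
  # body = transcription unit minus the promoter window (possibly 2 pieces)
  left <- transmute(genes, .data$gene_id, region = "body", .data$chrom,
                    start = .data$tx_start,
                    end = pmin(.data$tx_end, pmax(.data$tx_start, .data$tss - half)))
  right <- transmute(genes, .data$gene_id, region = "body", .data$chrom,
                     start = pmax(.data$tx_start, pmin(.data$tx_end, .data$tss + half)),
                     end = .data$tx_end)
  body <- bind_rows(left, right) |> filter(.data$start < .data$end)
  bind_rows(prom, body) |> arrange(.data$gene_id, .data$region, .data$start)
}

# Map probes (tiles fully contained in a region) to region rows.
# Returns tibble(region_row, probe_row).
probes_within <- function(track, regions) {
  if (nrow(track) == 0 || nrow(regions) == 0) {
    return(tibble(region_row = integer(), probe_row = integer()))
  }
  hits <- GenomicRanges::findOverlaps(
    probe_granges(track),
    as_granges0(regions$chrom, regions$start, regions$end),
    type = "within"
  )
  tibble(region_row = subjectHits(hits), probe_row = queryHits(hits))
}

#' Integrated per-gene occupancy change
#'
#' For each region, sums the scores of all probes contained within the
#' region in both conditions (shared probes only) and reports the
#' difference `depleted - control`. Regions covering no shared probes are
#' flagged `no_data` (distinct from a true delta of 0).
#'
#' @param control,depleted [probe_track()] objects.
#' @param regions A region tibble (`gene_id`, `chrom`, `start`, `end`,
#'   optionally `region`), e.g. from [gene_regions()] or the transcription
#'   units themselves.
#' @return A tibble with `gene_id` (and `region` if present),
#'   `delta_total`, `total_control`, `total_depleted`, `n_probes`,
#'   `no_data`.
#' @export
integrated_gene_delta <- function(control, depleted, regions) {
  regions <- as_tibble(regions)
  check_columns(regions, c("gene_id", "chrom", "start", "end"), "regions")
  paired <- suppressWarnings(align_tracks(control, depleted))
  paired_track <- new_probe_track(paired, tile_width(control))
  hits <- probes_within(paired_track, regions)
  keys <- intersect(c("gene_id", "region"), names(regions))
  sums <- hits |>
    mutate(sc = paired$score_a[.data$probe_row],
           sd_ = paired$score_b[.data$probe_row]) |>
    group_by(.data$region_row) |>
    summarise(total_control = sum(.data$sc), total_depleted = sum(.data$sd_),
              n_probes = dplyr::n(), .groups = "drop")
  out <- regions |>
    mutate(region_row = dplyr::row_number()) |>
    left_join(sums, by = "region_row") |>
    mutate(n_probes = as.integer(replace_na(.data$n_probes, 0L))) |>
    group_by(across(all_of(keys))) |>
    summarise(total_control = sum(.data$total_control, na.rm = TRUE),
              total_depleted = sum(.data$total_depleted, na.rm = TRUE),
              n_probes = sum(.data$n_probes), .groups = "drop") |>
    mutate(no_data = .data$n_probes == 0,
           delta_total = ifelse(.data$no_data, NA_real_,
                                .data$total_depleted - .data$total_control)) |>
    select(all_of(keys), "delta_total", "total_control", "total_depleted",
           "n_probes", "no_data")
  out
}

#' Pause index per gene
#'
#' Ratio of the promoter-region statistic to the gene-body statistic of
#' Pol II occupancy: by default the median probe score in the
#' promoter window (width `promoter_width`, centred on the TSS,
#' strand-aware) divided by the median in the rest of the transcription
#' unit. `stat = "density"` uses summed score per bp instead.
#'
#' @param track A [probe_track()] (e.g. total Pol II / Rpb3).
#' @param genes Gene model tibble.
#' @param promoter_width Promoter window in bp (default 400).
#' @param stat `"median"` (default) or `"density"` (sum per bp).
#' @return A tibble `gene_id`, `pause_index`, `promoter`, `body`,
#'   `flag` (`"ok"`, `"no_data"` when either region has no probes,
#'   `"undefined"` when the body statistic is <= 0).
#' @export
pause_index <- function(track, genes, promoter_width = 400,
                        stat = c("median", "density")) {
  stat <- match.arg(stat)
  # probe medians: compute directly on per-probe scores per gene region
  regions <- gene_regions(genes, promoter_width)
  hits <- probes_within(track, regions)
  per_region <- hits |>
    mutate(score = track$score[.data$probe_row],
           gene_id = regions$gene_id[.data$region_row],
           region = regions$region[.data$region_row])
  widths <- regions |>
    group_by(.data$gene_id, .data$region) |>
    summarise(width = sum(.data$end - .data$start), .groups = "drop")
  vals <- per_region |>
    group_by(.data$gene_id, .data$region) |>
    summarise(med = median(.data$score), total = sum(.data$score),
              n_probes = dplyr::n(), .groups = "drop") |>
    left_join(widths, by = c("gene_id", "region")) |>
    mutate(value = if (stat == "median") .data$med else .data$total / .data$width)
  wide <- vals |>
    select("gene_id", "region", "value", "n_probes") |>
    pivot_wider(names_from = "region", values_from = c("value", "n_probes"))
  for (col in c("value_promoter", "value_body", "n_probes_promoter", "n_probes_body")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  out <- tibble(gene_id = genes$gene_id) |>
    left_join(wide, by = "gene_id") |>
    mutate(
      flag = case_when(
        is.na(.data$value_promoter) | is.na(.data$value_body) ~ "no_data",
        .data$value_body <= 0 ~ "undefined",
        TRUE ~ "ok"),
      pause_index = ifelse(.data$flag == "ok",
                           .data$value_promoter / .data$value_body, NA_real_)
    ) |>
    select("gene_id", "pause_index", promoter = "value_promoter",
           body = "value_body", "flag")
  out
}

#' Elongation ratio (Ser2P / total Pol II) per gene body
#'
#' Median elongating-Pol II (Ser2P) score divided by the median total
#' Pol II (Rpb3) score over the probes shared by the two tracks in each
#' gene body (transcription unit minus the promoter window).
#'
#' @param ser2p,rpb3 [probe_track()] objects.
#' @param genes Gene model tibble.
#' @param promoter_width Promoter window excluded from the body (default
#'   400 bp, matching [pause_index()]).
#' @return A tibble `gene_id`, `ratio`, `ser2p_body`, `rpb3_body`, `flag`
#'   (`"ok"`, `"no_data"`, `"undefined"` when the Rpb3 body median <= 0).
#' @export
elongation_ratio <- function(ser2p, rpb3, genes, promoter_width = 400) {
  paired <- suppressWarnings(align_tracks(ser2p, rpb3))
  body <- gene_regions(genes, promoter_width) |> filter(.data$region == "body")
  paired_track <- new_probe_track(paired, tile_width(ser2p))
  hits <- probes_within(paired_track, body)
  vals <- hits |>
    mutate(gene_id = body$gene_id[.data$region_row],
           s = paired$score_a[.data$probe_row],
           r = paired$score_b[.data$probe_row]) |>
    group_by(.data$gene_id) |>
    summarise(ser2p_body = median(.data$s), rpb3_body = median(.data$r),
              n_probes = dplyr::n(), .groups = "drop")
  tibble(gene_id = unique(genes$gene_id)) |>
    left_join(vals, by = "gene_id") |>
    mutate(
      flag = case_when(
        is.na(.data$rpb3_body) ~ "no_data",
        .data$rpb3_body <= 0 ~ "undefined",
        TRUE ~ "ok"),
      ratio = ifelse(.data$flag == "ok", .data$ser2p_body / .data$rpb3_body,
                     NA_real_)
    ) |>
    select("gene_id", "ratio", "ser2p_body", "rpb3_body", "flag")
}

#' Classify per-gene occupancy changes from called intervals
#'
#' For each gene and region (promoter window of `promoter_width` bp and
#' gene body), intersects the signed change intervals with the region
#' (>= 1 bp overlap, strand ignored) and assigns: `UP` if only increase
#' intervals overlap, `DOWN` if only decreases, `AMBIGUOUS` if both,
#' `NONE` otherwise. Ambiguous cases carry an automatic resolution: the
#' sign with the larger summed `|mean delta| * span` weight
#' (`resolved_class`); exact ties stay unresolved (`NA`).
#'
#' @param calls Change-call intervals from [call_change_intervals()].
#' @param genes Gene model tibble.
#' @param promoter_width Promoter window in bp (default 200).
#' @return A tibble `gene_id`, `region`, `class`, `resolved_class`,
#'   `weight_up`, `weight_down`.
#' @export
classify_gene_changes <- function(calls, genes, promoter_width = 200) {
  regions <- gene_regions(genes, promoter_width)
  base <- regions |> distinct(.data$gene_id, .data$region)
  if (nrow(calls) == 0) {
    return(base |> mutate(class = "NONE", resolved_class = NA_character_,
                          weight_up = 0, weight_down = 0))
  }
  hits <- GenomicRanges::findOverlaps(
    as_granges0(regions$chrom, regions$start, regions$end),
    as_granges0(calls$chrom, calls$start, calls$end),
    minoverlap = 1L
  )
  ov <- tibble(region_row = queryHits(hits), call_row = subjectHits(hits)) |>
    mutate(gene_id = regions$gene_id[.data$region_row],
           region = regions$region[.data$region_row],
           sign = calls$sign[.data$call_row],
           weight = abs(calls$score[.data$call_row]) *
             (calls$end[.data$call_row] - calls$start[.data$call_row])) |>
    # a single call may hit both body pieces of one gene; count it once
    distinct(.data$gene_id, .data$region, .data$call_row, .keep_all = TRUE) |>
    group_by(.data$gene_id, .data$region) |>
    summarise(weight_up = sum(.data$weight[.data$sign > 0]),
              weight_down = sum(.data$weight[.data$sign < 0]),
              any_up = any(.data$sign > 0), any_down = any(.data$sign < 0),
              .groups = "drop")
  base |>
    left_join(ov, by = c("gene_id", "region")) |>
    mutate(any_up = replace_na(.data$any_up, FALSE),
           any_down = replace_na(.data$any_down, FALSE),
           weight_up = replace_na(.data$weight_up, 0),
           weight_down = replace_na(.data$weight_down, 0),
           class = case_when(
             .data$any_up & .data$any_down ~ "AMBIGUOUS",
             .data$any_up ~ "UP",
             .data$any_down ~ "DOWN",
             TRUE ~ "NONE"),
           resolved_class = case_when(
             .data$class == "UP" ~ "UP",
             .data$class == "DOWN" ~ "DOWN",
             .data$class == "AMBIGUOUS" & .data$weight_up > .data$weight_down ~ "UP",
             .data$class == "AMBIGUOUS" & .data$weight_down > .data$weight_up ~ "DOWN",
             TRUE ~ NA_character_)) |>
    select("gene_id", "region", "class", "resolved_class",
           "weight_up", "weight_down")
}

#' Percentage of genes per group showing occupancy changes
#'
#' For each group (e.g. cohesin-binding vs non-binding genes) reports the
#' percentage of genes classified UP and DOWN. Ambiguous genes are counted
#' under their automatic resolution and also reported separately. Empty
#' groups are flagged rather than reported as 0%.
#'
#' @param classes Output of [classify_gene_changes()], optionally
#'   pre-filtered to one region.
#' @param groups A tibble `gene_id`, `group` assigning every gene to a
#'   group; `group` may be a factor whose empty levels are retained.
#' @return A tibble per group (and region, if present in `classes`):
#'   `n_genes`, `pct_up`, `pct_down`, `pct_ambiguous`, `empty_group`.
#' @export
category_percentages <- function(classes, groups) {
  check_columns(groups, c("gene_id", "group"), "groups")
  keys <- intersect("region", names(classes))
  joined <- inner_join(classes, groups, by = "gene_id")
  if (is.factor(groups$group)) {
    joined$group <- factor(joined$group, levels = levels(groups$group))
  }
  out <- joined |>
    group_by(across(all_of(c("group", keys))), .drop = FALSE) |>
    summarise(
      n_genes = dplyr::n(),
      pct_up = 100 * sum(.data$resolved_class %in% "UP") / dplyr::n(),
      pct_down = 100 * sum(.data$resolved_class %in% "DOWN") / dplyr::n(),
      pct_ambiguous = 100 * sum(.data$class == "AMBIGUOUS") / dplyr::n(),
      .groups = "drop") |>
    mutate(empty_group = .data$n_genes == 0,
           across(c("pct_up", "pct_down", "pct_ambiguous"),
                  ~ ifelse(.data$n_genes == 0, NA_real_, .x)))
  out
}
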