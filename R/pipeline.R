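#' Pipeline configuration
#'
#' Collects input paths and stage parameters for [run_pipeline()]. Every
#' default that carries over from the underlying method is exposed here:
#' `k_sd = 2` and `min_run = 3` / `min_span = 105` for change calls,
#' a 200 bp promoter window for change classification, a 400 bp window
#' for the pause index, and a 2 kb cohesin/H3K27me3 overlap for the
#' restrained state.
#'
#' @param tracks Named list per factor; each element a named list with a
#'   `control` path and optionally a `depleted` path (bedGraph).
#' @param genes Path to the gene annotation.
#' @param genes_format `"tsv"` or `"gff3"`.
#' @param expression Path to the expression TSV.
#' @param pres Optional path to a PRE BED file.
#' @param tau Binding-call score threshold.
#' @param binding A [binding_call_params()]; built from `tau` if `NULL`.
#' @param change A [change_call_params()].
#' @param states A [state_params()].
#' @param tile_width Probe tile width in bp.
#' @param change_promoter_width Promoter window for UP/DOWN region
#'   classification (bp).
#' @param pause_promoter_width Promoter window for the pause index (bp).
#' @param venn_factors Factors for the overlap (Venn) table.
#' @param grouping_factor Factor whose binding defines the category
#'   grouping for percentage tables (default `"Rad21"`).
#' @param state_factors Named character vector mapping the classifier
#'   roles `cohesin`, `pc`, `k27` to factor names.
#' @param out_dir Output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tracks, genes, genes_format = "tsv", expression,
                            pres = NULL, tau, binding = NULL,
                            change = change_call_params(),
                            states = state_params(), tile_width = 35,
                            change_promoter_width = 200,
                            pause_promoter_width = 400,
                            venn_factors = c("Rad21", "Pc", "H3K27me3"),
                            grouping_factor = "Rad21",
                            state_factors = c(cohesin = "Rad21", pc = "Pc",
                                              k27 = "H3K27me3"),
                            out_dir = "polystate_out") {
  if (is.null(binding)) binding <- binding_call_params(tau)
  structure(list(tracks = tracks, genes = genes, genes_format = genes_format,
                 expression = expression, pres = pres, binding = binding,
                 change = change, states = states, tile_width = tile_width,
                 change_promoter_width = change_promoter_width,
                 pause_promoter_width = pause_promoter_width,
                 venn_factors = venn_factors,
                 grouping_factor = grouping_factor,
                 state_factors = state_factors, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors the arguments of [pipeline_config()]; nested
#' parameter blocks `binding`, `change` and `states` are passed to the
#' corresponding parameter constructors.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$binding)) args$binding <- do.call(binding_call_params, y$binding)
  if (!is.null(y$change)) args$change <- do.call(change_call_params, y$change)
  if (!is.null(y$states)) args$states <- do.call(state_params, y$states)
  if (!is.null(y$state_factors)) args$state_factors <- unlist(y$state_factors)
  if (!is.null(y$venn_factors)) args$venn_factors <- unlist(y$venn_factors)
  do.call(pipeline_config, args)
}

stage_abort <- function(stage, msg) {
  abort(sprintf("pipeline stage '%s' failed: %s", stage, msg))
}

#' Run the full occupancy pipeline
#'
#' Stages: binding calls per factor, gene binding matrix and Venn overlap
#' counts; per-depletion delta tracks, null diagnostics, signed change
#' intervals and per-gene UP/DOWN classification with category-percentage
#' tables; cohesin-PcG state calls; pause-index and elongation-ratio
#' summaries before/after depletion. All tables are written as TSV (BED6
#' for intervals) under `config$out_dir` together with a machine-readable
#' run manifest (parameters plus input checksums). The run is
#' deterministic given inputs and configuration.
#'
#' @param config A [pipeline_config()].
#' @return A list of result tibbles (`binding`, `matrix`, `venn`,
#'   `differential`, `states`, `pause`, `manifest` paths), invisibly
#'   written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message("[polystate] ", line)
    log_lines <<- c(log_lines, line)
  }

  # inputs -------------------------------------------------------------
  for (f in names(config$tracks)) {
    for (cond in names(config$tracks[[f]])) {
      p <- config$tracks[[f]][[cond]]
      if (!file.exists(p)) stage_abort("inputs", sprintf(
        "track file for factor '%s' (%s) not found: %s", f, cond, p))
    }
  }
  genes <- read_genes(config$genes, config$genes_format)
  expression <- read_expression(config$expression)
  pres <- if (!is.null(config$pres)) read_bed(config$pres) else NULL
  tracks <- lapply(config$tracks, function(tt) {
    lapply(tt, read_track, format = "bedGraph", tile_width = config$tile_width)
  })
  say("read %d genes, %d factors", nrow(genes), length(tracks))

  # stage: binding calls ------------------------------------------------
  bound <- lapply(names(tracks), function(f) {
    iv <- call_bound_intervals(tracks[[f]]$control, config$binding)
    write_bed(iv, file.path(config$out_dir, sprintf("bound_%s.bed", f)))
    iv
  })
  names(bound) <- names(tracks)
  mat <- binding_matrix(genes, bound)
  readr::write_tsv(mat, file.path(config$out_dir, "binding_matrix.tsv"))
  venn <- NULL
  vf <- intersect(config$venn_factors, names(mat))
  if (length(setdiff(config$venn_factors, names(mat))) > 0) {
    say("venn factors not all mapped (%s); using %s",
        paste(setdiff(config$venn_factors, names(mat)), collapse = ","),
        paste(vf, collapse = ","))
  }
  if (length(vf) >= 2) {
    venn <- overlap_counts(mat, vf)
    readr::write_tsv(venn, file.path(config$out_dir, "venn_counts.tsv"))
  }
  say("binding calls done (%s)", paste(sprintf(
    "%s:%d", names(bound), vapply(bound, nrow, 1L)), collapse = ", "))

  # stage: differential occupancy ---------------------------------------
  if (!config$grouping_factor %in% names(mat)) {
    stage_abort("differential", sprintf(
      "grouping factor '%s' has no track", config$grouping_factor))
  }
  act <- active_genes(mat, expression,
                      k27 = config$state_factors[["k27"]],
                      polii = if ("Rpb3" %in% names(mat)) "Rpb3" else NULL)
  groups <- tibble(
    gene_id = mat$gene_id,
    group = factor(ifelse(mat[[config$grouping_factor]] == 1,
                          "cohesin_bound", "cohesin_free"),
                   levels = c("cohesin_bound", "cohesin_free")))
  differential <- list()
  null_diag <- list()
  depleted_factors <- names(tracks)[vapply(tracks, function(tt)
    "depleted" %in% names(tt), TRUE)]
  for (f in depleted_factors) {
    dt <- delta_track(tracks[[f]]$control, tracks[[f]]$depleted)
    ns <- withCallingHandlers(
      null_stats(dt),
      warning = function(w) {
        say("delta diagnostics (%s): %s", f, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    null_diag[[f]] <- tidy(ns)
    say("delta null (%s): median %.3g, mean %.3g, sd %.3g over %d probes",
        f, ns$median, ns$mean, ns$sd, ns$n)
    calls <- call_change_intervals(dt, ns, config$change)
    write_bed(calls, file.path(config$out_dir, sprintf("changes_%s.bed", f)))
    classes <- classify_gene_changes(calls, genes,
                                     config$change_promoter_width)
    metrics <- integrated_gene_delta(
      tracks[[f]]$control, tracks[[f]]$depleted,
      transmute(genes, .data$gene_id, .data$chrom,
                start = .data$tx_start, end = .data$tx_end))
    readr::write_tsv(classes,
                     file.path(config$out_dir, sprintf("classes_%s.tsv", f)))
    readr::write_tsv(metrics,
                     file.path(config$out_dir, sprintf("gene_delta_%s.tsv", f)))
    pct_active <- category_percentages(
      semi_join(classes, filter(act, .data$active), by = "gene_id"), groups)
    readr::write_tsv(pct_active, file.path(
      config$out_dir, sprintf("category_percentages_active_%s.tsv", f)))
    differential[[f]] <- list(calls = calls, classes = classes,
                              metrics = metrics, null = ns,
                              percentages_active = pct_active)
  }

  # stage: chromatin states ---------------------------------------------
  states <- NULL
  sf <- config$state_factors
  if (all(sf %in% names(mat))) {
    states <- classify_states(genes, mat,
                              cohesin_intervals = bound[[sf[["cohesin"]]]],
                              k27_intervals = bound[[sf[["k27"]]]],
                              expression = expression, pre_intervals = pres,
                              params = config$states,
                              cohesin = sf[["cohesin"]], pc = sf[["pc"]],
                              k27 = sf[["k27"]])
    readr::write_tsv(states, file.path(config$out_dir, "state_calls.tsv"))
    say("states: %s", paste(sprintf("%s=%d", names(table(states$state)),
                                    table(states$state)), collapse = ", "))
  } else {
    say("state classification skipped: factors %s not all mapped",
        paste(sf, collapse = ","))
  }

  # stage: pause index / elongation ratio --------------------------------
  pause <- NULL
  if ("Rpb3" %in% names(tracks)) {
    pi_list <- list(control = pause_index(tracks$Rpb3$control, genes,
                                          config$pause_promoter_width))
    if ("depleted" %in% names(tracks$Rpb3)) {
      pi_list$depleted <- pause_index(tracks$Rpb3$depleted, genes,
                                      config$pause_promoter_width)
    }
    pause <- bind_rows(pi_list, .id = "condition")
    if ("Ser2P" %in% names(tracks)) {
      er <- list(control = elongation_ratio(tracks$Ser2P$control,
                                            tracks$Rpb3$control, genes,
                                            config$pause_promoter_width))
      if (all(c("depleted") %in% names(tracks$Ser2P)) &&
          "depleted" %in% names(tracks$Rpb3)) {
        er$depleted <- elongation_ratio(tracks$Ser2P$depleted,
                                        tracks$Rpb3$depleted, genes,
                                        config$pause_promoter_width)
      }
      er <- bind_rows(er, .id = "condition")
      readr::write_tsv(er, file.path(config$out_dir, "elongation_ratio.tsv"))
    }
    readr::write_tsv(pause, file.path(config$out_dir, "pause_index.tsv"))
    summ <- pause |>
      filter(.data$flag == "ok") |>
      group_by(.data$condition) |>
      summarise(median_pause_index = median(.data$pause_index),
                n_genes = dplyr::n(), .groups = "drop")
    readr::write_tsv(summ, file.path(config$out_dir, "pause_summary.tsv"))
    say("pause index: %s", paste(sprintf(
      "%s median %.3f", summ$condition, summ$median_pause_index),
      collapse = ", "))
  }

  # manifest -------------------------------------------------------------
  input_files <- c(unlist(config$tracks, use.names = TRUE),
                   genes = config$genes, expression = config$expression,
                   pres = config$pres)
  manifest <- list(
    package = "polystate",
    version = as.character(utils::packageVersion("polystate")),
    parameters = list(
      binding = unclass(config$binding), change = unclass(config$change),
      states = unclass(config$states)[c("restrained_min_overlap", "pre_slack")],
      tile_width = config$tile_width,
      change_promoter_width = config$change_promoter_width,
      pause_promoter_width = config$pause_promoter_width,
      grouping_factor = config$grouping_factor),
    null_diagnostics = null_diag,
    inputs = as.list(tools::md5sum(unlist(input_files))),
    log = log_lines)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(genes = genes, expression = expression, binding = bound,
                 matrix = mat, venn = venn, differential = differential,
                 states = states, pause = pause, active = act,
                 out_dir = config$out_dir))
}
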