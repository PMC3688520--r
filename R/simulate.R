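# Synthetic tiling-array data with exported ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# a regular 35-bp probe grid, iid near-normal per-probe noise
# (sigma0 = 0.8 score units per track, so a condition difference has
# SD sigma0 * sqrt(2)), promoter-peaked (cohesin, Pol II) vs broad-domain
# (H3K27me3) binding architectures, paired control/depletion tracks where
# stated fractions of genes carry directional additive effects, and
# state-correlated mRNA values.

#' Simulation configuration
#'
#' @param n_genes Number of genes.
#' @param tile_width Probe tile width in bp (default 35).
#' @param noise_sd Per-track probe noise SD sigma0, enrichment units
#'   (default 0.8; a delta track then has null SD `noise_sd * sqrt(2)`).
#' @param chrom Chromosome name for the simulated genome.
#' @param state_fractions Named fractions for `silenced`, `restrained`,
#'   `active`, `other` (sum <= 1; any remainder goes to `other`).
#' @param exact_counts If `TRUE` (default) state counts are deterministic
#'   (`round(fraction * n_genes)`); otherwise a multinomial draw.
#' @param factors Factors to emit tracks for.
#' @param effects Optional effect table: columns `factor`, `region`
#'   (`"promoter"`, `"body"`, `"whole"`, or `"promoter_to_body"`),
#'   `category` (`"all"`, `"active"`, `"silenced"`, `"restrained"`,
#'   `"other"`, or `"cohesin_active"`), `fraction` of eligible genes
#'   affected (exact count), `effect_size` (in units of `noise_sd`) and
#'   `direction` (`"up"`/`"down"`). Affected genes get an additive
#'   `direction * effect_size * noise_sd` shift over the region in the
#'   depleted track (scores are log-linear, so additive shifts model
#'   fold-changes).
#' @param gene_length_meanlog,gene_length_sdlog Lognormal transcription
#'   unit length parameters (default: median 3 kb).
#' @param gap_meanlog,gap_sdlog Lognormal intergenic gap parameters
#'   (default: median 1.5 kb).
#' @param promoter_width Promoter window used for effect regions, bp
#'   (default 400, the pause-index window).
#' @param missing_probe_rate Fraction of grid positions dropped (masked
#'   probes); default 0.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500, tile_width = 35, noise_sd = 0.8,
                       chrom = "chr2L",
                       state_fractions = c(silenced = 0.10, restrained = 0.05,
                                           active = 0.60, other = 0.25),
                       exact_counts = TRUE,
                       factors = c("Rad21", "Pc", "H3K27me3", "Rpb3", "Ser2P"),
                       effects = NULL,
                       gene_length_meanlog = log(3000),
                       gene_length_sdlog = 0.4,
                       gap_meanlog = log(1500), gap_sdlog = 0.4,
                       promoter_width = 400,
                       missing_probe_rate = 0) {
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  need <- c("silenced", "restrained", "active", "other")
  if (!all(need %in% names(state_fractions))) {
    abort("state_fractions must name silenced, restrained, active, other")
  }
  if (sum(state_fractions) > 1 + 1e-9) abort("state_fractions must sum to <= 1")
  if (!is.null(effects)) {
    effects <- as_tibble(effects)
    check_columns(effects, c("factor", "region", "category", "fraction",
                             "effect_size", "direction"), "effects")
    if (any(effects$effect_size < 0)) abort("effect_size must be >= 0")
    if (!all(effects$region %in% c("promoter", "body", "whole",
                                   "promoter_to_body"))) {
      abort("effects$region must be promoter/body/whole/promoter_to_body")
    }
    if (!all(effects$direction %in% c("up", "down"))) {
      abort("effects$direction must be 'up' or 'down'")
    }
  }
  structure(list(n_genes = n_genes, tile_width = tile_width,
                 noise_sd = noise_sd, chrom = chrom,
                 state_fractions = state_fractions[need],
                 exact_counts = exact_counts, factors = factors,
                 effects = effects,
                 gene_length_meanlog = gene_length_meanlog,
                 gene_length_sdlog = gene_length_sdlog,
                 gap_meanlog = gap_meanlog, gap_sdlog = gap_sdlog,
                 promoter_width = promoter_width,
                 missing_probe_rate = missing_probe_rate),
            class = "sim_config")
}

# Signal architecture: amplitudes (score units) per factor and state.
# Promoter peaks are Gaussian (sd 150 bp; PRE peaks sd 60 bp); plateaus
# cover the transcription unit; broad domains extend 500 bp beyond it.
sim_architecture <- function() {
  list(
    Rad21 = list(active = list(peak = 5),
                 restrained = list(plateau = 3.5),
                 silenced = list(pre_peak = 4)),
    `Nipped-B` = list(active = list(peak = 4.5),
                      restrained = list(plateau = 3),
                      silenced = list(pre_peak = 3.5)),
    Pc = list(active = list(peak = 4),
              restrained = list(plateau = 3.5),
              silenced = list(plateau = 4)),
    Ph = list(active = list(peak = 4),
              restrained = list(plateau = 3.5),
              silenced = list(plateau = 4)),
    H3K27me3 = list(restrained = list(domain = 4),
                    silenced = list(domain = 4)),
    Rpb3 = list(active = list(peak = 6, plateau = 2),
                restrained = list(peak = 3, plateau = 0.5)),
    Ser2P = list(active = list(plateau = 2),
                 restrained = list(plateau = 0.5))
  )
}

# Grid-index helpers: probe i (1-based) has start (i - 1) * tw.
grid_range <- function(a, b, tw, np) {
  i1 <- max(1L, as.integer(floor(a / tw)) + 1L)
  i2 <- min(np, as.integer(ceiling(b / tw)))
  if (i1 > i2) integer(0) else i1:i2
}

add_peak <- function(mu, center, amp, sd_bp, tw, np) {
  idx <- grid_range(center - 4 * sd_bp, center + 4 * sd_bp, tw, np)
  if (length(idx) == 0) return(mu)
  p <- (idx - 1) * tw
  mu[idx] <- mu[idx] + amp * exp(-(p - center)^2 / (2 * sd_bp^2))
  mu
}

add_plateau <- function(mu, a, b, amp, tw, np) {
  idx <- grid_range(a, b, tw, np)
  mu[idx] <- mu[idx] + amp
  mu
}

#' Simulate a complete synthetic dataset
#'
#' Generates a gene annotation, state-correlated expression values,
#' paired control/depleted probe tracks for each factor, PRE annotations
#' for silenced genes, and ground truth for every stage. Deterministic
#' given the seed; control and depleted tracks share the probe grid and
#' differ only by independent noise plus the configured effects.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with elements `tracks` (per factor: `$control` and,
#'   for factors with effects, `$depleted` [probe_track()]s), `genes`,
#'   `expression`, `pres` (PRE intervals), `truth` (per-gene state and
#'   per-factor bound flags), `effects_truth` (affected gene/factor/region
#'   /sign), and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(as.integer(seed), simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  n <- config$n_genes
  tw <- config$tile_width
  fr <- config$state_fractions

  # states ------------------------------------------------------------
  if (config$exact_counts) {
    counts <- round(fr * n)
    counts["other"] <- n - sum(counts[c("silenced", "restrained", "active")])
    if (counts["other"] < 0) abort("state fractions leave no room for 'other'")
    states <- sample(rep(names(counts), counts))
  } else {
    states <- sample(names(fr), n, replace = TRUE, prob = fr)
  }

  # gene layout: sequential placement with lognormal lengths and gaps --
  len <- rlnorm(n, config$gene_length_meanlog, config$gene_length_sdlog)
  len <- pmax(500, round(len / tw) * tw)
  len[states == "restrained"] <- pmax(len[states == "restrained"], 5000)
  # gaps stay wider than twice the broad-domain flank (500 bp) so a
  # domain never reaches a neighboring transcription unit and ground
  # truth stays consistent with the emitted tracks by construction
  gap <- pmax(1100, round(rlnorm(n, config$gap_meanlog, config$gap_sdlog)))
  tx_start <- cumsum(c(2000, head(len + gap, -1)))
  tx_end <- tx_start + len
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- gene_models(tibble(
    gene_id = sprintf("g%04d", seq_len(n)), chrom = config$chrom,
    strand = strand, tx_start = tx_start, tx_end = tx_end))
  chrom_length <- max(tx_end) + 3000
  if (max(tx_end) > chrom_length) abort("genes do not fit on the chromosome")

  np <- as.integer(chrom_length %/% tw)
  probe_start <- (seq_len(np) - 1) * tw

  # PREs inside silenced transcription units, at the TSS-proximal end --
  sil <- which(states == "silenced")
  pres <- tibble(chrom = character(), start = numeric(), end = numeric())
  if (length(sil) > 0) {
    pre_start <- ifelse(strand[sil] == "+", tx_start[sil], tx_end[sil] - 300)
    pres <- tibble(chrom = config$chrom, start = pre_start,
                   end = pre_start + 300,
                   gene_id = genes$gene_id[sil])
  }

  # noise-free mean track per factor -----------------------------------
  arch <- sim_architecture()
  unknown <- setdiff(config$factors, names(arch))
  if (length(unknown) > 0) {
    abort(sprintf("no architecture for factor(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  tss <- genes$tss
  means <- list()
  bound <- matrix(0L, n, length(config$factors),
                  dimnames = list(NULL, config$factors))
  for (f in config$factors) {
    mu <- numeric(np)
    spec <- arch[[f]]
    for (g in seq_len(n)) {
      comp <- spec[[states[g]]]
      if (is.null(comp)) next
      if (!is.null(comp$peak)) {
        mu <- add_peak(mu, tss[g], comp$peak, 150, tw, np)
      }
      if (!is.null(comp$plateau)) {
        mu <- add_plateau(mu, tx_start[g], tx_end[g], comp$plateau, tw, np)
      }
      if (!is.null(comp$domain)) {
        mu <- add_plateau(mu, tx_start[g] - 500, tx_end[g] + 500,
                          comp$domain, tw, np)
      }
      if (!is.null(comp$pre_peak)) {
        k <- match(g, sil)
        mu <- add_peak(mu, (pres$start[k] + pres$end[k]) / 2, comp$pre_peak,
                       60, tw, np)
      }
      if (max(unlist(comp)) >= 2) bound[g, f] <- 1L
    }
    means[[f]] <- mu
  }

  # effects -------------------------------------------------------------
  half <- config$promoter_width / 2
  effect_shift <- setNames(vector("list", length(config$factors)),
                           config$factors)
  effects_truth <- tibble(gene_id = character(), factor = character(),
                          region = character(), sign = numeric())
  if (!is.null(config$effects)) {
    for (k in seq_len(nrow(config$effects))) {
      e <- config$effects[k, ]
      if (!e$factor %in% config$factors) {
        abort(sprintf("effect references factor '%s' not in config$factors",
                      e$factor))
      }
      eligible <- switch(e$category,
        all = seq_len(n),
        cohesin_active = which(states == "active" & bound[, "Rad21"] == 1),
        which(states == e$category))
      if (length(eligible) == 0) abort(sprintf("no eligible genes for category '%s'", e$category))
      n_aff <- round(e$fraction * length(eligible))
      aff <- sort(sample(eligible, n_aff))
      shift <- (if (e$direction == "down") -1 else 1) *
        e$effect_size * config$noise_sd
      if (is.null(effect_shift[[e$factor]])) {
        effect_shift[[e$factor]] <- numeric(np)
      }
      for (g in aff) {
        prom <- c(max(0, tss[g] - half), tss[g] + half)
        body <- if (strand[g] == "+") c(tss[g] + half, tx_end[g])
                else c(tx_start[g], tss[g] - half)
        if (e$region %in% c("promoter", "whole", "promoter_to_body")) {
          w <- if (e$region == "whole") c(tx_start[g], tx_end[g]) else prom
          s <- if (e$region == "promoter_to_body") -abs(shift) else shift
          effect_shift[[e$factor]] <- add_plateau(effect_shift[[e$factor]],
                                                  w[1], w[2], s, tw, np)
        }
        if (e$region %in% c("body", "promoter_to_body")) {
          s <- if (e$region == "promoter_to_body") abs(shift) else shift
          if (body[2] > body[1]) {
            effect_shift[[e$factor]] <- add_plateau(effect_shift[[e$factor]],
                                                    body[1], body[2], s, tw, np)
          }
        }
      }
      effects_truth <- bind_rows(effects_truth, tibble(
        gene_id = genes$gene_id[aff], factor = e$factor, region = e$region,
        sign = if (e$region == "promoter_to_body") NA_real_
               else if (e$direction == "down") -1 else 1))
    }
  }

  # probe grid (optionally with masked probes), tracks ------------------
  keep <- rep(TRUE, np)
  if (config$missing_probe_rate > 0) {
    keep <- runif(np) >= config$missing_probe_rate
  }
  tracks <- list()
  for (f in config$factors) {
    ctrl <- means[[f]] + rnorm(np, 0, config$noise_sd)
    tracks[[f]] <- list(control = probe_track(tibble(
      chrom = config$chrom, start = probe_start[keep],
      score = ctrl[keep]), tw))
    if (!is.null(effect_shift[[f]])) {
      depl <- means[[f]] + effect_shift[[f]] + rnorm(np, 0, config$noise_sd)
      tracks[[f]]$depleted <- probe_track(tibble(
        chrom = config$chrom, start = probe_start[keep],
        score = depl[keep]), tw)
    }
  }

  # state-correlated expression ----------------------------------------
  expr_mu <- c(silenced = 2, other = 4, restrained = 6, active = 8)
  expr_sd <- c(silenced = 1, other = 1.5, restrained = 1, active = 1.5)
  expression <- tibble(gene_id = genes$gene_id,
                       expression = rnorm(n, expr_mu[states], expr_sd[states]))

  truth <- bind_cols(tibble(gene_id = genes$gene_id, state = states),
                     as_tibble(bound, .name_repair = \(x) paste0("bound_", x)))

  list(tracks = tracks, genes = genes, expression = expression,
       pres = select(pres, any_of(c("chrom", "start", "end", "gene_id"))),
       truth = truth, effects_truth = effects_truth, config = config)
}

#' Simulate a pure-noise control/depleted track pair
#'
#' Two tracks on a shared regular grid whose scores are independent
#' `N(mean, noise_sd)` draws, so their difference is a pure null delta
#' with SD `noise_sd * sqrt(2)`.
#'
#' @param n_probes Number of probes.
#' @param noise_sd Per-track noise SD (default 0.8).
#' @param tile_width Tile width in bp (default 35).
#' @param mean Mean score (default 0).
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return A list with `control` and `depleted` [probe_track()]s.
#' @export
simulate_track_pair <- function(n_probes, noise_sd = 0.8, tile_width = 35,
                                mean = 0, chrom = "chr2L", seed = 1) {
  with_seed(as.integer(seed), {
    start <- (seq_len(n_probes) - 1) * tile_width
    list(
      control = probe_track(tibble(
        chrom = chrom, start = start,
        score = rnorm(n_probes, mean, noise_sd)), tile_width),
      depleted = probe_track(tibble(
        chrom = chrom, start = start,
        score = rnorm(n_probes, mean, noise_sd)), tile_width)
    )
  })
}

#' Simulate a 3C qPCR quantity table
#'
#' Reaction quantities are `true_I * bac_quantity * lognormal noise` with
#' the requested coefficient of variation (mean-one noise; `cv = 0` gives
#' exact recovery). Deterministic given the seed.
#'
#' @param loops A tibble `anchor_id`, `fragment_id`, `true_I` (>= 0).
#' @param cv Coefficient of variation of replicate noise (default 0.1).
#' @param n_biological,n_reactions Biological replicates and RT-PCR
#'   reactions per replicate (defaults 2 and 2).
#' @param bac Optional tibble `anchor_id`, `fragment_id`, `bac_quantity`;
#'   by default primer efficiencies are drawn uniformly in [0.5, 5].
#' @param seed Integer seed.
#' @return A list with `qpcr` (reaction-level quantities, with
#'   `biological` labels), `bac`, and `truth` (= `loops`).
#' @export
simulate_3c <- function(loops, cv = 0.1, n_biological = 2, n_reactions = 2,
                        bac = NULL, seed = 1) {
  loops <- as_tibble(loops)
  check_columns(loops, c("anchor_id", "fragment_id", "true_I"), "loops")
  if (any(loops$true_I < 0)) abort("loop strengths (true_I) must be >= 0")
  with_seed(as.integer(seed), {
    if (is.null(bac)) {
      bac <- tibble(anchor_id = loops$anchor_id,
                    fragment_id = loops$fragment_id,
                    bac_quantity = runif(nrow(loops), 0.5, 5))
    }
    reps <- tidyr::expand_grid(pair = seq_len(nrow(loops)),
                               biological = seq_len(n_biological),
                               reaction = seq_len(n_reactions))
    sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
    noise <- if (cv > 0) {
      exp(rnorm(nrow(reps), -sdlog^2 / 2, sdlog))
    } else {
      rep(1, nrow(reps))
    }
    qpcr <- tibble(
      anchor_id = loops$anchor_id[reps$pair],
      fragment_id = loops$fragment_id[reps$pair],
      biological = paste0("bio", reps$biological),
      quantity = loops$true_I[reps$pair] *
        bac$bac_quantity[match(
          paste(loops$anchor_id[reps$pair], loops$fragment_id[reps$pair]),
          paste(bac$anchor_id, bac$fragment_id))] * noise)
    list(qpcr = qpcr, bac = bac, truth = loops)
  })
}

#' Write a simulated dataset in the formats the pipeline reads
#'
#' Emits one bedGraph per factor/condition, a TSV gene annotation, a TSV
#' expression table, a BED of PREs, and TSV ground-truth tables.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return A named list of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (f in names(sim$tracks)) {
    for (cond in names(sim$tracks[[f]])) {
      p <- file.path(dir, sprintf("%s_%s.bedGraph", f, cond))
      write_track(sim$tracks[[f]][[cond]], p)
      paths[[sprintf("%s_%s", f, cond)]] <- p
    }
  }
  p <- file.path(dir, "genes.tsv")
  readr::write_tsv(sim$genes[, c("gene_id", "chrom", "strand", "tx_start",
                                 "tx_end")], p, col_names = FALSE)
  paths$genes <- p
  p <- file.path(dir, "expression.tsv")
  readr::write_tsv(sim$expression, p, col_names = FALSE)
  paths$expression <- p
  if (nrow(sim$pres) > 0) {
    p <- file.path(dir, "pres.bed")
    write_bed(sim$pres, p)
    paths$pres <- p
  }
  p <- file.path(dir, "truth.tsv")
  readr::write_tsv(sim$truth, p)
  paths$truth <- p
  if (nrow(sim$effects_truth) > 0) {
    p <- file.path(dir, "effects_truth.tsv")
    readr::write_tsv(sim$effects_truth, p)
    paths$effects_truth <- p
  }
  invisible(paths)
}
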