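#' Normalize 3C qPCR interactions against a BAC control
#'
#' Each anchor-fragment primer pair is normalized by the quantity obtained
#' from a randomly religated BAC template, which measures the pair's
#' amplification efficiency: `I = mean(quantity) / bac`. The standard
#' error is computed over all RT-PCR reaction replicates pooled
#' (`SE of quantity / bac`); the SE over biological-replicate means is
#' reported alongside when a `biological` column is present.
#'
#' @param qpcr A tibble of reaction-level quantities with columns
#'   `anchor_id`, `fragment_id`, `quantity` (>= 0, arbitrary qPCR units),
#'   optionally `biological` (biological-replicate label).
#' @param bac A tibble `anchor_id`, `fragment_id`, `bac_quantity` (> 0)
#'   with one row per primer pair.
#' @return A tibble per primer pair: `anchor_id`, `fragment_id`,
#'   `interaction` (I), `se`, `se_biological`, `n_reps`, `flag`
#'   (`"ok"` or `"single_replicate"`, where the SE is undefined).
#' @export
normalize_interactions <- function(qpcr, bac) {
  check_columns(qpcr, c("anchor_id", "fragment_id", "quantity"), "qpcr table")
  check_columns(bac, c("anchor_id", "fragment_id", "bac_quantity"), "bac table")
  if (any(qpcr$quantity < 0)) abort("qpcr quantities must be >= 0")
  if (anyDuplicated(bac[, c("anchor_id", "fragment_id")])) {
    abort("bac table: duplicate primer pair")
  }
  joined <- left_join(qpcr, bac, by = c("anchor_id", "fragment_id"))
  if (anyNA(joined$bac_quantity)) {
    miss <- joined |> filter(is.na(.data$bac_quantity)) |> slice(1)
    abort(sprintf("no BAC control quantity for pair %s/%s",
                  miss$anchor_id, miss$fragment_id))
  }
  if (any(joined$bac_quantity <= 0)) {
    abort("unusable primer pair: BAC control quantity must be > 0")
  }
  has_bio <- "biological" %in% names(qpcr)
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  joined |>
    mutate(norm = .data$quantity / .data$bac_quantity) |>
    group_by(.data$anchor_id, .data$fragment_id) |>
    summarise(
      interaction = mean(.data$norm),
      se = se(.data$norm),
      se_biological = if (has_bio) {
        se(tapply(.data$norm, .data$biological, mean))
      } else {
        NA_real_
      },
      n_reps = dplyr::n(),
      .groups = "drop") |>
    mutate(flag = ifelse(.data$n_reps < 2, "single_replicate", "ok"))
}

#' Anchor-centric 3C interaction profile
#'
#' Orders the normalized interactions of one anchor by the genomic
#' position of the fragment midpoints and annotates the anchor's own
#' fragment (self-ligation position).
#'
#' @param points Output of [normalize_interactions()] (one or more
#'   anchors).
#' @param anchor Anchor id to profile.
#' @param fragments A tibble mapping `fragment_id` to coordinates
#'   (`chrom`, `start`, `end`), e.g. EcoRI fragments from a BED file.
#' @return An `interaction_profile` tibble sorted by `midpoint`, with
#'   `self_ligation` flagging the anchor fragment.
#' @export
interaction_profile <- function(points, anchor, fragments) {
  check_columns(fragments, c("fragment_id", "chrom", "start", "end"),
                "fragments")
  pts <- filter(points, .data$anchor_id == anchor)
  if (nrow(pts) == 0) {
    return(structure(tibble(anchor_id = character(), fragment_id = character(),
                            chrom = character(), midpoint = numeric(),
                            interaction = numeric(), se = numeric(),
                            self_ligation = logical()),
                     class = c("interaction_profile", class(tibble()))))
  }
  unmapped <- setdiff(pts$fragment_id, fragments$fragment_id)
  if (length(unmapped) > 0) {
    abort(sprintf("fragment id(s) without coordinates: %s",
                  paste(unmapped, collapse = ", ")))
  }
  out <- pts |>
    left_join(select(fragments, "fragment_id", "chrom", "start", "end"),
              by = "fragment_id") |>
    mutate(midpoint = (.data$start + .data$end) / 2,
           self_ligation = .data$fragment_id == anchor) |>
    arrange(.data$midpoint) |>
    select("anchor_id", "fragment_id", "chrom", "midpoint", "interaction",
           "se", "self_ligation")
  class(out) <- unique(c("interaction_profile", class(out)))
  out
}

#' Compare 3C profiles between conditions
#'
#' Per-fragment ratio `depleted / control` of normalized interaction
#' frequencies, with the SE propagated in quadrature on the ratio scale.
#' Fragments whose ratio plus its propagated SE stays below 1 are flagged
#' `decreased`; fragments with a zero control interaction are flagged
#' `undefined`.
#'
#' @param control,depleted Profiles from [interaction_profile()] (same
#'   anchor, same fragment set).
#' @return A tibble `fragment_id`, `midpoint`, `ratio`, `ratio_se`,
#'   `decreased`, `flag`.
#' @export
compare_conditions <- function(control, depleted) {
  if (!setequal(control$fragment_id, depleted$fragment_id) ||
      nrow(control) != nrow(depleted)) {
    abort("control and depleted profiles cover different fragment sets")
  }
  joined <- inner_join(
    select(control, "fragment_id", "midpoint", i_c = "interaction", se_c = "se"),
    select(depleted, "fragment_id", i_d = "interaction", se_d = "se"),
    by = "fragment_id")
  joined |>
    mutate(
      flag = ifelse(.data$i_c == 0, "undefined", "ok"),
      ratio = ifelse(.data$flag == "ok", .data$i_d / .data$i_c, NA_real_),
      rel_c = ifelse(.data$i_c > 0, replace_na(.data$se_c, 0) / .data$i_c, NA_real_),
      rel_d = ifelse(.data$i_d > 0, replace_na(.data$se_d, 0) / .data$i_d, 0),
      ratio_se = .data$ratio * sqrt(.data$rel_c^2 + .data$rel_d^2),
      decreased = !is.na(.data$ratio) & (.data$ratio + .data$ratio_se) < 1) |>
    select("fragment_id", "midpoint", "ratio", "ratio_se", "decreased", "flag")
}
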