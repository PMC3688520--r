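---
title: "Differential tiling-array occupancy and cohesin-PcG chromatin states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential tiling-array occupancy and cohesin-PcG chromatin states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polystate)
library(dplyr)
```

# The measurement model

polystate works on probe-level tiling-array ChIP enrichment tracks. Each
probe represents a 35 bp tile, so three contiguous features span 105 bp,
and its score has MAT-score semantics: enrichment relative to an input
control, linear in the log2 IP/control ratio. Because the score scale is
log-linear, *additive* differences between conditions correspond to
fold-changes of occupancy, which is why the whole differential pipeline
works on per-probe differences rather than ratios.

Two complementary measurements of an occupancy change are implemented:

* **Integrated gene deltas** (`integrated_gene_delta()`): the scores of
  all probes contained within a region (transcription unit, promoter or
  body) are summed per condition and the control total is subtracted
  from the depleted total. This gives one signed number per gene, useful
  for ranking and for plotting against mRNA levels.
* **Delta-null interval calling** (`delta_track()`, `null_stats()`,
  `call_change_intervals()`): per-probe differences
  `delta = depleted - control` form a genome-wide distribution whose
  median m and standard deviation s define an empirical null. Maximal
  runs of at least `min_run = 3` contiguous probes with
  `delta >= m + 2s` (increases) or `delta <= m - 2s` (decreases),
  spanning at least `min_span = 105` bp, are emitted as signed
  intervals. Intersecting those intervals with gene annotations yields
  per-gene UP/DOWN calls.

The same run-length machinery, with a plain score threshold `tau` in
place of the delta thresholds, produces binding calls
(`call_bound_intervals()`). `tau` deliberately has no default: it stands
in for a p-value cutoff of an upstream peak-calling model and must be
calibrated per dataset (for the synthetic data in this package, `tau = 2`
sits 2.5 per-track noise SDs above background; for real tracks one would
calibrate `tau` so that the genome-wide called-gene count matches
deposited reference calls).

Pol II behaviour is summarised by two ratios. The **pause index** of a
gene is the median Pol II score in a 400 bp window centred on the TSS
divided by the median in the rest of the transcription unit; promoter-
proximal pausing gives values well above 1, and a global decrease after
a depletion indicates that polymerase is released into the body without
the usual promoter dwell. The **elongation ratio** is the median
Ser2-phosphorylated Pol II score divided by the median total Pol II
(Rpb3) score over shared probes in the gene body; it drops when
polymerase enters the body under-phosphorylated.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `tile_width` | 35 | bp | array tile; 3 tiles = 105 bp |
| `k_sd` | 2 | null SDs | change-call threshold |
| `min_run` | 3 | probes | shortest believable signal |
| `min_span` | 105 | bp | 3 x 35 bp restated; both enforced |
| `max_gap` / `merge_gap` | one tile | bp | tolerate one masked probe |
| change promoter window | 200 | bp | region classification |
| pause-index window | 400 | bp | pausing statistic |
| `restrained_min_overlap` | 2000 | bp | "several kb" operationalized |
| `pre_slack` | 100 | bp | tile-quantized call overhang |
| `noise_sd` (generator) | 0.8 | score units | typical per-track noise |

Notes on the less obvious ones:

* **Two promoter widths.** Region classification of changes uses a
  200 bp window; the pause index uses 400 bp. Both conventions are in
  routine use for these two purposes, so both are exposed rather than
  unified.
* **Medians by default.** The pause index and elongation ratio use
  medians of probe scores, which are robust to single hot probes; a
  summed score-per-bp variant is available via `stat = "density"` in
  `pause_index()`.
* **Contiguity.** A probe *below* threshold always breaks a run --
  every probe inside an emitted interval satisfies the calling
  condition -- but a *missing* grid position (masked probe) up to one
  tile wide does not. Stricter behaviour: `merge_gap = 0` /
  `max_gap = tile_width`.
* **Ambiguity resolution.** A gene region overlapped by both increase
  and decrease intervals is AMBIGUOUS. Instead of manual inspection, an
  automatic, auditable rule resolves it: the sign with the larger summed
  `|mean delta| * span` weight wins; exact ties stay unresolved and are
  counted in neither UP nor DOWN. The AMBIGUOUS flag is always retained
  in the output so resolved calls can be audited.
* **Null SD.** `null_stats()` uses the sample (n-1) standard deviation
  with no outlier trimming; at genome scale the estimator choice is
  negligible, and trimming would silently change the threshold. A
  diagnostic warns when `|median| > 0.25 * sd`, the practical limit
  beyond which the "null centred near zero" assumption is doubtful.
  Real delta distributions contain true effects, which inflate the SD
  slightly and make the caller conservative; that bias is inherent to
  the empirical-null design.
* **Strand.** ChIP signal is unstranded, so interval/gene intersection
  ignores strand; strand only enters via the TSS (promoter placement).

# The chromatin-state classifier

Genes are assigned exactly one of four cohesin-Polycomb states, in
decision order (`classify_states()`):

1. **RESTRAINED** -- cohesin and H3K27me3 both bound, and their called
   intervals overlap by at least 2 kb within the transcription unit.
   The 2 kb default makes "large overlapping domains of several
   kilobases" concrete while staying conservative; it is a config key,
   and raising it can only shrink the restrained set (tested).
2. **SILENCED** -- H3K27me3 and Pc bound, expression below the cohort
   median, and cohesin absent from the transcription unit *outside*
   annotated PREs. Binding-call boundaries are tile-quantized, so up to
   `pre_slack = 100` bp (about three tiles) of called-cohesin overhang
   beyond a PRE is not treated as binding outside it. Without a PRE
   annotation the rule degrades to "cohesin not bound at gene level" and
   the output flags `pre_fallback`.
3. **ACTIVE** -- cohesin and Pc bound, H3K27me3 absent.
4. **OTHER** -- everything else.

Whether RESTRAINED should additionally require Pc binding is left open
by the source material; it is not required here (the evidence columns
record Pc anyway, so the stricter rule is a one-line filter).

The "active gene" denominator used by percentage tables is likewise not
uniquely determined; `active_genes()` exposes the predicate (default:
not H3K27me3-bound AND (Pol II-bound OR expression at/above the cohort
median)) so analyses can tighten or relax it.

# 3C normalization

For each anchor-fragment primer pair, qPCR quantities from a randomly
religated BAC template measure amplification efficiency. The normalized
interaction frequency is `I = mean(quantity) / bac`, which cancels any
per-pair efficiency factor exactly (a tested invariance). The standard
error is taken over all RT-PCR reaction replicates pooled, matching how
such error bars are usually reported; the SE over biological-replicate
means is returned alongside, since the pooled SE understates
between-culture variability. Condition ratios propagate SEs in
quadrature, and a loop is only flagged "decreased" when
`ratio + SE < 1`. No distance-decay background model is fitted; profiles
are presented as raw BAC-normalized frequencies.

# What the generator emulates -- and what it does not

`simulate_dataset()` builds a single-chromosome genome with lognormal
gene lengths (median 3 kb, floored at 500 bp; restrained genes at least
5 kb so a multi-kb overlap is even possible) and lognormal intergenic
gaps (median 1.5 kb, floored at 1.1 kb so that a broad domain's 500 bp
flank can never reach a neighbouring transcription unit -- ground truth
stays consistent with the emitted tracks by construction). Factor
architectures are Gaussian promoter peaks (SD 150 bp) for cohesin and
Pol II, transcription-unit plateaus for body-bound factors, broad
domains (transcription unit plus 500 bp flanks) for H3K27me3, and a
narrow PRE peak (SD 60 bp) for cohesin at silenced genes. Expression is
drawn per state (silenced 2, other 4, restrained 6, active 8 log2 units,
SD 1-1.5), mirroring the ordering these states show in real data.

Per-probe noise is iid normal with `noise_sd = 0.8` score units per
track -- the middle of the 0.6-1 range typical for such data -- so a
condition difference has null SD `0.8 * sqrt(2) ~ 1.13`. Depletion
effects are additive shifts in units of `noise_sd` over a designated
region (promoter, body, whole unit, or a promoter-to-body
redistribution) applied to an exact-count fraction of eligible genes.
Where a study condition is stated as a shift of "3 SDs" of the *delta*
distribution, that corresponds to `effect_size = 3 * sqrt(2)` in these
per-track units.

The generator does **not** emulate: probe-sequence affinity effects
(assumed removed upstream by within-array normalization), spatially
correlated noise, replicate-level variation (tracks model
replicate-averaged scores), copy-number or mappability artifacts, mixed
cell populations, or annotation errors. Passing tests therefore show
that the algorithms are correct under the model's assumptions -- they do
not show robustness to the violations real arrays exhibit, of which
correlated noise (which widens the effective null) is the most
consequential.

Determinism: all randomness flows from one seed via `withr::with_seed`,
so identical configurations give bit-identical datasets and the pipeline
itself is free of randomness (re-runs are byte-identical).

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; GFF3 (1-based closed) is
  converted on read, BED is native. A single validation utility
  (`validate_intervals()`) enforces the contract.
* Duplicate probe positions are an error, never averaged -- averaging
  would shrink the delta null and inflate call rates silently.
* A region with no shared probes yields a `no_data` flag, distinct from
  a true zero; a non-positive body median yields `undefined` rather than
  a negative or infinite ratio.
* An all-equal delta vector is a degenerate null (error), since the
  thresholds would collapse onto the median.
* Empty groups in percentage tables are flagged, not reported as 0%.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to make the statistical checks sharp while staying
quick on a laptop: 200 random tracks of up to 1,000 probes for the
oracle-equivalence checks, 100,000 probes (one pass plus 50 Monte-Carlo
replicates) for null calibration, 2,000 genes for effect recovery,
1,200 for the pause-index shift, and 1,000 for state recovery. The
recovery margins at these sizes are wide (sign accuracy ~99.7%, category
percentage within 0.1 points of truth, state accuracy >99.5%), so the
conclusions do not hinge on the exact sizes.

# Worked micro-example

```{r example}
eff <- tibble::tibble(factor = "Pc", region = "body",
                      category = "cohesin_active", fraction = 0.3,
                      effect_size = 3 * sqrt(2), direction = "down")
sim <- simulate_dataset(sim_config(n_genes = 300, effects = eff), seed = 1)

d <- delta_track(sim$tracks$Pc$control, sim$tracks$Pc$depleted)
ns <- null_stats(d)
ns
calls <- call_change_intervals(d, ns)
glance(calls)

classes <- classify_gene_changes(calls, sim$genes)
table(classes$class[classes$region == "body"])
```

# Known limitations

* `tau` calibration against real deposited binding calls is the user's
  responsibility; the package provides the machinery, not the cutoff.
* The empirical null conflates noise with genuine effects; datasets
  where a large fraction of the genome changes will be called
  conservatively (the diagnostic warning flags the worst cases).
* Gene-level classification counts any overlap of at least 1 bp; very
  long intervals can tag neighbouring genes.
* The 3C module targets anchor-profile qPCR designs, not genome-wide
  contact matrices.
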