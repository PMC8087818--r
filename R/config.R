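#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults follow the published analysis of the amplicon study this package
#' models: boundary variants need support from more than 5\% of
#' exon-containing reads; exon states are split at 10\% (variable vs rare)
#' and 90\% ("nearly all" reads, stable); isoforms are tiered at 20
#' supporting reads (high confidence) and 3 reads (minimum evidence).
#'
#' @param variant_frac Fraction of exon-containing reads a non-representative
#'   boundary pair must strictly exceed to be admitted as a variant.
#' @param variable_frac Exon frequency above which an exon is "variable"
#'   rather than "rare".
#' @param rare_min_frac Minimum exon frequency kept in the catalog; exons
#'   below it are dropped.
#' @param stable_frac Exon frequency above which an exon is "stable".
#' @param high_conf_reads Total read count from which an isoform is
#'   high-confidence.
#' @param min_evidence_reads Total read count from which an isoform has
#'   minimum evidence.
#' @param primer_intervals Optional list of two `c(start, end)` 0-based
#'   half-open genomic intervals (first and last amplified exons); alignments
#'   must overlap both to pass [primer_filter()].
#' @param anchor_k K-mer size of the built-in spliced aligner.
#' @param intron_min_gap Genomic gap (bp) between chained anchors, in excess
#'   of the read gap, at which an intron is opened.
#' @param min_anchor_cov Minimum fraction of read bases covered by chained
#'   anchors for an alignment to be reported.
#' @param band_frac Band width of the banded edit-distance alignments, as a
#'   fraction of the longer sequence.
#' @param max_correct_event Largest indel (bp) that consensus correction is
#'   allowed to overwrite in a read; longer indels are treated as structural
#'   (true exon differences) and preserved.
#' @param match_tolerance Boundary tolerance (bp) for isoform matching;
#'   0 means base-pair exact.
#' @param error_rates Named numeric vector `c(sub=, ins=, del=)` of per-base
#'   error probabilities used by the simulator.
#' @param outer_boundaries Optional `c(start, end)`: model-based outer
#'   boundaries clamped onto the first representative's start and the last
#'   representative's end (the primer-design convention).
#' @param seed Integer seed used by [run_pipeline()].
#'
#' @return An object of class `pipeline_config` (a validated list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$variant_frac
#' @export
pipeline_config <- function(variant_frac = 0.05,
                            variable_frac = 0.10,
                            rare_min_frac = 1e-4,
                            stable_frac = 0.90,
                            high_conf_reads = 20L,
                            min_evidence_reads = 3L,
                            primer_intervals = NULL,
                            anchor_k = 12L,
                            intron_min_gap = 30L,
                            min_anchor_cov = 0.25,
                            band_frac = 0.12,
                            max_correct_event = 10L,
                            match_tolerance = 0L,
                            error_rates = c(sub = 0.04, ins = 0.03, del = 0.03),
                            outer_boundaries = NULL,
                            seed = 1L) {
  cfg <- list(
    variant_frac = variant_frac, variable_frac = variable_frac,
    rare_min_frac = rare_min_frac, stable_frac = stable_frac,
    high_conf_reads = as.integer(high_conf_reads),
    min_evidence_reads = as.integer(min_evidence_reads),
    primer_intervals = primer_intervals,
    anchor_k = as.integer(anchor_k),
    intron_min_gap = as.integer(intron_min_gap),
    min_anchor_cov = min_anchor_cov,
    band_frac = band_frac,
    max_correct_event = as.integer(max_correct_event),
    match_tolerance = as.integer(match_tolerance),
    error_rates = error_rates,
    outer_boundaries = outer_boundaries,
    seed = as.integer(seed)
  )
  stopifnot(
    "thresholds must satisfy 0 < rare_min_frac < variable_frac < stable_frac < 1" =
      0 < rare_min_frac && rare_min_frac < variable_frac &&
      variable_frac < stable_frac && stable_frac < 1,
    "high_conf_reads >= min_evidence_reads >= 1 required" =
      cfg$high_conf_reads >= cfg$min_evidence_reads &&
      cfg$min_evidence_reads >= 1L,
    variant_frac > 0, variant_frac < 1,
    anchor_k >= 4L, band_frac > 0,
    all(c("sub", "ins", "del") %in% names(error_rates)),
    all(error_rates >= 0), all(error_rates < 1)
  )
  if (!is.null(primer_intervals)) {
    stopifnot(length(primer_intervals) == 2L,
              all(vapply(primer_intervals, length, 1L) == 2L))
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  variant_frac=%g  exon states: rare [%g, %g], variable (%g, %g], stable (%g, 1]\n",
              x$variant_frac, x$rare_min_frac, x$variable_frac,
              x$variable_frac, x$stable_frac, x$stable_frac))
  cat(sprintf("  isoform tiers: high-confidence >= %d reads, minimum evidence >= %d\n",
              x$high_conf_reads, x$min_evidence_reads))
  cat(sprintf("  aligner: k=%d, intron gap >= %d bp, anchor coverage >= %g\n",
              x$anchor_k, x$intron_min_gap, x$min_anchor_cov))
  invisible(x)
}
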