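#' @title End-to-end pipeline
#' @description Ties the stages together: two-round grouped correction,
#'   final spliced alignment of the corrected reads, primer filtering,
#'   exon-catalog construction, exact-match isoform calling and reporting.
#'   A run manifest records the configuration and the read-count funnel
#'   (input >= aligned >= corrected >= primer-filtered >= exact-matched).
#' @name pipeline
NULL

#' Run the complete isoform-discovery pipeline
#'
#' @param reads Tibble of reads (`read_id`, `sequence`, optionally
#'   `sample_id`), e.g. from [read_fastq()] or a `sim_dataset`'s `$reads`.
#' @param reference Named character scalar: the locus sequence.
#' @param config [pipeline_config()].
#' @param alignments Optional imported external alignments of the raw reads;
#'   when supplied the built-in aligner is bypassed for round 1.
#' @param annotation Optional annotated exon tibble ([read_annotation()]).
#' @param out_dir Optional directory; when set, all reports are written
#'   there via [write_reports()].
#' @return An `isoscope_run`: list with `catalog`, `isoforms`, `junctions`,
#'   `cumulative`, `matches`, `correction`, `alignments` (final,
#'   primer-filtered) and `manifest`.
#' @export
run_pipeline <- function(reads, reference, config = pipeline_config(),
                         alignments = NULL, annotation = NULL,
                         out_dir = NULL) {
  t0 <- Sys.time()
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  corr <- stage("correct",
                run_grouped_correction(reads, reference, config, alignments))
  aln <- stage("align-corrected",
               align_reads(corr$corrected, reference, config))
  n_aligned_corrected <- nrow(aln)
  filtered <- if (!is.null(config$primer_intervals)) {
    stage("primer-filter", primer_filter(aln, config$primer_intervals))
  } else aln
  cfg_nofilter <- config
  cfg_nofilter$primer_intervals <- NULL # already applied
  catalog <- stage("call-exons", call_exons(filtered, cfg_nofilter, annotation))
  matches <- stage("call-isoforms", match_all(filtered, catalog, config))
  records <- stage("call-isoforms", count_isoforms(matches, config))
  junctions <- stage("report", junction_frequencies(matches))
  cumulative <- if (nrow(records) > 0L) cumulative_coverage(records) else NULL
  manifest <- list(
    config = unclass(config),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    funnel = list(
      input = nrow(reads),
      aligned = corr$stats$n_aligned,
      corrected = corr$stats$n_corrected,
      primer_filtered = nrow(filtered),
      exact_matched = nrow(matches)
    )
  )
  f <- unlist(manifest$funnel)
  stopifnot("stage funnel must be non-increasing" = all(diff(f) <= 0))
  out <- structure(list(catalog = catalog, isoforms = records,
                        junctions = junctions, cumulative = cumulative,
                        matches = matches, correction = corr,
                        alignments = filtered, manifest = manifest),
                   class = "isoscope_run")
  if (!is.null(out_dir)) write_reports(out, out_dir)
  out
}

#' Write pipeline reports as TSV/JSON
#'
#' Writes the exon table (representative boundaries with length, symmetry,
#' frequency, state, annotation), the boundary-variant table (parent,
#' pattern, length change, symmetry), the isoform matrix (per-sample counts,
#' total, rank, tier), the junction table, corrected reads as FASTQ and the
#' run manifest as JSON.
#'
#' @param run An `isoscope_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_reports <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(run$catalog$representatives, "exons.tsv")
  tsv(run$catalog$variants[, c("variant_id", "parent", "start", "end",
                               "pattern", "length_change",
                               "change_symmetric", "support_frac",
                               "shares_boundary")], "exon_variants.tsv")
  tsv(run$isoforms, "isoforms.tsv")
  tsv(run$junctions, "junctions.tsv")
  write_fastq(run$correction$corrected, file.path(out_dir, "corrected.fastq"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.isoscope_run <- function(x, ...) {
  f <- x$manifest$funnel
  cat("<isoscope_run>\n")
  cat(sprintf("  reads: %d input -> %d aligned -> %d corrected -> %d primer-filtered -> %d exact-matched\n",
              f$input, f$aligned, f$corrected, f$primer_filtered,
              f$exact_matched))
  cat(sprintf("  catalog: %d representative exon(s), %d variant(s); %d isoform(s)\n",
              nrow(x$catalog$representatives), nrow(x$catalog$variants),
              nrow(x$isoforms)))
  invisible(x)
}
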