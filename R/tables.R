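#' @title Published amplicon exon catalog (TACC2 intronic promoter)
#' @description The representative exon boundaries and boundary variants
#'   reported for the long-read amplicon survey of the TACC2
#'   intronic-promoter (p10) locus on human chromosome 10 (GRCh37), shipped
#'   as plain-text tables. They serve as worked examples and as a fixed
#'   validation input: the package's symmetry, pattern and classification
#'   operations must reproduce every derived column of these tables from
#'   the printed coordinates alone.
#' @name published_tables
NULL

#' Representative exon boundaries of the TACC2 p10 amplicon
#'
#' 29 representative exon regions (`rex01`..`rex29`) with 0-based half-open
#' GRCh37 chr10 coordinates, published length, reading-frame symmetry,
#' frequency state (stable/variable/rare) and annotation status.
#'
#' @return Tibble with columns `rex_id`, `label`, `start`, `end`,
#'   `length_bp`, `symmetric`, `state`, `annotation`.
#' @examples
#' ex <- tacc2_exons()
#' all(ex$length_bp == ex$end - ex$start)
#' @export
tacc2_exons <- function() {
  path <- system.file("extdata", "tacc2_rex_boundaries.tsv",
                      package = "isoscope", mustWork = TRUE)
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}

#' Boundary variants of the TACC2 p10 amplicon
#'
#' The 21 published boundary variants across 13 representative exon regions,
#' as `"L{d5}:R{d3}"` patterns with their published length change and
#' reading-frame symmetry of the change.
#'
#' @return Tibble with columns `parent`, `pattern`, `length_change`,
#'   `change_symmetric`.
#' @examples
#' v <- tacc2_exon_variants()
#' nrow(v)
#' @export
tacc2_exon_variants <- function() {
  path <- system.file("extdata", "tacc2_rex_variants.tsv",
                      package = "isoscope", mustWork = TRUE)
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}
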