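#' @title Representative exons and boundary variants
#' @description Per merged block, the most frequent aligned (start, end)
#'   boundary pair is elected as the representative exon ("rex"); alternative
#'   pairs supported by more than `variant_frac` of the block's
#'   exon-containing reads are admitted as boundary variants, described by an
#'   "L{d5}:R{d3}" pattern relative to the representative. Exons are
#'   classified by frequency (stable / variable / rare), by reading-frame
#'   symmetry (length divisible by 3), and by annotation status against
#'   known gene models.
#' @name exon_consensus
NULL

#' Keep only alignments spanning both primer target intervals
#'
#' Off-target alignments (non-specific amplification) and fragments missing
#' a primer-side exon are removed: a chain is kept iff it overlaps both
#' primer intervals by at least 1 bp.
#'
#' @param alignments Alignment tibble.
#' @param primer_intervals List of two `c(start, end)` 0-based half-open
#'   intervals (the first and last amplified exons).
#' @return Filtered alignment tibble.
#' @export
primer_filter <- function(alignments, primer_intervals) {
  stopifnot(length(primer_intervals) == 2L)
  if (nrow(alignments) == 0L) return(alignments)
  hits_one <- function(iv) {
    vapply(alignments$exons, function(ex) {
      any(ex[, 1L] < iv[2L] & ex[, 2L] > iv[1L])
    }, logical(1))
  }
  keep <- hits_one(primer_intervals[[1L]]) & hits_one(primer_intervals[[2L]])
  alignments[keep, , drop = FALSE]
}

# exon occurrences across alignments, annotated with their block
exon_occurrences <- function(alignments, blocks) {
  nex <- vapply(alignments$exons, nrow, 1L)
  ex <- do.call(rbind, alignments$exons)
  owner <- rep(seq_len(nrow(alignments)), nex)
  q <- IRanges::IRanges(ex[, 1L] + 1L, ex[, 2L])
  s <- IRanges::IRanges(blocks$start + 1L, blocks$end)
  hits <- IRanges::findOverlaps(q, s, select = "first")
  tibble::tibble(read_idx = owner, start = ex[, 1L], end = ex[, 2L],
                 block_id = blocks$block_id[hits])
}

#' Elect representative exon boundaries
#'
#' For every merged block, the (start, end) pair observed in the most reads
#' becomes the representative; ties break toward the smaller start, then the
#' smaller end. Representatives are named `rex01`, `rex02`, ... in genomic
#' order. When `config$outer_boundaries` is set, the first representative's
#' start and the last representative's end are clamped to those model-derived
#' coordinates (the primer-design convention for the outermost boundaries).
#'
#' @param alignments Corrected, primer-filtered alignment tibble.
#' @param config [pipeline_config()].
#' @param blocks Optional precomputed block tibble.
#' @return An `exon_catalog`: list with `representatives`, `variants`
#'   (empty here; see [detect_variants()]) and `blocks`.
#' @export
elect_representatives <- function(alignments, config = pipeline_config(),
                                  blocks = NULL) {
  stopifnot(nrow(alignments) >= 1L)
  blocks <- blocks %||% merge_exon_blocks(alignments)
  occ <- exon_occurrences(alignments, blocks)
  reps <- lapply(split(occ, occ$block_id), function(b) {
    cnt <- stats::aggregate(read_idx ~ start + end, data = b,
                            FUN = function(x) length(unique(x)))
    cnt <- cnt[order(-cnt$read_idx, cnt$start, cnt$end), , drop = FALSE]
    tibble::tibble(block_id = b$block_id[1L], start = cnt$start[1L],
                   end = cnt$end[1L], n_reads = cnt$read_idx[1L])
  })
  reps <- do.call(rbind, reps)
  reps <- reps[order(reps$start), , drop = FALSE]
  if (!is.null(config$outer_boundaries)) {
    reps$start[1L] <- as.integer(config$outer_boundaries[1L])
    reps$end[nrow(reps)] <- as.integer(config$outer_boundaries[2L])
  }
  representatives <- tibble::tibble(
    rex_id = sprintf("rex%02d", seq_len(nrow(reps))),
    block_id = reps$block_id,
    chrom = alignments$chrom[1L],
    start = as.integer(reps$start),
    end = as.integer(reps$end),
    length = as.integer(reps$end - reps$start),
    symmetric = is_symmetric(reps$end - reps$start),
    frequency = NA_real_,
    state = NA_character_,
    annotation = NA_character_
  )
  structure(list(representatives = representatives,
                 variants = empty_variants(),
                 blocks = blocks),
            class = "exon_catalog")
}

empty_variants <- function() {
  tibble::tibble(variant_id = character(), parent = character(),
                 chrom = character(), start = integer(), end = integer(),
                 pattern = character(), length_change = integer(),
                 change_symmetric = logical(), support_frac = numeric(),
                 n_reads = integer(), shares_boundary = logical())
}

#' Admit boundary variants above the support threshold
#'
#' Every non-representative (start, end) pair in a block whose read support
#' strictly exceeds `variant_frac` of the block's exon-containing reads
#' becomes a variant of that block's representative. Sharing a boundary with
#' the representative is recorded (`shares_boundary`) but not required. The
#' variant's `change_symmetric` flag states whether the length change is a
#' multiple of 3, i.e. whether choosing the variant over the representative
#' preserves the downstream reading frame.
#'
#' @param alignments Corrected, primer-filtered alignment tibble (same set
#'   used for election).
#' @param catalog Catalog from [elect_representatives()].
#' @param config [pipeline_config()].
#' @return The catalog with `variants` filled, ordered by block then support.
#' @export
detect_variants <- function(alignments, catalog, config = pipeline_config()) {
  reps <- catalog$representatives
  occ <- exon_occurrences(alignments, catalog$blocks)
  rows <- list()
  for (i in seq_len(nrow(reps))) {
    b <- occ[occ$block_id == reps$block_id[i] & !is.na(occ$block_id), ,
             drop = FALSE]
    denom <- length(unique(b$read_idx))
    if (denom == 0L) next
    cnt <- stats::aggregate(read_idx ~ start + end, data = b,
                            FUN = function(x) length(unique(x)))
    alt <- cnt[!(cnt$start == reps$start[i] & cnt$end == reps$end[i]), ,
               drop = FALSE]
    alt <- alt[alt$read_idx > config$variant_frac * denom, , drop = FALSE]
    if (nrow(alt) == 0L) next
    alt <- alt[order(-alt$read_idx, alt$start, alt$end), , drop = FALSE]
    pat <- pattern_string(cbind(alt$start, alt$end),
                          c(reps$start[i], reps$end[i]))
    dl <- (alt$end - alt$start) - reps$length[i]
    rows[[reps$rex_id[i]]] <- tibble::tibble(
      variant_id = sprintf("%s.v%d", reps$rex_id[i], seq_len(nrow(alt))),
      parent = reps$rex_id[i],
      chrom = reps$chrom[i],
      start = as.integer(alt$start), end = as.integer(alt$end),
      pattern = pat,
      length_change = as.integer(dl),
      change_symmetric = abs(dl) %% 3L == 0L,
      support_frac = alt$read_idx / denom,
      n_reads = as.integer(alt$read_idx),
      shares_boundary = alt$start == reps$start[i] | alt$end == reps$end[i]
    )
  }
  catalog$variants <- if (length(rows)) do.call(rbind, unname(rows)) else
    empty_variants()
  catalog
}

#' Boundary-variant pattern string
#'
#' Encodes a variant's boundaries relative to its representative as
#' `"L{d5}:R{d3}"`: `L` is the change at the 5' (genomic start) end and `R`
#' at the 3' (genomic end) end; positive values extend the exon and negative
#' values truncate it. So `d5 = rep_start - var_start` and
#' `d3 = var_end - rep_end`.
#'
#' @param variant_interval `c(start, end)` or a 2-column matrix of variants.
#' @param representative_interval `c(start, end)` of the representative.
#' @return Character vector of pattern strings.
#' @examples
#' pattern_string(c(123846573, 123847474), c(123842161, 123847474))
#' @export
pattern_string <- function(variant_interval, representative_interval) {
  v <- matrix(as.numeric(variant_interval), ncol = 2L)
  r <- as.numeric(representative_interval)
  d5 <- r[1L] - v[, 1L]
  d3 <- v[, 2L] - r[2L]
  sprintf("L%d:R%d", as.integer(d5), as.integer(d3))
}

#' Parse a pattern string back into boundary deltas
#'
#' @param pattern Pattern string(s) like `"L0:R-2445"`.
#' @return Matrix with columns `d5`, `d3`.
#' @export
parse_pattern <- function(pattern) {
  m <- regmatches(pattern,
                  regexec("^L(-?[0-9]+):R(-?[0-9]+)$", pattern))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed pattern string: ", pattern[bad][1L])
  cbind(d5 = vapply(m, function(x) as.integer(x[2L]), 1L),
        d3 = vapply(m, function(x) as.integer(x[3L]), 1L))
}

#' Apply a pattern to representative boundaries
#'
#' @param pattern Pattern string(s).
#' @param start,end Representative boundaries (0-based half-open).
#' @return Matrix with columns `start`, `end` of the variant interval(s).
#' @export
apply_pattern <- function(pattern, start, end) {
  d <- parse_pattern(pattern)
  cbind(start = as.integer(start - d[, "d5"]),
        end = as.integer(end + d[, "d3"]))
}

#' Reading-frame symmetry of an exon length
#'
#' An exon is symmetric when its length is a multiple of 3, so skipping or
#' including it leaves the downstream reading frame unchanged.
#'
#' @param length Exon length(s) in bp, non-negative.
#' @return Logical vector.
#' @examples
#' is_symmetric(c(78, 61, 0))
#' @export
is_symmetric <- function(length) {
  if (any(length < 0)) stop("exon length must be non-negative")
  as.integer(length) %% 3L == 0L
}

#' Classify exon state from its read frequency
#'
#' Stable exons are present in nearly all reads (`> stable_frac`); variable
#' exons in more than `variable_frac`; rare exons in at least
#' `rare_min_frac`. Frequencies below `rare_min_frac` return `NA`: such
#' exons are excluded from the catalog.
#'
#' @param frequency Fraction(s) in \[0, 1\].
#' @param config [pipeline_config()].
#' @return Character vector: `"stable"`, `"variable"`, `"rare"` or `NA`.
#' @export
classify_exon_state <- function(frequency, config = pipeline_config()) {
  stopifnot(all(frequency >= 0 & frequency <= 1, na.rm = TRUE))
  out <- rep(NA_character_, length(frequency))
  out[frequency >= config$rare_min_frac] <- "rare"
  out[frequency > config$variable_frac] <- "variable"
  out[frequency > config$stable_frac] <- "stable"
  out
}

#' Annotate catalog exons against known gene models
#'
#' `known`: both boundaries match an annotated exon exactly;
#' `partially_known`: overlaps an annotated exon by >= 1 bp but is not
#' boundary-exact; `novel`: overlaps nothing. With `models = NULL` every
#' exon is reported as `unannotated`.
#'
#' @param catalog An `exon_catalog`.
#' @param models Tibble of annotated exons (`chrom`, `start`, `end`; 0-based
#'   half-open), e.g. from [read_annotation()], or `NULL`.
#' @return The catalog with the `annotation` column filled.
#' @export
annotate_exons <- function(catalog, models = NULL) {
  reps <- catalog$representatives
  if (is.null(models) || nrow(models) == 0L) {
    catalog$representatives$annotation <- "unannotated"
    return(catalog)
  }
  ann <- vapply(seq_len(nrow(reps)), function(i) {
    same <- models$chrom == reps$chrom[i]
    exact <- same & models$start == reps$start[i] & models$end == reps$end[i]
    if (any(exact)) return("known")
    overlap <- same & models$start < reps$end[i] & models$end > reps$start[i]
    if (any(overlap)) return("partially_known")
    "novel"
  }, character(1))
  catalog$representatives$annotation <- ann
  catalog
}

#' Build the full exon catalog from corrected alignments
#'
#' Orchestrates primer filtering, block merging, representative election,
#' variant admission, exact-match frequency computation and state/annotation
#' classification. Two denominators are used and logged: variant support is
#' measured against the block's exon-containing reads, while exon frequency
#' (and hence state) is measured against the reads whose whole chain exactly
#' matches the catalog.
#'
#' @param alignments Corrected alignment tibble (primary alignments).
#' @param config [pipeline_config()]; `primer_intervals`, when set, are
#'   applied first.
#' @param annotation Optional annotated exon tibble (see [read_annotation()]).
#' @return An `exon_catalog` with frequencies, states and annotation filled.
#'   Attribute `"denominators"` records both denominators per block.
#' @export
call_exons <- function(alignments, config = pipeline_config(),
                       annotation = NULL) {
  if (!is.null(config$primer_intervals)) {
    alignments <- primer_filter(alignments, config$primer_intervals)
  }
  if (nrow(alignments) == 0L) stop("no alignments left after primer filter")
  catalog <- elect_representatives(alignments, config)
  catalog <- detect_variants(alignments, catalog, config)
  matches <- match_all(alignments, catalog, config)
  n_matched <- nrow(matches)
  reps <- catalog$representatives
  freq <- vapply(seq_len(nrow(reps)), function(i) {
    ids <- c(reps$rex_id[i],
             catalog$variants$variant_id[catalog$variants$parent ==
                                           reps$rex_id[i]])
    if (n_matched == 0L) return(NA_real_)
    mean(vapply(matches$elements, function(e) any(e %in% ids), logical(1)))
  }, numeric(1))
  catalog$representatives$frequency <- freq
  catalog$representatives$state <- classify_exon_state(freq, config)
  drop <- !is.na(freq) & freq < config$rare_min_frac
  if (any(drop)) {
    kept <- catalog$representatives$rex_id[!drop]
    catalog$representatives <- catalog$representatives[!drop, , drop = FALSE]
    catalog$variants <- catalog$variants[catalog$variants$parent %in% kept, ,
                                         drop = FALSE]
  }
  catalog <- annotate_exons(catalog, annotation)
  occ <- exon_occurrences(alignments, catalog$blocks)
  denom <- stats::aggregate(read_idx ~ block_id, data = occ,
                            FUN = function(x) length(unique(x)))
  attr(catalog, "denominators") <- tibble::tibble(
    block_id = denom$block_id,
    exon_containing_reads = denom$read_idx,
    matched_reads = n_matched
  )
  catalog
}

#' @export
print.exon_catalog <- function(x, ...) {
  cat(sprintf("<exon_catalog> %d representative exon(s), %d variant(s), %d block(s)\n",
              nrow(x$representatives), nrow(x$variants), nrow(x$blocks)))
  print(x$representatives[, c("rex_id", "start", "end", "length",
                              "symmetric", "frequency", "state",
                              "annotation")])
  invisible(x)
}
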