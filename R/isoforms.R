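#' @title Exact-match isoform calling
#' @description A corrected read is counted toward an isoform only when its
#'   whole exon chain matches, base-pair exactly, a combination of catalog
#'   representatives and admitted variants across ascending blocks. Matched
#'   keys are aggregated per sample, ranked by pooled read total, and tiered
#'   by supporting evidence (>= 20 reads: high confidence; >= 3 reads:
#'   minimum evidence).
#' @name isoform_calling
NULL

# lookup table from exact (start,end) to catalog element
catalog_lookup <- function(catalog) {
  reps <- catalog$representatives
  el <- tibble::tibble(element_id = reps$rex_id, start = reps$start,
                       end = reps$end, block_id = reps$block_id)
  if (nrow(catalog$variants) > 0L) {
    v <- catalog$variants
    bl <- reps$block_id[match(v$parent, reps$rex_id)]
    el <- rbind(el, tibble::tibble(element_id = v$variant_id,
                                   start = v$start, end = v$end,
                                   block_id = bl))
  }
  el$key <- paste(el$start, el$end, sep = ":")
  el
}

#' Match one exon chain against the catalog
#'
#' @param exons 2-column exon matrix (0-based half-open).
#' @param catalog An `exon_catalog`.
#' @param config [pipeline_config()]; `match_tolerance` > 0 allows a
#'   per-boundary tolerance in bp (default 0: exact).
#' @return Character vector of catalog element ids (the isoform key), or
#'   `NULL` when any exon fails to match.
#' @export
match_isoform <- function(exons, catalog, config = pipeline_config()) {
  validate_exons(exons)
  el <- catalog_lookup(catalog)
  tol <- config$match_tolerance
  ids <- character(nrow(exons))
  blocks <- integer(nrow(exons))
  for (i in seq_len(nrow(exons))) {
    if (tol == 0L) {
      j <- match(paste(exons[i, 1L], exons[i, 2L], sep = ":"), el$key)
    } else {
      cand <- which(abs(el$start - exons[i, 1L]) <= tol &
                      abs(el$end - exons[i, 2L]) <= tol)
      j <- if (length(cand) == 0L) NA_integer_ else
        cand[which.min(abs(el$start[cand] - exons[i, 1L]) +
                         abs(el$end[cand] - exons[i, 2L]))]
    }
    if (is.na(j)) return(NULL)
    ids[i] <- el$element_id[j]
    blocks[i] <- el$block_id[j]
  }
  if (any(diff(blocks) <= 0L)) return(NULL) # one element per block, ascending
  ids
}

#' Match all alignments against the catalog
#'
#' @param alignments Corrected, primer-filtered alignment tibble.
#' @param catalog An `exon_catalog`.
#' @param config [pipeline_config()].
#' @return Tibble of matched reads: `read_id`, `sample_id`, `key`
#'   (comma-joined element ids), `elements` (list).
#' @export
match_all <- function(alignments, catalog, config = pipeline_config()) {
  el <- catalog_lookup(catalog)
  tol <- config$match_tolerance
  res <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    ex <- alignments$exons[[i]]
    if (tol == 0L) {
      j <- match(paste(ex[, 1L], ex[, 2L], sep = ":"), el$key)
      if (anyNA(j)) next
      if (nrow(ex) > 1L && any(diff(el$block_id[j]) <= 0L)) next
      res[[i]] <- el$element_id[j]
    } else {
      res[[i]] <- match_isoform(ex, catalog, config)
    }
  }
  keep <- !vapply(res, is.null, logical(1))
  tibble::tibble(
    read_id = alignments$read_id[keep],
    sample_id = (alignments[["sample_id"]] %||%
                   rep(NA_character_, nrow(alignments)))[keep],
    key = vapply(res[keep], paste, character(1), collapse = ","),
    elements = res[keep]
  )
}

#' Aggregate matched reads into ranked isoform records
#'
#' Counts are pooled across samples for ranking (ties break toward the
#' lexicographically smaller key); per-sample counts are retained as one
#' column per sample. Tiers: `high_confidence` (total >=
#' `config$high_conf_reads`), `minimum_evidence` (total >=
#' `config$min_evidence_reads`), else `singleton_zone`.
#'
#' @param matches Tibble from [match_all()].
#' @param config [pipeline_config()].
#' @return Tibble: `key`, one count column per sample, `total`, `rank`,
#'   `tier`.
#' @export
count_isoforms <- function(matches, config = pipeline_config()) {
  if (nrow(matches) == 0L) {
    return(tibble::tibble(key = character(), total = integer(),
                          rank = integer(), tier = character()))
  }
  samp <- matches$sample_id
  samp[is.na(samp)] <- "sample"
  tab <- table(matches$key, samp)
  counts <- as.data.frame.matrix(tab)
  out <- tibble::as_tibble(counts)
  names(out) <- colnames(tab)
  out$key <- rownames(tab)
  out$total <- as.integer(rowSums(counts))
  out <- out[order(-out$total, out$key), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tier <- ifelse(out$total >= config$high_conf_reads, "high_confidence",
                     ifelse(out$total >= config$min_evidence_reads,
                            "minimum_evidence", "singleton_zone"))
  out[, c("key", setdiff(names(out), c("key", "total", "rank", "tier")),
          "total", "rank", "tier")]
}

#' Exon-exon junction frequencies
#'
#' Counts adjacent catalog-element pairs across all matched reads (the arch
#' weights of a junction plot).
#'
#' @param matches Tibble from [match_all()].
#' @return Tibble: `from`, `to`, `count`, ordered by decreasing count.
#' @export
junction_frequencies <- function(matches) {
  if (nrow(matches) == 0L) {
    return(tibble::tibble(from = character(), to = character(),
                          count = integer()))
  }
  pairs <- lapply(matches$elements, function(e) {
    if (length(e) < 2L) return(NULL)
    cbind(from = e[-length(e)], to = e[-1L])
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    return(tibble::tibble(from = character(), to = character(),
                          count = integer()))
  }
  key <- paste(pairs[, "from"], pairs[, "to"], sep = "\r")
  cnt <- table(key)
  parts <- strsplit(names(cnt), "\r", fixed = TRUE)
  out <- tibble::tibble(from = vapply(parts, `[[`, "", 1L),
                        to = vapply(parts, `[[`, "", 2L),
                        count = as.integer(cnt))
  out[order(-out$count, out$from, out$to), , drop = FALSE]
}

#' Cumulative read coverage by isoform rank
#'
#' @param records Ranked tibble from [count_isoforms()].
#' @return Tibble: `rank`, `cumulative_fraction` (monotone, ending at 1).
#' @export
cumulative_coverage <- function(records) {
  stopifnot(nrow(records) >= 1L)
  ord <- records[order(records$rank), , drop = FALSE]
  tibble::tibble(rank = ord$rank,
                 cumulative_fraction = cumsum(ord$total) / sum(ord$total))
}

#' Number of isoform combinations over independently chosen variable exons
#'
#' With `n` variable exons each independently present or absent, `2^n`
#' isoform structures are possible; comparing this to the observed count
#' indicates whether exon choice is regulated.
#'
#' @param n_variable Number of variable exons (>= 0).
#' @return `2^n_variable`.
#' @examples
#' variable_combination_count(4)
#' @export
variable_combination_count <- function(n_variable) {
  stopifnot(n_variable >= 0, n_variable == as.integer(n_variable))
  2^as.integer(n_variable)
}

#' Spearman correlation of isoform counts between two samples
#'
#' Restricted to isoforms observed in at least one of the two samples
#' (zeros filled for the other); with fewer than 3 such isoforms the
#' correlation is not computable and `NA` is returned with a warning.
#'
#' @param records Tibble from [count_isoforms()].
#' @param sample_a,sample_b Sample column names.
#' @return Spearman rank correlation coefficient, or `NA`.
#' @export
replicate_correlation <- function(records, sample_a, sample_b) {
  stopifnot(sample_a %in% names(records), sample_b %in% names(records))
  a <- records[[sample_a]]
  b <- records[[sample_b]]
  keep <- a > 0 | b > 0
  if (sum(keep) < 3L) {
    warning("fewer than 3 isoforms observed in either sample; ",
            "correlation not computable")
    return(NA_real_)
  }
  stats::cor(a[keep], b[keep], method = "spearman")
}
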