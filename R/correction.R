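#' @title Grouped two-round self-correction
#' @description Error-prone reads from one amplified locus are grouped by
#'   loosely defined exon structure (the set of merged exon blocks their
#'   primary alignment touches) and corrected by within-group consensus
#'   voting against a medoid template. A second round re-derives blocks and
#'   groups from the round-1 consensi — now boundary-accurate — and
#'   re-corrects the *original raw reads* inside the refined groups, so that
#'   any bias introduced by coarse round-1 grouping does not propagate.
#' @name grouped_correction
NULL

#' Merge overlapping aligned exons into blocks
#'
#' The union of all exon intervals across alignments is partitioned into
#' maximal connected components; each component becomes one block. Blocks
#' are the units of the loose grouping signature.
#'
#' @param alignments Alignment tibble.
#' @return Tibble with columns `block_id`, `start`, `end` (0-based
#'   half-open), ascending.
#' @examples
#' aln <- isoscope:::new_alignments("r1", "locus", "+", 1,
#'   list(isoscope:::exon_matrix(c(100, 300), c(200, 400))))
#' merge_exon_blocks(aln)
#' @export
merge_exon_blocks <- function(alignments) {
  if (nrow(alignments) == 0L) stop("no alignments to merge")
  ex <- do.call(rbind, alignments$exons)
  ir <- IRanges::IRanges(start = ex[, 1L] + 1L, end = ex[, 2L])
  red <- IRanges::reduce(ir) # merges overlapping and book-ended intervals
  tibble::tibble(block_id = seq_along(red),
                 start = BiocGenerics::start(red) - 1L,
                 end = BiocGenerics::end(red))
}

#' Block signature of an exon chain
#'
#' @param exons 2-column exon matrix (0-based half-open).
#' @param blocks Block tibble from [merge_exon_blocks()].
#' @return Integer vector of block ids the chain overlaps by >= 1 bp,
#'   ascending.
#' @export
read_signature <- function(exons, blocks) {
  validate_exons(exons)
  q <- IRanges::IRanges(exons[, 1L] + 1L, exons[, 2L])
  s <- IRanges::IRanges(blocks$start + 1L, blocks$end)
  hits <- IRanges::findOverlaps(q, s)
  ids <- sort(unique(S4Vectors::subjectHits(hits)))
  if (length(ids) == 0L) stop("exon chain overlaps no block")
  blocks$block_id[ids]
}

# signatures for every alignment at once; returns character keys like "1,3,4"
signature_keys <- function(alignments, blocks) {
  if (nrow(alignments) == 0L) return(character(0))
  nex <- vapply(alignments$exons, nrow, 1L)
  ex <- do.call(rbind, alignments$exons)
  owner <- rep(seq_len(nrow(alignments)), nex)
  q <- IRanges::IRanges(ex[, 1L] + 1L, ex[, 2L])
  s <- IRanges::IRanges(blocks$start + 1L, blocks$end)
  hits <- IRanges::findOverlaps(q, s)
  per <- split(blocks$block_id[S4Vectors::subjectHits(hits)],
               owner[S4Vectors::queryHits(hits)])
  keys <- rep(NA_character_, nrow(alignments))
  keys[as.integer(names(per))] <-
    vapply(per, function(v) paste(sort(unique(v)), collapse = ","),
           character(1))
  keys
}

#' Consensus-correct one read group
#'
#' Chooses a medoid template (the member with the highest mean pairwise
#' identity; ties broken by length, then read id), aligns every member to it
#' with banded edit distance, and takes a per-template-position majority over
#' match/substitution/deletion events (insertions are voted per gap). Each
#' member's corrected sequence follows the column consensus except across its
#' own structural indels — indel runs longer than `config$max_correct_event`
#' bp — which are preserved verbatim, so reads of a minority exon structure
#' that share a group are corrected without being collapsed into the
#' majority structure. Groups of size 1 are passed through uncorrected and
#' flagged.
#'
#' @param sequences Character vector of member sequences (same orientation).
#' @param read_ids Character vector of member read ids.
#' @param config [pipeline_config()].
#' @return List with `sequences` (corrected, same order), `corrected`
#'   (logical per member), `consensus` (the group consensus sequence) and
#'   `template_id`.
#' @export
correct_group <- function(sequences, read_ids = as.character(seq_along(sequences)),
                          config = pipeline_config()) {
  n <- length(sequences)
  stopifnot(n == length(read_ids))
  if (n == 1L) {
    return(list(sequences = sequences, corrected = FALSE,
                consensus = sequences, template_id = read_ids))
  }
  med <- pick_medoid(sequences, read_ids, config)
  res <- .cpp_correct_members(sequences, sequences[med], config$band_frac,
                              32L, config$max_correct_event)
  list(sequences = as.character(res$sequences),
       corrected = as.logical(res$corrected),
       consensus = res$consensus,
       template_id = read_ids[med])
}

# medoid on a deterministic subsample (evenly spaced in read-id order) to
# keep the pairwise stage linear-ish in group size
pick_medoid <- function(sequences, read_ids, config, max_sample = 12L) {
  n <- length(sequences)
  ord <- order(read_ids)
  idx <- ord[unique(round(seq(1L, n, length.out = min(n, max_sample))))]
  d <- .cpp_pairwise_dist(sequences[idx], config$band_frac)
  len <- nchar(sequences[idx])
  maxlen <- outer(len, len, pmax)
  iden <- 1 - d / pmax(1, maxlen)
  diag(iden) <- NA
  score <- rowMeans(iden, na.rm = TRUE)
  best <- which(score == max(score))
  if (length(best) > 1L) {
    best <- best[order(-len[best], read_ids[idx][best])][1L]
  }
  idx[best]
}

#' Run the full two-round grouped correction
#'
#' Round 1 aligns the raw reads (built-in aligner, or supplied external
#' alignments), merges exon blocks, groups reads by block signature, and
#' corrects each multi-member group. Round 2 aligns the round-1 corrected
#' sequences, re-derives blocks and groups, maps every original raw read to
#' its round-2 group through its round-1 output, and re-runs consensus
#' correction on the *raw* sequences within the refined groups. Reads whose
#' round-1 output fails round-2 alignment, and reads alone in their group,
#' are excluded from the corrected output (correction is partial by design).
#'
#' @param reads Tibble with `read_id`, `sequence`, optionally `sample_id`.
#' @param reference Named character scalar (locus sequence); ignored when
#'   `alignments` is supplied for round 1.
#' @param config [pipeline_config()].
#' @param alignments Optional imported external alignments of the raw reads
#'   (round 1 only; later rounds always use the built-in aligner).
#' @return List with `corrected` (tibble: `read_id`, `sample_id`,
#'   `sequence`), `groups` (tibble: `read_id`, `round`, `signature`,
#'   `group_size`, `corrected`), and `stats` (funnel counts).
#' @export
run_grouped_correction <- function(reads, reference, config = pipeline_config(),
                                   alignments = NULL) {
  stopifnot(nrow(reads) >= 1L, !anyDuplicated(reads$read_id))
  sample_id <- reads[["sample_id"]] %||% rep(NA_character_, nrow(reads))
  names(sample_id) <- reads$read_id

  aln1 <- alignments %||% align_reads(reads, reference, config)
  aln1 <- aln1[aln1$is_primary, , drop = FALSE]
  if (nrow(aln1) == 0L) stop("no raw read aligned in round 1")
  blocks1 <- merge_exon_blocks(aln1)
  key1 <- signature_keys(aln1, blocks1)

  # orient every aligned raw read to the forward genome strand
  seqs <- stats::setNames(reads$sequence, reads$read_id)
  oriented <- seqs[aln1$read_id]
  neg <- aln1$strand == "-"
  if (any(neg)) oriented[neg] <- revcomp(oriented[neg])

  groups1 <- split(seq_len(nrow(aln1)), key1)
  r1_seq <- character(0)
  r1_ids <- character(0)
  grp_rows <- list()
  for (key in names(groups1)) {
    members <- groups1[[key]]
    ids <- aln1$read_id[members]
    res <- correct_group(unname(oriented[members]), ids, config)
    grp_rows[[key]] <- tibble::tibble(
      read_id = ids, round = 1L, signature = key,
      group_size = length(members), corrected = res$corrected
    )
    keep <- res$corrected
    r1_seq <- c(r1_seq, res$sequences[keep])
    r1_ids <- c(r1_ids, ids[keep])
  }
  r1_out <- stats::setNames(r1_seq, r1_ids)

  if (length(r1_out) == 0L) {
    return(list(
      corrected = tibble::tibble(read_id = character(),
                                 sample_id = character(),
                                 sequence = character()),
      groups = do.call(rbind, grp_rows),
      stats = list(n_input = nrow(reads), n_aligned = nrow(aln1),
                   n_corrected = 0L)
    ))
  }

  # round 2: align the distinct round-1 outputs once, then fan back out
  uniq <- !duplicated(unname(r1_out))
  utab <- tibble::tibble(read_id = names(r1_out)[uniq],
                         sequence = unname(r1_out)[uniq])
  aln2u <- align_reads(utab, reference, config)
  seq2key <- stats::setNames(rep(NA_character_, nrow(utab)), utab$sequence)
  if (nrow(aln2u) > 0L) {
    blocks2 <- merge_exon_blocks(aln2u)
    key2u <- signature_keys(aln2u, blocks2)
    seq2key[utab$sequence[match(aln2u$read_id, utab$read_id)]] <- key2u
  } else {
    blocks2 <- blocks1
  }
  key2 <- unname(seq2key[unname(r1_out)]) # per surviving raw read
  survivors <- names(r1_out)[!is.na(key2)]
  key2 <- key2[!is.na(key2)]

  final_seq <- character(0)
  final_ids <- character(0)
  groups2 <- split(survivors, key2)
  for (key in names(groups2)) {
    ids <- groups2[[key]]
    res <- correct_group(unname(oriented[ids]), ids, config)
    grp_rows[[paste0("r2_", key)]] <- tibble::tibble(
      read_id = ids, round = 2L, signature = key,
      group_size = length(ids), corrected = res$corrected
    )
    keep <- res$corrected
    final_seq <- c(final_seq, res$sequences[keep])
    final_ids <- c(final_ids, ids[keep])
  }
  ord <- order(match(final_ids, reads$read_id))
  corrected <- tibble::tibble(
    read_id = final_ids[ord],
    sample_id = unname(sample_id[final_ids[ord]]),
    sequence = final_seq[ord]
  )
  list(
    corrected = corrected,
    groups = do.call(rbind, unname(grp_rows)),
    stats = list(n_input = nrow(reads), n_aligned = nrow(aln1),
                 n_corrected = nrow(corrected))
  )
}
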