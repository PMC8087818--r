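#' @title Built-in spliced aligner
#' @description A minimal spliced aligner for single-locus amplicon work:
#'   exact k-mer anchors are chained colinearly, a genomic gap at least
#'   `intron_min_gap` bp in excess of the read gap opens an intron, junction
#'   placement within the unanchored window maximizes base matches with a
#'   bonus for canonical GT..AG intron motifs, and reads whose chained
#'   anchors cover less than `min_anchor_cov` of their length are rejected.
#'   External aligner output (SAM/PAF/BED12) imported with
#'   [import_alignments()] can be used instead; the two sources are never
#'   mixed within one run.
#' @name spliced_aligner
NULL

# motif bonus: worth slightly more than two base matches so a canonical
# GT..AG placement wins against up to two mismatching split positions
MOTIF_BONUS <- 2.5
# how far (bp) a splice boundary may be shifted toward a canonical motif
MOTIF_WINDOW <- 6L

#' Align a single read to the locus reference
#'
#' @param sequence Read sequence (character scalar).
#' @param reference Named character scalar: the amplified locus.
#' @param config [pipeline_config()].
#' @param read_id Read identifier stored in the result.
#' @return One-row alignment tibble, or `NULL` when the read does not reach
#'   the anchor-coverage threshold (e.g. off-target reads).
#' @examples
#' ref <- c(locus = strrep("ACGTTGCAAGCTTGCATGCCGCTTAAGCGT", 20))
#' aln <- align_spliced(substr(ref, 41, 160), ref, pipeline_config(seed = 1))
#' aln$exons[[1]]
#' @export
align_spliced <- function(sequence, reference, config = pipeline_config(),
                          read_id = "read") {
  reads <- tibble::tibble(read_id = read_id, sample_id = NA_character_,
                          sequence = sequence)
  out <- align_reads(reads, reference, config)
  if (nrow(out) == 0L) NULL else out
}

#' Align a batch of reads to the locus reference
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally `sample_id`.
#' @param reference Named character scalar (the locus); names supply `chrom`.
#' @param config [pipeline_config()].
#' @return Alignment tibble (unaligned reads are absent).
#' @export
align_reads <- function(reads, reference, config = pipeline_config()) {
  stopifnot(length(reference) == 1L)
  ref <- unname(reference)
  chrom <- names(reference) %||% "locus"
  if (is.na(chrom)) chrom <- "locus"
  k <- config$anchor_k
  if (nchar(ref) < k) stop("reference shorter than anchor k-mer size")
  if (nrow(reads) == 0L) return(empty_alignments())
  refchars <- strsplit(ref, "", fixed = TRUE)[[1]]
  rc <- revcomp(reads$sequence)
  sample_id <- reads[["sample_id"]] %||% rep(NA_character_, nrow(reads))
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rows[[i]] <- align_one(reads$sequence[i], rc[i], ref, refchars, config)
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) return(empty_alignments())
  rows_k <- rows[keep]
  new_alignments(
    read_id = reads$read_id[keep],
    sample_id = sample_id[keep],
    chrom = chrom,
    strand = vapply(rows_k, `[[`, "", "strand"),
    identity = vapply(rows_k, `[[`, 0, "identity"),
    exons = lapply(rows_k, `[[`, "exons")
  )
}

align_one <- function(seq_fwd, seq_rc, ref, refchars, config) {
  k <- config$anchor_k
  n <- nchar(seq_fwd)
  if (n < k) return(NULL)
  cf <- .cpp_chain_anchors(seq_fwd, ref, k, 8L, config$intron_min_gap)
  cr <- .cpp_chain_anchors(seq_rc, ref, k, 8L, config$intron_min_gap)
  if (cf$score >= cr$score) {
    chain <- cf; oriented <- seq_fwd; strand <- "+"
  } else {
    chain <- cr; oriented <- seq_rc; strand <- "-"
  }
  if (chain$coverage < config$min_anchor_cov * n) return(NULL)
  anchors <- chain$anchors
  if (nrow(anchors) == 0L) return(NULL)
  oc <- strsplit(oriented, "", fixed = TRUE)[[1]]
  exons <- place_exons(anchors, oc, refchars, k, config$intron_min_gap,
                       nchar(ref))
  if (is.null(exons)) return(NULL)
  spliced <- paste(substring(ref, exons[, 1L] + 1L, exons[, 2L]),
                   collapse = "")
  d <- .cpp_edit_distance(oriented, spliced, config$band_frac)
  identity <- max(0, 1 - d / max(n, nchar(spliced)))
  list(strand = strand, identity = identity, exons = exons)
}

# derive exon intervals from a chained anchor set; rp/gp are 0-based
place_exons <- function(anchors, oc, refchars, k, intron_min, reflen) {
  rp <- anchors[, 1L]; gp <- anchors[, 2L]
  nA <- length(rp)
  # junction between anchor i and i+1 when the genomic advance exceeds the
  # read advance by at least intron_min
  gapdiff <- if (nA > 1L) (gp[-1L] - gp[-nA]) - (rp[-1L] - rp[-nA]) else integer(0)
  cut <- which(gapdiff >= intron_min)
  seg_start <- c(1L, cut + 1L)
  seg_end <- c(cut, nA)
  S <- length(seg_start)
  # per segment: read/genome extents from terminal anchors
  g_lo <- gp[seg_start]; g_hi <- gp[seg_end] + k
  r_lo <- rp[seg_start]; r_hi <- rp[seg_end] + k
  # terminal exons run to the read ends along the diagonal
  g_lo[1L] <- max(0L, g_lo[1L] - r_lo[1L])
  g_hi[S] <- min(reflen, g_hi[S] + (length(oc) - r_hi[S]))
  if (S > 1L) {
    for (j in seq_len(S - 1L)) {
      # unanchored read window between segment j and j+1
      ra <- r_hi[j]; ga <- g_hi[j]
      rb <- r_lo[j + 1L]; gb <- g_lo[j + 1L]
      if (rb < ra) { # anchor overlap across the junction: trim the left side
        ga <- ga - (ra - rb)
        ra <- rb
      }
      # widen the split window into the anchored flanks so that at
      # sequence-ambiguous junctions (where several placements match
      # equally) the canonical-motif bonus can pick the true one
      el <- max(0L, min(MOTIF_WINDOW, ra - r_lo[j], ga - g_lo[j] - 1L))
      er <- max(0L, min(MOTIF_WINDOW, r_hi[j + 1L] - rb,
                        g_hi[j + 1L] - gb - 1L))
      ra <- ra - el; ga <- ga - el
      rb <- rb + er; gb <- gb + er
      m <- rb - ra
      t_best <- best_split(oc, refchars, ra, ga, rb, gb, m)
      g_hi[j] <- ga + t_best
      g_lo[j + 1L] <- gb - (m - t_best)
    }
  }
  ok <- g_lo < g_hi
  g_lo <- g_lo[ok]; g_hi <- g_hi[ok]
  if (length(g_lo) == 0L) return(NULL)
  if (any(g_lo[-1L] < g_hi[-length(g_hi)])) return(NULL) # degenerate chain
  exon_matrix(g_lo, g_hi)
}

# choose how many of the m unanchored read bases belong to the left exon:
# maximize diagonal base matches on both sides plus a GT..AG motif bonus
best_split <- function(oc, refchars, ra, ga, rb, gb, m) {
  if (m <= 0L) return(0L)
  read_win <- oc[(ra + 1L):rb]
  left_idx <- (ga + 1L):(ga + m)
  right_idx <- (gb - m + 1L):gb
  left_ok <- left_idx <= length(refchars)
  right_ok <- right_idx >= 1L
  lmatch <- (read_win == refchars[pmin(left_idx, length(refchars))]) & left_ok
  rmatch <- (read_win == refchars[pmax(right_idx, 1L)]) & right_ok
  lcum <- c(0, cumsum(lmatch))          # left score for t = 0..m
  rcum <- c(rev(cumsum(rev(rmatch))), 0) # right score for t = 0..m
  t <- 0:m
  donor <- ga + t          # 0-based intron start after the left exon
  acc <- gb - m + t        # 0-based start of the right exon
  motif <- donor + 2L <= length(refchars) & acc - 2L >= 1L &
    refchars[pmin(donor + 1L, length(refchars))] == "G" &
    refchars[pmin(donor + 2L, length(refchars))] == "T" &
    refchars[pmax(acc - 1L, 1L)] == "A" &
    refchars[pmax(acc, 1L)] == "G"
  score <- lcum + rcum + MOTIF_BONUS * motif
  t[which.max(score)]
}
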