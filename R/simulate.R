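#' @title Amplicon read simulator with ground truth
#' @description Generates a multi-exon locus with canonical GT..AG intron
#'   motifs, an isoform mixture over stable/variable/rare exons, and
#'   barcoded error-laden long reads (i.i.d. per-base substitutions,
#'   insertions and deletions at roughly the 10\% combined rate typical of
#'   1D nanopore reads), plus a fraction of off-target reads. Full per-read
#'   provenance is emitted so pipeline recovery can be tested without any
#'   external data.
#' @name simulator
NULL

#' Simulate a multi-exon locus
#'
#' Exons are placed in ascending order separated by introns that start with
#' `GT` and end with `AG`; the locus is padded with flanking sequence.
#'
#' @param n_exons Number of exons (>= 2).
#' @param exon_length,intron_length Length ranges `c(min, max)` in bp;
#'   introns must allow at least 35 bp so the aligner's intron-opening
#'   threshold and the splice motifs fit.
#' @param flank Flanking sequence length on each side.
#' @param seed Integer seed (`NULL` leaves the RNG state untouched).
#' @return A `sim_locus`: list with `chrom`, `reference` (named character),
#'   `exons` (tibble `start`, `end`, 0-based half-open).
#' @examples
#' loc <- make_locus(n_exons = 3, seed = 7)
#' loc$exons
#' @export
make_locus <- function(n_exons = 20L, exon_length = c(40L, 400L),
                       intron_length = c(60L, 400L), flank = 100L,
                       seed = NULL) {
  stopifnot(n_exons >= 2L, exon_length[1L] >= 1L,
            exon_length[1L] <= exon_length[2L],
            intron_length[1L] <= intron_length[2L])
  if (intron_length[1L] < 35L)
    stop("intron_length must allow at least 35 bp")
  if (!is.null(seed)) set.seed(seed)
  elens <- sample(seq(exon_length[1L], exon_length[2L]), n_exons,
                  replace = TRUE)
  ilens <- sample(seq(intron_length[1L], intron_length[2L]), n_exons - 1L,
                  replace = TRUE)
  pieces <- character(2L * n_exons - 1L + 2L)
  pieces[1L] <- random_dna(flank)
  starts <- integer(n_exons)
  pos <- flank
  pi <- 2L
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    pieces[pi] <- random_dna(elens[i])
    pos <- pos + elens[i]
    pi <- pi + 1L
    if (i < n_exons) {
      intron <- random_dna(ilens[i])
      substr(intron, 1L, 2L) <- "GT"
      substr(intron, ilens[i] - 1L, ilens[i]) <- "AG"
      pieces[pi] <- intron
      pos <- pos + ilens[i]
      pi <- pi + 1L
    }
  }
  pieces[pi] <- random_dna(flank)
  ref <- paste(pieces, collapse = "")
  structure(list(
    chrom = "simlocus",
    reference = c(simlocus = ref),
    exons = tibble::tibble(start = starts, end = starts + elens)
  ), class = "sim_locus")
}

#' Sample an isoform mixture over exon classes
#'
#' Stable exons are present in every isoform; variable exons are included
#' independently with probability `p_variable`; rare exons with `p_rare`.
#' The first and last exons must be stable (they carry the primer sites).
#' Mixture frequencies are drawn from a symmetric Dirichlet
#' (gamma(`concentration`) draws, normalized). Duplicate structures are
#' merged; `mode = "exhaustive"` instead enumerates all `2^v` variable-exon
#' combinations (rare exons excluded).
#'
#' @param locus A `sim_locus`.
#' @param classes Character vector (`"stable"`, `"variable"`, `"rare"`) per
#'   exon.
#' @param n_isoforms Number of distinct isoforms to sample.
#' @param p_variable,p_rare Inclusion probabilities.
#' @param concentration Dirichlet concentration for frequencies.
#' @param mode `"sample"` or `"exhaustive"`.
#' @param seed Integer seed (`NULL` leaves the RNG state untouched).
#' @return Tibble: `isoform_id`, `exon_idx` (list of exon indices),
#'   `frequency` (sums to 1).
#' @export
make_isoforms <- function(locus, classes, n_isoforms = 12L,
                          p_variable = 0.5, p_rare = 0.1,
                          concentration = 1, mode = c("sample", "exhaustive"),
                          seed = NULL) {
  mode <- match.arg(mode)
  n <- nrow(locus$exons)
  stopifnot(length(classes) == n,
            all(classes %in% c("stable", "variable", "rare")))
  if (classes[1L] != "stable" || classes[n] != "stable")
    stop("first and last exons must be stable (primer targets)")
  if (!is.null(seed)) set.seed(seed)
  if (mode == "exhaustive") {
    vidx <- which(classes == "variable")
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(vidx)))
    sets <- lapply(seq_len(nrow(combos)), function(i) {
      sort(c(which(classes == "stable"), vidx[unlist(combos[i, ])]))
    })
  } else {
    sets <- list()
    tries <- 0L
    while (length(sets) < n_isoforms && tries < 200L * n_isoforms) {
      tries <- tries + 1L
      inc <- classes == "stable" |
        (classes == "variable" & stats::runif(n) < p_variable) |
        (classes == "rare" & stats::runif(n) < p_rare)
      s <- which(inc)
      if (!any(vapply(sets, identical, logical(1), y = s))) {
        sets[[length(sets) + 1L]] <- s
      }
    }
    if (length(sets) == 0L) stop("no isoforms could be sampled")
  }
  k <- length(sets)
  freq <- stats::rgamma(k, shape = concentration)
  freq <- freq / sum(freq)
  tibble::tibble(
    isoform_id = sprintf("iso%02d", seq_len(k)),
    exon_idx = sets,
    frequency = freq
  )
}

# i.i.d. per-base corruption: substitution, deletion, and insertion after
# each base, at the given probabilities
mutate_sequence <- function(s, sub, ins, del) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  u <- stats::runif(n)
  is_del <- u < del
  is_sub <- !is_del & u < del + sub
  if (any(is_sub)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    picks <- ceiling(stats::runif(sum(is_sub)) * 3)
    chars[is_sub] <- vapply(seq_len(sum(is_sub)), function(i) {
      substr(alt[[chars[is_sub][i]]], picks[i], picks[i])
    }, character(1))
  }
  chars[is_del] <- ""
  is_ins <- stats::runif(n) < ins
  if (any(is_ins)) {
    chars[is_ins] <- paste0(chars[is_ins],
                            sample(c("A", "C", "G", "T"), sum(is_ins),
                                   replace = TRUE))
  }
  paste(chars, collapse = "")
}

#' Simulate error-laden barcoded reads from an isoform mixture
#'
#' Each read is drawn from an isoform according to the mixture frequencies,
#' spliced from the locus, corrupted with i.i.d. per-base errors, optionally
#' reverse-complemented, and assigned round-robin to samples. A fraction of
#' reads is replaced by random off-target sequence (emulating non-specific
#' priming). Ground truth is recorded for every read.
#'
#' @param locus A `sim_locus`.
#' @param isoforms Tibble from [make_isoforms()].
#' @param n_reads Number of reads.
#' @param error_rates Named vector `c(sub=, ins=, del=)` of per-base rates.
#' @param n_samples Number of barcoded samples (`rep1`, `rep2`, ...).
#' @param offtarget_frac Fraction of off-target reads.
#' @param frac_reverse Fraction of reads emitted as the reverse complement.
#' @param seed Integer seed (`NULL` leaves the RNG state untouched).
#' @return A `sim_dataset`: list with `reads` (tibble `read_id`,
#'   `sample_id`, `sequence`, `qualities`), `truth` (tibble `read_id`,
#'   `sample_id`, `isoform_id` (`NA` for off-target), `strand`,
#'   `offtarget`), `locus`, `isoforms`.
#' @export
simulate_reads <- function(locus, isoforms, n_reads = 2000L,
                           error_rates = c(sub = 0.04, ins = 0.03, del = 0.03),
                           n_samples = 2L, offtarget_frac = 0.05,
                           frac_reverse = 0.5, seed = NULL) {
  stopifnot(n_reads >= 1L, all(error_rates >= 0), all(error_rates < 1),
            offtarget_frac >= 0, offtarget_frac < 1)
  if (!is.null(seed)) set.seed(seed)
  ref <- unname(locus$reference)
  spliced <- vapply(isoforms$exon_idx, function(idx) {
    paste(substring(ref, locus$exons$start[idx] + 1L,
                    locus$exons$end[idx]), collapse = "")
  }, character(1))
  mean_len <- round(mean(nchar(spliced)))
  off <- stats::runif(n_reads) < offtarget_frac
  iso <- sample.int(nrow(isoforms), n_reads, replace = TRUE,
                    prob = isoforms$frequency)
  rev <- stats::runif(n_reads) < frac_reverse
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    base <- if (off[i]) random_dna(mean_len) else spliced[iso[i]]
    seqs[i] <- mutate_sequence(base, error_rates[["sub"]],
                               error_rates[["ins"]], error_rates[["del"]])
  }
  if (any(rev)) seqs[rev] <- revcomp(seqs[rev])
  sample_id <- paste0("rep", ((seq_len(n_reads) - 1L) %% n_samples) + 1L)
  read_id <- sprintf("read%06d", seq_len(n_reads))
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  structure(list(
    reads = tibble::tibble(read_id = read_id, sample_id = sample_id,
                           sequence = seqs, qualities = qual),
    truth = tibble::tibble(
      read_id = read_id, sample_id = sample_id,
      isoform_id = ifelse(off, NA_character_, isoforms$isoform_id[iso]),
      strand = ifelse(rev, "-", "+"),
      offtarget = off
    ),
    locus = locus, isoforms = isoforms
  ), class = "sim_dataset")
}

#' True alignments of simulated reads
#'
#' Exon chains each on-target read should align to, in the alignment-tibble
#' format, for running the pipeline with imported (truth) alignments.
#'
#' @param sim A `sim_dataset`.
#' @return Alignment tibble (off-target reads absent; identity 1).
#' @export
truth_alignments <- function(sim) {
  tr <- sim$truth[!sim$truth$offtarget, , drop = FALSE]
  iso_idx <- match(tr$isoform_id, sim$isoforms$isoform_id)
  exons <- lapply(iso_idx, function(j) {
    idx <- sim$isoforms$exon_idx[[j]]
    exon_matrix(sim$locus$exons$start[idx], sim$locus$exons$end[idx])
  })
  new_alignments(read_id = tr$read_id, sample_id = tr$sample_id,
                 chrom = sim$locus$chrom, strand = tr$strand,
                 identity = 1, exons = exons)
}

#' Simulate a complete benchmark dataset
#'
#' One call building locus, classes, mixture and reads. The defaults define
#' the package's standard desk-scale recovery benchmark: a 20-exon locus
#' (14 stable including both primer-side exons, 3 variable, 3 rare), 12
#' isoforms, 2,000 reads across 2 samples at 7\% combined error with 5\%
#' off-target reads.
#'
#' @param n_exons,n_variable,n_rare Locus composition; remaining exons are
#'   stable.
#' @param n_isoforms,n_reads,error_rates,n_samples,offtarget_frac,frac_reverse
#'   Passed through to [make_isoforms()] / [simulate_reads()].
#' @param exon_length,intron_length Passed to [make_locus()].
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @return A `sim_dataset` with an extra `classes` element.
#' @export
simulate_dataset <- function(n_exons = 20L, n_variable = 3L, n_rare = 3L,
                             n_isoforms = 12L, n_reads = 2000L,
                             error_rates = c(sub = 0.03, ins = 0.02,
                                             del = 0.02),
                             n_samples = 2L, offtarget_frac = 0.05,
                             frac_reverse = 0.5,
                             exon_length = c(40L, 400L),
                             intron_length = c(60L, 400L),
                             seed = 1L) {
  stopifnot(n_variable + n_rare <= n_exons - 2L)
  set.seed(seed)
  locus <- make_locus(n_exons, exon_length, intron_length)
  classes <- rep("stable", n_exons)
  special <- sample(2:(n_exons - 1L), n_variable + n_rare)
  classes[special[seq_len(n_variable)]] <- "variable"
  if (n_rare > 0L) classes[special[n_variable + seq_len(n_rare)]] <- "rare"
  isoforms <- make_isoforms(locus, classes, n_isoforms = n_isoforms)
  sim <- simulate_reads(locus, isoforms, n_reads = n_reads,
                        error_rates = error_rates, n_samples = n_samples,
                        offtarget_frac = offtarget_frac,
                        frac_reverse = frac_reverse)
  sim$classes <- classes
  sim
}

#' Write a simulated dataset to disk
#'
#' Emits the reference FASTA, one FASTQ per sample, truth alignments as
#' BED12, and the isoform/read truth tables as TSV.
#'
#' @param sim A `sim_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- Biostrings::DNAStringSet(sim$locus$reference)
  Biostrings::writeXStringSet(ref, file.path(out_dir, "reference.fasta"))
  for (s in unique(sim$reads$sample_id)) {
    write_fastq(sim$reads[sim$reads$sample_id == s, , drop = FALSE],
                file.path(out_dir, paste0(s, ".fastq")))
  }
  export_bed12(truth_alignments(sim), file.path(out_dir, "truth.bed"))
  write.table(sim$truth, file.path(out_dir, "truth_reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  iso <- sim$isoforms
  iso$exon_idx <- vapply(iso$exon_idx, paste, character(1), collapse = ",")
  write.table(iso, file.path(out_dir, "truth_isoforms.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
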