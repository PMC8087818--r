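#' @title Reading and writing the pipeline's file formats
#' @description FASTQ reads, FASTA references, spliced alignments
#'   (SAM/BAM/PAF/BED12) and BED12 export. All genomic coordinates in this
#'   package are 0-based half-open on the forward genome strand, so an
#'   exon's length is always `end - start`.
#' @name io
NULL

# ---- exon-chain containers -------------------------------------------------

# exon chains are integer matrices with columns start, end (0-based
# half-open), strictly ascending and non-overlapping
exon_matrix <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  validate_exons(m)
  m
}

validate_exons <- function(m) {
  if (!is.matrix(m) || ncol(m) != 2L || nrow(m) < 1L)
    stop("exon chain must be a matrix with columns start, end and >= 1 row")
  if (any(m[, 1L] >= m[, 2L]))
    stop("exon intervals must satisfy start < end")
  if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L]))
    stop("exon chain must be strictly ascending and non-overlapping")
  invisible(m)
}

new_alignments <- function(read_id, chrom, strand, identity, exons,
                           sample_id = NA_character_, is_primary = TRUE) {
  lapply(exons, validate_exons)
  tibble::tibble(
    read_id = as.character(read_id),
    sample_id = rep_len(as.character(sample_id), length(read_id)),
    chrom = rep_len(as.character(chrom), length(read_id)),
    strand = rep_len(as.character(strand), length(read_id)),
    is_primary = rep_len(as.logical(is_primary), length(read_id)),
    identity = rep_len(as.numeric(identity), length(read_id)),
    exons = exons
  )
}

empty_alignments <- function() {
  tibble::tibble(read_id = character(), sample_id = character(),
                 chrom = character(), strand = character(),
                 is_primary = logical(), identity = numeric(),
                 exons = list())
}

# ---- FASTQ -----------------------------------------------------------------

#' Read long reads from a FASTQ file
#'
#' @param path FASTQ file, optionally gzipped.
#' @param sample_id Sample label attached to every read; defaults to the file
#'   name without extensions.
#' @return A tibble with columns `read_id`, `sample_id`, `sequence`,
#'   `qualities` (one row per record; zero rows for an empty file).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGTACGTAC", "+", "IIIIIIIIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  }
  if (file.size(path) == 0L) {
    return(tibble::tibble(read_id = character(), sample_id = character(),
                          sequence = character(), qualities = character()))
  }
  defect <- locate_fastq_defect(path)
  if (!is.na(defect)) {
    stop("malformed FASTQ record in ", path, " near line ", defect,
         call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop("malformed FASTQ record in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate read ids in ", path)
  tibble::tibble(
    read_id = unname(ids),
    sample_id = sample_id,
    sequence = unname(as.character(set)),
    qualities = unname(as.character(S4Vectors::mcols(set)$qualities))
  )
}

# best-effort location of the first structurally broken 4-line FASTQ record
locate_fastq_defect <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  i <- 1L
  while (i <= n) {
    if (!startsWith(lines[i], "@")) return(i)
    if (i + 3L > n) return(i) # truncated final record
    if (!startsWith(lines[i + 2L], "+")) return(i + 2L)
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L])) return(i + 3L)
    i <- i + 4L
  }
  NA_integer_
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally `qualities`
#'   (a constant placeholder quality is written when absent).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads[["qualities"]]
  if (is.null(qual) || all(is.na(qual))) {
    qual <- vapply(nchar(reads$sequence),
                   function(n) strrep("I", n), character(1))
  }
  out <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                         "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Read a reference sequence from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (usually length 1: the
#'   amplified locus).
#' @export
read_reference <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

# ---- spliced alignment import ----------------------------------------------

#' Import spliced alignments
#'
#' Reads spliced read-to-genome alignments and normalizes them to 0-based
#' half-open exon chains on the forward genome strand. Secondary and
#' supplementary records are discarded: only each read's primary placement
#' enters grouping and isoform calling. Intron gaps (CIGAR `N` operations, or
#' BED12 block gaps) split the exon chain.
#'
#' @param path Alignment file.
#' @param format One of `"auto"`, `"sam"`, `"bam"`, `"paf"`, `"bed12"`.
#'   `"auto"` guesses from the file extension.
#' @param sample_id Optional sample label attached to all records.
#' @return Alignment tibble with columns `read_id`, `sample_id`, `chrom`,
#'   `strand`, `is_primary`, `identity`, `exons` (list of 2-column integer
#'   matrices).
#' @export
import_alignments <- function(path, format = c("auto", "sam", "bam", "paf",
                                               "bed12"),
                              sample_id = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
                     sam = "sam", bam = "bam", paf = "paf", bed = "bed12",
                     bed12 = "bed12",
                     stop("cannot guess alignment format from extension '",
                          ext, "'; pass format= explicitly"))
  }
  out <- switch(format,
                sam = import_sam(path, is_bam = FALSE),
                bam = import_sam(path, is_bam = TRUE),
                paf = import_paf(path),
                bed12 = import_bed12(path))
  out$sample_id <- rep_len(as.character(sample_id), nrow(out))
  out
}

import_sam <- function(path, is_bam = FALSE) {
  bam <- if (is_bam) path else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE),
    what = "qname", tag = "NM"
  )
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(gal) == 0L) return(empty_alignments())
  grl <- GenomicAlignments::grglist(gal)
  nm <- S4Vectors::mcols(gal)$NM
  wid <- GenomicAlignments::qwidth(gal)
  identity <- if (is.null(nm)) rep(NA_real_, length(gal)) else {
    pmax(0, 1 - as.numeric(nm) / pmax(1L, wid))
  }
  exons <- lapply(seq_along(grl), function(i) {
    s <- BiocGenerics::start(grl[[i]])
    e <- BiocGenerics::end(grl[[i]])
    o <- order(s)
    exon_matrix(s[o] - 1L, e[o])
  })
  new_alignments(
    read_id = S4Vectors::mcols(gal)$qname,
    chrom = as.character(GenomicRanges::seqnames(gal)),
    strand = as.character(BiocGenerics::strand(gal)),
    identity = identity,
    exons = exons
  )
}

import_paf <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(empty_alignments())
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) stop("malformed PAF line (fewer than 12 fields)")
    tags <- f[-(1:12)]
    tp <- sub("^tp:A:", "", grep("^tp:A:", tags, value = TRUE))
    if (length(tp) == 1L && tp != "P") return(NULL) # secondary/supplementary
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", tags, value = TRUE))
    if (length(cg) != 1L)
      stop("PAF record for ", f[1], " lacks a cg:Z CIGAR tag")
    exons <- cigar_to_exons(cg, tstart = as.integer(f[8]))
    list(read_id = f[1], chrom = f[6], strand = f[5],
         identity = as.numeric(f[10]) / max(1, as.numeric(f[11])),
         exons = exons)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(empty_alignments())
  new_alignments(
    read_id = vapply(rows, `[[`, "", "read_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    identity = vapply(rows, `[[`, 0, "identity"),
    exons = lapply(rows, `[[`, "exons")
  )
}

# walk a CIGAR string along the target, splitting exons at N operations
cigar_to_exons <- function(cigar, tstart) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1L) stop("unparseable CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^\\d+", "", toks)
  pos <- tstart
  starts <- integer(0); ends <- integer(0)
  cur_start <- NA_integer_
  for (i in seq_along(op)) {
    consumes_t <- op[i] %in% c("M", "D", "N", "=", "X")
    if (op[i] == "N") {
      if (!is.na(cur_start)) {
        starts <- c(starts, cur_start); ends <- c(ends, pos)
        cur_start <- NA_integer_
      }
      pos <- pos + len[i]
    } else if (consumes_t) {
      if (is.na(cur_start)) cur_start <- pos
      pos <- pos + len[i]
    }
  }
  if (!is.na(cur_start)) { starts <- c(starts, cur_start); ends <- c(ends, pos) }
  exon_matrix(starts, ends)
}

import_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) return(empty_alignments())
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(blocks))
    stop("BED file has no block structure; BED12 input is required")
  exons <- lapply(seq_along(gr), function(i) {
    b <- blocks[[i]] # block ranges relative to chromStart, 1-based
    abs_start <- BiocGenerics::start(gr[i]) - 1L # 0-based chromStart
    exon_matrix(abs_start + BiocGenerics::start(b) - 1L,
                abs_start + BiocGenerics::end(b))
  })
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- paste0("aln", seq_along(gr))
  new_alignments(
    read_id = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    identity = NA_real_,
    exons = exons
  )
}

#' Export exon chains as BED12
#'
#' Writes one BED12 line per alignment; re-importing with
#' [import_alignments()] reproduces the exon chains exactly.
#'
#' @param alignments Alignment tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_bed12 <- function(alignments, path) {
  if (nrow(alignments) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- vapply(seq_len(nrow(alignments)), function(i) {
    ex <- alignments$exons[[i]]
    chrom_start <- ex[1L, 1L]
    chrom_end <- ex[nrow(ex), 2L]
    strand <- alignments$strand[i]
    if (!strand %in% c("+", "-")) strand <- "+"
    paste(alignments$chrom[i], chrom_start, chrom_end,
          alignments$read_id[i], 0L, strand,
          chrom_start, chrom_end, "0,0,0", nrow(ex),
          paste(ex[, 2L] - ex[, 1L], collapse = ","),
          paste(ex[, 1L] - chrom_start, collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read exon annotation models
#'
#' Loads known gene models from GTF/GFF (rows of type `exon`) or BED12 and
#' returns the distinct annotated exon intervals, 0-based half-open.
#'
#' @param path Annotation file (`.gtf`, `.gff`, `.gff3`, `.bed`).
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
    df <- tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = BiocGenerics::start(gr) - 1L,
                         end = BiocGenerics::end(gr))
  } else if (ext %in% c("bed", "bed12")) {
    aln <- import_bed12(path)
    df <- do.call(rbind, lapply(seq_len(nrow(aln)), function(i) {
      ex <- aln$exons[[i]]
      data.frame(chrom = aln$chrom[i], start = ex[, 1L], end = ex[, 2L])
    }))
    df <- tibble::as_tibble(df)
  } else {
    stop("unsupported annotation format: ", ext)
  }
  unique(df)
}
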