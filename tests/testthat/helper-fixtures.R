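# shared in-code fixtures: tiny loci, noisy reads, hand-built files

exon_mat <- isoscope:::exon_matrix

mk_alignments <- function(exon_list, read_id = paste0("r", seq_along(exon_list)),
                          strand = "+", chrom = "locus", identity = 1,
                          sample_id = NA_character_) {
  isoscope:::new_alignments(read_id, chrom, strand, identity, exon_list,
                            sample_id = sample_id)
}

# spliced sequence of an exon subset of a sim_locus
spliced_seq <- function(locus, idx) {
  paste(substring(unname(locus$reference), locus$exons$start[idx] + 1L,
                  locus$exons$end[idx]), collapse = "")
}

noisy <- function(s, sub = 0.04, ins = 0.03, del = 0.03) {
  isoscope:::mutate_sequence(s, sub, ins, del)
}

write_sam_fixture <- function(path, records,
                              header = c("@HD\tVN:1.6\tSO:unknown",
                                         "@SQ\tSN:chr1\tLN:100000")) {
  writeLines(c(header, records), path)
  path
}

# per-base union oracle for block merging: mark covered bases, then take
# maximal covered runs
union_blocks_oracle <- function(exons) {
  hi <- max(exons[, 2L])
  cov <- logical(hi)
  for (i in seq_len(nrow(exons))) {
    cov[(exons[i, 1L] + 1L):exons[i, 2L]] <- TRUE
  }
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep] - 1L, end = ends[keep])
}
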