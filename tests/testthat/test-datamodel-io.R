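test_that("FASTQ reading handles normal, empty and truncated files", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGTAC", "+", "IIIIIIIIII"), fq)
  reads <- read_fastq(fq)
  expect_equal(nrow(reads), 1L)
  expect_equal(nchar(reads$sequence), 10L)
  expect_equal(reads$read_id, "r1")

  empty <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty)
  expect_equal(nrow(read_fastq(empty)), 0L)

  trunc <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGTAC", "+", "IIIIIIIIII", "@r2", "ACGT"), trunc)
  expect_error(read_fastq(trunc), "line 5")
})

test_that("FASTQ writing round-trips reads", {
  reads <- tibble::tibble(read_id = c("a", "b"),
                          sample_id = "s1",
                          sequence = c("ACGT", "GGCCTT"),
                          qualities = c("IIII", "IIIIII"))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq, sample_id = "s1")
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$qualities, reads$qualities)
})

test_that("SAM import splits exons at N gaps and keeps primaries only", {
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_fixture(sam, c(
    paste0("r1\t0\tchr1\t1001\t60\t100M500N100M\t*\t0\t0\t",
           strrep("A", 200), "\t*\tNM:i:0"),
    "r2\t256\tchr1\t1001\t60\t200M\t*\t0\t0\t*\t*",
    paste0("r3\t0\tchr1\t2001\t60\t50M\t*\t0\t0\t", strrep("C", 50), "\t*")
  ))
  aln <- import_alignments(sam, "sam")
  expect_setequal(aln$read_id, c("r1", "r3")) # secondary r2 dropped
  expect_equal(aln$exons[[match("r1", aln$read_id)]],
               exon_mat(c(1000, 1600), c(1100, 1700)))
  expect_equal(nrow(aln$exons[[match("r3", aln$read_id)]]), 1L)
})

test_that("PAF import walks the cg CIGAR and drops non-primaries", {
  paf <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(
    "r1\t200\t0\t200\t+\tchr1\t5000\t1000\t1700\t197\t700\t60\ttp:A:P\tcg:Z:100M500N100M",
    "r2\t200\t0\t200\t+\tchr1\t5000\t1000\t1200\t190\t200\t0\ttp:A:S\tcg:Z:200M"
  ), paf)
  aln <- import_alignments(paf, "paf")
  expect_equal(aln$read_id, "r1")
  expect_equal(aln$exons[[1]], exon_mat(c(1000, 1600), c(1100, 1700)))
  expect_equal(aln$identity[1], 197 / 700)
})

test_that("BED12 export/import round-trips exon chains exactly", {
  set.seed(42)
  chains <- lapply(1:100, function(i) {
    n <- sample(1:6, 1)
    len <- sample(30:300, n, replace = TRUE)
    gap <- sample(40:500, n, replace = TRUE)
    starts <- cumsum(gap) + cumsum(c(0, len[-n]))
    exon_mat(starts, starts + len)
  })
  aln <- mk_alignments(chains, strand = rep(c("+", "-"), length.out = 100))
  bed <- withr::local_tempfile(fileext = ".bed")
  export_bed12(aln, bed)
  back <- import_alignments(bed, "bed12")
  expect_equal(nrow(back), 100L)
  ord <- match(aln$read_id, back$read_id)
  for (i in seq_len(100)) {
    expect_identical(back$exons[[ord[i]]], chains[[i]])
  }
  expect_equal(back$strand[ord], aln$strand)

  # empty export gives an empty file that imports to zero alignments
  bed0 <- withr::local_tempfile(fileext = ".bed")
  export_bed12(aln[0, ], bed0)
  expect_equal(nrow(import_alignments(bed0, "bed12")), 0L)
})

test_that("exon chains enforce the half-open ascending invariant", {
  expect_error(exon_mat(10, 10), "start < end")
  expect_error(exon_mat(c(10, 15), c(20, 30)), "ascending")
  m <- exon_mat(c(10, 20), c(20, 30)) # book-ended is legal
  expect_equal(m[, "end"] - m[, "start"], c(10L, 10L))
})

test_that("published boundary table is coherent under the half-open convention", {
  ex <- tacc2_exons()
  expect_equal(nrow(ex), 29L)
  expect_equal(ex$end - ex$start, ex$length_bp)
})
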