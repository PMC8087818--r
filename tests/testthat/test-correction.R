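cfg <- pipeline_config()

test_that("block merging equals the per-base union of exon intervals", {
  aln <- mk_alignments(list(exon_mat(c(100, 300), c(200, 400)),
                            exon_mat(150, 250)))
  blocks <- merge_exon_blocks(aln)
  expect_equal(blocks$start, c(100L, 300L))
  expect_equal(blocks$end, c(250L, 400L))

  one <- mk_alignments(list(exon_mat(500, 600)))
  b1 <- merge_exon_blocks(one)
  expect_equal(nrow(b1), 1L)
  expect_equal(c(b1$start, b1$end), c(500L, 600L))

  expect_error(merge_exon_blocks(mk_alignments(list())), "no alignments")
})

test_that("a 29-exon locus with non-overlapping exons yields 29 merged blocks", {
  loc <- make_locus(n_exons = 29, exon_length = c(31, 400),
                    intron_length = c(60, 300), seed = 29)
  # full-length chain plus assorted skipping chains
  chains <- list(
    exon_mat(loc$exons$start, loc$exons$end),
    exon_mat(loc$exons$start[c(1, 5, 29)], loc$exons$end[c(1, 5, 29)]),
    exon_mat(loc$exons$start[seq(1, 29, 2)], loc$exons$end[seq(1, 29, 2)])
  )
  blocks <- merge_exon_blocks(mk_alignments(chains))
  expect_equal(nrow(blocks), 29L)
  expect_equal(blocks$start, loc$exons$start)
  expect_equal(blocks$end, loc$exons$end)
})

test_that("signatures are stable under boundary jitter but not exon skipping", {
  blocks <- tibble::tibble(block_id = 1:3,
                           start = c(100L, 300L, 500L),
                           end = c(200L, 400L, 600L))
  expect_equal(read_signature(exon_mat(c(110, 510), c(190, 590)), blocks),
               c(1L, 3L))
  jitter_a <- read_signature(exon_mat(c(100, 300), c(200, 400)), blocks)
  jitter_b <- read_signature(exon_mat(c(110, 290), c(210, 410)), blocks)
  expect_equal(jitter_a, jitter_b)
  with_two <- read_signature(exon_mat(c(100, 300), c(200, 400)), blocks)
  skipping <- read_signature(exon_mat(100, 200), blocks)
  expect_false(identical(with_two, skipping))
  expect_error(read_signature(exon_mat(1000, 1100), blocks), "no block")
})

test_that("consensus voting fixes a lone substitution and is idempotent", {
  set.seed(21)
  a <- isoscope:::random_dna(400)
  mutant <- a
  substr(mutant, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                      substr(a, 100, 100))[1]
  res <- correct_group(c(a, a, mutant), c("r1", "r2", "r3"), cfg)
  expect_true(all(res$sequences == a))
  expect_true(all(res$corrected))

  same <- correct_group(rep(a, 4), paste0("s", 1:4), cfg)
  expect_true(all(same$sequences == a))
  expect_equal(same$consensus, a)
})

test_that("singleton groups pass through unchanged and flagged", {
  res <- correct_group("ACGTACGTAC", "only", cfg)
  expect_equal(res$sequences, "ACGTACGTAC")
  expect_false(res$corrected)
})

test_that("a 20-read group at 10% error yields a near-perfect consensus", {
  set.seed(33)
  truth <- isoscope:::random_dna(1200)
  reads <- vapply(1:20, function(i) noisy(truth), character(1))
  res <- correct_group(reads, sprintf("r%02d", 1:20), cfg)
  d <- isoscope:::.cpp_edit_distance(res$consensus, truth, 0.2)
  expect_gt(1 - d / nchar(truth), 0.99)
})

test_that("minority exon structures inside a group survive correction", {
  set.seed(44)
  ref <- isoscope:::random_dna(900)
  with_exon <- paste0(substr(ref, 1, 300), substr(ref, 401, 900))
  without <- paste0(substr(ref, 1, 300), substr(ref, 701, 900))
  seqs <- c(vapply(1:9, function(i) noisy(with_exon, .03, .02, .02), character(1)),
            vapply(1:6, function(i) noisy(without, .03, .02, .02), character(1)))
  res <- correct_group(seqs, sprintf("m%02d", 1:15), cfg)
  d_with <- isoscope:::.cpp_edit_distance_many(res$sequences[1:9], with_exon, 0.5)
  d_without <- isoscope:::.cpp_edit_distance_many(res$sequences[10:15], without, 0.5)
  expect_true(all(d_with < 20))
  expect_true(all(d_without < 20))
})

test_that("two-round correction is a fixed point on noise-free input", {
  loc <- make_locus(n_exons = 4, seed = 55)
  a <- spliced_seq(loc, 1:4)
  b <- spliced_seq(loc, c(1, 2, 4))
  reads <- tibble::tibble(read_id = sprintf("r%02d", 1:10),
                          sample_id = "s",
                          sequence = c(rep(a, 6), rep(b, 4)))
  out <- run_grouped_correction(reads, loc$reference, cfg)
  expect_equal(out$corrected$sequence,
               reads$sequence[match(out$corrected$read_id, reads$read_id)])
  expect_equal(out$stats$n_corrected, 10L)
})

test_that("grouping partitions the aligned reads in every round", {
  sim <- simulate_dataset(n_exons = 6, n_variable = 1, n_rare = 1,
                          n_isoforms = 3, n_reads = 80, seed = 66)
  out <- run_grouped_correction(sim$reads, sim$locus$reference, cfg)
  for (r in unique(out$groups$round)) {
    ids <- out$groups$read_id[out$groups$round == r]
    expect_false(anyDuplicated(ids) > 0)
  }
  expect_lte(out$stats$n_corrected, out$stats$n_aligned)
})

test_that("isoforms merged by coarse round-1 alignment separate in round 2", {
  # three-exon locus: isoform A uses all exons, isoform B skips the middle
  # one; round-1 alignments are supplied as a single merged span for every
  # read, emulating jitter-bridged blocks that collapse the two isoforms
  # into one coarse group
  loc <- make_locus(n_exons = 3, exon_length = c(120, 180),
                    intron_length = c(60, 120), seed = 77)
  iso_a <- spliced_seq(loc, 1:3)
  iso_b <- spliced_seq(loc, c(1, 3))
  set.seed(78)
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:24),
    sample_id = "s",
    sequence = c(vapply(1:13, function(i) noisy(iso_a, .03, .02, .02), character(1)),
                 vapply(1:11, function(i) noisy(iso_b, .03, .02, .02), character(1)))
  )
  span <- exon_mat(loc$exons$start[1], loc$exons$end[3])
  coarse <- mk_alignments(rep(list(span), 24), read_id = reads$read_id)
  out <- run_grouped_correction(reads, loc$reference, cfg,
                                alignments = coarse)
  r1 <- out$groups[out$groups$round == 1, ]
  expect_equal(length(unique(r1$signature)), 1L)
  r2 <- out$groups[out$groups$round == 2, ]
  expect_equal(length(unique(r2$signature)), 2L)
  # both true sequences are recovered exactly; individual reads may retain
  # read-specific structural events, so demand exactness for the bulk
  expect_equal(sum(out$corrected$sequence == iso_a), 13L)
  expect_gte(sum(out$corrected$sequence == iso_b), 10L)
})
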