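cfg <- pipeline_config()

test_that("primer filtering keeps only chains spanning both primer exons", {
  primers <- list(c(100L, 200L), c(900L, 1000L))
  full <- exon_mat(c(100, 500, 900), c(200, 600, 1000))
  missing_3p <- exon_mat(c(100, 500), c(200, 600))
  offtarget <- exon_mat(5000, 5400)
  aln <- mk_alignments(list(full, missing_3p, offtarget))
  kept <- primer_filter(aln, primers)
  expect_equal(kept$read_id, "r1")
})

test_that("representative election takes the most frequent boundary pair", {
  chains <- c(rep(list(exon_mat(10, 20)), 5), rep(list(exon_mat(10, 25)), 3))
  aln <- mk_alignments(chains, read_id = paste0("r", 1:8))
  cat <- elect_representatives(aln, cfg)
  expect_equal(nrow(cat$representatives), 1L)
  expect_equal(cat$representatives$start, 10L)
  expect_equal(cat$representatives$end, 20L)

  single <- elect_representatives(mk_alignments(list(exon_mat(40, 100))), cfg)
  expect_equal(c(single$representatives$start, single$representatives$end),
               c(40L, 100L))
})

test_that("election ties break toward the smaller start then end", {
  chains <- c(rep(list(exon_mat(12, 20)), 3), rep(list(exon_mat(10, 22)), 3))
  aln <- mk_alignments(chains, read_id = paste0("r", 1:6))
  cat <- elect_representatives(aln, cfg)
  expect_equal(c(cat$representatives$start, cat$representatives$end),
               c(10L, 22L))
})

test_that("variants are admitted strictly above the support threshold", {
  chains <- c(rep(list(exon_mat(10, 20)), 90),
              rep(list(exon_mat(10, 17)), 8),
              rep(list(exon_mat(12, 20)), 2))
  aln <- mk_alignments(chains, read_id = paste0("r", 1:100))
  cat <- elect_representatives(aln, cfg)
  cat <- detect_variants(aln, cat, cfg)
  expect_equal(nrow(cat$variants), 1L)
  expect_equal(cat$variants$pattern, "L0:R-3")
  expect_equal(cat$variants$length_change, -3L)
  expect_true(cat$variants$change_symmetric)
  expect_true(cat$variants$shares_boundary)
  expect_equal(cat$variants$n_reads, 8L)

  # no pair above threshold -> empty variant list
  uni <- mk_alignments(rep(list(exon_mat(10, 20)), 30),
                       read_id = paste0("u", 1:30))
  cat2 <- detect_variants(uni, elect_representatives(uni, cfg), cfg)
  expect_equal(nrow(cat2$variants), 0L)
})

test_that("pattern strings encode 5'/3' extension and truncation", {
  # 5' truncation by 4412 bp of the long fourth exon
  expect_equal(pattern_string(c(123846573, 123847474),
                              c(123842161, 123847474)), "L-4412:R0")
  expect_equal(pattern_string(c(10, 20), c(10, 20)), "L0:R0")
  # 3' extension by 12
  expect_equal(pattern_string(c(123969911, 123971235),
                              c(123969911, 123971223)), "L0:R12")
  expect_equal(parse_pattern("L-4412:R0")[1, ], c(d5 = -4412L, d3 = 0L))
  expect_equal(apply_pattern("L0:R-2445", 123842161, 123847474)[1, ],
               c(start = 123842161L, end = 123845029L))
  expect_error(parse_pattern("L1R2"), "malformed")
})

test_that("reading-frame symmetry is length modulo 3", {
  expect_true(is_symmetric(78))
  expect_false(is_symmetric(61))
  expect_true(is_symmetric(0))
  expect_equal(is_symmetric(c(78, 61, 5313, 1312)),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_error(is_symmetric(-3), "non-negative")
})

test_that("exon states follow the frequency thresholds", {
  expect_equal(classify_exon_state(0.98, cfg), "stable")
  expect_equal(classify_exon_state(0.45, cfg), "variable")
  expect_equal(classify_exon_state(0.005, cfg), "rare")
  expect_equal(classify_exon_state(0.10, cfg), "rare") # boundary: not above
  expect_true(is.na(classify_exon_state(1e-5, cfg)))
})

test_that("annotation status distinguishes exact, partial and novel", {
  aln <- mk_alignments(list(exon_mat(c(100, 300, 500), c(200, 400, 600)),
                            exon_mat(c(100, 300, 500), c(200, 400, 600))))
  cat <- elect_representatives(aln, cfg)
  models <- tibble::tibble(chrom = "locus",
                           start = c(100L, 350L),
                           end = c(200L, 450L))
  ann <- annotate_exons(cat, models)$representatives$annotation
  expect_equal(ann, c("known", "partially_known", "novel"))
  none <- annotate_exons(cat, NULL)$representatives$annotation
  expect_equal(unique(none), "unannotated")
})

test_that("catalog construction logs both denominators", {
  chains <- c(rep(list(exon_mat(c(10, 50), c(20, 60))), 9),
              rep(list(exon_mat(10, 20)), 3))
  aln <- mk_alignments(chains, read_id = paste0("r", 1:12), sample_id = "s")
  cat <- call_exons(aln, cfg)
  den <- attr(cat, "denominators")
  expect_equal(den$exon_containing_reads[den$block_id == 1], 12L)
  expect_equal(den$exon_containing_reads[den$block_id == 2], 9L)
  expect_equal(unique(den$matched_reads), 12L)
  expect_equal(cat$representatives$frequency, c(1, 0.75))
})
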