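cfg <- pipeline_config()

# a small catalog built from explicit alignments: two blocks, one variant
make_toy_catalog <- function() {
  chains <- c(rep(list(exon_mat(c(10, 50), c(20, 60))), 80),
              rep(list(exon_mat(c(10, 50), c(20, 57))), 20))
  aln <- mk_alignments(chains, read_id = paste0("r", 1:100))
  detect_variants(aln, elect_representatives(aln, cfg), cfg)
}

test_that("exact-match keys require every boundary to match the catalog", {
  cat <- make_toy_catalog()
  expect_equal(match_isoform(exon_mat(c(10, 50), c(20, 60)), cat, cfg),
               c("rex01", "rex02"))
  # one boundary off by 1 bp -> no match
  expect_null(match_isoform(exon_mat(c(10, 50), c(20, 61)), cat, cfg))
  # variant element used in place of the representative
  expect_equal(match_isoform(exon_mat(c(10, 50), c(20, 57)), cat, cfg),
               c("rex01", "rex02.v1"))
  # skipping a block is a valid isoform
  expect_equal(match_isoform(exon_mat(10, 20), cat, cfg), "rex01")
})

test_that("isoform records are ranked, tiered and partition the reads", {
  cat <- make_toy_catalog()
  chains <- c(rep(list(exon_mat(c(10, 50), c(20, 60))), 25),
              rep(list(exon_mat(c(10, 50), c(20, 57))), 19),
              rep(list(exon_mat(10, 20)), 2))
  aln <- mk_alignments(chains, read_id = paste0("q", 1:46),
                       sample_id = rep(c("rep1", "rep2"), 23))
  matches <- match_all(aln, cat, cfg)
  expect_equal(nrow(matches), 46L)
  rec <- count_isoforms(matches, cfg)
  expect_equal(sum(rec$total), 46L)
  expect_equal(rec$tier, c("high_confidence", "minimum_evidence",
                           "singleton_zone"))
  expect_equal(rec$rank, 1:3)
  expect_equal(rec$rep1 + rec$rep2, rec$total)

  expect_equal(nrow(count_isoforms(matches[0, ], cfg)), 0L)
})

test_that("junction counts are flow-consistent with element usage", {
  cat <- make_toy_catalog()
  chains <- c(rep(list(exon_mat(c(10, 50), c(20, 60))), 98),
              rep(list(exon_mat(c(10, 50), c(20, 57))), 2))
  aln <- mk_alignments(chains, read_id = paste0("j", 1:100))
  matches <- match_all(aln, cat, cfg)
  jf <- junction_frequencies(matches)
  expect_equal(jf$count[jf$from == "rex01" & jf$to == "rex02"], 98L)
  expect_equal(jf$count[jf$from == "rex01" & jf$to == "rex02.v1"], 2L)
  # outbound total from rex01 equals its read usage
  expect_equal(sum(jf$count[jf$from == "rex01"]), 100L)
  expect_equal(nrow(junction_frequencies(matches[0, ])), 0L)
})

test_that("cumulative coverage is monotone and ends at 1", {
  rec <- tibble::tibble(key = c("a", "b", "c"), total = c(60L, 30L, 10L),
                        rank = 1:3, tier = "high_confidence")
  cc <- cumulative_coverage(rec)
  expect_equal(cc$cumulative_fraction, c(0.6, 0.9, 1.0))
  one <- cumulative_coverage(rec[1, ])
  expect_equal(one$cumulative_fraction, 1.0)
  unif <- tibble::tibble(key = letters[1:10], total = rep(10L, 10),
                         rank = 1:10, tier = "x")
  expect_equal(cumulative_coverage(unif)$cumulative_fraction, (1:10) / 10)
})

test_that("variable-exon combinatorics follow 2^n", {
  expect_equal(variable_combination_count(4), 16)
  expect_equal(variable_combination_count(0), 1)
  expect_equal(variable_combination_count(10), 1024)
  expect_error(variable_combination_count(-1))
})

test_that("tier thresholds are monotone in the high-confidence cutoff", {
  cat <- make_toy_catalog()
  chains <- c(rep(list(exon_mat(c(10, 50), c(20, 60))), 25),
              rep(list(exon_mat(c(10, 50), c(20, 57))), 12),
              rep(list(exon_mat(10, 20)), 5))
  aln <- mk_alignments(chains, read_id = paste0("t", 1:42))
  matches <- match_all(aln, cat, cfg)
  hc <- function(threshold) {
    c2 <- pipeline_config(high_conf_reads = threshold)
    rec <- count_isoforms(matches, c2)
    rec$key[rec$tier == "high_confidence"]
  }
  expect_true(all(hc(20) %in% hc(10)))
  expect_true(all(hc(10) %in% hc(3)))
})

test_that("replicate correlation behaves at the extremes and degenerates", {
  rec <- tibble::tibble(key = letters[1:5],
                        rep1 = c(50L, 40L, 30L, 20L, 10L),
                        rep2 = c(50L, 40L, 30L, 20L, 10L),
                        total = 0L, rank = 1:5, tier = "x")
  expect_equal(replicate_correlation(rec, "rep1", "rep2"), 1.0)
  rec$rep2 <- rev(rec$rep1)
  expect_equal(replicate_correlation(rec, "rep1", "rep2"), -1.0)
  tiny <- rec[1:2, ]
  expect_warning(r <- replicate_correlation(tiny, "rep1", "rep2"),
                 "not computable")
  expect_true(is.na(r))
})

test_that("replicate draws from one mixture correlate strongly", {
  set.seed(88)
  freq <- c(0.4, 0.25, 0.15, 0.1, 0.05, 0.03, 0.02)
  keys <- paste0("iso", seq_along(freq))
  draw <- function() table(factor(sample(keys, 600, TRUE, freq), levels = keys))
  a <- draw(); b <- draw()
  rec <- tibble::tibble(key = keys, rep1 = as.integer(a), rep2 = as.integer(b),
                        total = as.integer(a + b),
                        rank = seq_along(keys), tier = "x")
  expect_gt(replicate_correlation(rec, "rep1", "rep2"), 0.8)
})
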