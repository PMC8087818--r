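test_that("locus simulation is deterministic with recorded coordinates", {
  a <- make_locus(n_exons = 6, seed = 11)
  b <- make_locus(n_exons = 6, seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a$exons), 6L)
  ref <- unname(a$reference)
  # recorded exon sequences really sit at the recorded coordinates
  for (i in 1:6) {
    expect_equal(nchar(substring(ref, a$exons$start[i] + 1, a$exons$end[i])),
                 a$exons$end[i] - a$exons$start[i])
  }
  # introns carry canonical GT..AG motifs
  for (i in 1:5) {
    expect_equal(substring(ref, a$exons$end[i] + 1, a$exons$end[i] + 2), "GT")
    expect_equal(substring(ref, a$exons$start[i + 1] - 1, a$exons$start[i + 1]),
                 "AG")
  }
  expect_error(make_locus(n_exons = 1), "n_exons")
  expect_error(make_locus(n_exons = 3, intron_length = c(10, 20)), "35")
})

test_that("isoform mixtures respect exon classes", {
  loc <- make_locus(n_exons = 6, seed = 12)
  all_stable <- make_isoforms(loc, rep("stable", 6), n_isoforms = 5, seed = 1)
  expect_equal(nrow(all_stable), 1L) # one structure possible
  expect_equal(all_stable$frequency, 1)

  classes <- c("stable", "variable", "variable", "variable", "variable",
               "stable")
  ex <- make_isoforms(loc, classes, mode = "exhaustive", seed = 2)
  expect_equal(nrow(ex), 16L)
  expect_equal(sum(ex$frequency), 1)

  s1 <- make_isoforms(loc, classes, n_isoforms = 6, seed = 3)
  s2 <- make_isoforms(loc, classes, n_isoforms = 6, seed = 3)
  expect_identical(s1, s2)
  # stable exons present in every isoform
  expect_true(all(vapply(s1$exon_idx, function(i) all(c(1, 6) %in% i),
                         logical(1))))
  expect_error(make_isoforms(loc, c("rare", rep("stable", 5))), "primer")
})

test_that("error-free simulation emits exact spliced sequences", {
  loc <- make_locus(n_exons = 5, seed = 13)
  iso <- make_isoforms(loc, c("stable", "variable", "stable", "rare",
                              "stable"), n_isoforms = 4, seed = 4)
  sim <- simulate_reads(loc, iso, n_reads = 50,
                        error_rates = c(sub = 0, ins = 0, del = 0),
                        offtarget_frac = 0, frac_reverse = 0, seed = 5)
  spl <- vapply(iso$exon_idx, function(idx) spliced_seq(loc, idx),
                character(1))
  names(spl) <- iso$isoform_id
  expect_equal(sim$reads$sequence, unname(spl[sim$truth$isoform_id]))
})

test_that("realized error rate matches the configured rates", {
  set.seed(6)
  truth <- isoscope:::random_dna(1000)
  rates <- vapply(1:300, function(i) {
    r <- noisy(truth, 0.04, 0.03, 0.03)
    isoscope:::.cpp_edit_distance(r, truth, 0.2) / nchar(truth)
  }, numeric(1))
  expect_gt(mean(rates), 0.09)
  expect_lt(mean(rates), 0.11)
})

test_that("off-target fraction and strand mixing follow their settings", {
  loc <- make_locus(n_exons = 4, seed = 14)
  iso <- make_isoforms(loc, c("stable", "variable", "rare", "stable"),
                       n_isoforms = 3, seed = 7)
  sim <- simulate_reads(loc, iso, n_reads = 2000, offtarget_frac = 0.1,
                        seed = 8)
  p <- mean(sim$truth$offtarget)
  expect_gt(p, 0.1 - 3 * sqrt(0.1 * 0.9 / 2000))
  expect_lt(p, 0.1 + 3 * sqrt(0.1 * 0.9 / 2000))
  expect_gt(mean(sim$truth$strand == "-"), 0.4)
  expect_lt(mean(sim$truth$strand == "-"), 0.6)
  expect_equal(sort(unique(sim$reads$sample_id)), c("rep1", "rep2"))
})

test_that("identical seeds reproduce the dataset byte for byte", {
  s1 <- simulate_dataset(n_exons = 6, n_variable = 1, n_rare = 1,
                         n_isoforms = 3, n_reads = 40, seed = 99)
  s2 <- simulate_dataset(n_exons = 6, n_variable = 1, n_rare = 1,
                         n_isoforms = 3, n_reads = 40, seed = 99)
  expect_identical(s1, s2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("truth alignments re-import losslessly through BED12", {
  sim <- simulate_dataset(n_exons = 6, n_variable = 1, n_rare = 1,
                          n_isoforms = 3, n_reads = 30, seed = 15)
  ta <- truth_alignments(sim)
  bed <- withr::local_tempfile(fileext = ".bed")
  export_bed12(ta, bed)
  back <- import_alignments(bed, "bed12")
  ord <- match(ta$read_id, back$read_id)
  expect_identical(back$exons[ord], ta$exons)
})
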