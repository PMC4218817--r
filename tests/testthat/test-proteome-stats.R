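test_that("proteome_summary derives frequencies from integer totals", {
  s <- proteome_summary("toy", 4, 1000, 5, 2, 60)
  expect_equal(s$ppp_freq_per_1e4, 50)
  expect_equal(s$ppg_freq_per_1e4, 20)
  expect_equal(s$proline_pct, 6)
  # recomputing from stored totals reproduces the stored reals exactly
  expect_identical(s$ppp_freq_per_1e4, s$total_ppp_units / s$total_aa * 1e4)

  one <- summarize_proteome(scan_proteome(toy_proteome("PPP")), "one")
  expect_identical(one$total_ppp_units, 1L)
  expect_identical(one$total_proline, 3L)
  expect_equal(one$ppp_freq_per_1e4, 1e4 / 3)
  expect_equal(one$proline_pct, 100)

  expect_error(summarize_proteome(data.frame()), "non-empty")
})

test_that("run_length_table buckets maximal run lengths", {
  rl <- run_length_table(c(rep(3, 5), 4, 11, 14))
  expect_identical(as.integer(rl$counts[c("3", "4", ">10")]), c(5L, 1L, 2L))
  expect_identical(rl$total_runs, 8L)
  expect_identical(rl$overflow_lengths, c(11L, 14L))

  # bucket boundary: a run of 11 is >10, a run of 10 is not
  rl <- run_length_table(c(10, 11))
  expect_identical(as.integer(rl$counts[c("10", ">10")]), c(1L, 1L))

  empty <- run_length_table(integer(0))
  expect_identical(empty$total_runs, 0L)
  expect_equal(empty$pct_3p, 0)
  expect_false(empty$pct_3p_defined)

  expect_error(run_length_table(c(2, 3)), "below the repeat threshold")
})

test_that("units_from_table applies the triplet rule per bucket", {
  rl <- run_length_table(c(3, 3, 6))
  expect_identical(units_from_table(rl), 4L)

  expect_identical(units_from_table(run_length_table(integer(0))), 0L)

  # overflow lengths are required to match the >10 bucket
  rl <- run_length_table(c(3, 12))
  expect_identical(units_from_table(rl), 5L)
  expect_error(units_from_table(rl, integer(0)), ">10 bucket")
})

test_that("run-length table and summary unit totals agree on any proteome", {
  set.seed(21)
  for (i in 1:10) {
    seqs <- vapply(1:25, function(j) random_motif_seq(sample(20:150, 1)),
                   character(1))
    profiles <- scan_proteome(toy_proteome(seqs))
    rl <- run_length_table(profiles)
    expect_identical(units_from_table(rl),
                     summarize_proteome(profiles)$total_ppp_units)
  }
})

test_that("gene_groups counts genes at nested unit thresholds", {
  profiles <- scan_proteome(toy_proteome(c(
    "MKLV",                      # 0 units
    "APPPA",                     # 1 unit
    "APPPAPPPA",                 # 2 units
    paste(rep("APPP", 5), collapse = "")  # 5 units
  )))
  g <- gene_groups(profiles, "PPP", c(1, 2, 3))
  expect_identical(g$count, c(3L, 2L, 1L))
  expect_equal(g$pct_of_proteome, c(75, 50, 25))
  # nesting
  expect_true(all(g$member_gene_ids[[3]] %in% g$member_gene_ids[[2]]))
  expect_true(all(g$member_gene_ids[[2]] %in% g$member_gene_ids[[1]]))

  zeros <- scan_proteome(toy_proteome(c("MKV", "MAA")))
  expect_identical(gene_groups(zeros, "PPP")$count, c(0L, 0L, 0L))

  all_in <- gene_groups(profiles[-1, ], "PPP", 1)
  expect_equal(all_in$pct_of_proteome, 100)
})

test_that("length_stats matches sort-based order statistics", {
  s <- length_stats(c(1, 2, 3, 4, 5))
  expect_equal(s$min, 1); expect_equal(s$median, 3)
  expect_equal(s$mean, 3); expect_equal(s$max, 5)

  s <- length_stats(c(2, 2, 2, 2))
  expect_equal(unlist(s[c("min", "q1", "median", "mean", "q3", "max")]),
               rep(2, 6), ignore_attr = TRUE)

  # linear interpolation between closest order statistics
  s <- length_stats(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$q1, unname(quantile(1:4, 0.25, type = 7)))
  expect_equal(s$q3, unname(quantile(1:4, 0.75, type = 7)))

  # invariant chain on random data
  set.seed(3)
  x <- sample(50:4000, 200, replace = TRUE)
  s <- length_stats(x)
  expect_true(s$min <= s$q1 && s$q1 <= s$median &&
              s$median <= s$q3 && s$q3 <= s$max)
  expect_true(s$mean >= s$min && s$mean <= s$max)
  expect_error(length_stats(numeric(0)), "no lengths")
})

test_that("aa_composition counts residues and triplet units", {
  prof <- scan_proteome(toy_proteome("AAAPPP"))
  comp <- aa_composition(prof)
  a <- comp[comp$residue == "A", ]
  expect_identical(a$count, 3L)
  expect_equal(a$frequency, 0.5)
  expect_identical(a$triplet_units, 1L)
  expect_identical(comp$triplet_units[comp$residue == "P"], 1L)

  # ambiguity letter breaks the run and lands in "other"
  prof <- scan_proteome(toy_proteome("PPXPP"))
  comp <- aa_composition(prof)
  expect_identical(comp$count[comp$residue == "P"], 4L)
  expect_identical(comp$triplet_units[comp$residue == "P"], 0L)
  expect_identical(comp$count[comp$residue == "other"], 1L)
  expect_identical(sum(comp$count), 5L)
})

test_that("uniform random composition is near 1/20 per residue", {
  set.seed(17)
  letters20 <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
  seqs <- vapply(1:20, function(i)
    paste(sample(letters20, 500, replace = TRUE), collapse = ""), character(1))
  comp <- aa_composition(scan_proteome(toy_proteome(seqs)))
  n <- sum(comp$count)
  sigma <- sqrt(n * (1 / 20) * (19 / 20))
  std <- comp[comp$residue != "other", ]
  expect_true(all(abs(std$count - n / 20) <= 5 * sigma))
})

test_that("frequencies are invariant under proteome duplication", {
  set.seed(31)
  seqs <- vapply(1:15, function(i) random_motif_seq(80), character(1))
  one <- summarize_proteome(scan_proteome(toy_proteome(seqs)))
  two <- summarize_proteome(scan_proteome(toy_proteome(c(seqs, seqs))))
  expect_identical(two$total_ppp_units, 2L * one$total_ppp_units)
  expect_equal(two$ppp_freq_per_1e4, one$ppp_freq_per_1e4)
  expect_equal(two$proline_pct, one$proline_pct)
})

test_that("report rounding is half-up at printed precision", {
  expect_equal(round_half_up(8.275, 2), 8.28)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(90.909, 1), 90.9)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
})
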