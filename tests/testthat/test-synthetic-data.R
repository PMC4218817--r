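test_that("spec validation rejects malformed requests", {
  expect_error(synthetic_proteome_spec(5, planted_runs = data.frame(
    residue = "P", length = 2L, count = 1L)), ">= 3")
  expect_error(synthetic_proteome_spec(5, planted_runs = data.frame(
    residue = "X", length = 3L, count = 1L)), "standard")
  expect_error(aa_background(full = c(A = 1)), "20 standard")
  bad <- rep(0.05, 20); names(bad) <- polyproscan:::AA_STANDARD; bad["A"] <- 0.2
  expect_error(aa_background(full = bad), "20 standard|sum")
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- synthetic_proteome_spec(
    8, lengths = list(kind = "uniform", min = 100, max = 300),
    planted_runs = data.frame(residue = "P", length = 4L, count = 3L),
    ppg_plants = 2L, seed = 42)
  a <- generate_proteome(spec)
  b <- generate_proteome(spec)
  expect_identical(a$proteome, b$proteome)
  expect_identical(a$truth, b$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_proteome_fasta(a$proteome, f1)
  write_proteome_fasta(b$proteome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero-proline background with no plants yields zero everywhere", {
  spec <- synthetic_proteome_spec(
    5, lengths = list(kind = "fixed", length = 150),
    background = aa_background(proline = 0), seed = 2)
  sim <- generate_proteome(spec)
  s <- summarize_proteome(scan_proteome(sim$proteome))
  expect_identical(s$total_ppp_units, 0L)
  expect_identical(s$total_proline, 0L)
  expect_identical(s$total_ppg, 0L)
})

test_that("scanner recovers planted runs exactly on zero-proline background", {
  spec <- synthetic_proteome_spec(
    10, lengths = list(kind = "fixed", length = 200),
    background = aa_background(proline = 0),
    planted_runs = data.frame(residue = "P", length = c(5L, 3L),
                              count = c(3L, 4L)),
    ppg_plants = 3L, seed = 7)
  sim <- generate_proteome(spec)
  profiles <- scan_proteome(sim$proteome)

  expect_identical(sum(profiles$ppp_units), sim$truth$planted_units)
  expect_identical(sum(profiles$ppp_units), 7L) # 3 * floor(5/3) + 4 * floor(3/3)
  expect_identical(sum(profiles$ppg_count), 3L)
  expect_identical(sum(profiles$proline_count), sim$truth$planted_proline)

  # protein-by-protein: recovered run positions equal the planted ones
  runs_truth <- sim$truth$plants[sim$truth$plants$kind == "run", ]
  for (pid in unique(profiles$protein_id)) {
    found <- find_runs(
      sim$proteome$sequence[sim$proteome$protein_id == pid], "P")
    planted <- runs_truth[runs_truth$protein_id == pid, ]
    expect_identical(found$start, planted$start)
    expect_identical(found$length, planted$length)
  }
})

test_that("planted runs of non-proline residues are recovered too", {
  spec <- synthetic_proteome_spec(
    6, lengths = list(kind = "fixed", length = 120),
    background = aa_background(proline = 0),
    planted_runs = data.frame(residue = c("Q", "A"), length = c(7L, 4L),
                              count = c(2L, 2L)), seed = 9)
  sim <- generate_proteome(spec)
  profiles <- scan_proteome(sim$proteome)
  units <- attr(profiles, "triplet_units")
  expect_gte(sum(units[, "Q"]), 2L * 2L) # 2 runs of 7 -> 2 units each
  truth_q <- sim$truth$plants[sim$truth$plants$residue == "Q", ]
  expect_identical(sum(run_units(truth_q$length)), 4L)
})

test_that("an infeasible plant request is a hard error", {
  spec <- synthetic_proteome_spec(
    2, lengths = list(kind = "fixed", length = 40),
    planted_runs = data.frame(residue = "P", length = 30L, count = 5L),
    seed = 1)
  expect_error(generate_proteome(spec), "infeasible")
})

test_that("closed-form expectation matches simulation for background runs", {
  make_spec <- function(seed) synthetic_proteome_spec(
    60, lengths = list(kind = "fixed", length = 400),
    background = aa_background(proline = 0.05), seed = seed)
  ef <- expected_frequencies(make_spec(1), generate_proteome(make_spec(1))$truth)
  obs <- vapply(1:20, function(s) {
    sim <- generate_proteome(make_spec(s))
    as.numeric(sum(scan_proteome(sim$proteome)$ppp_units))
  }, numeric(1))
  sem <- stats::sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - ef$expected_ppp_units), 5 * sem)
})

test_that("expectation is exact with plants only, and scales with duplication", {
  spec <- synthetic_proteome_spec(
    10, lengths = list(kind = "fixed", length = 200),
    background = aa_background(proline = 0),
    planted_runs = data.frame(residue = "P", length = 6L, count = 4L),
    seed = 3)
  sim <- generate_proteome(spec)
  ef <- expected_frequencies(spec, sim$truth)
  expect_equal(ef$expected_ppp_units, 8) # 4 * floor(6/3), no background term

  spec2 <- synthetic_proteome_spec(
    20, lengths = list(kind = "fixed", length = 200),
    background = aa_background(proline = 0),
    planted_runs = data.frame(residue = "P", length = 6L, count = 8L),
    seed = 3)
  ef2 <- expected_frequencies(spec2, generate_proteome(spec2)$truth)
  expect_equal(ef2$expected_ppp_units, 2 * ef$expected_ppp_units)
  expect_equal(ef2$expected_ppp_freq_per_1e4, ef$expected_ppp_freq_per_1e4)
})

test_that("designed ortholog pools are recovered exactly", {
  orth <- generate_ortholog_tables(
    species = c("focal", "s1", "s2", "s3", "s4"),
    shared_fractions = c(0.1, 0.2, 0.4, 0.6),
    genes_per_species = 100, seed = 5)
  sets <- lapply(orth$comparators, function(cm)
    filter_seed_orthologs(orth$tables[[cm]])[[orth$focal]])
  names(sets) <- orth$comparators
  for (j in 1:4) {
    pool <- build_pool(orth$focal, sets[j:4], j)
    expect_identical(pool$member_gene_ids, orth$designed_pools[[j]])
  }
  expect_identical(lengths(orth$designed_pools), c(`1` = 10L, `2` = 20L,
                                                   `3` = 40L, `4` = 60L))
})

test_that("degenerate sharing fractions behave as designed", {
  all_shared <- generate_ortholog_tables(
    c("f", "a", "b"), c(1, 1), genes_per_species = 20, seed = 1)
  expect_identical(lengths(all_shared$designed_pools),
                   c(`1` = 20L, `2` = 20L))

  none_old <- generate_ortholog_tables(
    c("f", "a", "b"), c(0, 0.5), genes_per_species = 20, seed = 1)
  expect_identical(length(none_old$designed_pools[["1"]]), 0L)
  expect_identical(length(none_old$designed_pools[["2"]]), 10L)

  expect_error(generate_ortholog_tables(
    c("f", "a", "b"), c(0.8, 0.2), 20, seed = 1), "infeasible nesting")
})

test_that("written ortholog tables parse back through the pool pipeline", {
  dir <- tempfile()
  orth <- generate_ortholog_tables(
    c("focal", "x", "y"), c(0.2, 0.5), genes_per_species = 40, seed = 11,
    dir = dir)
  for (cm in orth$comparators) {
    rec <- parse_ortholog_table(orth$paths[[cm]], "focal", cm)
    expect_identical(
      filter_seed_orthologs(rec)[["focal"]],
      sort(orth$designed_pools[[which(orth$comparators == cm)]]))
  }
})
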