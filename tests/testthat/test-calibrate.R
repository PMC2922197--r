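test_that("simulate_reads honours the coverage arithmetic and the seed", {
  withr::local_seed(1)
  g <- random_dna_string(10000)
  r <- simulate_reads(g, 50, 5, seed = 3)
  expect_equal(nrow(r), 1000)
  expect_true(all(nchar(r$sequence) == 50))
  r2 <- simulate_reads(g, 50, 5, seed = 3)
  expect_identical(r, r2)
  r3 <- simulate_reads(g, 50, 5, seed = 4)
  expect_false(identical(r$sequence, r3$sequence))

  expect_error(simulate_reads("ACGTACGT", 50, 5), "exceeds genome length")
  expect_warning(simulate_reads(random_dna_string(200), 200, 1e-9, seed = 1),
                 "1 read")
})

test_that("relative efficiency reproduces the 16-residue window geometry", {
  # 50-nt reads: window 16 aa, efficiency (17 - L)/16
  expect_equal(relative_efficiency(17, 50), 0)
  expect_equal(relative_efficiency(1, 50), 1)
  expect_equal(relative_efficiency(9, 50), 0.5)
  for (L in 1:20) {
    expect_equal(relative_efficiency(L, 50), max(0, 17 - L) / 16)
  }
  expect_error(relative_efficiency(0, 50), "L must be")
  expect_error(relative_efficiency(7, 2), "at least 3")
})

test_that("total efficiency averages correctly and approaches 1 with long reads", {
  expect_equal(total_efficiency(c(`7` = 1), 50), 10 / 16)
  unif <- tibble::tibble(length = 7:16, prob = rep(0.1, 10))
  expect_equal(total_efficiency(unif, 50),
               mean((17 - (7:16)) / 16))
  expect_gt(total_efficiency(unif, 3e6), 0.9999)
  lens <- c(50, 75, 100, 150, 200, 400)
  effs <- vapply(lens, function(n) total_efficiency(unif, n), numeric(1))
  expect_true(all(diff(effs) >= 0))
  expect_error(total_efficiency(c(`7` = 0.5), 50), "sum to 1")
  expect_error(total_efficiency(c(`5` = 1), 50), "starts at 7")
})

test_that("raw factors divide hits by genes (per coverage unit)", {
  hits <- tibble::tibble(category = c("6.1.1", "1.1.1"),
                         n_hits = c(98556L, 0L))
  genes <- tibble::tibble(category = c("6.1.1", "1.1.1"),
                          n_genes = c(7752L, 10L))
  ft <- raw_factors(hits, genes)
  expect_equal(round(ft$rf[ft$category == "6.1.1"], 2), 12.71)
  expect_equal(ft$rf[ft$category == "1.1.1"], 0)

  ft2 <- raw_factors(tibble::tibble(category = "6.1.1", n_hits = 260L),
                     tibble::tibble(category = "6.1.1", n_genes = 259L))
  expect_equal(round(ft2$rf, 2), 1.00)

  # coverage scales out
  ft5 <- raw_factors(hits, genes, coverage = 5)
  expect_equal(ft5$rf, ft$rf / 5)

  # hits without an annotated gene stay visible but undivided
  orphan <- raw_factors(tibble::tibble(category = "9.9.9", n_hits = 7L),
                        genes)
  expect_true(is.na(orphan$rf[orphan$category == "9.9.9"]))
})

test_that("normalisation pins the reference at exactly 1 and is idempotent", {
  ft <- raw_factors(tibble::tibble(category = c("6.1.1", "1.1.1"),
                                   n_hits = c(100L, 20L)),
                    tibble::tibble(category = c("6.1.1", "1.1.1"),
                                   n_genes = c(10L, 10L)))
  nf <- normalize_factors(ft)
  expect_identical(nf$nf[nf$category == "6.1.1"], 1)
  expect_equal(nf$nf[nf$category == "1.1.1"], 0.2)
  nf2 <- normalize_factors(nf)
  expect_equal(nf2$nf, nf$nf)

  zero <- raw_factors(tibble::tibble(category = "6.1.1", n_hits = 0L),
                      tibble::tibble(category = "6.1.1", n_genes = 5L))
  expect_error(normalize_factors(zero), "zero")
  expect_error(normalize_factors(ft, reference = "8.8.8"), "absent")
})

test_that("factor tables round-trip through TSV", {
  ft <- raw_factors(tibble::tibble(category = c("6.1.1", "1.1.1"),
                                   n_hits = c(100L, 20L)),
                    tibble::tibble(category = c("6.1.1", "1.1.1"),
                                   n_genes = c(10L, 10L)),
                    coverage = 5, read_length_nt = 50)
  ft <- normalize_factors(ft)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_factor_table(ft, tf)
  back <- read_factor_table(tf)
  expect_equal(as.data.frame(back), as.data.frame(ft))
  expect_equal(attr(back, "read_length"), 50)
  expect_equal(attr(back, "reference"), "6.1.1")
})

test_that("super-organism training yields per-EC means with seed-stable output", {
  fx <- build_fixture(fixture_spec(
    n_genomes = 4, genome_length_nt = 8000,
    genes_per_ec = c("1.1.1" = 4, "6.1.1" = 4),
    sps_per_gene = 2, seed = 19
  ))
  ft <- train_factors(fx$genomes, fx$dictionary, k = 2, n_combinations = 3,
                      read_length_nt = 50, coverage = 5, seed = 5)
  expect_s3_class(ft, "factor_table")
  expect_setequal(ft$category, c("1.1.1", "6.1.1"))
  expect_identical(ft$nf[ft$category == "6.1.1"], 1)
  expect_identical(ft$nf_sd[ft$category == "6.1.1"], 0)
  expect_true(all(ft$rf >= 0))
  ft_again <- train_factors(fx$genomes, fx$dictionary, k = 2,
                            n_combinations = 3, read_length_nt = 50,
                            coverage = 5, seed = 5)
  expect_equal(as.data.frame(ft_again), as.data.frame(ft))

  # single combination: no spread to estimate
  ft1 <- train_factors(fx$genomes, fx$dictionary, k = 2, n_combinations = 1,
                       read_length_nt = 50, coverage = 5, seed = 5)
  expect_true(all(ft1$rf_sd == 0))
  expect_error(train_factors(fx$genomes, fx$dictionary, k = 9), "exceeds")
  expect_error(train_factors(fx$genomes, fx$dictionary, k = 2,
                             n_combinations = 100), "choose")
})

test_that("finite-read factors rise with read length toward the asymptote", {
  fx <- build_fixture(fixture_spec(
    n_genomes = 1, genome_length_nt = 15000,
    genes_per_ec = c("1.1.1" = 8, "6.1.1" = 8),
    sps_per_gene = 2, seed = 23
  ))
  g <- fx$genomes[[1]]
  counts <- enzyme_counts(g)
  m <- sp_matcher(fx$dictionary)
  rf_at <- function(len) {
    reads <- simulate_reads(g, len, 10, seed = 41)
    tab <- hit_table(scan_reads(reads, m, warn_length = FALSE))
    ft <- raw_factors(tab, counts, coverage = 10)
    mean(ft$rf)
  }
  rf50 <- rf_at(50)
  rf200 <- rf_at(200)
  asym <- fx$truth$sps_per_gene
  expect_gt(rf200, rf50)
  expect_lt(rf50, asym)
  expect_lt(rf200, asym)
})
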