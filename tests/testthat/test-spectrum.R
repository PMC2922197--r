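make_factor_table <- function(cats, rf, read_length = 50) {
  ft <- raw_factors(
    tibble::tibble(category = cats, n_hits = as.integer(rf * 10)),
    tibble::tibble(category = cats, n_genes = rep(10L, length(cats))),
    read_length_nt = read_length
  )
  ft
}

test_that("spectrum prediction divides hits by factors and normalises to reference", {
  ft <- make_factor_table(c("6.1.1", "1.1.1"), c(2.0, 0.5))
  hits <- tibble::tibble(category = c("6.1.1", "1.1.1"),
                         n_hits = c(120L, 30L))
  sp <- predict_spectrum(hits, ft)
  expect_equal(sp$predicted[sp$category == "6.1.1"], 60)
  expect_equal(sp$predicted[sp$category == "1.1.1"], 60)
  expect_equal(sp$relative[sp$category == "1.1.1"], 1)
  # about 20 aaRS genes per genome: 60 predicted ~ three genome equivalents
  expect_equal(cells_estimate(sp), 3)

  # known coverage rescales to true gene counts
  sp5 <- predict_spectrum(hits, ft, coverage = 5)
  expect_equal(sp5$predicted[sp5$category == "6.1.1"], 12)
})

test_that("uncalibrated categories are reported, not dropped; missing reference warns", {
  ft <- make_factor_table("6.1.1", 2.0)
  hits <- tibble::tibble(category = c("6.1.1", "9.9.9"),
                         n_hits = c(10L, 5L))
  sp <- predict_spectrum(hits, ft)
  expect_true("9.9.9" %in% sp$category)
  expect_true(sp$uncalibrated[sp$category == "9.9.9"])

  hits2 <- tibble::tibble(category = "1.1.1", n_hits = 10L)
  ft2 <- make_factor_table(c("6.1.1", "1.1.1"), c(2, 1))
  expect_warning(sp2 <- predict_spectrum(hits2, ft2), "reference")
  expect_true(all(is.na(sp2$relative)))
  expect_equal(sp2$predicted[sp2$category == "1.1.1"], 10)
  expect_equal(cells_estimate(sp2), 0)
})

test_that("chi-square fit matches its definition and guards zero sd", {
  p <- c(a = 10, b = 20, c = 30)
  expect_equal(chi_square_fit(p, p, c(a = 1, b = 1, c = 1))$chi2_per_dof, 0)
  off <- p + c(1, -1, 1)
  fit <- chi_square_fit(off, p, c(a = 1, b = 1, c = 1))
  expect_equal(fit$chi2_per_dof, 1)
  expect_equal(fit$n_dof, 3)
  expect_equal(nrow(tidy(fit)), 3)
  expect_equal(glance(fit)$chi2, 3)
  expect_error(chi_square_fit(off, p, c(a = 0, b = 1, c = 1)), "sd = 0")
  expect_equal(chi_square_fit(p, p, c(a = 0, b = 1, c = 1))$chi2_per_dof, 0)
  expect_error(chi_square_fit(c(x = 1), c(y = 1), c(z = 1)), "common")
})

test_that("doubling the read set doubles predictions but not the relative spectrum", {
  fx <- build_fixture(fixture_spec(
    n_genomes = 1, genome_length_nt = 15000,
    genes_per_ec = c("1.1.1" = 8, "2.7.7" = 4, "6.1.1" = 8),
    sps_per_gene = 2, seed = 29
  ))
  g <- fx$genomes[[1]]
  m <- sp_matcher(fx$dictionary)
  counts <- enzyme_counts(g)
  cal_reads <- simulate_reads(g, 50, 10, seed = 61)
  ft <- raw_factors(hit_table(scan_reads(cal_reads, m, warn_length = FALSE)),
                    counts, coverage = 10, read_length_nt = 50)

  r1 <- simulate_reads(g, 50, 4, seed = 62)
  r2 <- dplyr::bind_rows(r1, dplyr::mutate(
    simulate_reads(g, 50, 4, seed = 63),
    id = paste0(id, "_b")
  ))
  s1 <- predict_spectrum(hit_table(scan_reads(r1, m, warn_length = FALSE)), ft)
  s2 <- predict_spectrum(hit_table(scan_reads(r2, m, warn_length = FALSE)), ft)
  j <- dplyr::inner_join(as_tibble(s1), as_tibble(s2), by = "category",
                         suffix = c("_1", "_2"))
  expect_equal(j$predicted_2 / j$predicted_1, rep(2, nrow(j)),
               tolerance = 0.25)
  expect_equal(j$relative_2, j$relative_1, tolerance = 0.2)
})

test_that("heterogeneous read lengths trigger the calibration-transfer warning", {
  withr::local_seed(71)
  d <- sp_dictionary("ACDEFGHIK", "6.1.1")
  reads <- tibble::tibble(
    id = c("a", "b"),
    sequence = c(make_sp_read("ACDEFGHIK", flank = 12),
                 paste0(make_sp_read("ACDEFGHIK", flank = 12),
                        random_dna_string(147)))
  )
  hits <- scan_reads(reads, d, warn_length = FALSE)
  ft <- make_factor_table("6.1.1", 2)
  expect_warning(predict_spectrum(hit_table(hits), ft), "heterogeneous")
})

test_that("spectrum writers emit TSV and JSON reports", {
  ft <- make_factor_table(c("6.1.1", "1.1.1"), c(2, 1))
  sp <- predict_spectrum(tibble::tibble(category = c("6.1.1", "1.1.1"),
                                        n_hits = c(40L, 10L)), ft)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, tsv)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 2)
  jf <- withr::local_tempfile(fileext = ".json")
  write_spectrum_json(sp, jf)
  expect_equal(jsonlite::read_json(jf)$reference, "6.1.1")
})

test_that("autoplot methods return ggplot objects", {
  ft <- make_factor_table(c("6.1.1", "1.1.1"), c(2, 1))
  sp <- predict_spectrum(tibble::tibble(category = c("6.1.1", "1.1.1"),
                                        n_hits = c(40L, 10L)), ft)
  expect_s3_class(autoplot(sp), "ggplot")
  expect_s3_class(autoplot(normalize_factors(ft)), "ggplot")
  mix <- predict_taxon_mixture(
    tibble::tibble(category = c("Bacteria", "Archaea"),
                   n_hits = c(1271L, 2L)),
    s61_taxon_factors()
  )
  expect_s3_class(autoplot(mix), "ggplot")
})
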