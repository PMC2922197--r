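test_that("matcher reports tandem and overlapping occurrences", {
  d <- sp_dictionary("ACDEFGH", "1.1.1")
  m <- sp_matcher(d)
  hits <- find_sp_hits("ACDEFGHACDEFGH", m)
  expect_equal(sort(hits$offset_aa), c(0L, 7L))

  d2 <- sp_dictionary("AAAAAAA", "1.1.1")
  hits2 <- find_sp_hits("AAAAAAAA", sp_matcher(d2))
  expect_equal(sort(hits2$offset_aa), c(0L, 1L))

  expect_error(sp_matcher(sp_dictionary(character(0), character(0))),
               "empty dictionary")
})

test_that("matcher equals the naive sliding-window oracle on random instances", {
  withr::local_seed(17)
  for (rep in 1:40) {
    # small alphabet raises collision/overlap rates
    alpha <- strsplit("ACDEF", "")[[1]]
    peps <- unique(replicate(12, random_aa_string(sample(7:12, 1), alpha)))
    d <- sp_dictionary(peps, rep("1.1.1", length(peps)))
    query <- random_aa_string(150, alpha)
    # plant a couple of patterns to guarantee hits
    query <- paste0(query, peps[1], peps[1], substring(peps[2], 1, 6))
    got <- find_sp_hits(query, sp_matcher(d))
    want <- naive_scan(d$peptide, query)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$peptide, got$offset_aa + 1L),
                    paste(want$pattern, want$start))
  }
})

test_that("scan_reads finds planted SPs and aggregates at EC level 3", {
  withr::local_seed(30)
  d <- sp_dictionary(c("NSISISGYH", "ISISGYHMQEAG"),
                     c("5.4.99.2", "5.4.99.2"))
  read <- make_sp_read("NSISISGYH", flank = 12)
  hits <- scan_reads(c(r1 = read), d, warn_length = FALSE)
  expect_equal(nrow(hits), 1)
  tab <- hit_table(hits)
  expect_equal(tab$category, "5.4.99")
  expect_equal(tab$n_hits, 1L)

  # the merged 14-mer carries both overlapping SPs: two occurrences
  both <- make_sp_read("NSISISGYHMQEAG", flank = 6)
  tab2 <- hit_table(scan_reads(c(r1 = both), d, warn_length = FALSE))
  expect_equal(tab2$n_hits, 2L)
  expect_equal(tab2$n_sps, 2L)

  # an SP split across two reads is lost: hits must lie entirely inside
  # a pseudo-peptide
  enc <- encode_first_codon("NSISISGYH")
  left <- paste0(random_dna_string(40), substr(enc, 1, 13))
  right <- paste0(substr(enc, 14, nchar(enc)), random_dna_string(40))
  hits3 <- scan_reads(tibble::tibble(id = c("a", "b"),
                                     sequence = c(left, right)),
                      d, warn_length = FALSE)
  expect_equal(nrow(hits3), 0)
})

test_that("hit counts are invariant to read reverse-complementation and frame shifts", {
  withr::local_seed(31)
  d <- sp_dictionary(c("ACDEFGHIK", "MNPQRSTVW"), c("1.1.1", "2.7.7"))
  reads <- tibble::tibble(
    id = c("a", "b", "c"),
    sequence = c(make_sp_read("ACDEFGHIK", 15),
                 make_sp_read("MNPQRSTVW", 15, strand = "-"),
                 random_dna_string(60))
  )
  tab <- hit_table(scan_reads(reads, d, warn_length = FALSE))
  rc <- dplyr::mutate(reads, sequence = reverse_complement(sequence))
  tab_rc <- hit_table(scan_reads(rc, d, warn_length = FALSE))
  expect_equal(as.data.frame(tab), as.data.frame(tab_rc))

  # prepending 3m bases shifts frame-0 offsets by m residues, same count
  shifted <- dplyr::mutate(reads,
                           sequence = paste0(random_dna_string(9), sequence))
  tab_sh <- hit_table(scan_reads(shifted, d, warn_length = FALSE))
  expect_equal(tab_sh$n_hits, tab$n_hits)
})

test_that("read-level counting collapses multiple occurrences per read", {
  withr::local_seed(32)
  d <- sp_dictionary("ACDEFGHIK", "1.1.1")
  enc <- encode_first_codon("ACDEFGHIK")
  read <- paste0(random_dna_string(6), enc, random_dna_string(6), enc)
  hits <- scan_reads(c(r = read), d, warn_length = FALSE)
  expect_equal(hit_table(hits)$n_hits, 2L)
  expect_equal(hit_table(hits, count = "reads")$n_hits, 1L)
})

test_that("anomaly flagging detects few-SP-dominated categories only", {
  dominated <- tibble::tibble(
    category = c("5.4.99", paste0("1.1.", 1:9)),
    n_hits = c(461L, rep(40L, 9)),
    n_sps = c(2L, rep(5L, 9))
  )
  flags <- flag_anomalies(dominated)
  expect_equal(flags$category, "5.4.99")
  expect_equal(flags$n_hits, 461L)

  uniform <- tibble::tibble(category = paste0("1.1.", 1:10),
                            n_hits = rep(40L, 10), n_sps = rep(3L, 10))
  expect_equal(nrow(flag_anomalies(uniform)), 0)

  # dominance by many distinct SPs is genuine signal, not an anomaly
  broad <- dplyr::mutate(dominated, n_sps = c(30L, rep(5L, 9)))
  expect_equal(nrow(flag_anomalies(broad)), 0)

  single <- tibble::tibble(category = "1.1.1", n_hits = 500L, n_sps = 1L)
  expect_equal(nrow(flag_anomalies(single)), 0)
})

test_that("hit table counts sum to the number of hit records", {
  withr::local_seed(33)
  d <- sp_dictionary(c("ACDEFGHIK", "MNPQRSTVW", "GHIKLMNPQ"),
                     c("1.1.1", "2.7.7.1", "2.7.7"))
  reads <- tibble::tibble(
    id = as.character(1:6),
    sequence = c(make_sp_read("ACDEFGHIK"), make_sp_read("MNPQRSTVW"),
                 make_sp_read("GHIKLMNPQ"), make_sp_read("ACDEFGHIK", strand = "-"),
                 random_dna_string(50), random_dna_string(50))
  )
  hits <- scan_reads(reads, d, warn_length = FALSE)
  tab <- hit_table(hits)
  expect_equal(sum(tab$n_hits), nrow(hits))
  # level-4 labels roll up into their level-3 parent
  expect_true(all(tab$category %in% c("1.1.1", "2.7.7")))
  expect_equal(attr(tab, "n_reads"), 6)
})

test_that("hit stream and table writers produce readable files", {
  withr::local_seed(34)
  d <- sp_dictionary("ACDEFGHIK", "1.1.1")
  hits <- scan_reads(c(r = make_sp_read("ACDEFGHIK")), d, warn_length = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, tsv)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), nrow(hits))
  jf <- withr::local_tempfile(fileext = ".json")
  write_hit_table_json(hit_table(hits), jf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$counts[[1]]$category, "1.1.1")
})
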