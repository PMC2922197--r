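#' Annotated genome container
#'
#' Bundles a genome sequence with its gene annotation: a tibble with
#' columns `gene_id`, `start`, `end` (1-based, inclusive), `strand`
#' (`"+"`/`"-"`) and `ec`. Enzyme counts per level-3 EC category are
#' derived from the annotation and used as the calibration denominator.
#'
#' @param sequence genome nucleotide string.
#' @param genes annotation tibble (`gene_id`, `start`, `end`, `strand`,
#'   `ec`).
#' @param id genome identifier.
#' @param taxon optional list with `rank`, `name` (and optionally
#'   `lineage`) assigning the genome to a taxon.
#' @return an `annotated_genome` object.
#' @export
annotated_genome <- function(sequence, genes, id = "genome",
                             taxon = NULL) {
  sequence <- toupper(sequence)
  check_nucleotides(sequence)
  genes <- as_tibble(genes)
  need <- c("gene_id", "start", "end", "strand", "ec")
  if (!all(need %in% names(genes))) {
    abort(paste0("gene annotation needs columns: ",
                 paste(need, collapse = ", ")))
  }
  if (nrow(genes)) {
    ec_parse(genes$ec)
    if (any(genes$start < 1 | genes$end > nchar(sequence))) {
      abort(sprintf("gene coordinates outside genome '%s' (length %d)",
                    id, nchar(sequence)))
    }
  }
  structure(list(id = id, sequence = sequence, genes = genes,
                 taxon = taxon),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d nt, %d genes, %d EC categories\n",
              x$id, nchar(x$sequence), nrow(x$genes),
              length(unique(ec_level3(x$genes$ec)))))
  invisible(x)
}

#' Enzyme-gene counts per level-3 EC category
#'
#' @param genomes an `annotated_genome` or a list of them; counts are
#'   pooled over the list (the "super-organism" view of a metagenome).
#' @return a tibble with columns `category`, `n_genes`.
#' @export
enzyme_counts <- function(genomes) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  purrr::map(genomes, function(g) {
    tibble(category = ec_level3(g$genes$ec))
  }) |>
    bind_rows() |>
    count(.data$category, name = "n_genes")
}

#' Read an annotated genome from FASTA + annotation TSV
#'
#' The annotation TSV has a header and columns `gene_id`, `start`, `end`,
#' `strand`, `ec`, with 1-based inclusive coordinates.
#'
#' @param fasta_path genome FASTA (single record).
#' @param annotation_path annotation TSV.
#' @param taxon optional taxon assignment (list with `rank`, `name`).
#' @return an `annotated_genome`.
#' @export
read_annotated_genome <- function(fasta_path, annotation_path, taxon = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1) {
    abort(sprintf("expected a single-record genome FASTA, got %d records",
                  length(seqs)))
  }
  ann <- readr::read_tsv(annotation_path, col_types = "ciicc",
                         progress = FALSE)
  annotated_genome(as.character(seqs[[1]]), ann,
                   id = sub("\\s.*$", "", names(seqs)[1]), taxon = taxon)
}

#' Simulate uniform shotgun short reads from a genome
#'
#' Fragments a genome into single-strand reads of fixed length with
#' uniformly random, independent start positions (sampling with
#' replacement). The number of reads is `ceiling(coverage * genome_length /
#' read_length)`; six-frame search downstream restores strand symmetry, so
#' reads are drawn from the forward strand only. No sequencing-error model
#' is applied.
#'
#' @param genome nucleotide string or `annotated_genome`.
#' @param read_length_nt read length in nucleotides.
#' @param coverage mean number of times each base is sampled.
#' @param seed integer seed; the same seed reproduces the same read set.
#' @return a tibble with columns `id`, `sequence`.
#' @examples
#' g <- paste(rep("ACGT", 250), collapse = "")
#' nrow(simulate_reads(g, 50, 5, seed = 1))  # ceiling(5 * 1000 / 50) = 100
#' @export
simulate_reads <- function(genome, read_length_nt, coverage, seed = 1L) {
  if (inherits(genome, "annotated_genome")) genome <- genome$sequence
  genome <- toupper(genome)
  glen <- nchar(genome)
  if (read_length_nt > glen) {
    abort(sprintf("read length %d exceeds genome length %d",
                  read_length_nt, glen))
  }
  if (coverage <= 0) abort("coverage must be positive")
  n_expected <- coverage * glen / read_length_nt
  n_reads <- ceiling(n_expected)
  if (n_expected < 1) {
    warn("coverage so low that less than 1 read is expected; emitting 1 read")
    n_reads <- 1L
  }
  withr::with_seed(seed, {
    starts <- sample.int(glen - read_length_nt + 1L, n_reads, replace = TRUE)
  })
  tibble(
    id = sprintf("read_%06d", seq_len(n_reads)),
    sequence = substring(genome, starts, starts + read_length_nt - 1L)
  )
}

#' Geometric detection efficiency of an SP inside a short read
#'
#' A read of `n` nucleotides offers a window of `W = floor(n/3)` residues
#' per frame; an SP of `L` amino acids fits at `W - L + 1` positions, so
#' its relative detection efficiency is `max(0, W - L + 1)/W`. For 50-nt
#' reads `W = 16` and the expression reduces to `(17 - L)/16`: no SP longer
#' than 16 residues can ever be seen in a 50-nt read.
#'
#' @param L SP length(s) in amino acids (`>= 1`).
#' @param read_length_nt read length in nucleotides (`>= 3`).
#' @return efficiency in `[0, 1]`, vectorised over `L`.
#' @examples
#' relative_efficiency(9, 50)   # (17 - 9)/16 = 0.5
#' relative_efficiency(17, 50)  # 0: cannot fit
#' @export
relative_efficiency <- function(L, read_length_nt) {
  if (read_length_nt < 3) abort("read_length_nt must be at least 3")
  if (any(L < 1)) abort("SP length L must be >= 1")
  W <- read_length_nt %/% 3
  pmax(0, W - L + 1) / W
}

#' Total detection efficiency for an SP-length distribution
#'
#' The expectation of [relative_efficiency()] under the dictionary's
#' SP-length distribution: the fraction of SP occurrences in the underlying
#' genomes that reads of the given length can reveal. Monotonically
#' non-decreasing in read length, with limit 1.
#'
#' @param sp_length_distribution a named numeric vector (names = lengths in
#'   aa, values = probabilities summing to 1, support at `L >= 7`) or a
#'   tibble with columns `length`, `prob`.
#' @param read_length_nt read length in nucleotides.
#' @return scalar efficiency in `[0, 1]`.
#' @export
total_efficiency <- function(sp_length_distribution, read_length_nt) {
  d <- sp_length_distribution
  if (is.data.frame(d)) {
    lens <- d$length
    probs <- d$prob
  } else {
    lens <- as.numeric(names(d))
    probs <- as.numeric(d)
  }
  if (any(is.na(lens))) abort("length distribution must be named by length")
  if (abs(sum(probs) - 1) > 1e-8) abort("probabilities must sum to 1")
  if (any(lens < 7)) abort("SP length support starts at 7 aa")
  sum(probs * relative_efficiency(lens, read_length_nt))
}

#' Empirical SP-length distribution of a dictionary
#'
#' @param dict an `sp_dictionary`.
#' @return tibble with columns `length`, `prob`.
#' @export
sp_length_distribution <- function(dict) {
  df <- as_tibble(dict)
  tab <- table(nchar(df$peptide))
  tibble(length = as.integer(names(tab)),
         prob = as.numeric(tab) / sum(tab))
}

new_factor_table <- function(df, read_length, reference = "6.1.1") {
  df <- as_tibble(df)
  class(df) <- unique(c("factor_table", class(df)))
  attr(df, "read_length") <- read_length
  attr(df, "reference") <- reference
  df
}

#' Raw calibration factors from a hit table
#'
#' The raw factor of an EC category, `RF(EC) = (SP hits)/(enzymatic
#' genes)`, converts hit counts into gene counts. Because hit counts scale
#' linearly with sequencing depth, factors derived from simulated reads are
#' expressed per 1x genome equivalent by dividing by the simulated
#' `coverage`; factors from a full-genome (unfragmented) scan use
#' `coverage = 1` and equal the average number of SP hits per annotated
#' enzyme — the asymptotic value that finite-read factors approach from
#' below as reads lengthen. Categories with hits but no annotated gene are
#' kept with `rf = NA` rather than divided by zero.
#'
#' @param hits a `hit_table` keyed by EC category (or any tibble with
#'   `category`, `n_hits`).
#' @param enzyme_counts tibble with `category`, `n_genes` (see
#'   [enzyme_counts()]).
#' @param coverage sequencing depth of the read set the hits came from.
#' @param read_length_nt read length recorded in the table
#'   (`"asymptotic"` for full-genome scans).
#' @return a `factor_table` tibble with columns `category`, `n_hits`,
#'   `n_genes`, `rf`.
#' @export
raw_factors <- function(hits, enzyme_counts, coverage = 1,
                        read_length_nt = "asymptotic") {
  df <- as_tibble(hits)[, c("category", "n_hits")]
  full <- dplyr::full_join(df, as_tibble(enzyme_counts), by = "category")
  full$n_hits[is.na(full$n_hits)] <- 0L
  full$rf <- ifelse(is.na(full$n_genes) | full$n_genes == 0,
                    NA_real_,
                    full$n_hits / coverage / full$n_genes)
  new_factor_table(arrange(full, .data$category), read_length_nt)
}

#' Normalise factors to a reference EC category
#'
#' Divides every raw factor by the reference category's (default 6.1.1, the
#' aminoacyl-tRNA synthetases — the largest factor, since aaRS enzymes are
#' near-universal and SP-rich). Normalised factors are approximately
#' read-length invariant, which is what makes them transferable across read
#' sets of different lengths. Idempotent.
#'
#' @param ft a `factor_table` with an `rf` column.
#' @param reference reference EC category (level 3).
#' @return the `factor_table` with an `nf` column added;
#'   `nf[reference] == 1` exactly.
#' @export
normalize_factors <- function(ft, reference = "6.1.1") {
  df <- as_tibble(ft)
  ref <- df$rf[df$category == reference]
  if (length(ref) != 1 || is.na(ref) || ref == 0) {
    abort(sprintf(
      "reference category %s absent or has zero/unknown raw factor", reference
    ))
  }
  df$nf <- df$rf / ref
  if ("nf_sd" %in% names(df)) df$nf_sd[df$category == reference] <- 0
  new_factor_table(df, attr(ft, "read_length"), reference)
}

simulate_pool_reads <- function(genomes, read_length_nt, coverage, seed) {
  purrr::imap(genomes, function(g, i) {
    r <- simulate_reads(g$sequence, read_length_nt, coverage,
                        seed = seed + 7919L * (as.integer(i) - 1L))
    r$id <- paste0(g$id, ":", r$id)
    r
  }) |> bind_rows()
}

#' Train calibration factors on super-organism combinations
#'
#' Pools random combinations of `k` annotated genomes into artificial
#' metagenomes ("super-organisms"), fragments each into reads at the given
#' coverage, counts SP hits, and computes raw and normalised factors per
#' combination. The returned table reports per-category means and sample
#' standard deviations (`ddof = 1`) over combinations — the standard
#' deviations are the error bars later used in chi-square fit diagnostics.
#' Combinations are sampled uniformly without replacement among the
#' `choose(n, k)` subsets. Categories absent from a combination's
#' annotation are skipped for that combination.
#'
#' @param genomes list of `annotated_genome` objects.
#' @param dict an `sp_dictionary`.
#' @param k genomes per super-organism.
#' @param n_combinations number of super-organisms to sample.
#' @param read_length_nt,coverage read-simulation settings.
#' @param seed integer seed controlling both combination sampling and read
#'   simulation.
#' @param reference reference category for normalisation.
#' @return a `factor_table` with columns `category`, `n_genes` (mean over
#'   combinations), `rf`, `rf_sd`, `nf`, `nf_sd`, `n_combinations`.
#' @export
train_factors <- function(genomes, dict, k = 7L, n_combinations = 15L,
                          read_length_nt = 50L, coverage = 5,
                          seed = 1L, reference = "6.1.1") {
  n <- length(genomes)
  if (k > n) abort("k exceeds the number of genomes")
  if (n_combinations > choose(n, k)) {
    abort(sprintf("n_combinations exceeds choose(%d, %d) = %d",
                  n, k, choose(n, k)))
  }
  combos <- withr::with_seed(seed, {
    seen <- character(0)
    out <- list()
    while (length(out) < n_combinations) {
      cand <- sort(sample.int(n, k))
      key <- paste(cand, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- cand
      }
    }
    out
  })
  matcher <- sp_matcher(dict)
  per_combo <- purrr::imap(combos, function(idx, ci) {
    pool <- genomes[idx]
    reads <- simulate_pool_reads(pool, read_length_nt, coverage,
                                 seed = seed + 104729L * as.integer(ci))
    tab <- hit_table(scan_reads(reads, matcher, warn_length = FALSE))
    ft <- raw_factors(tab, enzyme_counts(pool), coverage = coverage,
                      read_length_nt = read_length_nt)
    ft <- normalize_factors(ft, reference)
    mutate(as_tibble(ft), combo = ci)
  })
  stats_tbl <- bind_rows(per_combo) |>
    filter(!is.na(.data$rf)) |>
    group_by(.data$category) |>
    summarise(
      n_genes = mean(.data$n_genes),
      rf_sd = if (n() > 1) stats::sd(.data$rf) else 0,
      rf = mean(.data$rf),
      nf_sd = if (n() > 1) stats::sd(.data$nf) else 0,
      nf = mean(.data$nf),
      n_combinations = n(),
      .groups = "drop"
    ) |>
    select("category", "n_genes", "rf", "rf_sd", "nf", "nf_sd",
           "n_combinations")
  stats_tbl$nf[stats_tbl$category == reference] <- 1
  stats_tbl$nf_sd[stats_tbl$category == reference] <- 0
  new_factor_table(stats_tbl, read_length_nt, reference)
}

#' Read and write factor tables
#'
#' TSV round-trip for `factor_table` objects; columns are `category` plus
#' whichever of `n_hits`, `n_genes`, `rf`, `rf_sd`, `nf`, `nf_sd`,
#' `n_combinations` are present, with `read_length` and `reference`
#' repeated per row for self-containment.
#'
#' @param ft a `factor_table`.
#' @param path file path.
#' @return `write_factor_table()` returns `path` invisibly;
#'   `read_factor_table()` returns a `factor_table`.
#' @export
write_factor_table <- function(ft, path) {
  df <- as_tibble(ft)
  df$read_length <- as.character(attr(ft, "read_length"))
  df$reference <- attr(ft, "reference")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_factor_table
#' @export
read_factor_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    category = "c", read_length = "c", reference = "c", .default = "d"
  ), progress = FALSE)
  rl <- unique(df$read_length)
  ref <- unique(df$reference)
  if (length(rl) != 1 || length(ref) != 1) {
    abort("factor table mixes read lengths or references")
  }
  rl_num <- suppressWarnings(as.numeric(rl))
  df$read_length <- NULL
  df$reference <- NULL
  new_factor_table(df, if (is.na(rl_num)) rl else rl_num, ref)
}

#' @export
print.factor_table <- function(x, ...) {
  cat(sprintf("<factor_table> read length %s, reference %s\n",
              as.character(attr(x, "read_length")),
              attr(x, "reference")))
  NextMethod()
  invisible(x)
}
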