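#' Default SP-length distribution for synthetic dictionaries
#'
#' Short deterministic motifs are dominated by the shortest admissible
#' lengths; the generator's default halves the probability per extra
#' residue over the 7-16 aa support (16 aa being the longest SP a 50-nt
#' read can reveal).
#'
#' @return a tibble with columns `length`, `prob` summing to 1.
#' @export
default_sp_length_distribution <- function() {
  w <- 2^-(0:9)
  tibble(length = 7:16, prob = w / sum(w))
}

#' Random peptide generator for synthetic dictionaries
#'
#' Draws a peptide uniformly over the 20-letter alphabet, rejecting
#' candidates that contain, or are contained in, any peptide of `avoid`
#' (so no dictionary member is a substring of another, and counts stay
#' unambiguous). Uses the current RNG state; seed the caller for
#' determinism.
#'
#' @param length peptide length (`>= 7`).
#' @param avoid character vector of peptides to stay clear of.
#' @return an amino-acid string.
#' @export
random_peptide <- function(length, avoid = character()) {
  if (length < 7) abort("synthetic SPs must be at least 7 aa")
  repeat {
    cand <- paste(sample(AA20, length, replace = TRUE), collapse = "")
    clash <- length(avoid) && any(
      stringr::str_detect(cand, stringr::fixed(avoid)) |
        stringr::str_detect(avoid, stringr::fixed(cand))
    )
    if (!clash) return(cand)
  }
}

REV_CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

encode_peptide <- function(peptide) {
  aa <- strsplit(peptide, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- REV_CODON[[a]]
    cods[sample.int(length(cods), 1)]
  }, character(1), USE.NAMES = FALSE), collapse = "")
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Specification for a synthetic fixture
#'
#' Describes a set of toy genomes with planted, EC-annotated genes that
#' encode known Specific Peptides — the ground truth against which every
#' pipeline stage can be checked without external data.
#'
#' Every gene of an EC category encodes exactly `sps_per_gene` SP
#' occurrences, so the asymptotic raw factor of every category equals
#' `sps_per_gene` by construction. When `sps_per_ec` exceeds
#' `sps_per_gene` and `genome_sp_bias` is `TRUE`, each genome draws its
#' genes' SPs from the category pool with genome-specific weights —
#' emulating organisms whose enzymes carry different subsets of a
#' category's marker peptides, the between-organism variability that makes
#' metagenomic pooling smoother than single-genome prediction.
#'
#' @param n_genomes number of genomes.
#' @param genome_length_nt approximate genome length (background fills the
#'   space between genes; at least 250 nt of gene-free margin is kept at
#'   each end so read sampling near the edges is unbiased).
#' @param genes_per_ec named integer vector (`EC -> genes per genome`), or
#'   a list of such vectors, one per genome, for heterogeneous
#'   compositions.
#' @param sps_per_gene number of SP occurrences encoded by every gene.
#' @param sps_per_ec size of each EC's SP pool (default `sps_per_gene`).
#' @param genome_sp_bias draw each gene's SPs from the pool with
#'   genome-specific weights (default `FALSE`: every gene encodes the
#'   first `sps_per_gene` pool members once each).
#' @param sp_lengths SP length distribution (tibble `length`, `prob`).
#' @param taxa optional character vector (length `n_genomes`) of taxon
#'   names per genome, for taxon-specific fixtures.
#' @param taxon_rank rank of `taxa` (default `"phylum"`).
#' @param taxon_genes named integer vector (`level-4 aaRS EC -> genes per
#'   genome`) of taxon-marker genes planted in each taxon-labelled genome;
#'   each taxon gets its own TSP set.
#' @param seed integer seed; the entire fixture is a deterministic function
#'   of the spec.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_genomes = 5L, genome_length_nt = 20000L,
                         genes_per_ec = c("1.1.1" = 10L, "2.7.7" = 8L,
                                          "3.6.1" = 6L, "6.1.1" = 10L),
                         sps_per_gene = 2L, sps_per_ec = NULL,
                         genome_sp_bias = FALSE,
                         sp_lengths = default_sp_length_distribution(),
                         taxa = NULL, taxon_rank = "phylum",
                         taxon_genes = NULL, seed = 1L) {
  if (is.list(genes_per_ec) && length(genes_per_ec) != n_genomes) {
    abort("genes_per_ec list must have one element per genome")
  }
  if (!is.null(taxa) && length(taxa) != n_genomes) {
    abort("taxa must have one entry per genome")
  }
  sps_per_ec <- sps_per_ec %||% sps_per_gene
  if (sps_per_ec < sps_per_gene && !genome_sp_bias) {
    abort("sps_per_ec must be >= sps_per_gene")
  }
  structure(list(
    n_genomes = n_genomes, genome_length_nt = genome_length_nt,
    genes_per_ec = genes_per_ec, sps_per_gene = sps_per_gene,
    sps_per_ec = sps_per_ec, genome_sp_bias = genome_sp_bias,
    sp_lengths = as_tibble(sp_lengths), taxa = taxa,
    taxon_rank = taxon_rank, taxon_genes = taxon_genes, seed = seed
  ), class = "fixture_spec")
}

sample_sp_length <- function(sp_lengths) {
  sample(sp_lengths$length, 1, prob = sp_lengths$prob)
}

# gene_plan: tibble(ec, sp_rows = list of dict_rows row indices)
build_one_genome <- function(id, gene_plan, dict_df, genome_length_nt,
                             matcher, max_tries = 25L) {
  margin <- 250L
  gene_nt <- vapply(gene_plan$sp_rows, function(rows) {
    sum(nchar(dict_df$peptide[rows])) * 3L
  }, numeric(1))
  n_gaps <- nrow(gene_plan) + 1L
  budget <- genome_length_nt - sum(gene_nt) - 2L * margin
  if (budget < n_gaps * 20L) {
    abort("infeasible packing: genome_length_nt too small for planted genes")
  }
  expected <- tibble(peptide = dict_df$peptide[unlist(gene_plan$sp_rows)]) |>
    count(.data$peptide, name = "expected")
  for (try in seq_len(max_tries)) {
    genes <- list()
    pieces <- character(0)
    pos <- 0L
    add <- function(seqs) {
      pieces[[length(pieces) + 1L]] <<- seqs
      pos <<- pos + nchar(seqs)
    }
    gaps <- as.integer(stats::rmultinom(1, budget - n_gaps * 20L,
                                        rep(1, n_gaps))) + 20L
    add(random_dna(margin))
    order_idx <- sample.int(nrow(gene_plan))
    for (j in seq_along(order_idx)) {
      add(random_dna(gaps[j]))
      i <- order_idx[j]
      sps <- dict_df$peptide[gene_plan$sp_rows[[i]]]
      enc <- paste(vapply(sps, encode_peptide, character(1)), collapse = "")
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      planted <- if (strand == "+") enc else reverse_complement(enc)
      start <- pos + 1L
      add(planted)
      genes[[length(genes) + 1L]] <- tibble(
        gene_id = sprintf("%s_g%03d", id, i),
        start = start, end = pos, strand = strand,
        ec = gene_plan$ec[i]
      )
    }
    add(random_dna(gaps[n_gaps]))
    add(random_dna(margin))
    sequence <- paste(pieces, collapse = "")
    gene_tbl <- if (length(genes)) bind_rows(genes) else
      tibble(gene_id = character(), start = integer(), end = integer(),
             strand = character(), ec = character())

    # ground-truth closure: a full-genome six-frame scan must find each
    # planted SP exactly its planted number of times, nothing else
    scan <- scan_reads(tibble(id = id, sequence = sequence), matcher,
                       warn_length = FALSE)
    got <- count(as_tibble(scan), .data$peptide, name = "got")
    chk <- dplyr::full_join(expected, got, by = "peptide")
    chk$expected[is.na(chk$expected)] <- 0L
    chk$got[is.na(chk$got)] <- 0L
    if (all(chk$expected == chk$got)) {
      return(list(sequence = sequence, genes = gene_tbl))
    }
  }
  abort(sprintf("could not build a clean background for genome %s in %d tries",
                id, max_tries))
}

#' Build a synthetic fixture with known ground truth
#'
#' Generates the SP dictionary and the genomes described by a
#' [fixture_spec()]. Each gene encodes its SPs through independently
#' randomised synonymous codons (so matches can only arise via
#' translation, not nucleotide-level repeats); about half the genes are
#' planted on the reverse strand to exercise all six frames; backgrounds
#' are re-rolled until a full-genome six-frame scan finds exactly the
#' planted occurrences and nothing else.
#'
#' @param spec a [fixture_spec()].
#' @return a list with elements
#'   * `genomes`: list of [annotated_genome()] objects,
#'   * `dictionary`: the `sp_dictionary` (taxon-labelled rows for TSPs),
#'   * `truth`: list with `asymptotic_rf` (tibble `category`, `rf`),
#'     `enzyme_counts` (pooled tibble `category`, `n_genes`),
#'     `enzyme_counts_by_genome`, `taxon_enzymes` (tibble `taxon`,
#'     `n_genes`), `sp_length_dist` (planted-occurrence-weighted tibble
#'     `length`, `prob`) and `sps_per_gene`.
#' @examples
#' fx <- build_fixture(fixture_spec(n_genomes = 2,
#'   genome_length_nt = 6000,
#'   genes_per_ec = c("1.1.1" = 3, "6.1.1" = 3), seed = 42))
#' fx$truth$asymptotic_rf
#' @export
build_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, build_fixture_impl(spec))
}

build_fixture_impl <- function(spec) {
  plans <- if (is.list(spec$genes_per_ec)) spec$genes_per_ec else
    rep(list(spec$genes_per_ec), spec$n_genomes)

  # one SP pool per (EC, taxon) combination
  groups <- tibble(ec = unique(unlist(lapply(plans, names))),
                   taxon_rank = NA_character_, taxon_name = NA_character_)
  if (!is.null(spec$taxa) && !is.null(spec$taxon_genes)) {
    tax_groups <- tidyr::expand_grid(
      ec = names(spec$taxon_genes),
      taxon_name = unique(spec$taxa)
    )
    tax_groups$taxon_rank <- spec$taxon_rank
    groups <- bind_rows(groups, tax_groups)
  }
  groups$group <- seq_len(nrow(groups))

  dict_rows <- purrr::pmap(groups, function(ec, taxon_rank, taxon_name, group) {
    tibble(ec = ec, taxon_rank = taxon_rank, taxon_name = taxon_name,
           group = group,
           peptide = rep(NA_character_, spec$sps_per_ec))
  }) |> bind_rows()
  all_peps <- character(0)
  for (i in seq_len(nrow(dict_rows))) {
    p <- random_peptide(sample_sp_length(spec$sp_lengths), avoid = all_peps)
    dict_rows$peptide[i] <- p
    all_peps <- c(all_peps, p)
  }
  dict <- sp_dictionary(dict_rows$peptide, dict_rows$ec,
                        taxon_rank = dict_rows$taxon_rank,
                        taxon_name = dict_rows$taxon_name,
                        provenance = "synthetic fixture")
  matcher <- sp_matcher(dict)

  group_for <- function(e, taxon) {
    cand <- groups$group[groups$ec == e & is.na(groups$taxon_name)]
    if (!is.na(taxon)) {
      tcand <- groups$group[groups$ec == e & !is.na(groups$taxon_name) &
                              groups$taxon_name == taxon]
      if (length(tcand)) return(tcand[1])
    }
    cand[1]
  }

  genomes <- list()
  plans_realized <- list()
  for (gi in seq_len(spec$n_genomes)) {
    plan_vec <- plans[[gi]]
    taxon_name <- if (!is.null(spec$taxa)) spec$taxa[gi] else NA_character_
    ecs <- rep(names(plan_vec), as.integer(plan_vec))
    tax_flag <- rep(NA_character_, length(ecs))
    if (!is.na(taxon_name) && !is.null(spec$taxon_genes)) {
      ecs <- c(ecs, rep(names(spec$taxon_genes),
                        as.integer(spec$taxon_genes)))
      tax_flag <- c(tax_flag,
                    rep(taxon_name, sum(as.integer(spec$taxon_genes))))
    }
    # genome-specific SP usage weights per pool
    pool_weights <- lapply(groups$group, function(g) {
      n <- spec$sps_per_ec
      if (spec$genome_sp_bias) {
        w <- stats::rgamma(n, shape = 1)
        w / sum(w)
      } else rep(1 / n, n)
    })
    sp_rows <- purrr::map2(ecs, tax_flag, function(e, t) {
      grp <- group_for(e, t)
      rows <- which(dict_rows$group == grp)
      if (spec$genome_sp_bias) {
        sort(sample(rows, spec$sps_per_gene, replace = TRUE,
                    prob = pool_weights[[grp]]))
      } else {
        rows[seq_len(spec$sps_per_gene)]
      }
    })
    id <- sprintf("genome_%02d", gi)
    gene_plan <- tibble(ec = ecs, sp_rows = sp_rows)
    built <- build_one_genome(id, gene_plan, dict_rows,
                              spec$genome_length_nt, matcher)
    genomes[[gi]] <- annotated_genome(
      built$sequence, built$genes, id = id,
      taxon = if (is.na(taxon_name)) NULL else
        list(rank = spec$taxon_rank, name = taxon_name)
    )
    plans_realized[[gi]] <- gene_plan
  }

  # ground truth from the realized plans
  occ_rows <- unlist(purrr::map(plans_realized, function(p) unlist(p$sp_rows)))
  pooled_counts <- purrr::map(genomes, enzyme_counts) |>
    bind_rows() |>
    group_by(.data$category) |>
    summarise(n_genes = sum(.data$n_genes), .groups = "drop")
  asym <- pooled_counts[, "category"]
  asym$rf <- spec$sps_per_gene
  len_tab <- table(nchar(dict_rows$peptide[occ_rows]))
  taxon_tbl <- purrr::map(genomes, function(g) {
    if (is.null(g$taxon)) return(NULL)
    n_tax <- sum(g$genes$ec %in% names(spec$taxon_genes %||% character()))
    tibble(taxon = g$taxon$name, n_genes = n_tax)
  }) |> bind_rows()
  if (nrow(taxon_tbl)) {
    taxon_tbl <- taxon_tbl |> group_by(.data$taxon) |>
      summarise(n_genes = sum(.data$n_genes), .groups = "drop")
  }

  list(
    genomes = genomes,
    dictionary = dict,
    truth = list(
      asymptotic_rf = asym,
      enzyme_counts = pooled_counts,
      enzyme_counts_by_genome = purrr::map(genomes, enzyme_counts) |>
        stats::setNames(purrr::map_chr(genomes, "id")),
      taxon_enzymes = taxon_tbl,
      sp_length_dist = tibble(length = as.integer(names(len_tab)),
                              prob = as.numeric(len_tab) / sum(len_tab)),
      sps_per_gene = spec$sps_per_gene
    )
  )
}

#' Write a fixture to disk in standard formats
#'
#' One FASTA + annotation TSV per genome, plus the dictionary TSV, so the
#' command-line interface consumes fixtures exactly like real data.
#'
#' @param fixture result of [build_fixture()].
#' @param dir output directory (created if missing).
#' @return a list of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genomes = character(0), annotations = character(0))
  for (g in fixture$genomes) {
    fa <- file.path(dir, paste0(g$id, ".fasta"))
    writeLines(c(paste0(">", g$id),
                 gsub("(.{70})", "\\1\n", g$sequence)), fa)
    ann <- file.path(dir, paste0(g$id, "_genes.tsv"))
    readr::write_tsv(g$genes, ann, progress = FALSE)
    paths$genomes <- c(paths$genomes, fa)
    paths$annotations <- c(paths$annotations, ann)
  }
  paths$dictionary <- file.path(dir, "dictionary.tsv")
  write_sp_dictionary(fixture$dictionary, paths$dictionary)
  invisible(paths)
}
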