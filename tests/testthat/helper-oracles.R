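# Independent oracles, deliberately naive: used only to cross-check the
# package's fast paths on small instances.

# all (pattern, 1-based start) occurrences of each pattern in query,
# by brute-force sliding window
naive_scan <- function(patterns, query) {
  out <- list()
  for (p in patterns) {
    np <- nchar(p)
    nq <- nchar(query)
    if (np > nq) next
    starts <- which(vapply(seq_len(nq - np + 1L), function(i) {
      substr(query, i, i + np - 1L) == p
    }, logical(1)))
    if (length(starts)) {
      out[[length(out) + 1L]] <- data.frame(pattern = p, start = starts)
    }
  }
  if (!length(out)) {
    return(data.frame(pattern = character(), start = integer()))
  }
  df <- do.call(rbind, out)
  df[order(df$pattern, df$start), , drop = FALSE]
}

# hand-rolled codon-by-codon translation (standard code), independent of
# the Biostrings translate path
naive_translate <- function(dna) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(dna) %/% 3L
  if (n == 0) return("")
  paste(vapply(seq_len(n), function(i) {
    codon <- substr(dna, 3L * i - 2L, 3L * i)
    if (grepl("N", codon)) "X" else unname(code[[codon]])
  }, character(1)), collapse = "")
}

# brute-force all-pairs redundancy filter oracle
naive_redundancy_filter <- function(df) {
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j) next
      if (df$ec[j] == df$ec[i] &&
          nchar(df$peptide[j]) < nchar(df$peptide[i]) &&
          grepl(df$peptide[j], df$peptide[i], fixed = TRUE)) {
        keep[i] <- FALSE
      }
    }
  }
  df[keep, , drop = FALSE]
}

random_aa_string <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# encode a peptide into DNA deterministically (first codon of each residue)
encode_first_codon <- function(peptide) {
  gc <- Biostrings::GENETIC_CODE
  rev <- split(names(gc), unname(gc))
  paste(vapply(strsplit(peptide, "")[[1]], function(a) rev[[a]][1],
               character(1)), collapse = "")
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a read carrying one planted SP encoding between random flanks
make_sp_read <- function(sp, flank = 10, strand = "+") {
  enc <- encode_first_codon(sp)
  ins <- if (strand == "+") enc else pepspectra::reverse_complement(enc)
  paste0(random_dna_string(flank), ins, random_dna_string(flank))
}
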