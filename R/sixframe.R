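#' Reverse-complement nucleotide sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()];
#' `N` maps to `N`, and the operation is an involution.
#'
#' @param seq character vector over the alphabet A, C, G, T, N
#'   (lowercase accepted).
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  check_nucleotides(seq)
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seq))
  )
  unname(out)
}

check_nucleotides <- function(seq) {
  bad <- !grepl("^[ACGTN]*$", seq)
  if (any(bad)) {
    abort(sprintf(
      "sequence %d contains letters outside {A,C,G,T,N}: '%s'",
      which(bad)[1],
      substr(seq[which(bad)[1]], 1, 40)
    ))
  }
  invisible(seq)
}

as_read_tbl <- function(reads) {
  if (inherits(reads, "DNAStringSet") || inherits(reads, "XStringSet")) {
    reads <- tibble(
      id = names(reads) %||% as.character(seq_along(reads)),
      sequence = as.character(reads)
    )
  }
  if (is.character(reads)) {
    reads <- tibble(
      id = names(reads) %||% as.character(seq_along(reads)),
      sequence = unname(reads)
    )
  }
  reads <- as_tibble(reads)
  if (!all(c("id", "sequence") %in% names(reads))) {
    abort("reads must have 'id' and 'sequence' columns")
  }
  reads$sequence <- toupper(reads$sequence)
  check_nucleotides(reads$sequence)
  reads
}

#' Read short reads from FASTA or FASTQ
#'
#' Plain or gzip-compressed input; format is detected from the file
#' extension (`.fq`/`.fastq` vs anything else). Quality strings are
#' discarded: exact peptide matching uses no quality filtering.
#'
#' @param path input file.
#' @return a tibble with columns `id`, `sequence`.
#' @export
read_short_reads <- function(path) {
  if (!file.exists(path)) abort(paste0("read file not found: ", path))
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble(
    id = sub("\\s.*$", "", names(x) %||% as.character(seq_along(x))),
    sequence = unname(as.character(x))
  )
}

#' Six-frame translation of short reads into pseudo-peptides
#'
#' Every read yields exactly six pseudo-peptides: reading frames 0, 1, 2 on
#' the forward strand and on the reverse complement. Frame `f` skips the
#' first `f` bases, so the peptide in frame `f` of a read of `k` nucleotides
#' has `floor((k - f)/3)` residues. Translation uses the standard genetic
#' code; stop codons become `*` and codons containing `N` become `X`.
#' Neither letter occurs in any Specific Peptide, so matches can never span
#' a stop or an ambiguous codon — SP hits are required to sit entirely
#' inside a pseudo-peptide, which makes open-reading-frame calling
#' unnecessary.
#'
#' @param reads a tibble with columns `id` and `sequence`, a named character
#'   vector, or a [Biostrings::DNAStringSet].
#' @param warn_length warn when read lengths fall outside the 50-200 nt
#'   design band (default `TRUE`).
#' @return a tibble with columns `read_id`, `strand` (`"+"`/`"-"`),
#'   `frame` (0, 1, 2) and `peptide`; six rows per read.
#' @examples
#' six_frame_translate(c(r1 = "ATGGCAGCT"))
#' @export
six_frame_translate <- function(reads, warn_length = TRUE) {
  reads <- as_read_tbl(reads)
  k <- nchar(reads$sequence)
  if (warn_length && nrow(reads) && any(k < 50 | k > 200)) {
    warn(sprintf(
      "%d read(s) outside the 50-200 nt design band; results may be unreliable",
      sum(k < 50 | k > 200)
    ))
  }
  fwd <- Biostrings::DNAStringSet(reads$sequence)
  rev <- Biostrings::reverseComplement(fwd)
  frames <- purrr::map(c("+" = "fwd", "-" = "rev"), function(strand) {
    src <- if (strand == "fwd") fwd else rev
    purrr::map(0:2, function(f) {
      len <- pmax(0L, (k - f) %/% 3L)
      sub <- Biostrings::subseq(src, start = pmin(f + 1L, k + 1L),
                                width = 3L * len)
      tibble(
        read_id = reads$id,
        strand = if (strand == "fwd") "+" else "-",
        frame = f,
        peptide = as.character(Biostrings::translate(
          sub, if.fuzzy.codon = "X", no.init.codon = TRUE
        ))
      )
    })
  })
  out <- bind_rows(purrr::flatten(frames))
  out <- out[order(match(out$read_id, reads$id), out$strand == "-", out$frame), ]
  out$peptide[is.na(out$peptide)] <- ""
  as_tibble(out)
}
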