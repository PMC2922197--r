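---
title: "Peptide-marker spectra from short reads: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-marker spectra from short reads: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepspectra)
```

## The model

`pepspectra` estimates, from a bag of short nucleotide reads, how many
enzyme genes of each Enzyme Commission (EC) category the underlying
community carries, and in what coarse taxonomic proportions. Its central
assumption is that exact occurrences of short amino-acid markers —
Specific Peptides (SPs), ≥ 7 residues, each diagnostic of one EC category
— are frequent enough on real enzymes, and rare enough elsewhere, that
counting them on translated reads is a quantitative signal. Three model
components sit on top of that assumption.

**Six-frame observation model.** A read of $k$ nucleotides is translated
in all six frame/strand combinations; a marker of $L$ amino acids is
observed only if its $3L$ coding bases fall entirely inside the read, in
any frame. Per frame the read offers a window of $W = \lfloor k/3 \rfloor$
residues, so the relative detection efficiency of a length-$L$ marker is

$$e(L, k) = \max(0,\; W - L + 1)/W,$$

which for $k = 50$ (so $W = 16$) is $(17 - L)/16$: markers longer than 16
residues are invisible to 50-nt reads. The total efficiency of a read
length is the expectation of $e(L,k)$ under the dictionary's SP-length
distribution (`total_efficiency()`); it is non-decreasing in $k$ with
limit 1. The package generalises the window to any read length via
$W = \lfloor k/3 \rfloor$; the exact containment probability on a genome
is $(k - 3L + 1)/k$, which the window form approximates to within a few
percent across the 50–200 nt design band — the fixtures quantify this
(tests assert agreement within 10%).

**Count-to-gene calibration.** The raw factor
$\mathrm{RF}(\mathrm{EC}) = \text{hits}/\text{genes}$ converts hit counts
to gene counts. Because hit counts scale linearly with sequencing depth,
the package expresses RF per 1× genome equivalent: factors computed from
simulated reads divide by the known simulation coverage
(`raw_factors(..., coverage = )`). Two consequences follow. First, the
full-genome (unfragmented) RF equals the mean number of SP hits per
annotated enzyme, and finite-read RFs approach it from below as
$\mathrm{RF}_k \approx e_{\mathrm{tot}}(k)\,\mathrm{RF}_\infty$. Second,
when a real metagenome's coverage is unknown, predictions
$\text{hits}/\mathrm{RF}$ are *coverage-weighted* gene counts: a
predicted 60 aminoacyl-tRNA synthetases, at roughly 20 aaRS genes per
bacterial genome, means the read set covers about three genomes' worth of
cells (`cells_estimate()`).

Normalised factors $\mathrm{NF} = \mathrm{RF}/\mathrm{RF}(6.1.1)$ use the
aaRS category as reference because aaRS enzymes are near-universal,
SP-rich (hence the largest factor), and near-single-copy. NFs are
approximately read-length invariant — the efficiency depression largely
cancels in the ratio, up to differences between categories' SP-length
distributions — which is what allows a factor table trained at one read
length to be applied, in relative terms, to another.

**Taxonomic mixtures.** Within EC 6.1.1, taxon-specific peptides (TSPs)
at kingdom, phylum and class rank are counted the same way; dividing by
per-taxon factors corrects for unequal TSP pool sizes, yielding predicted
marker-enzyme numbers proportional to cell numbers. Only the level-4 aaRS
categories with at most 2% multiple entries per species (the S61 set,
selected by `select_s61()` with rounding to one decimal before
thresholding) are used, so that one corrected enzyme ≈ one genome.
Predictions below 1 enzyme are no-calls. The packaged per-taxon factors
were calibrated against curated proteomes, which are richer in marker
hits than novel environmental lineages; absolute predictions from them
are therefore lower bounds, and reports carry that caveat.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_length` | 7 aa | minimum SP length retained; shorter exact matches lose specificity |
| read length band | 50–200 nt | supported design band; outside it a warning is issued |
| `coverage` | 5× (training) | read-simulation depth for factor training |
| `k`, `n_combinations` | 7 of n, 15 | genomes per super-organism and number of sampled combinations |
| reference category | 6.1.1 | normalisation anchor (aaRS) |
| `aars_per_genome` | 20 | aaRS genes per genome for cell-count estimates |
| anomaly `fold`, `max_sps` | 10, 2 | dominance ratio and maximum distinct SPs for an artifact flag |
| `no_call_threshold` | 1 enzyme | minimum prediction for a taxonomic call, applied unrounded |

## Counting policy and numerical choices

* **Occurrences, not reads.** Every occurrence counts: the same SP twice
  on one read, or in two frames, gives two hits. The alternative
  (read-level counting) is isolated behind
  `hit_table(count = "reads")`, one argument away.
* **Level-4 aggregation.** SPs labelled at EC level 4 contribute to their
  level-3 parent for spectra; they never fan out to sibling level-4
  categories. Taxonomic runs at different ranks are independent.
* **Stops and ambiguity.** Stop codons translate to `*`, codons containing
  `N` to `X`; neither letter can occur in an SP, so matches cannot span
  them and no pseudo-peptide splitting is needed. The automaton resets on
  such letters, which is exact, not approximate.
* **Ties and degenerate input.** An empty dictionary refuses to build a
  matcher; a hit table with fewer than two categories is never flagged
  anomalous (no comparator); categories with hits but no annotated genes
  are reported with `rf = NA` rather than divided by zero; a zero
  reference factor is an error, not an `Inf`.
* **Heterogeneous read lengths.** Factors are calibrated at one read
  length; applying them to a read set whose length coefficient of
  variation exceeds 20% triggers a warning (mean-length factors are the
  documented approximation).
* **Standard deviations.** Factor SDs are sample SDs (ddof = 1) across
  super-organism combinations; the reference NF is pinned at exactly 1
  with SD exactly 0. The chi-square statistic is the mean of
  $((X-\mu)/\sigma)^2$ over compared categories; $\sigma = 0$ is only
  admitted when the terms are exactly equal.
* **Seeding.** Every stochastic step (read simulation, combination
  sampling, fixture generation) flows from explicit integer seeds;
  identical seeds give byte-identical outputs.

## The synthetic-data generator

`fixture_spec()`/`build_fixture()` create toy genomes in which every
planted gene encodes a known number of SP occurrences via independently
randomised synonymous codons, so matches can only arise through
translation, never through nucleotide-level repeats. Roughly half the
genes go on the reverse strand, exercising all six frames. Backgrounds
are re-rolled until a full-genome six-frame scan finds exactly the
planted occurrences — *ground-truth closure*: every quantity the pipeline
later predicts has a recorded expected value fixed at construction time.
In particular the asymptotic raw factor of every category equals
`sps_per_gene` exactly.

Design choices made once, with their rationale:

* **SP length distribution** (unknown for real dictionaries at the
  package's scale): geometric-style decay on 7–16 aa, halving per extra
  residue — short deterministic motifs are dominated by the shortest
  admissible lengths, and 16 aa is the longest marker a 50-nt read can
  reveal. Consequently the generator makes no claim to reproduce any
  particular real dictionary's total efficiency; tests assert the
  *properties* of the efficiency model (window formula, monotonicity,
  limit 1), not a specific total.
* **Between-organism marker variability**: with `genome_sp_bias = TRUE`
  each genome draws its genes' SPs from the category pool with
  genome-specific weights, emulating organisms whose enzymes carry
  different subsets of a category's markers. This is what makes pooled
  "metagenomes" genuinely smoother than single genomes: single-genome
  spectra then deviate beyond counting noise while pooled spectra
  average out, reproducing the qualitative chi-square gap.
* **Read simulation**: uniform independent start positions on the forward
  strand (six-frame search restores strand symmetry), no sequencing-error
  model, sampling with replacement. Genes are kept ≥ 250 nt away from
  genome ends so edge effects do not bias containment probabilities.
* **Taxon fixtures**: ~20 near-single-copy marker genes per genome
  (four level-4 aaRS categories × 5 genes), matching the real aaRS
  complement of a bacterial genome; per-taxon calibration uses a 50×
  read set so that calibration shot noise (~3%) is small against the
  mixture sampling error the recovery tests actually probe.

What the generator does **not** emulate: sequencing errors and quality
variation, GC/codon bias, paralogues and horizontally transferred genes,
intergenic SP look-alikes, unequal genome sizes within a mixture, and
real dictionaries' cross-category sequence correlations. Passing the
fixture tests therefore demonstrates the pipeline's internal correctness
and calibration logic, not field accuracy on environmental data — for
real data the packaged factors remain lower-bound calibrations from
curated proteomes.

## Problem sizes used by the test suite

The shipped tests run on 5–20 kb toy genomes, 2–5 genomes per fixture,
5× coverage at read lengths 50–200 nt, 8–15 super-organism combinations,
and a 1000-instance randomized cross-check of the matcher against a
naive sliding-window oracle. These sizes were chosen so the full suite
exercises every pipeline stage (including end-to-end recovery) in a few
minutes on a single core while keeping counting noise small relative to
the tolerances under test.

## Known limitations

* Exact matching only: a single substitution in a marker's coding
  sequence destroys the hit. This is intrinsic to the SP approach (and
  to its speed); sensitivity on divergent lineages is bounded by
  dictionary breadth.
* Absolute predictions require either known coverage or the
  genome-equivalent reading; the two are deliberately not conflated in
  the API (`coverage` argument vs `cells_estimate()`).
* Factor transfer across read lengths relies on NF stability, which holds
  only approximately when categories' SP-length distributions differ.
* The anomaly flag is a heuristic for one failure mode (few-marker
  dominance); it is a prompt for re-examination, not a verdict.
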