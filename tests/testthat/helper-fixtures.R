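# Shared fixtures, built once per test run.

# calibrated default model and a matching usage table
test_model <- default_promoter_model(seed = 42L)
test_usage <- synth_usage_table(0.508)

random_dna <- function(n, len, seed = NULL) {
  denovoprom:::with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1)))
}

# a sequence with the full consensus promoter (spacer `spacer`) embedded at
# 0-based offset `at` in the given background
embed_consensus <- function(background, at, spacer = 17L,
                            m35 = "TTGACA", m10 = "TATAAT",
                            spacer_fill = "C") {
  stopifnot(nchar(background) >= at + 12L + spacer)
  window <- paste0(m35, strrep(spacer_fill, spacer), m10)
  paste0(substr(background, 1L, at),
         window,
         substr(background, at + nchar(window) + 1L, nchar(background)))
}

# random in-frame CDS: ATG + uniformly random non-stop codons + TAA
random_cds <- function(n_codons, seed = NULL) {
  gc <- Biostrings::GENETIC_CODE
  nonstop <- names(gc)[gc != "*"]
  denovoprom:::with_seed(seed, paste(
    c("ATG", sample(nonstop, n_codons - 2L, replace = TRUE), "TAA"),
    collapse = ""))
}

# minimal GenBank flat file with a plus-strand CDS (4..9, "ATGAAA"-style),
# a minus-strand CDS, and optionally a pseudo CDS and a non-multiple-of-3 CDS
write_toy_genbank <- function(path, with_bad = FALSE) {
  ## genome layout (1-based):
  ##   4..12   plus-strand CDS  geneA (9 nt)
  ##  21..32   minus-strand CDS geneB (12 nt)
  genome <- paste0("GGG", "ATGAAATAA", "CCCCCCCC",
                   denovoprom::revcomp("ATGGGCTTTTAA"), "CCCC")
  lines <- c(
    "LOCUS       TOYGENOME             36 bp    DNA     circular BCT",
    "DEFINITION  toy genome for parser tests.",
    "FEATURES             Location/Qualifiers",
    "     source          1..36",
    "     CDS             4..12",
    '                     /gene="geneA"',
    '                     /locus_tag="TOY_0001"',
    "     CDS             complement(21..32)",
    '                     /locus_tag="TOY_0002"')
  if (with_bad) {
    lines <- c(lines,
      "     CDS             2..11",
      '                     /locus_tag="TOY_BAD"',
      "     CDS             4..12",
      '                     /locus_tag="TOY_PSEUDO"',
      "                     /pseudo")
  }
  lines <- c(lines, "ORIGIN",
             paste0("        1 ", tolower(genome)), "//")
  writeLines(lines, path)
  invisible(genome)
}

# a small GenBank "genome" with enough CDSs for run_minimization
write_mini_genome_genbank <- function(path, n_genes = 12L, seed = 99L) {
  cds <- vapply(seq_len(n_genes), function(i)
    random_cds(80L, seed = seed + i), character(1))
  genome <- paste(cds, collapse = "")
  starts <- cumsum(c(1L, head(nchar(cds), -1L)))
  feat <- unlist(lapply(seq_len(n_genes), function(i) c(
    sprintf("     CDS             %d..%d", starts[i],
            starts[i] + nchar(cds[i]) - 1L),
    sprintf('                     /locus_tag="MG_%04d"', i))))
  writeLines(c(
    sprintf("LOCUS       MINIGENOME            %d bp    DNA     linear BCT",
            nchar(genome)),
    "FEATURES             Location/Qualifiers",
    feat, "ORIGIN", paste0("        1 ", tolower(genome)), "//"), path)
  invisible(genome)
}
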