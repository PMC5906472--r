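# Synonymous-recoding and codon-shuffle null models for coding sequences.

#' Construct a codon-usage table
#'
#' @param df a `data.frame` with columns `codon`, `aa`, `prob` (conditional
#'   probability of the codon within its amino-acid family).
#' @return a `codon_usage` object.
#' @export
codon_usage <- function(df) {
  stopifnot(all(c("codon", "aa", "prob") %in% names(df)))
  gc <- genetic_code()
  if (!setequal(df$codon, names(gc)) || anyDuplicated(df$codon))
    stop("usage table must contain each of the 64 codons exactly once")
  sums <- tapply(df$prob, df$aa, sum)
  # a family may carry zero mass (amino acid unseen in the source genes);
  # recoding such an amino acid errors at sampling time
  if (any(abs(sums - 1) > 1e-9 & abs(sums) > 1e-9))
    stop("codon probabilities must sum to 1 within each amino-acid family")
  structure(df[order(df$aa, df$codon), c("codon", "aa", "prob")],
            class = c("codon_usage", "data.frame"))
}

#' Genome-wide codon usage from a set of genes
#'
#' Counts every codon over all CDSs and normalizes within amino-acid
#' families (standard genetic code). Internal stop codons trigger a warning
#' but still count toward stop usage. An amino-acid family never observed
#' carries zero probability mass; recoding a gene that needs it errors.
#'
#' @param genes a gene table (column `cds`) or character vector of CDSs.
#' @return a `codon_usage` object with an extra `count` column.
#' @export
usage_from_genes <- function(genes) {
  cds <- if (is.data.frame(genes)) genes$cds else as_char_seqs(genes)
  if (length(cds) == 0L) stop("no genes supplied")
  gc <- genetic_code()
  counts <- stats::setNames(integer(length(gc)), names(gc))
  n_internal_stop <- 0L
  for (s in cds) {
    cod <- split_codons(toupper(s))
    aa <- gc[cod]
    if (any(aa[-length(aa)] == "*")) n_internal_stop <- n_internal_stop + 1L
    t <- table(cod)
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  if (n_internal_stop > 0L)
    warning(n_internal_stop, " gene(s) contain internal stop codons")
  df <- data.frame(codon = names(gc), aa = unname(gc),
                   count = as.integer(counts), stringsAsFactors = FALSE)
  fam_tot <- stats::ave(df$count, df$aa, FUN = sum)
  df$prob <- ifelse(fam_tot > 0, df$count / fam_tot, 0)
  codon_usage(df)
}

# family lookup: list aa -> list(codons, prob)
usage_families <- function(usage) {
  split(usage[, c("codon", "prob")], usage$aa)
}

#' Synonymously recode a gene
#'
#' Replaces every codon with a synonymous codon drawn independently from the
#' usage table conditional on its amino acid, preserving the translation
#' exactly and the codon bias in expectation. The terminal stop codon is
#' kept verbatim.
#'
#' @param cds a single in-frame DNA string.
#' @param usage a `codon_usage` object.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return the recoded CDS string.
#' @export
recode_gene <- function(cds, usage, seed = NULL) {
  stopifnot(inherits(usage, "codon_usage"))
  cod <- split_codons(toupper(cds))
  aa <- genetic_code()[cod]
  n <- length(cod)
  keep_terminal <- aa[n] == "*"
  fam <- usage_families(usage)
  with_seed(seed, {
    out <- cod
    idx <- if (keep_terminal) seq_len(n - 1L) else seq_len(n)
    for (a in unique(aa[idx])) {
      f <- fam[[a]]
      if (is.null(f) || sum(f$prob) <= 0)
        stop("usage table has no probability mass for amino acid '", a, "'")
      at <- idx[aa[idx] == a]
      if (nrow(f) == 1L) out[at] <- f$codon
      else out[at] <- sample(f$codon, length(at), replace = TRUE,
                             prob = f$prob)
    }
    paste(out, collapse = "")
  })
}

#' Shuffle the codons of a gene
#'
#' A uniformly random permutation of the codon sequence: the codon multiset
#' (and hence the exact GC content) is preserved, the protein generally is
#' not. A terminal stop codon stays in place.
#'
#' @inheritParams recode_gene
#' @return the shuffled CDS string.
#' @export
shuffle_codons <- function(cds, seed = NULL) {
  cod <- split_codons(toupper(cds))
  n <- length(cod)
  keep_terminal <- genetic_code()[cod[n]] == "*"
  m <- if (keep_terminal) n - 1L else n
  if (m <= 1L) return(paste(cod, collapse = ""))
  with_seed(seed, {
    cod[seq_len(m)] <- cod[sample.int(m)]
    paste(cod, collapse = "")
  })
}

#' Null ensemble of recoded or codon-shuffled gene versions
#'
#' Generates `n` independent null versions of a CDS. Each replicate `i` is
#' seeded by a stable hash of `(seed, gene_id, i)`, so any replicate is
#' reproducible in isolation.
#'
#' @param cds a single in-frame DNA string.
#' @param mode `"usage"` (synonymous recoding) or `"shuffle"` (codon
#'   permutation).
#' @param n number of replicates.
#' @param usage a `codon_usage` object (required for `mode = "usage"`).
#' @param seed root integer seed.
#' @param gene_id id entering the per-replicate sub-seed.
#' @return a character vector of `n` null CDSs named `gene_id|i`.
#' @export
make_ensemble <- function(cds, mode = c("usage", "shuffle"), n = 100L,
                          usage = NULL, seed = 1L, gene_id = "gene") {
  mode <- match.arg(mode)
  if (n < 1L) stop("n must be at least 1")
  if (mode == "usage" && is.null(usage))
    stop("usage mode requires a codon_usage table")
  out <- character(n)
  for (i in seq_len(n)) {
    s <- subseed(seed, gene_id, i)
    out[i] <- if (mode == "usage") recode_gene(cds, usage, seed = s)
              else shuffle_codons(cds, seed = s)
  }
  names(out) <- paste0(gene_id, "|", seq_len(n))
  out
}
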