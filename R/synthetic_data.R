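# Fully synthetic genomes and promoter sets with known ground truth, so
# every pipeline stage is testable without external downloads.

#' Codon-usage table with a target GC content
#'
#' Within each amino-acid family, codon probabilities are proportional to
#' `t^gc(codon)` with a single tilt `t` chosen so that the implied coding
#' GC content under a uniform amino-acid composition matches `gc_target`
#' (within 1 percentage point).
#'
#' @param gc_target target GC fraction, strictly between the minimum and
#'   maximum achievable by codon choice (~0.29 to ~0.82).
#' @return a `codon_usage` object.
#' @export
synth_usage_table <- function(gc_target = 0.508) {
  if (gc_target <= 0 || gc_target >= 1) stop("gc_target must be in (0, 1)")
  gc <- genetic_code()
  gc_count <- vapply(names(gc), function(c)
    sum(strsplit(c, "")[[1]] %in% c("G", "C")), numeric(1))
  aas <- setdiff(unique(gc), "*")   # uniform composition over the 20 AAs
  implied_gc <- function(logt) {
    t <- exp(logt)
    mean(vapply(aas, function(a) {
      i <- gc == a
      w <- t^gc_count[i]
      sum(w * gc_count[i] / 3) / sum(w)
    }, numeric(1)))
  }
  lo <- implied_gc(-15); hi <- implied_gc(15)
  if (gc_target < lo || gc_target > hi)
    stop("gc_target ", gc_target, " outside the codon-achievable range [",
         round(lo, 3), ", ", round(hi, 3), "]")
  logt <- stats::uniroot(function(x) implied_gc(x) - gc_target,
                         c(-15, 15), tol = 1e-10)$root
  t <- exp(logt)
  prob <- numeric(length(gc))
  for (a in unique(gc)) {
    i <- gc == a
    w <- t^gc_count[i]
    prob[i] <- w / sum(w)
  }
  codon_usage(data.frame(codon = names(gc), aa = unname(gc), prob = prob,
                         stringsAsFactors = FALSE))
}

#' Specification for a synthetic genome
#'
#' @param n_genes number of genes.
#' @param length_range gene length range in codons (uniform; includes start
#'   and stop). Default 150-500 codons, mean ~325, close to a typical
#'   bacterial gene.
#' @param usage a `codon_usage` table genes are sampled from.
#' @param group_fractions named fractions over
#'   `c("essential","toxin","antitoxin","none")`, summing to 1. Toxins and
#'   antitoxins are paired one-to-one.
#' @param avoidance either one of `"neutral"`, `"avoid"`, `"enrich"` applied
#'   to every gene, or a named vector giving a mode per group.
#' @param antisense_bias_for_toxins plant antisense promoter sites into
#'   toxin genes (emulating stronger antisense accidental expression of
#'   toxins).
#' @param enrich_per_kb planted core-motif sites per kb in `"enrich"` mode.
#' @param seed root seed; every generator draw derives from it.
#' @return a `synth_genome_spec` list.
#' @export
synth_genome_spec <- function(n_genes = 200L, length_range = c(150L, 500L),
                              usage = synth_usage_table(0.508),
                              group_fractions = c(essential = 0.1,
                                                  toxin = 0.05,
                                                  antitoxin = 0.05,
                                                  none = 0.8),
                              avoidance = "neutral",
                              antisense_bias_for_toxins = FALSE,
                              enrich_per_kb = 1,
                              seed = 1L) {
  stopifnot(n_genes >= 1L,
            abs(sum(group_fractions) - 1) < 1e-9,
            all(names(group_fractions) %in%
                  c("essential", "toxin", "antitoxin", "none")))
  for (g in c("essential", "toxin", "antitoxin", "none"))
    if (!g %in% names(group_fractions)) group_fractions[[g]] <- 0
  structure(list(n_genes = as.integer(n_genes),
                 length_range = as.integer(length_range),
                 usage = usage, group_fractions = group_fractions,
                 avoidance = avoidance,
                 antisense_bias_for_toxins = antisense_bias_for_toxins,
                 enrich_per_kb = enrich_per_kb, seed = as.integer(seed)),
            class = "synth_genome_spec")
}

# sample one gene: start codon, body sampled uniformly over the 20 amino
# acids with codons from `usage`, terminal stop from stop usage
sample_gene <- function(n_codons, fam) {
  aas <- setdiff(names(fam), "*")
  body_aa <- sample(aas, n_codons - 2L, replace = TRUE)
  body <- character(n_codons - 2L)
  for (a in unique(body_aa)) {
    f <- fam[[a]]
    at <- body_aa == a
    body[at] <- if (nrow(f) == 1L) f$codon
                else sample(f$codon, sum(at), replace = TRUE, prob = f$prob)
  }
  stopf <- fam[["*"]]
  stop_cod <- if (nrow(stopf) == 1L) stopf$codon
              else sample(stopf$codon, 1L, prob = stopf$prob)
  paste(c("ATG", body, stop_cod), collapse = "")
}

# synonymous repair: resample codons overlapping core-motif hits (both
# strands) until none remain or `max_rounds` is exhausted
avoid_core_hits <- function(cds, fam, spacer_range = c(15L, 19L),
                            max_rounds = 30L) {
  gc <- genetic_code()
  for (round in seq_len(max_rounds)) {
    hits <- core_motif_hits(cds, spacer_range, strands = c("+", "-"))
    if (nrow(hits) == 0L) return(list(cds = cds, partial = FALSE))
    L <- nchar(cds)
    ## sense-strand spans covered by any hit's fixed bases
    spans <- lapply(seq_len(nrow(hits)), function(r) {
      a <- hits$pos35[r] + 1L          # 1-based start on scanned strand
      b <- hits$pos10[r] + 6L          # 1-based end on scanned strand
      if (hits$strand[r] == "+") c(a, b) else c(L - b + 1L, L - a + 1L)
    })
    cod <- split_codons(cds)
    touched <- unique(unlist(lapply(spans, function(sp) {
      seq.int((sp[1] - 1L) %/% 3L + 1L, (sp[2] - 1L) %/% 3L + 1L)
    })))
    touched <- touched[touched >= 2L & touched < length(cod)]  # keep ends
    for (k in touched) {
      a <- gc[[cod[k]]]
      f <- fam[[a]]
      if (nrow(f) > 1L) cod[k] <- sample(f$codon, 1L, prob = f$prob)
    }
    cds <- paste(cod, collapse = "")
  }
  list(cds = cds, partial = nrow(core_motif_hits(cds, spacer_range,
                                                 strands = c("+", "-"))) > 0L)
}

# overwrite consensus hexamers (TTGACA +17nt+ TATAAT) at `starts` (1-based,
# scanned strand); strand "-" plants into the reverse complement
plant_sites <- function(cds, starts, strand = "+") {
  enc <- encode_dna(cds)
  e <- if (strand == "+") enc else revcomp_enc(enc)
  con35 <- encode_dna("TTGACA"); con10 <- encode_dna("TATAAT")
  for (p in starts) {
    e[p:(p + 5L)] <- con35
    e[(p + 23L):(p + 28L)] <- con10
  }
  if (strand == "-") e <- revcomp_enc(e)
  decode_dna(e)
}

#' Generate a synthetic genome with known ground truth
#'
#' Genes are sampled codon-by-codon from the usage table. In `"avoid"` mode
#' any codon choice creating a core-motif hit (either strand) is resampled
#' synonymously (bounded retries; genes still carrying hits are labelled
#' `partial`). In `"enrich"` mode consensus -35/-10 hexamers (spacer 17 nt)
#' are written over the sampled bases at `enrich_per_kb` sites per kb; note
#' planting is nucleotide-level and may create internal stop codons. With
#' `antisense_bias_for_toxins`, toxin genes additionally receive one planted
#' antisense site per kb.
#'
#' @param spec a [synth_genome_spec()].
#' @return a list with `genes` (a gene table as from [read_genbank_cds()],
#'   consecutive genomic coordinates) and `truth` (a `data.frame` with
#'   `gene_id`, `group`, `pair_id`, `avoidance`, `planted_sense`,
#'   `planted_antisense`, `partial`).
#' @export
synth_genome <- function(spec) {
  stopifnot(inherits(spec, "synth_genome_spec"))
  fam <- usage_families(spec$usage)
  n <- spec$n_genes

  ## group assignment: deterministic counts from fractions, toxins paired
  counts <- floor(spec$group_fractions * n)
  counts["none"] <- n - sum(counts[setdiff(names(counts), "none")])
  npair <- min(counts["toxin"], counts["antitoxin"])
  groups <- rep(names(counts), counts)[seq_len(n)]
  pair_id <- rep(NA_character_, n)
  pair_id[which(groups == "toxin")[seq_len(npair)]] <-
    paste0("TA", seq_len(npair))
  pair_id[which(groups == "antitoxin")[seq_len(npair)]] <-
    paste0("TA", seq_len(npair))

  mode_of <- function(group) {
    if (length(spec$avoidance) == 1L && is.null(names(spec$avoidance)))
      spec$avoidance
    else if (group %in% names(spec$avoidance)) spec$avoidance[[group]]
    else "neutral"
  }

  genes <- vector("list", n)
  truth <- vector("list", n)
  pos <- 0L
  for (g in seq_len(n)) {
    id <- sprintf("sg%04d", g)
    res <- with_seed(subseed(spec$seed, id, 0L), {
      n_codons <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
      cds <- sample_gene(n_codons, fam)
      mode <- mode_of(groups[g])
      partial <- FALSE
      planted_sense <- 0L; planted_antisense <- 0L
      if (mode == "avoid") {
        av <- avoid_core_hits(cds, fam)
        cds <- av$cds; partial <- av$partial
      } else if (mode == "enrich") {
        L <- nchar(cds)
        k <- max(1L, round(spec$enrich_per_kb * L / 1000))
        starts <- pmin(pmax(round(L * (seq_len(k) - 0.5) / k) - 14L, 4L),
                       L - 32L)
        cds <- plant_sites(cds, starts, "+")
        planted_sense <- k
      }
      if (spec$antisense_bias_for_toxins && groups[g] == "toxin") {
        L <- nchar(cds)
        k <- max(1L, round(L / 1000))
        starts <- pmin(pmax(round(L * (seq_len(k) - 0.25) / k) - 14L, 4L),
                       L - 32L)
        cds <- plant_sites(cds, starts, "-")
        planted_antisense <- k
      }
      list(cds = cds, mode = mode, partial = partial,
           planted_sense = planted_sense,
           planted_antisense = planted_antisense)
    })
    L <- nchar(res$cds)
    genes[[g]] <- data.frame(
      gene_id = id, cds = res$cds, strand = "+",
      genome_start = pos, genome_end = pos + L,
      essential = groups[g] == "essential",
      toxin = groups[g] == "toxin",
      antitoxin = groups[g] == "antitoxin",
      prophage = FALSE, stringsAsFactors = FALSE)
    truth[[g]] <- data.frame(
      gene_id = id, group = groups[g], pair_id = pair_id[g],
      avoidance = res$mode, planted_sense = res$planted_sense,
      planted_antisense = res$planted_antisense, partial = res$partial,
      stringsAsFactors = FALSE)
    pos <- pos + L + 50L   # 50-nt intergenic gap in the coordinate system
  }
  list(genes = do.call(rbind, genes), truth = do.call(rbind, truth))
}

#' Synthetic constitutive-promoter set
#'
#' Consensus-derived promoters embedded in random flanks: `TTGACA`, a spacer
#' drawn from a 17-nt-peaked length distribution with random content, and
#' `TATAAT`, with every consensus position mutated independently with
#' probability `noise_per_position` (to a uniformly random different base).
#' Stands in for a set of real constitutive promoters when calibrating the
#' score threshold.
#'
#' @param n number of promoter sequences (at least 2).
#' @param noise_per_position per-position mutation probability in `[0, 1)`.
#' @param flank random flank length on each side, nt.
#' @param spacer_lengths,spacer_probs spacer-length distribution.
#' @param seed integer seed.
#' @return a [Biostrings::DNAStringSet] named `prom_0001, ...`.
#' @export
synth_promoter_set <- function(n = 556L, noise_per_position = 0.30,
                               flank = 40L,
                               spacer_lengths = 15:19,
                               spacer_probs = c(0.08, 0.20, 0.44, 0.20, 0.08),
                               seed = NULL) {
  if (n < 2L) stop("n must be at least 2")
  if (noise_per_position < 0 || noise_per_position >= 1)
    stop("noise_per_position must be in [0, 1)")
  con <- c(encode_dna("TTGACA"), encode_dna("TATAAT"))
  with_seed(seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      core <- con
      mut <- which(stats::runif(12L) < noise_per_position)
      for (j in mut) core[j] <- sample(setdiff(1:4, core[j]), 1L)
      sp <- if (length(spacer_lengths) == 1L) spacer_lengths
            else sample(spacer_lengths, 1L, prob = spacer_probs)
      enc <- c(sample.int(4L, flank, replace = TRUE),
               core[1:6],
               sample.int(4L, sp, replace = TRUE),
               core[7:12],
               sample.int(4L, flank, replace = TRUE))
      out[i] <- decode_dna(enc)
    }
    names(out) <- sprintf("prom_%04d", seq_len(n))
    Biostrings::DNAStringSet(out)
  })
}
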