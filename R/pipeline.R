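# Orchestration of the two end-to-end analyses: promoter accessibility of
# random sequences, and minimization of accidental intragenic promoters.

#' Promoter accessibility of random sequences
#'
#' Generates filtered random sequences and computes, per sequence, the
#' mutational distance to promoter activity under the core-motif criterion
#' (exact) or the PWM criterion (greedy trajectory to the calibrated
#' threshold), plus the 0 / 1 / >=2 distance histogram. Under the PWM
#' criterion the promoter scores before evolution and after the first
#' selected mutation are also returned.
#'
#' @param n number of random sequences.
#' @param length sequence length, nt.
#' @param criterion `"core"` or `"pwm"`.
#' @param model a calibrated `promoter_model` (required for `"pwm"`).
#' @param spacer_range valid spacer lengths for the core criterion.
#' @param strands strands scanned (default sense only: a promoter must face
#'   the downstream reporter).
#' @param max_steps cap on greedy mutations under the PWM criterion.
#' @param seed root seed.
#' @param ... further arguments to [generate_random_sequences()].
#' @return a list with `criterion`, `histogram` (from
#'   [distance_histogram()]), `per_sequence` (a `data.frame` with `seq_id`,
#'   `distance_bin`, `exact_distance`), `scores` (PWM criterion only: a list
#'   with `before` and `after_first`), `seed`, `n`.
#' @export
run_accessibility <- function(n = 30000L, length = 103L,
                              criterion = c("core", "pwm"), model = NULL,
                              spacer_range = c(15L, 19L), strands = "+",
                              max_steps = 5L, seed = 1L, ...) {
  criterion <- match.arg(criterion)
  if (criterion == "pwm") {
    if (is.null(model) || is.na(model$threshold))
      stop("the pwm criterion requires a calibrated model")
  }
  seqs <- as_char_seqs(generate_random_sequences(n, length = length,
                                                 seed = seed, ...))
  scores <- NULL
  if (criterion == "core") {
    results <- lapply(seq_along(seqs), function(i)
      core_distance(seqs[[i]], spacer_range, seq_id = names(seqs)[i]))
  } else {
    results <- lapply(seq_along(seqs), function(i)
      greedy_pwm_evolve(seqs[[i]], model, max_steps = max_steps,
                        strands = strands, seq_id = names(seqs)[i]))
    before <- vapply(results, function(r) attr(r, "trajectory")[1L],
                     numeric(1))
    after_first <- vapply(results, function(r) {
      tr <- attr(r, "trajectory")
      if (length(tr) >= 2L) tr[2L] else tr[1L]
    }, numeric(1))
    scores <- list(before = before, after_first = after_first)
  }
  per_sequence <- data.frame(
    seq_id = vapply(results, function(r) r$seq_id, character(1)),
    distance_bin = vapply(results, function(r) r$distance_bin, character(1)),
    exact_distance = vapply(results, function(r)
      if (is.na(r$exact_distance)) NA_integer_ else r$exact_distance,
      integer(1)),
    stringsAsFactors = FALSE)
  list(criterion = criterion,
       histogram = distance_histogram(per_sequence$distance_bin),
       per_sequence = per_sequence, scores = scores,
       seed = seed, n = n)
}

#' Genome-wide minimization analysis of accidental promoters
#'
#' For every gene: the wild-type accidental-expression score (sense,
#' antisense, total per kb), an `n_nulls`-replicate null ensemble
#' (synonymous recoding or codon shuffling), the mid-rank percentile and
#' decile of the wild type within its ensemble, and the ensemble median.
#' Group statistics: decile histograms (all genes and the essential
#' subset), a KS contrast of essential vs non-essential percentiles, the
#' paired sign test over toxin-antitoxin couples, KS contrasts of sense vs
#' antisense scores within toxins and within antitoxins, and the six-mer
#' enrichment table of the wild-type coding region against the null
#' replicates.
#'
#' @param genes a gene table (columns `gene_id`, `cds`, optional logical
#'   `essential`, `toxin`, `antitoxin`), e.g. from [read_genbank_cds()] or
#'   [synth_genome()].
#' @param model a calibrated `promoter_model`.
#' @param mode null-ensemble mode, `"usage"` or `"shuffle"`.
#' @param n_nulls replicates per gene.
#' @param usage a `codon_usage` table; derived from `genes` when `NULL`.
#' @param ta_pairs optional `data.frame` with columns `toxin`, `antitoxin`
#'   (gene ids) defining the couples for the paired sign test; omitted
#'   couples are skipped.
#' @param sixmer compute the six-mer enrichment table (logical).
#' @param z_cut six-mer flagging cutoff.
#' @param seed root seed for the null ensembles.
#' @return a list with `per_gene`, `decile_hist`, `decile_hist_essential`
#'   (when the subset is non-empty), `group_stats`, `sixmer`, `metadata`.
#' @export
run_minimization <- function(genes, model, mode = c("usage", "shuffle"),
                             n_nulls = 100L, usage = NULL, ta_pairs = NULL,
                             sixmer = TRUE, z_cut = 3, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(genes), nrow(genes) >= 10L,
            all(c("gene_id", "cds") %in% names(genes)))
  if (is.na(model$threshold)) stop("model threshold is not calibrated")
  for (lab in c("essential", "toxin", "antitoxin"))
    if (is.null(genes[[lab]])) genes[[lab]] <- FALSE
  if (mode == "usage" && is.null(usage)) usage <- usage_from_genes(genes)

  n <- nrow(genes)
  null_counts <- NULL
  null_windows <- numeric(n_nulls)
  rows <- vector("list", n)
  for (g in seq_len(n)) {
    id <- genes$gene_id[g]
    cds <- genes$cds[g]
    wt <- score_gene(cds, model)
    nulls <- make_ensemble(cds, mode = mode, n = n_nulls, usage = usage,
                           seed = seed, gene_id = id)
    null_scores <- vapply(nulls, function(s)
      score_gene(s, model)$total_per_kb, numeric(1))
    rk <- rank_gene(unname(null_scores), wt$total_per_kb)
    if (sixmer) {
      m <- Biostrings::oligonucleotideFrequency(
        Biostrings::DNAStringSet(nulls), width = 6L)
      null_counts <- if (is.null(null_counts)) t(m) else null_counts + t(m)
      null_windows <- null_windows + pmax(nchar(nulls) - 5L, 0L)
    }
    rows[[g]] <- data.frame(
      gene_id = id, length_nt = nchar(cds),
      sense_per_kb = wt$sense_per_kb,
      antisense_per_kb = wt$antisense_per_kb,
      total_per_kb = wt$total_per_kb,
      null_median = stats::median(null_scores),
      percentile = rk$percentile, decile = rk$decile,
      essential = genes$essential[g], toxin = genes$toxin[g],
      antitoxin = genes$antitoxin[g], stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, rows)
  rownames(per_gene) <- NULL

  group_stats <- list()
  if (any(per_gene$essential) && sum(!per_gene$essential) >= 2L &&
      sum(per_gene$essential) >= 2L) {
    group_stats$essential_vs_rest_ks <- group_ks(
      per_gene$percentile[per_gene$essential],
      per_gene$percentile[!per_gene$essential])
  }
  if (!is.null(ta_pairs) && nrow(ta_pairs) > 0L) {
    tox <- per_gene[match(ta_pairs$toxin, per_gene$gene_id), ]
    ant <- per_gene[match(ta_pairs$antitoxin, per_gene$gene_id), ]
    ok <- !is.na(tox$gene_id) & !is.na(ant$gene_id)
    if (sum(ok) >= 1L) {
      group_stats$toxin_vs_antitoxin_sign <- paired_sign_test(
        tox$total_per_kb[ok], ant$total_per_kb[ok])
    }
  }
  if (sum(per_gene$toxin) >= 2L)
    group_stats$toxin_sense_vs_antisense_ks <- group_ks(
      per_gene$sense_per_kb[per_gene$toxin],
      per_gene$antisense_per_kb[per_gene$toxin])
  if (sum(per_gene$antitoxin) >= 2L)
    group_stats$antitoxin_sense_vs_antisense_ks <- group_ks(
      per_gene$sense_per_kb[per_gene$antitoxin],
      per_gene$antisense_per_kb[per_gene$antitoxin])

  sixmer_table <- NULL
  if (sixmer) {
    wt_profile <- count_sixmers(genes$cds, source = "wt")
    null_profiles <- lapply(seq_len(n_nulls), function(r)
      structure(list(counts = null_counts[, r],
                     total_windows = null_windows[r],
                     source = paste0("null_", r)),
                class = "sixmer_profile"))
    sixmer_table <- sixmer_enrichment(wt_profile, null_profiles,
                                      z_cut = z_cut)
  }

  list(per_gene = per_gene,
       decile_hist = decile_histogram(per_gene),
       decile_hist_essential = if (any(per_gene$essential))
         decile_histogram(per_gene, per_gene$gene_id[per_gene$essential],
                          "essential genes") else NULL,
       group_stats = group_stats,
       sixmer = sixmer_table,
       metadata = list(seed = seed, n_nulls = n_nulls, mode = mode,
                       n_genes = n, threshold = model$threshold))
}
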