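# Scoring putative accidental promoters inside coding sequences, ranking
# wild-type genes against their null ensembles, and the group statistics.

#' Accidental-expression score of a coding sequence
#'
#' Scans both strands for promoter placements scoring at or above the
#' calibrated threshold, retains local maxima by non-maximum suppression (no
#' two retained hits with -10 starts closer than `nms_radius` nt on the same
#' strand; the higher total wins, ties to the leftmost), and sums per-hit
#' contributions `(s35 + s10) * (1 + (total - threshold))`. The second
#' factor is a monotone discriminant-margin surrogate, so comparative
#' results (wild type vs nulls, group contrasts) are meaningful while
#' absolute magnitudes are scorer-specific. Per-strand sums are normalized
#' to the gene's length and reported per kb.
#'
#' @param cds a single DNA string (a coding sequence).
#' @param model a calibrated `promoter_model`.
#' @param strands strands scanned (default both: accidental promoters count
#'   in sense and antisense orientation).
#' @param nms_radius suppression radius on -10 starts, nt.
#' @return an `accidental_score` object: `sense_per_kb`, `antisense_per_kb`,
#'   `total_per_kb`, and `hits` (a `data.frame` with `strand`, 0-based
#'   `pos35`, `pos10`, `spacer`, `s35`, `s10`, `total`, `margin`,
#'   `contribution`).
#' @export
score_gene <- function(cds, model, strands = c("+", "-"), nms_radius = 10L) {
  stopifnot(inherits(model, "promoter_model"))
  if (is.na(model$threshold)) stop("model threshold is not calibrated")
  enc <- encode_dna(cds)
  L <- length(enc)
  if (L < min_window(model$spacer_range))
    stop("coding sequence shorter than the minimal promoter window")
  per_strand <- stats::setNames(c(0, 0), c("+", "-"))
  hits <- list()
  for (st in strands) {
    e <- if (st == "+") enc else revcomp_enc(enc)
    sc <- scan_strand(e, model)
    above <- which(sc$total >= model$threshold)
    if (!length(above)) next
    cand <- data.frame(pos35 = sc$pos35[above], pos10 = sc$pos10[above],
                       spacer = sc$spacer[above], s35 = sc$s35[above],
                       s10 = sc$s10[above], total = sc$total[above])
    ## non-maximum suppression on -10 starts
    cand <- cand[order(-cand$total, cand$pos10, cand$pos35), , drop = FALSE]
    kept_pos10 <- integer(0)
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (!length(kept_pos10) ||
          all(abs(cand$pos10[r] - kept_pos10) >= nms_radius)) {
        keep[r] <- TRUE
        kept_pos10 <- c(kept_pos10, cand$pos10[r])
      }
    }
    cand <- cand[keep, , drop = FALSE]
    cand$strand <- st
    cand$margin <- cand$total - model$threshold
    cand$contribution <- (cand$s35 + cand$s10) * (1 + cand$margin)
    per_strand[[st]] <- sum(cand$contribution) * 1000 / L
    hits[[length(hits) + 1L]] <- cand
  }
  hits <- if (length(hits)) do.call(rbind, hits)
          else data.frame(pos35 = integer(0), pos10 = integer(0),
                          spacer = integer(0), s35 = numeric(0),
                          s10 = numeric(0), total = numeric(0),
                          strand = character(0), margin = numeric(0),
                          contribution = numeric(0))
  hits$pos35 <- hits$pos35 - 1L   # 0-based
  hits$pos10 <- hits$pos10 - 1L
  hits <- hits[order(hits$strand != "+", hits$pos35), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(sense_per_kb = unname(per_strand[["+"]]),
                 antisense_per_kb = unname(per_strand[["-"]]),
                 total_per_kb = unname(sum(per_strand)),
                 hits = hits[, c("strand", "pos35", "pos10", "spacer",
                                 "s35", "s10", "total", "margin",
                                 "contribution")]),
            class = "accidental_score")
}

#' Null ensemble of accidental-expression scores for one gene
#'
#' Scores the wild-type CDS and `n` null versions ([make_ensemble()]) with
#' [score_gene()].
#'
#' @inheritParams make_ensemble
#' @param model a calibrated `promoter_model`.
#' @return a `null_ensemble` object: `gene_id`, `mode`, `wt_score`
#'   (total per kb), `null_scores` (length `n`), plus the per-strand
#'   wild-type components `wt_sense`, `wt_antisense`.
#' @export
null_ensemble <- function(cds, model, mode = c("usage", "shuffle"),
                          n = 100L, usage = NULL, seed = 1L,
                          gene_id = "gene") {
  mode <- match.arg(mode)
  wt <- score_gene(cds, model)
  nulls <- make_ensemble(cds, mode = mode, n = n, usage = usage,
                         seed = seed, gene_id = gene_id)
  null_scores <- vapply(nulls, function(s) score_gene(s, model)$total_per_kb,
                        numeric(1))
  structure(list(gene_id = gene_id, mode = mode,
                 wt_score = wt$total_per_kb,
                 wt_sense = wt$sense_per_kb,
                 wt_antisense = wt$antisense_per_kb,
                 null_scores = unname(null_scores)),
            class = "null_ensemble")
}

#' Rank a wild-type gene within its null ensemble
#'
#' Mid-rank percentile: `(#\{null < wt\} + 0.5 #\{null == wt\}) / N`. Deciles
#' are `floor(10 * percentile) + 1` clipped to `[1, 10]`; a low decile means
#' fewer predicted accidental promoters than the null.
#'
#' @param ensemble a `null_ensemble`, or a numeric vector of null scores.
#' @param wt_score wild-type score when `ensemble` is a plain vector.
#' @return a list with `gene_id`, `percentile`, `decile` (`NA` when the
#'   ensemble has fewer than 10 replicates).
#' @export
rank_gene <- function(ensemble, wt_score = NULL) {
  if (inherits(ensemble, "null_ensemble")) {
    nulls <- ensemble$null_scores
    wt <- ensemble$wt_score
    id <- ensemble$gene_id
  } else {
    nulls <- ensemble
    wt <- wt_score
    id <- "gene"
  }
  N <- length(nulls)
  if (N < 1L) stop("empty null ensemble")
  percentile <- (sum(nulls < wt) + 0.5 * sum(nulls == wt)) / N
  decile <- if (N >= 10L) min(floor(10 * percentile) + 1L, 10L) else NA_integer_
  list(gene_id = id, percentile = percentile, decile = as.integer(decile))
}

#' Decile histogram of gene ranks
#'
#' @param ranks a `data.frame` with columns `gene_id` and `decile`.
#' @param subset optional character vector of gene ids to restrict to.
#' @param subset_name name used in the error when the subset is empty.
#' @return a `data.frame` with `decile` (1-10), `count`, `percent` (summing
#'   to 100), and `expected_percent` (the flat 10% reference of a gene set
#'   indistinguishable from its nulls).
#' @export
decile_histogram <- function(ranks, subset = NULL, subset_name = "subset") {
  stopifnot(is.data.frame(ranks), all(c("gene_id", "decile") %in% names(ranks)))
  if (!is.null(subset)) {
    ranks <- ranks[ranks$gene_id %in% subset, , drop = FALSE]
    if (nrow(ranks) == 0L)
      stop("no genes left after restricting to ", subset_name)
  }
  if (nrow(ranks) == 0L) stop("no ranks supplied")
  counts <- table(factor(ranks$decile, levels = 1:10))
  data.frame(decile = 1:10, count = as.integer(counts),
             percent = 100 * as.integer(counts) / nrow(ranks),
             expected_percent = 10)
}

#' Two-sample Kolmogorov-Smirnov contrast between gene groups
#'
#' @param group_a,group_b numeric vectors (ranks or scores), each of size
#'   at least 2.
#' @return a list with the KS `D` statistic and the asymptotic `p_value`.
#' @export
group_ks <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("both groups need at least 2 values")
  kt <- suppressWarnings(stats::ks.test(group_a, group_b, exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Exact paired sign test
#'
#' Drops exact ties, counts `k = #\{a > b\}` among the remaining `n` pairs,
#' and returns the exact two-sided binomial p-value at p0 = 0.5 (summing the
#' probabilities of all outcomes no more likely than the observed one).
#'
#' @param score_a,score_b paired numeric vectors.
#' @return a list with `k`, `n`, `fraction` (`k/n`), `p_value`.
#' @export
paired_sign_test <- function(score_a, score_b) {
  stopifnot(length(score_a) == length(score_b))
  keep <- score_a != score_b
  n <- sum(keep)
  if (n < 1L) stop("all pairs are exactly tied")
  k <- sum(score_a[keep] > score_b[keep])
  p <- stats::binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
  list(k = as.integer(k), n = as.integer(n), fraction = k / n, p_value = p)
}
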