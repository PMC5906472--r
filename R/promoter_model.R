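# Sigma70 promoter scoring: position weight matrices for the -10 and -35
# hexamers plus an additive spacer-length weight, a calibrated threshold, and
# the simpler core-motif criterion (TTGnnn and TAnnnT with a valid spacer).

# Fixed positions of the core criterion within each hexamer (1-based):
# -35 "TTGnnn" fixes T,T,G at 1..3; -10 "TAnnnT" fixes T,A at 1..2 and T at 6.
CORE35_POS <- c(1L, 2L, 3L); CORE35_BASE <- c(4L, 4L, 3L)  # T,T,G
CORE10_POS <- c(1L, 2L, 6L); CORE10_BASE <- c(4L, 1L, 4L)  # T,A,T

#' Build a sigma70 promoter model from aligned training windows
#'
#' Each training window supplies a -35 hexamer, a spacer length, and a -10
#' hexamer. Per-position log-odds are
#' `log2((count + pseudocount) / (N + 4 * pseudocount) / 0.25)`; the spacer
#' weight is the log2 ratio of the add-one-smoothed empirical spacer-length
#' frequency to a uniform distribution over `spacer_range`.
#'
#' @param windows a `data.frame` with columns `minus35` (6-mer), `spacer`
#'   (integer nt), `minus10` (6-mer).
#' @param pseudocount additive pseudocount per base.
#' @param spacer_range inclusive `[min, max]` spacer length the model scores.
#' @return an object of class `promoter_model` with elements `w35`, `w10`
#'   (6x4 log-odds matrices, columns A,C,G,T), `spacer_weight` (named by
#'   length), `spacer_range`, and an unset `threshold`.
#' @export
build_pwm <- function(windows, pseudocount = 0.5, spacer_range = c(15L, 19L)) {
  stopifnot(is.data.frame(windows),
            all(c("minus35", "spacer", "minus10") %in% names(windows)))
  n <- nrow(windows)
  if (n < 2L) stop("need at least 2 training windows")
  sp <- as.integer(windows$spacer)
  if (any(sp < spacer_range[1L] | sp > spacer_range[2L]))
    stop("training spacer length outside spacer_range [",
         spacer_range[1L], ",", spacer_range[2L], "]")

  count_matrix <- function(hexamers) {
    m <- matrix(0L, nrow = 6L, ncol = 4L, dimnames = list(NULL, DNA_BASES))
    for (h in hexamers) {
      enc <- encode_dna(h)
      if (length(enc) != 6L) stop("training window is not a hexamer: ", h)
      for (j in 1:6) m[j, enc[j]] <- m[j, enc[j]] + 1L
    }
    m
  }
  logodds <- function(cnt)
    log2((cnt + pseudocount) / (n + 4 * pseudocount) / 0.25)

  lens <- spacer_range[1L]:spacer_range[2L]
  sp_cnt <- tabulate(sp - spacer_range[1L] + 1L, nbins = length(lens))
  sp_freq <- (sp_cnt + 1) / (n + length(lens))
  spacer_weight <- stats::setNames(log2(sp_freq * length(lens)), lens)
  if (17L %in% lens && which.max(spacer_weight) != match(17L, lens))
    warning("spacer weight is not maximal at 17 nt in this training set")

  structure(list(
    w35 = logodds(count_matrix(windows$minus35)),
    w10 = logodds(count_matrix(windows$minus10)),
    spacer_weight = spacer_weight,
    spacer_range = as.integer(spacer_range),
    threshold = NA_real_,
    pseudocount = pseudocount,
    n_train = n
  ), class = "promoter_model")
}

#' @export
print.promoter_model <- function(x, ...) {
  cat("sigma70 promoter model (", x$n_train, " training windows)\n", sep = "")
  cat("  -35 consensus:", paste(DNA_BASES[apply(x$w35, 1, which.max)],
                                collapse = ""), "\n")
  cat("  -10 consensus:", paste(DNA_BASES[apply(x$w10, 1, which.max)],
                                collapse = ""), "\n")
  cat("  spacer range: [", x$spacer_range[1L], ",", x$spacer_range[2L],
      "], optimum ", names(x$spacer_weight)[which.max(x$spacer_weight)],
      " nt\n", sep = "")
  cat("  threshold:", if (is.na(x$threshold)) "uncalibrated"
      else format(x$threshold, digits = 4), "\n")
  invisible(x)
}

min_window <- function(spacer_range) 6L + spacer_range[1L] + 6L

# Per-start element scores: s[i] = sum_j W[j, enc[i+j-1]], i = 1..L-5.
element_scores <- function(enc, W) {
  n <- length(enc) - 5L
  s <- W[1L, enc[1:n]]
  for (j in 2:6) s <- s + W[j, enc[j:(n + j - 1L)]]
  unname(s)
}

# All (pos35, spacer) placements and totals on one strand (1-based pos
# here). Returns parallel vectors, not a data.frame, for speed: the scan is
# the inner loop of the ensemble analyses.
scan_strand <- function(enc, model) {
  L <- length(enc)
  s35 <- element_scores(enc, model$w35)
  s10 <- element_scores(enc, model$w10)
  sps <- model$spacer_range[1L]:model$spacer_range[2L]
  spw <- unname(model$spacer_weight)
  sizes <- pmax(L - 11L - sps, 0L)
  ntot <- sum(sizes)
  if (ntot == 0L) return(NULL)
  pos35 <- integer(ntot); spacer <- integer(ntot)
  e35 <- numeric(ntot); e10 <- numeric(ntot); total <- numeric(ntot)
  at <- 0L
  for (k in seq_along(sps)) {
    imax <- sizes[k]
    if (imax == 0L) next
    sp <- sps[k]
    i35 <- seq_len(imax)
    slot <- at + i35
    a <- s35[i35]; b <- s10[i35 + 6L + sp]
    pos35[slot] <- i35
    spacer[slot] <- sp
    e35[slot] <- a; e10[slot] <- b
    total[slot] <- a + b + spw[k]
    at <- at + imax
  }
  list(pos35 = pos35, pos10 = pos35 + 6L + spacer, spacer = spacer,
       s35 = e35, s10 = e10, total = total)
}

# Deterministic tie-break: highest total, then smaller pos35, then smaller
# spacer (then "+" strand, applied by callers). Input/output: scan_strand
# list; returns a one-row data.frame.
pick_best <- function(sc) {
  top <- max(sc$total)
  i <- which(sc$total == top)
  if (length(i) > 1L) i <- i[order(sc$pos35[i], sc$spacer[i])][1L]
  data.frame(pos35 = sc$pos35[i], pos10 = sc$pos10[i],
             spacer = sc$spacer[i], s35 = sc$s35[i], s10 = sc$s10[i],
             total = sc$total[i])
}

#' Best sliding-window promoter score of a sequence
#'
#' Maximizes `s35 + s10 + spacer_weight` over all placements of the
#' -35/spacer/-10 template fully inside the sequence, over the requested
#' strands. Ties break to the smaller -35 start, then the smaller spacer,
#' then the `+` strand. The `-` strand is scored by scanning the reverse
#' complement; reported positions refer to the scanned strand.
#'
#' @param model a `promoter_model` (threshold not required).
#' @param seq a single DNA string.
#' @param strands subset of `c("+", "-")`.
#' @return a list with `score` and `hit`; `hit` is a one-row `data.frame`
#'   with `strand`, 0-based `pos35`, `pos10`, `spacer`, `s35`, `s10`,
#'   `total`, and `margin` (`max(0, total - threshold)`; `NA` when the model
#'   is uncalibrated).
#' @export
best_window_score <- function(model, seq, strands = "+") {
  stopifnot(inherits(model, "promoter_model"))
  enc <- encode_dna(seq)
  if (length(enc) < min_window(model$spacer_range))
    stop("sequence shorter than the minimal promoter window (",
         min_window(model$spacer_range), " nt)")
  best <- NULL
  for (st in c("+", "-")) {         # "+" first so ties prefer it
    if (!(st %in% strands)) next
    e <- if (st == "+") enc else revcomp_enc(enc)
    cand <- pick_best(scan_strand(e, model))
    cand$strand <- st
    if (is.null(best) || cand$total > best$total) best <- cand
  }
  best$pos35 <- best$pos35 - 1L   # 0-based at the API boundary
  best$pos10 <- best$pos10 - 1L
  best$margin <- if (is.na(model$threshold)) NA_real_
                 else max(0, best$total - model$threshold)
  rownames(best) <- NULL
  list(score = best$total,
       hit = best[, c("strand", "pos35", "pos10", "spacer",
                      "s35", "s10", "total", "margin")])
}

#' Calibrate the promoter-score threshold
#'
#' Sets the threshold to the median best-window score of a calibration set
#' (in the source study, constitutive promoters); the median of an
#' even-sized set is the mean of the two central values.
#'
#' @param model a `promoter_model`.
#' @param calibration_set character vector or `DNAStringSet` of sequences.
#' @param strands strands scanned during calibration (default sense only;
#'   promoters in a calibration set are oriented).
#' @return the model with `threshold` set.
#' @export
calibrate_threshold <- function(model, calibration_set, strands = "+") {
  seqs <- as_char_seqs(calibration_set)
  if (length(seqs) == 0L) stop("empty calibration set")
  short <- nchar(seqs) < min_window(model$spacer_range)
  if (any(short))
    stop("calibration sequence(s) shorter than the minimal window: ",
         paste(names(seqs)[short], collapse = ", "))
  scores <- vapply(seqs, function(s)
    best_window_score(model, s, strands)$score, numeric(1))
  model$threshold <- stats::median(scores)
  model
}

#' The packaged default sigma70 model
#'
#' Builds the PWM from the packaged synthetic alignment of canonical-like
#' windows (`inst/extdata/sigma70_training_windows.tsv`) and, by default,
#' calibrates its threshold as the median score of a synthetic
#' constitutive-promoter set ([synth_promoter_set()], n = 556, per-position
#' noise 0.30). Fully reproducible given `seed`; replaceable by any model
#' trained with [build_pwm()] on real promoter alignments.
#'
#' @param calibrate calibrate the threshold (logical).
#' @param n_calibration size of the synthetic calibration set.
#' @param noise per-position mutation probability of the calibration set.
#' @param seed seed for the calibration set.
#' @return a `promoter_model`.
#' @export
default_promoter_model <- function(calibrate = TRUE, n_calibration = 556L,
                                   noise = 0.30, seed = 42L) {
  path <- system.file("extdata", "sigma70_training_windows.tsv",
                      package = "denovoprom", mustWork = TRUE)
  windows <- utils::read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE)
  model <- build_pwm(windows)
  if (calibrate) {
    calib <- synth_promoter_set(n = n_calibration,
                                noise_per_position = noise, seed = seed)
    model <- calibrate_threshold(model, calib)
  }
  model
}

# ---- core-motif criterion --------------------------------------------------

core35_match <- function(enc) {
  n <- length(enc) - 5L
  enc[1:n] == 4L & enc[2:(n + 1L)] == 4L & enc[3:(n + 2L)] == 3L
}
core10_match <- function(enc) {
  n <- length(enc) - 5L
  enc[1:n] == 4L & enc[2:(n + 1L)] == 1L & enc[6:(n + 5L)] == 4L
}

#' Exact core-motif promoter hits
#'
#' Finds every placement where the six fixed bases of the core criterion
#' (`TTGnnn` for the -35, `TAnnnT` for the -10) match exactly with a spacer
#' inside `spacer_range`. Hits are ordered by (-35 start, spacer).
#'
#' @param seq a single DNA string.
#' @param spacer_range inclusive valid spacer lengths.
#' @param strands subset of `c("+", "-")`; the `-` strand scans the reverse
#'   complement and reports positions on the scanned strand.
#' @return a `data.frame` with `strand` and 0-based `pos35`, `pos10`,
#'   `spacer` (0 rows when there is no hit).
#' @export
core_motif_hits <- function(seq, spacer_range = c(15L, 19L), strands = "+") {
  enc0 <- encode_dna(seq)
  if (length(enc0) < min_window(spacer_range))
    stop("sequence shorter than the minimal core window (",
         min_window(spacer_range), " nt)")
  out <- list()
  for (st in strands) {
    enc <- if (st == "+") enc0 else revcomp_enc(enc0)
    m35 <- core35_match(enc)
    m10 <- core10_match(enc)
    n <- length(m35)
    for (sp in spacer_range[1L]:spacer_range[2L]) {
      imax <- length(enc) - 11L - sp
      if (imax < 1L) next
      i35 <- which(m35[seq_len(imax)] & m10[seq_len(imax) + 6L + sp])
      if (length(i35))
        out[[length(out) + 1L]] <- data.frame(
          strand = st, pos35 = i35 - 1L, pos10 = i35 + 5L + sp,
          spacer = sp)
    }
  }
  if (!length(out))
    return(data.frame(strand = character(0), pos35 = integer(0),
                      pos10 = integer(0), spacer = integer(0)))
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$strand != "+", hits$pos35, hits$spacer), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Minimum fixed-base mismatches to the core criterion
#'
#' Over all placements (sense strand), the minimum number of core fixed-base
#' mismatches; ties break to the smaller -35 start, then the smaller spacer.
#'
#' @inheritParams core_motif_hits
#' @return a list with `min_mismatch`, the 0-based `pos35`, `pos10`,
#'   `spacer` of the best placement, and `mismatches`, a `data.frame` of the
#'   fixed positions still wrong there (0-based `pos`, `from`, `to`).
#' @export
count_mismatches_to_core <- function(seq, spacer_range = c(15L, 19L)) {
  enc <- encode_dna(seq)
  if (length(enc) < min_window(spacer_range))
    stop("sequence shorter than the minimal core window (",
         min_window(spacer_range), " nt)")
  n <- length(enc) - 5L
  mm35 <- (enc[1:n] != 4L) + (enc[2:(n + 1L)] != 4L) + (enc[3:(n + 2L)] != 3L)
  mm10 <- (enc[1:n] != 4L) + (enc[2:(n + 1L)] != 1L) + (enc[6:(n + 5L)] != 4L)
  best <- list(mm = Inf, pos35 = NA_integer_, spacer = NA_integer_)
  for (sp in spacer_range[1L]:spacer_range[2L]) {   # ascending: tie-break
    imax <- length(enc) - 11L - sp
    if (imax < 1L) next
    tot <- mm35[seq_len(imax)] + mm10[seq_len(imax) + 6L + sp]
    i <- which.min(tot)
    if (tot[i] < best$mm) best <- list(mm = tot[i], pos35 = i, spacer = sp)
  }
  i35 <- best$pos35
  i10 <- i35 + 6L + best$spacer
  fix_pos <- c(i35 - 1L + CORE35_POS, i10 - 1L + CORE10_POS)
  fix_base <- c(CORE35_BASE, CORE10_BASE)
  bad <- enc[fix_pos] != fix_base
  mismatches <- data.frame(
    pos = fix_pos[bad] - 1L,
    from = DNA_BASES[enc[fix_pos[bad]]],
    to = DNA_BASES[fix_base[bad]],
    stringsAsFactors = FALSE
  )
  mismatches <- mismatches[order(mismatches$pos), , drop = FALSE]
  rownames(mismatches) <- NULL
  list(min_mismatch = as.integer(best$mm),
       pos35 = i35 - 1L, pos10 = i10 - 1L, spacer = best$spacer,
       mismatches = mismatches)
}
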