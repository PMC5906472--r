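# Mutational distance from a sequence to promoter activity, under the core
# criterion (exact: mismatches are independent single-base fixes) or under
# the PWM criterion (greedy hill climbing to the calibrated threshold).

mut_distance_result <- function(seq_id, criterion, exact_distance, capped,
                                path, final_score = NA_real_) {
  bin <- if (capped || exact_distance >= 2L) ">=2"
         else as.character(exact_distance)
  structure(list(seq_id = seq_id, criterion = criterion,
                 distance_bin = bin,
                 exact_distance = if (capped) NA_integer_
                                  else as.integer(exact_distance),
                 capped = capped, path = path, final_score = final_score),
            class = "mut_distance")
}

#' Mutational distance under the core-motif criterion
#'
#' The exact minimal number of substitutions: each fixed-base mismatch of
#' the best core placement costs exactly one substitution, so the minimum
#' over placements of [count_mismatches_to_core()] is the distance. The path
#' lists the substitutions fixing the best placement, ordered 5' to 3'.
#'
#' @param seq a single DNA string.
#' @param spacer_range valid spacer lengths.
#' @param cap distances above `cap` are reported as capped.
#' @param seq_id identifier carried into the result.
#' @return a `mut_distance` object: `seq_id`, `criterion`, `distance_bin`
#'   (`"0"`, `"1"`, `">=2"`), `exact_distance`, `path` (`data.frame` of
#'   0-based `pos`, `from`, `to`), `final_score` (`NA` for core).
#' @export
core_distance <- function(seq, spacer_range = c(15L, 19L), cap = 5L,
                          seq_id = "seq") {
  cm <- count_mismatches_to_core(seq, spacer_range)
  capped <- cm$min_mismatch > cap
  mut_distance_result(seq_id, "core", cm$min_mismatch, capped,
                      if (capped) NULL else cm$mismatches)
}

#' Greedy in-silico evolution under the PWM criterion
#'
#' Until [best_window_score()] reaches the calibrated threshold, evaluates
#' all `3L` single substitutions and applies the one maximizing the new
#' score (ties: leftmost position, then alphabetical target base). The score
#' trajectory is strictly increasing until the stop. Stops after `max_steps`
#' with a capped distance.
#'
#' @param seq a single DNA string.
#' @param model a calibrated `promoter_model`.
#' @param max_steps maximum number of substitutions to apply.
#' @param strands strands scanned when scoring.
#' @param seq_id identifier carried into the result.
#' @return a `mut_distance` object (criterion `"pwm"`); `final_score` is the
#'   score of the final sequence, and attribute `"trajectory"` holds the
#'   score after each step (starting score first).
#' @export
greedy_pwm_evolve <- function(seq, model, max_steps = 5L, strands = "+",
                              seq_id = "seq") {
  stopifnot(inherits(model, "promoter_model"))
  if (is.na(model$threshold)) stop("model threshold is not calibrated")
  if (max_steps < 1L) stop("max_steps must be at least 1")
  enc <- encode_dna(seq)
  L <- length(enc)
  score_of <- function(e) {
    best <- -Inf
    for (st in c("+", "-")) {
      if (!(st %in% strands)) next
      ee <- if (st == "+") e else revcomp_enc(e)
      s <- max(scan_strand(ee, model)$total)
      if (s > best) best <- s
    }
    best
  }
  cur <- score_of(enc)
  trajectory <- cur
  path <- list()
  steps <- 0L
  while (cur < model$threshold && steps < max_steps) {
    best_s <- -Inf; best_p <- NA_integer_; best_b <- NA_integer_
    for (p in seq_len(L)) {
      orig <- enc[p]
      for (b in 1:4) {                       # alphabetical A,C,G,T tie order
        if (b == orig) next
        enc[p] <- b
        s <- score_of(enc)
        if (s > best_s) { best_s <- s; best_p <- p; best_b <- b }
      }
      enc[p] <- orig
    }
    path[[length(path) + 1L]] <- data.frame(
      pos = best_p - 1L, from = DNA_BASES[enc[best_p]],
      to = DNA_BASES[best_b], stringsAsFactors = FALSE)
    enc[best_p] <- best_b
    cur <- best_s
    trajectory <- c(trajectory, cur)
    steps <- steps + 1L
  }
  capped <- cur < model$threshold
  res <- mut_distance_result(seq_id, "pwm", steps, capped,
                             if (length(path)) do.call(rbind, path)
                             else data.frame(pos = integer(0),
                                             from = character(0),
                                             to = character(0)),
                             final_score = cur)
  attr(res, "trajectory") <- trajectory
  res
}

#' Distance histogram over the bins 0 / 1 / >=2
#'
#' @param results a list of `mut_distance` objects, or a character vector of
#'   bins.
#' @return a `data.frame` with `bin`, `count`, `percent` (summing to 100)
#'   and the binomial standard error of each percentage.
#' @export
distance_histogram <- function(results) {
  bins <- if (is.character(results)) results
          else vapply(results, function(r) r$distance_bin, character(1))
  if (!length(bins)) stop("no results supplied")
  lev <- c("0", "1", ">=2")
  counts <- table(factor(bins, levels = lev))
  n <- sum(counts)
  p <- as.numeric(counts) / n
  data.frame(bin = lev, count = as.integer(counts),
             percent = 100 * p,
             se_percent = 100 * sqrt(p * (1 - p) / n))
}
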