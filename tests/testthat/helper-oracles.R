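# Independent oracles: deliberately naive re-implementations used to check
# the package's vectorized code paths.

BASES <- c("A", "C", "G", "T")

# regex-style core-criterion matcher (one alternation per spacer length)
oracle_core_pattern <- function(spacer_range = c(15, 19)) {
  paste(vapply(spacer_range[1]:spacer_range[2], function(sp)
    paste0("TTG.{", 3 + sp, "}TA...T"), character(1)), collapse = "|")
}
.core_default_pat <- oracle_core_pattern()
oracle_has_core <- function(seq, spacer_range = c(15, 19)) {
  pat <- if (identical(spacer_range, c(15, 19))) .core_default_pat
         else oracle_core_pattern(spacer_range)
  grepl(pat, seq)
}

# brute-force mismatch count over all placements, character by character
oracle_core_mismatches <- function(seq, spacer_range = c(15, 19)) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  best <- Inf
  for (sp in spacer_range[1]:spacer_range[2]) {
    for (i in seq_len(max(L - 11 - sp, 0))) {
      j <- i + 6 + sp
      mm <- (ch[i] != "T") + (ch[i + 1] != "T") + (ch[i + 2] != "G") +
            (ch[j] != "T") + (ch[j + 1] != "A") + (ch[j + 5] != "T")
      if (mm < best) best <- mm
    }
  }
  best
}

# exhaustive placement scorer: explicit double loop over the model matrices
oracle_best_window <- function(model, seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  best <- -Inf; best_pos35 <- NA; best_spacer <- NA
  for (sp in model$spacer_range[1]:model$spacer_range[2]) {
    for (i in seq_len(max(L - 11 - sp, 0))) {
      s <- model$spacer_weight[[as.character(sp)]]
      for (k in 0:5) s <- s + model$w35[k + 1, ch[i + k]]
      for (k in 0:5) s <- s + model$w10[k + 1, ch[i + 6 + sp + k]]
      s <- unname(s)
      if (s > best) { best <- s; best_pos35 <- i - 1; best_spacer <- sp }
    }
  }
  list(score = best, pos35 = best_pos35, spacer = best_spacer)
}

# distance by exhaustive enumeration of 0-, 1- and 2-substitution
# neighbours; neighbour strings are edited in place via substr<-
oracle_neighbour_distance <- function(seq, spacer_range = c(15, 19)) {
  pat <- if (identical(spacer_range, c(15, 19))) .core_default_pat
         else oracle_core_pattern(spacer_range)
  if (grepl(pat, seq)) return(0L)
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  one <- character(0)
  for (p in seq_len(L)) for (b in BASES) {
    if (b == ch[p]) next
    m <- seq; substr(m, p, p) <- b
    one <- c(one, m)
  }
  if (any(grepl(pat, one))) return(1L)
  for (p in seq_len(L - 1)) for (b1 in BASES) {
    if (b1 == ch[p]) next
    m1 <- seq; substr(m1, p, p) <- b1
    two <- character(0)
    for (q in (p + 1):L) for (b2 in BASES) {
      if (b2 == ch[q]) next
      m <- m1; substr(m, q, q) <- b2
      two <- c(two, m)
    }
    if (any(grepl(pat, two))) return(2L)
  }
  3L   # ">= 3"
}

# naive per-window six-mer tally into an environment-backed dictionary
oracle_sixmer_tally <- function(seqs) {
  d <- new.env()
  for (s in seqs) {
    L <- nchar(s)
    if (L < 6) next
    for (i in seq_len(L - 5)) {
      k <- substr(s, i, i + 5)
      d[[k]] <- (if (is.null(d[[k]])) 0 else d[[k]]) + 1
    }
  }
  out <- setNames(numeric(4096),
                  sort(apply(expand.grid(rep(list(BASES), 6))[, 6:1], 1,
                             paste, collapse = "")))
  for (k in ls(d)) out[k] <- d[[k]]
  out
}

# two-sample KS D by direct ECDF-gap enumeration
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# exact two-sided sign-test p: sum of P(X = j) over outcomes no more likely
# than the observed k, X ~ Binomial(n, 1/2)
oracle_sign_p <- function(k, n) {
  p <- dbinom(0:n, n, 0.5)
  sum(p[p <= p[k + 1] + 1e-12])
}

# naive codon tally per amino-acid family
oracle_codon_usage <- function(cds_vec) {
  gc <- Biostrings::GENETIC_CODE
  counts <- setNames(numeric(64), names(gc))
  for (s in cds_vec) {
    n <- nchar(s)
    for (i in seq(1, n, 3)) {
      cod <- substr(s, i, i + 2)
      counts[cod] <- counts[cod] + 1
    }
  }
  counts
}
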