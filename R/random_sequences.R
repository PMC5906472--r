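# Random candidate-promoter sequences: i.i.d. uniform bases filtered for
# genome-like GC content and against long homopolymer runs.

#' GC fraction of a sequence
#'
#' @param seq a single DNA string.
#' @return `(#G + #C) / length`.
#' @export
gc_fraction <- function(seq) {
  enc <- encode_dna(seq)
  mean(enc == 2L | enc == 3L)
}

#' Longest homopolymer run
#'
#' @param seq a single DNA string.
#' @return length (nt) of the longest single-letter run.
#' @export
max_homopolymer_run <- function(seq) {
  max(rle(encode_dna(seq))$lengths)
}

#' Generate filtered random sequences
#'
#' Draws sequences with all four bases at equal probability and keeps only
#' those whose GC fraction lies within `[gc_min, gc_max]` (bounds inclusive)
#' and whose longest homopolymer run is at most `max_run` nt. The defaults
#' emulate a 50.8%-GC bacterial genome: 103-nt sequences, GC between 45.6%
#' and 56.0%, runs of at most 5. Rejection sampling from a single RNG stream
#' seeded once, so the full batch is reproducible.
#'
#' @param n number of sequences to return.
#' @param length sequence length in nt.
#' @param gc_min,gc_max inclusive GC-fraction bounds.
#' @param max_run maximum tolerated homopolymer run (nt).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param max_attempts_per_seq cap on draws per requested sequence before the
#'   spec is declared infeasible.
#' @return a [Biostrings::DNAStringSet] of `n` sequences named
#'   `seq_000001, ...`.
#' @export
generate_random_sequences <- function(n, length = 103L,
                                      gc_min = 0.456, gc_max = 0.560,
                                      max_run = 5L, seed = NULL,
                                      max_attempts_per_seq = 10000L) {
  stopifnot(n >= 1L, length >= 1L, max_run >= 1L,
            gc_min >= 0, gc_max <= 1, gc_min <= gc_max)
  with_seed(seed, {
    kept <- vector("list", n)
    got <- 0L
    attempts <- 0L
    cap <- as.numeric(max_attempts_per_seq) * n
    while (got < n) {
      attempts <- attempts + 1L
      if (attempts > cap)
        stop("rejection sampling failed after ", format(cap),
             " attempts; filter specification looks infeasible")
      enc <- sample.int(4L, length, replace = TRUE)
      gc <- mean(enc == 2L | enc == 3L)
      if (gc < gc_min || gc > gc_max) next
      if (max(rle(enc)$lengths) > max_run) next
      got <- got + 1L
      kept[[got]] <- enc
    }
    chr <- vapply(kept, decode_dna, character(1))
    names(chr) <- sprintf("seq_%06d", seq_len(n))
    Biostrings::DNAStringSet(chr)
  })
}
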