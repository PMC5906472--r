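# Six-mer occurrence profiles over coding-region sets and motif-level
# depletion/overrepresentation relative to a recoded null ensemble.

#' Count all six-mers in a sequence set
#'
#' Overlapping windows, counted within each sequence only (no cross-gene
#' windows) and on the coding strand only. Sequences shorter than 6 nt
#' contribute zero windows.
#'
#' @param seqs character vector or `DNAStringSet` of coding sequences.
#' @param source a label stored with the profile (e.g. `"wt"` or a null
#'   replicate id).
#' @param both_strands also count windows of the reverse complement of each
#'   sequence (off by default: the analysis counts the coding strand only).
#' @return a `sixmer_profile` object with `counts` (length-4096 integer
#'   vector named by six-mer, lexicographic A<C<G<T), `total_windows`,
#'   `source`.
#' @export
count_sixmers <- function(seqs, source = "wt", both_strands = FALSE) {
  chr <- as_char_seqs(seqs)
  dss <- Biostrings::DNAStringSet(chr)
  if (both_strands)
    dss <- c(dss, Biostrings::reverseComplement(dss))
  m <- Biostrings::oligonucleotideFrequency(dss, width = 6L)
  counts <- if (nrow(m)) colSums(m) else
    stats::setNames(numeric(4096),
                    Biostrings::mkAllStrings(DNA_BASES, 6L))
  structure(list(counts = counts,
                 total_windows = sum(pmax(Biostrings::width(dss) - 5L, 0L)),
                 source = source),
            class = "sixmer_profile")
}

#' Six-mer enrichment of a wild-type profile against a null ensemble
#'
#' Per motif, `z = (wt_count - null_mean) / null_sd` over the null
#' replicates; motifs with `z <= -z_cut` are flagged depleted, `z >= z_cut`
#' overrepresented, everything else (including motifs whose null standard
#' deviation is zero, whose z is recorded as missing) neutral.
#'
#' @param wt a `sixmer_profile` of the wild-type set.
#' @param nulls a list of `sixmer_profile`s, one per null replicate (at
#'   least 2; fewer than 30 triggers a warning about an unstable sd).
#' @param z_cut flagging cutoff on `|z|`.
#' @return a `data.frame` with `motif`, `wt_count`, `null_mean`, `null_sd`,
#'   `z`, `flag`, sorted by `z` ascending (missing z last).
#' @export
sixmer_enrichment <- function(wt, nulls, z_cut = 3) {
  stopifnot(inherits(wt, "sixmer_profile"))
  if (length(nulls) < 2L) stop("need at least 2 null profiles")
  if (length(nulls) < 30L)
    warning("fewer than 30 null replicates; null sd may be unstable")
  M <- vapply(nulls, function(p) p$counts, numeric(4096))
  mu <- rowMeans(M)
  sd <- apply(M, 1L, stats::sd)
  z <- ifelse(sd > 0, (wt$counts - mu) / sd, NA_real_)
  flag <- rep("neutral", 4096L)
  flag[!is.na(z) & z <= -z_cut] <- "depleted"
  flag[!is.na(z) & z >= z_cut] <- "overrepresented"
  out <- data.frame(motif = names(wt$counts),
                    wt_count = unname(wt$counts),
                    null_mean = unname(mu), null_sd = unname(sd),
                    z = unname(z), flag = flag,
                    stringsAsFactors = FALSE)
  out <- out[order(is.na(out$z), out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}
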