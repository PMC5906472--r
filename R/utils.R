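# Internal helpers: DNA encoding, seeding, genetic code.

DNA_BASES <- c("A", "C", "G", "T")

# Integer encoding A=1, C=2, G=3, T=4. Complement is 5L - code.
encode_dna <- function(x) {
  v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1L]], DNA_BASES)
  if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T}")
  v
}

decode_dna <- function(enc) paste(DNA_BASES[enc], collapse = "")

revcomp_enc <- function(enc) rev(5L - enc)

#' Reverse complement of a DNA string
#'
#' @param x a single DNA string over \{A,C,G,T\}.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(x) decode_dna(revcomp_enc(encode_dna(x)))

# Coerce DNAStringSet / character to a named character vector of sequences.
as_char_seqs <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- toupper(x)
  } else {
    stop("expected a character vector or a Biostrings DNAStringSet")
  }
  if (length(out) && is.null(names(out)))
    names(out) <- paste0("seq_", seq_along(out))
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Stable 31-bit string hash (polynomial, exact in double precision).
str_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  h
}

# Deterministic per-replicate sub-seed from (root seed, id, replicate index).
# Keeps every derived seed below 2^31.
subseed <- function(root, id, i) {
  h <- (str_hash(id) + (root %% 2147483647) * 48271) %% 2147483647
  as.integer((h * 69621 + i) %% 2147483647)
}

# ---- genetic code ----------------------------------------------------------

genetic_code <- function() Biostrings::GENETIC_CODE

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length is not a multiple of 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons translate to \code{"*"}.
#'
#' @param cds a single in-frame DNA string (length a multiple of 3).
#' @return a character vector of one-letter amino acids, one per codon.
#' @export
translate_cds <- function(cds) {
  unname(genetic_code()[split_codons(toupper(cds))])
}
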