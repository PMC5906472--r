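# Reading and writing the formats the pipeline touches: FASTA, GenBank flat
# files (CDS features only), and plain-text gene-label lists.

#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased and validated against the strict 4-letter
#' alphabet \{A,C,G,T\}. Records carrying ambiguity codes are either rejected
#' (default) or dropped.
#'
#' @param path path to a FASTA file.
#' @param iupac \code{"strict"} (error on any non-ACGT character, naming the
#'   offending record) or \code{"skip"} (drop affected records with a warning).
#' @return a [Biostrings::DNAStringSet] named by FASTA record id.
#' @export
read_fasta <- function(path, iupac = c("strict", "skip")) {
  iupac <- match.arg(iupac)
  if (!file.exists(path)) stop("file not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("empty FASTA file: ", path)
  # keep only the first whitespace-delimited token of each header
  names(dss) <- sub("\\s.*$", "", names(dss))
  chr <- toupper(as.character(dss))
  ok <- !grepl("[^ACGT]", chr)
  if (!all(ok)) {
    bad <- names(dss)[!ok]
    if (iupac == "strict")
      stop("non-ACGT characters in record(s): ", paste(bad, collapse = ", "))
    warning("dropping record(s) with non-ACGT characters: ",
            paste(bad, collapse = ", "))
    chr <- chr[ok]
  }
  if (length(chr) == 0L) stop("no valid records left in ", path)
  Biostrings::DNAStringSet(chr)
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs a named character vector or [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  chr <- as_char_seqs(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(chr), path)
  invisible(path)
}

#' Read CDS features from a GenBank flat file
#'
#' A focused parser for the subset of GenBank needed here: the ORIGIN
#' sequence and CDS features with `complement()` / `join()` locations.
#' Pseudogenes (a `/pseudo` qualifier) are skipped, as are CDSs whose length
#' is not a multiple of 3 (with a warning). Coordinates are converted to
#' 0-based half-open; minus-strand CDSs are returned reverse-complemented so
#' `cds` is always the coding strand, start codon first. Features joined
#' across the origin of a circular genome are supported by wrap-aware
#' slicing.
#'
#' @param path path to a GenBank flat file with a single record.
#' @return a `data.frame` with columns `gene_id`, `cds`, `strand`,
#'   `genome_start`, `genome_end` (plus logical label columns `essential`,
#'   `toxin`, `antitoxin`, `prophage`, all `FALSE`; see [attach_labels()]).
#' @export
read_genbank_cds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  ## genome sequence from ORIGIN block
  o <- grep("^ORIGIN", lines)
  if (length(o) != 1L) stop("expected exactly one ORIGIN block in ", path)
  seq_lines <- lines[(o + 1L):length(lines)]
  end <- grep("^//", seq_lines)
  if (length(end)) seq_lines <- seq_lines[seq_len(end[1L] - 1L)]
  genome <- toupper(paste(gsub("[^A-Za-z]", "", seq_lines), collapse = ""))
  glen <- nchar(genome)

  ## collect feature lines (between FEATURES and ORIGIN)
  f <- grep("^FEATURES", lines)
  feat <- if (length(f)) lines[(f[1L] + 1L):(o - 1L)] else character(0)

  ## group into features: a new feature starts with a key in column 6
  starts <- grep("^ {5}\\S", feat)
  recs <- list()
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1L] - 1L else length(feat)
    block <- feat[from:to]
    key <- sub("^ +(\\S+).*$", "\\1", block[1L])
    if (key != "CDS") next
    recs[[length(recs) + 1L]] <- block
  }
  if (length(recs) == 0L) {
    warning("no CDS features found in ", path)
    return(empty_gene_table())
  }

  out <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    block <- recs[[k]]
    ## location string: continuation lines without a '/' belong to it
    loc <- sub("^ +CDS +", "", block[1L])
    j <- 2L
    while (j <= length(block) && !grepl("^ +/", block[j])) {
      loc <- paste0(loc, gsub(" ", "", block[j]))
      j <- j + 1L
    }
    quals <- block[grepl("^ +/", block)]
    if (any(grepl("^ +/pseudo\\b", quals))) next
    id <- qual_value(quals, "locus_tag")
    if (is.na(id)) id <- qual_value(quals, "gene")
    if (is.na(id)) id <- sprintf("CDS_%03d", k)

    p <- parse_location(loc)
    if (is.null(p)) {
      warning("unparseable CDS location '", loc, "' in ", path, "; skipped")
      next
    }
    cds <- paste(vapply(seq_len(nrow(p$spans)), function(r) {
      slice_wrap(genome, p$spans[r, 1L], p$spans[r, 2L], glen)
    }, character(1)), collapse = "")
    if (p$complement) cds <- revcomp(cds)
    if (nchar(cds) %% 3L != 0L) {
      warning("CDS ", id, " length ", nchar(cds),
              " not a multiple of 3; skipped")
      next
    }
    out[[k]] <- data.frame(
      gene_id = id, cds = cds,
      strand = if (p$complement) "-" else "+",
      genome_start = min(p$spans[, 1L]) - 1L,  # 0-based half-open
      genome_end = max(p$spans[, 2L]),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    warning("no usable CDS features in ", path)
    return(empty_gene_table())
  }
  genes <- do.call(rbind, out)
  rownames(genes) <- NULL
  for (lab in c("essential", "toxin", "antitoxin", "prophage"))
    genes[[lab]] <- FALSE
  genes
}

empty_gene_table <- function() {
  data.frame(gene_id = character(0), cds = character(0), strand = character(0),
             genome_start = integer(0), genome_end = integer(0),
             essential = logical(0), toxin = logical(0),
             antitoxin = logical(0), prophage = logical(0),
             stringsAsFactors = FALSE)
}

qual_value <- function(quals, name) {
  hit <- grep(paste0("^ +/", name, "="), quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub('^[^=]+="?|"$', "", hit[1L])
}

# Parse a GenBank location into 1-based inclusive spans + complement flag.
parse_location <- function(loc) {
  complement <- grepl("^complement\\(", loc)
  inner <- gsub("^complement\\(|\\)$", "", loc)
  inner <- gsub("^join\\(|\\)$", "", inner)
  inner <- gsub("[<>]", "", inner)
  parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
  spans <- matrix(NA_integer_, nrow = length(parts), ncol = 2L)
  for (r in seq_along(parts)) {
    m <- regmatches(parts[r], regexec("^(\\d+)\\.\\.(\\d+)$", parts[r]))[[1L]]
    if (length(m) == 3L) {
      spans[r, ] <- as.integer(m[2:3])
    } else if (grepl("^\\d+$", parts[r])) {
      spans[r, ] <- rep(as.integer(parts[r]), 2L)
    } else {
      return(NULL)
    }
  }
  list(spans = spans, complement = complement)
}

# 1-based inclusive slice; from > to wraps around the origin (circular genome).
slice_wrap <- function(genome, from, to, glen) {
  if (from <= to) substr(genome, from, to)
  else paste0(substr(genome, from, glen), substr(genome, 1L, to))
}

#' Read a plain-text gene-label list
#'
#' One gene id per line; `#` comment lines and blank lines are ignored;
#' duplicates are silently deduplicated.
#'
#' @param path path to the list file.
#' @param label optional label name used in messages.
#' @return a character vector of unique ids.
#' @export
read_label_table <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x <- unique(x[nzchar(x)])
  if (length(x) == 0L) warning("empty label list '", label, "'")
  x
}

#' Attach group labels to a gene table
#'
#' Sets the logical column `label` to `TRUE` for genes whose `gene_id` is in
#' `ids`. Ids absent from the gene table are reported with a warning.
#'
#' @param genes gene table as returned by [read_genbank_cds()].
#' @param ids character vector of gene ids.
#' @param label one of `"essential"`, `"toxin"`, `"antitoxin"`, `"prophage"`.
#' @return the gene table with the label column updated.
#' @export
attach_labels <- function(genes, ids,
                          label = c("essential", "toxin", "antitoxin",
                                    "prophage")) {
  label <- match.arg(label)
  missing <- setdiff(ids, genes$gene_id)
  if (length(missing))
    warning(length(missing), " ", label,
            " id(s) not present in the gene table: ",
            paste(utils::head(missing, 5L), collapse = ", "))
  genes[[label]] <- genes$gene_id %in% ids
  genes
}
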