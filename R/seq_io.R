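#' Read a FASTA file of nucleotide or protein sequences
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines), uppercases
#' the sequences and validates the alphabet: `A,C,G,T,N` for nucleotide
#' input, the 20 standard residues plus `U` (selenocysteine) and `X`
#' (unknown) for protein input. Record identifiers are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @param mode `"dna"` (default) or `"protein"`.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet] named
#'   by record id; an empty set (with a warning) for an empty file.
#' @export
read_fasta <- function(path, mode = c("dna", "protein")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) {
    warning("no records in FASTA file: ", path)
    return(if (mode == "dna") Biostrings::DNAStringSet() else
             Biostrings::AAStringSet())
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  allowed <- if (mode == "dna") "ACGTN" else "ACDEFGHIKLMNPQRSTVWYUX"
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad)) {
    stop("sequence characters outside the ", mode, " alphabet in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  out <- if (mode == "dna") Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs a named character vector or `XStringSet`.
#' @param path output path.
#' @param mode `"dna"` or `"protein"`, used when `seqs` is a character
#'   vector.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, mode = c("dna", "protein")) {
  mode <- match.arg(mode)
  if (is.character(seqs)) {
    seqs <- if (mode == "dna") Biostrings::DNAStringSet(seqs) else
      Biostrings::AAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# Coerce an XString/XStringSet element or character scalar to one
# uppercase string.
.as_seq_string <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  if (length(x) != 1) stop("expected a single sequence, got ", length(x))
  toupper(x)
}
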