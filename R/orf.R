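#' Trim a 3' polyA tail
#'
#' Removes the maximal trailing adenosine run, tolerating up to one non-A
#' base per 10 trailing bases (to absorb single-pass sequencing noise),
#' provided the run is at least `min_run` bases long and starts with an A.
#' Shorter tails are left untouched.
#'
#' @param seq nucleotide sequence (character or `XString`).
#' @param min_run minimum tail length to trim (default 8).
#' @return list with `trimmed` (character) and `polya_len` (integer, 0 if
#'   nothing was trimmed). Warns when trimming empties the sequence.
#' @export
trim_polya <- function(seq, min_run = 8L) {
  stopifnot(min_run >= 1)
  s <- .as_seq_string(seq)
  n <- nchar(s)
  if (n == 0) return(list(trimmed = s, polya_len = 0L))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  non_a <- rev(cumsum(rev(ch != "A")))   # non-A count in suffix starting at i
  suf_len <- n - seq_len(n) + 1L
  ok <- ch == "A" & non_a <= floor(suf_len / 10)
  best <- if (any(ok)) suf_len[which(ok)[1]] else 0L
  if (best < min_run) return(list(trimmed = s, polya_len = 0L))
  trimmed <- substr(s, 1L, n - best)
  if (!nzchar(trimmed)) warning("polyA trimming removed the whole sequence")
  list(trimmed = trimmed, polya_len = as.integer(best))
}

#' Translate a coding sequence
#'
#' Standard genetic code. Translation stops at the first stop codon,
#' except that up to `readthrough_uga` UGA codons are read as
#' selenocysteine (`U`) before UGA is treated as stop - the mechanism by
#' which selenoprotein mRNAs (e.g. some glutathione peroxidases) extend
#' their reading frame. UAA and UAG always terminate. Codons containing
#' `N` translate to `X`.
#'
#' @param codons nucleotide string whose length is a multiple of 3.
#' @param readthrough_uga maximum number of UGA codons to read as U.
#' @return character string of residues, with attribute `uga_readthroughs`
#'   giving the number of UGAs actually read through.
#' @export
translate_cds <- function(codons, readthrough_uga = 0L) {
  s <- .as_seq_string(codons)
  n <- nchar(s)
  if (n %% 3 != 0) stop("coding sequence length (", n, ") not a multiple of 3")
  if (n == 0) {
    return(structure("", uga_readthroughs = 0L))
  }
  cod <- substring(s, seq(1, n, 3), seq(3, n, 3))
  out <- character(0)
  used <- 0L
  for (c3 in cod) {
    if (c3 %in% c("TAA", "TAG")) break
    if (c3 == "TGA") {
      if (used < readthrough_uga) {
        used <- used + 1L
        out <- c(out, "U")
        next
      }
      break
    }
    aa <- if (grepl("N", c3, fixed = TRUE)) "X" else
      unname(Biostrings::GENETIC_CODE[c3])
    out <- c(out, aa)
  }
  structure(paste(out, collapse = ""), uga_readthroughs = used)
}

# Scan one frame of one strand for candidate ORFs. Returns a data.frame of
# candidates with codon-index start/stop and protein length in residues.
.scan_frame <- function(cod, require_atg, readthrough_uga, allow_open_end) {
  k <- length(cod)
  if (k == 0) return(NULL)
  is_hard_stop <- cod %in% c("TAA", "TAG")
  is_tga <- cod == "TGA"
  starts <- if (require_atg) which(cod == "ATG") else {
    after_stop <- which(is_hard_stop | is_tga) + 1L
    sort(unique(c(1L, after_stop[after_stop <= k])))
  }
  res <- list()
  for (i in starts) {
    allowed <- readthrough_uga
    j <- i
    stop_at <- NA_integer_
    while (j <= k) {
      if (is_hard_stop[j]) { stop_at <- j; break }
      if (is_tga[j]) {
        if (allowed > 0L) allowed <- allowed - 1L else { stop_at <- j; break }
      }
      j <- j + 1L
    }
    if (is.na(stop_at) && !allow_open_end) next
    prot_len <- if (is.na(stop_at)) k - i + 1L else stop_at - i
    if (prot_len < 1L) next
    res[[length(res) + 1L]] <- data.frame(
      start_codon = i,
      stop_codon = if (is.na(stop_at)) NA_integer_ else stop_at,
      prot_len = prot_len
    )
  }
  if (length(res) == 0) NULL else do.call(rbind, res)
}

#' Find the longest open reading frame
#'
#' Scans the three forward frames (and optionally the reverse strand) for
#' ATG-initiated, stop-terminated reading frames and returns the one
#' encoding the longest protein; ties are broken by the smaller start
#' position. Up to `readthrough_uga` internal UGA codons may be read as
#' selenocysteine, extending the frame past what would otherwise be a stop.
#' Coordinates are 1-based and inclusive, on the strand scanned; `end` is
#' the last base of the stop codon.
#'
#' @param seq nucleotide sequence (character or `XString`), ideally
#'   polyA-trimmed.
#' @param require_atg require an ATG initiator (default `TRUE`).
#' @param forward_only scan only the mRNA-sense strand (default `TRUE`).
#' @param readthrough_uga maximum UGA codons to read as U.
#' @param allow_open_end also consider ORFs running off the sequence end
#'   without a stop codon (default `FALSE`).
#' @return `NULL` when no qualifying ORF exists, else a list of class
#'   `"orf_annotation"` with `start`, `end`, `frame` (0/1/2), `strand`,
#'   `protein` (residue string) and `uga_readthroughs`.
#' @export
find_longest_orf <- function(seq, require_atg = TRUE, forward_only = TRUE,
                             readthrough_uga = 0L, allow_open_end = FALSE) {
  s <- .as_seq_string(seq)
  strands <- if (forward_only) "+" else c("+", "-")
  best <- NULL
  for (strand in strands) {
    b <- if (strand == "+") s else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    n <- nchar(b)
    for (frame in 0:2) {
      m <- n - frame
      k <- m %/% 3
      if (k < 2) next
      cod <- substring(b, frame + 1L + 3L * (seq_len(k) - 1L),
                       frame + 3L * seq_len(k))
      cand <- .scan_frame(cod, require_atg, readthrough_uga, allow_open_end)
      if (is.null(cand)) next
      cand$start <- frame + 1L + 3L * (cand$start_codon - 1L)
      cand$end <- ifelse(is.na(cand$stop_codon), frame + 3L * k,
                         frame + 3L * cand$stop_codon)
      cand$frame <- frame
      cand$strand <- strand
      for (r in seq_len(nrow(cand))) {
        row <- cand[r, ]
        if (is.null(best) || row$prot_len > best$prot_len ||
            (row$prot_len == best$prot_len && row$start < best$start)) {
          best <- row
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  b <- if (best$strand == "+") s else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  cds <- substr(b, best$start, best$end)
  prot <- translate_cds(cds, readthrough_uga = readthrough_uga)
  structure(list(
    start = as.integer(best$start),
    end = as.integer(best$end),
    frame = as.integer(best$frame),
    strand = best$strand,
    protein = as.character(prot),
    uga_readthroughs = attr(prot, "uga_readthroughs")
  ), class = "orf_annotation")
}
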