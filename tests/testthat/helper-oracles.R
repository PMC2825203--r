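# Independent oracles used to validate the package's own algorithms.
# They deliberately take different routes than the implementations they
# check.

# Exhaustive optimal global-alignment score: plain recursion over the
# whole alignment space (no dynamic programming). Feasible for short
# sequences only.
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  av <- if (nzchar(a)) strsplit(a, "", fixed = TRUE)[[1]] else character(0)
  bv <- if (nzchar(b)) strsplit(b, "", fixed = TRUE)[[1]] else character(0)
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L))
    }
    if (i <= length(av)) best <- max(best, gap + rec(i + 1L, j))
    if (j <= length(bv)) best <- max(best, gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

# Library-based alignment score oracle (affine machinery driven with
# zero opening cost to obtain linear gaps).
oracle_align_score_bio <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  stopifnot(gap == -1)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = mat, gapOpening = 0, gapExtension = 1,
    type = "global"))
}

# Maximal arithmetic-progression enumeration: for every occurrence that
# cannot be extended backwards, walk forward while the residue repeats
# at the given spacing.
oracle_periodic_runs <- function(p, period, min_run = 3) {
  res <- strsplit(p, "", fixed = TRUE)[[1]]
  n <- length(res)
  out <- list()
  for (s in seq_len(n)) {
    aa <- res[s]
    if (s - period >= 1 && res[s - period] == aa) next  # not a chain start
    len <- 1L
    while (s + len * period <= n && res[s + len * period] == aa) {
      len <- len + 1L
    }
    if (len >= min_run) {
      out[[length(out) + 1L]] <- data.frame(residue = aa, start = s,
                                            length = len)
    }
  }
  if (length(out) == 0) {
    return(data.frame(residue = character(0), start = integer(0),
                      length = integer(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$residue, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
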