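#' Needleman-Wunsch global alignment
#'
#' Optimal global alignment under linear scoring (match/mismatch/gap), as
#' used for spliced-leader family assignment and pairwise protein
#' comparison. Traceback ties are broken deterministically: diagonal is
#' preferred over a gap in the second sequence ("up"), which is preferred
#' over a gap in the first ("left").
#'
#' @param a,b sequence strings (either alphabet); `b` may be empty.
#' @param match,mismatch,gap linear scores (defaults +1/-1/-1).
#' @return list of class `"alignment_result"`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, `identity_percent`
#'   (100 x matches / alignment length) and `alignment_length`.
#' @export
global_align <- function(a, b, match = 1L, mismatch = -1L, gap = -1L) {
  a <- .as_seq_string(a); b <- .as_seq_string(b)
  av <- if (nzchar(a)) strsplit(a, "", fixed = TRUE)[[1]] else character(0)
  bv <- if (nzchar(b)) strsplit(b, "", fixed = TRUE)[[1]] else character(0)
  n <- length(av); m <- length(bv)
  f <- matrix(0, n + 1L, m + 1L)
  f[, 1L] <- gap * 0:n
  f[1L, ] <- gap * 0:m
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      f[i + 1L, j + 1L] <- max(f[i, j] + sub[j],
                               f[i, j + 1L] + gap,
                               f[i + 1L, j] + gap)
    }
  }
  # traceback, preferring diagonal, then up (consume a), then left
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        f[i + 1L, j + 1L] ==
          f[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0 && f[i + 1L, j + 1L] == f[i, j + 1L] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }
  len <- length(ra)
  matches <- sum(ra == rb & ra != "-")
  structure(list(
    aligned_a = paste(ra, collapse = ""),
    aligned_b = paste(rb, collapse = ""),
    score = f[n + 1L, m + 1L],
    identity_percent = if (len > 0) 100 * matches / len else 0,
    alignment_length = len
  ), class = "alignment_result")
}
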