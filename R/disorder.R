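# Charge-hydropathy disorder calls. The empirical boundary separating
# natively unfolded from folded proteins in (mean net charge, mean scaled
# hydropathy) space is <H>_b = (<R> + 1.151)/2.785; proteins below it are
# predicted unfolded. The same relation, applied per window, gives a
# FoldIndex-style unfoldability index I = 2.785<H> - |<R>| - 1.151.

#' Classify a protein on the charge-hydropathy plane
#'
#' @param h mean scaled hydropathy in \[0,1\].
#' @param r mean net charge in \[0,1\].
#' @return list of class `"uversky_point"` with `h`, `r`, `h_boundary`
#'   and `classification` (`"folded"` or `"unfolded"`). Points exactly on
#'   the boundary are called folded.
#' @export
uversky_classify <- function(h, r) {
  stopifnot(is.finite(h), is.finite(r))
  if (h < 0 || h > 1) stop("h out of range [0,1]: ", h)
  if (r < 0 || r > 1) stop("r out of range [0,1]: ", r)
  hb <- (r + 1.151) / 2.785
  structure(list(
    h = h, r = r, h_boundary = hb,
    classification = if (h < hb) "unfolded" else "folded"
  ), class = "uversky_point")
}

#' FoldIndex-style windowed disorder profile
#'
#' Per-residue unfoldability index from the window centred on each
#' residue (windows truncated at the ends): `I = 2.785*Hw - |Rw| - 1.151`,
#' where `Hw` is the window mean of rescaled Kyte-Doolittle hydropathy
#' and `Rw` the window mean signed charge (K,R = +1; D,E = -1). Negative
#' indices predict disorder.
#'
#' @param p protein sequence.
#' @param window window width in residues (default 51, the conventional
#'   server default); proteins shorter than the window use the full
#'   sequence as one window.
#' @return list of class `"foldindex_profile"`: `window`, `indices`
#'   (length = protein length) and `percent_disorder`.
#' @export
foldindex_profile <- function(p, window = 51L) {
  res <- .residue_vector(p)
  n <- length(res)
  if (n < window) window <- n
  kd <- hydropathy_scale("kyte-doolittle")
  h <- (kd[res] + 4.5) / 9
  q <- (res %in% c("K", "R")) - (res %in% c("D", "E"))
  half <- (window - 1L) %/% 2L
  idx <- vapply(seq_len(n), function(i) {
    w <- max(1L, i - half):min(n, i + half)
    2.785 * mean(h[w], na.rm = TRUE) - abs(mean(q[w])) - 1.151
  }, numeric(1))
  structure(list(
    window = as.integer(window),
    indices = unname(idx),
    percent_disorder = 100 * sum(idx < 0) / n
  ), class = "foldindex_profile")
}

#' Export a disorder profile as a data frame
#'
#' @param profile a `"foldindex_profile"`.
#' @return data.frame with columns `position`, `index`, `call`.
#' @export
foldindex_table <- function(profile) {
  stopifnot(inherits(profile, "foldindex_profile"))
  data.frame(
    position = seq_along(profile$indices),
    index = profile$indices,
    call = ifelse(profile$indices < 0, "disordered", "ordered")
  )
}
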