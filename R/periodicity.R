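# Amino-acid periodicity: residues recurring every `period` positions.
# In the peptide GAGPG, for instance, G occupies positions 1, 3 and 5 and
# so recurs with period 2. Group 3 LEA proteins characteristically show
# lysines recurring with period 11 ("K11"), often as interlaced runs in
# different phases.

#' Find maximal periodic runs of a residue
#'
#' For each residue type considered, reports every maximal arithmetic
#' chain of occurrence positions with common difference `period` and at
#' least `min_run` members. Chains in different phases (position modulo
#' period) are reported separately, which is what makes interlaced runs
#' visible. Runs are maximal: the residue does not occur at `first -
#' period` or `last + period`.
#'
#' @param p protein sequence.
#' @param period spacing in residues (>= 1).
#' @param min_run minimum chain length (default 3).
#' @param residue a single residue letter, or `NULL` to scan all residue
#'   types present.
#' @return data.frame with one row per run: `residue`, `period`, `start`,
#'   `length`, and `positions` (a list column of integer vectors), sorted
#'   by residue then start. Zero rows (with a warning) when `period` is
#'   not shorter than the protein.
#' @export
find_periodic_runs <- function(p, period, min_run = 3L, residue = NULL) {
  stopifnot(period >= 1, min_run >= 2)
  res <- .residue_vector(p)
  empty <- data.frame(residue = character(0), period = integer(0),
                      start = integer(0), length = integer(0))
  empty$positions <- list()
  if (period >= length(res)) {
    warning("period (", period, ") not shorter than protein (", length(res), ")")
    return(empty)
  }
  targets <- if (is.null(residue)) sort(unique(res)) else toupper(residue)
  runs <- list()
  for (aa in targets) {
    pos <- which(res == aa)
    if (length(pos) == 0) next
    for (phase in split(pos, pos %% period)) {
      # consecutive elements exactly `period` apart form one chain
      brk <- c(TRUE, diff(phase) != period)
      for (chain in split(phase, cumsum(brk))) {
        if (length(chain) >= min_run) {
          runs[[length(runs) + 1L]] <- list(residue = aa, chain = chain)
        }
      }
    }
  }
  if (length(runs) == 0) return(empty)
  out <- data.frame(
    residue = vapply(runs, `[[`, character(1), "residue"),
    period = as.integer(period),
    start = vapply(runs, function(x) x$chain[1], integer(1)),
    length = vapply(runs, function(x) length(x$chain), integer(1))
  )
  out$positions <- lapply(runs, `[[`, "chain")
  out <- out[order(out$residue, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise period-11 (K11) periodicity
#'
#' Aggregates [find_periodic_runs()] at period 11 over all residue types,
#' the signature used to recognise Group 3 LEA proteins.
#'
#' @param p protein sequence.
#' @param min_run minimum chain length (default 3).
#' @return list with `n_runs` (all residues), `n_lysine_runs` and
#'   `covered` (sorted positions participating in any run).
#' @export
k11_summary <- function(p, min_run = 3L) {
  runs <- suppressWarnings(find_periodic_runs(p, period = 11L, min_run = min_run))
  list(
    n_runs = nrow(runs),
    n_lysine_runs = sum(runs$residue == "K"),
    covered = sort(unique(unlist(runs$positions)))
  )
}

#' Export periodic runs as a flat table
#'
#' @param runs result of [find_periodic_runs()].
#' @return data.frame with `positions` flattened to a comma-separated
#'   string, suitable for TSV export.
#' @export
periodic_runs_table <- function(runs) {
  runs$positions <- vapply(runs$positions, paste, character(1), collapse = ",")
  runs
}
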