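# End-to-end pipeline surface. Data rows are deterministic for identical
# input and configuration; the effective configuration is echoed as
# '#'-prefixed comment lines so reports are self-describing without
# contaminating the data stream.

.write_report <- function(df, output, config) {
  con <- file(output, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# leascan %s",
                     as.character(utils::packageVersion("leascan"))), con)
  for (k in names(config)) {
    writeLines(sprintf("# %s=%s", k, config[[k]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(output)
}

#' Profile a FASTA file of ESTs
#'
#' Batched [characterise()]: polyA trimming, spliced-leader detection and
#' removal, longest-ORF extraction, physicochemical and disorder
#' profiling, K11 periodicity and LEA classification, one row per
#' record.
#'
#' @param input FASTA path, named character vector or `DNAStringSet`.
#' @param output optional TSV path; when given, the report is written
#'   with a '#'-prefixed configuration header.
#' @inheritParams characterise
#' @return the report data.frame, invisibly when `output` is given.
#' @export
est_profile <- function(input, output = NULL, criteria = lea_criteria(),
                        catalogue = load_default_catalogue(),
                        readthrough_uga = 0L, min_orf_aa = 20L,
                        foldindex_window = 51L) {
  df <- characterise(input, criteria = criteria, catalogue = catalogue,
                     readthrough_uga = readthrough_uga,
                     min_orf_aa = min_orf_aa,
                     foldindex_window = foldindex_window)
  if (!is.null(output)) {
    .write_report(df, output, list(
      command = "profile",
      gravy_max = criteria$gravy_max,
      disorder_min_percent = criteria$disorder_min_percent,
      min_k11_lysine_runs = criteria$min_k11_lysine_runs,
      forbid_cys_trp = criteria$forbid_cys_trp,
      readthrough_uga = readthrough_uga,
      min_orf_aa = min_orf_aa,
      foldindex_window = foldindex_window))
    return(invisible(df))
  }
  df
}

#' Scan a FASTA file for spliced leaders
#'
#' Runs [detect_sl()] over every record; sequences are polyA-trimmed
#' first so degenerate records do not confound offsets.
#'
#' @inheritParams est_profile
#' @param max_mismatch,max_offset thresholds passed to [detect_sl()].
#' @return data.frame with `id`, `sl_name`, `offset`, `mismatches`,
#'   `matched_length` (`NA`s when no leader was found).
#' @export
sl_scan <- function(input, output = NULL,
                    catalogue = load_default_catalogue(),
                    max_mismatch = 2L, max_offset = 3L) {
  if (is.character(input) && length(input) == 1 && file.exists(input)) {
    input <- read_fasta(input, mode = "dna")
  }
  seqs <- if (is.character(input)) input else as.character(input)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- lapply(seq_along(seqs), function(i) {
    m <- detect_sl(suppressWarnings(trim_polya(seqs[[i]]))$trimmed,
                   catalogue = catalogue,
                   max_mismatch = max_mismatch, max_offset = max_offset)
    data.frame(
      id = ids[i],
      sl_name = if (is.null(m)) NA_character_ else m$name,
      offset = if (is.null(m)) NA_integer_ else m$offset,
      mismatches = if (is.null(m)) NA_integer_ else m$mismatches,
      matched_length = if (is.null(m)) NA_integer_ else m$matched_length
    )
  })
  df <- do.call(rbind, rows)
  if (!is.null(df)) rownames(df) <- NULL
  if (!is.null(output)) {
    .write_report(df, output, list(command = "sl-scan",
                                   max_mismatch = max_mismatch,
                                   max_offset = max_offset))
    return(invisible(df))
  }
  df
}
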