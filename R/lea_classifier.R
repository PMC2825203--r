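# Rule-based LEA classification. The hallmarks of a Group 3 LEA protein
# are codified as an explicit cascade: extreme hydrophilicity (GRAVY
# below the bovine-serum-albumin reference of -0.43), predicted native
# disorder on the charge-hydropathy plane, period-11 lysine runs, and
# absence of cysteine and tryptophan.

#' Classification thresholds for LEA candidates
#'
#' @param gravy_max hydrophilicity threshold; proteins must score
#'   strictly below it (default -0.43, the GRAVY of bovine serum albumin).
#' @param disorder_min_percent percent-disorder threshold, strict
#'   (default 50).
#' @param min_k11_lysine_runs minimum number of period-11 lysine runs for
#'   the Group 3 call (default 1).
#' @param forbid_cys_trp require absence of C and W for the Group 3 call
#'   (default `TRUE`).
#' @return list of class `"lea_criteria"`.
#' @export
lea_criteria <- function(gravy_max = -0.43, disorder_min_percent = 50,
                         min_k11_lysine_runs = 1L, forbid_cys_trp = TRUE) {
  stopifnot(gravy_max < 0,
            disorder_min_percent > 0, disorder_min_percent < 100)
  structure(list(
    gravy_max = gravy_max,
    disorder_min_percent = disorder_min_percent,
    min_k11_lysine_runs = as.integer(min_k11_lysine_runs),
    forbid_cys_trp = isTRUE(forbid_cys_trp)
  ), class = "lea_criteria")
}

#' Classify a protein as LEA / LEA-like / hydrophilic-novel / neither
#'
#' Rule cascade, evaluated on precomputed evidence from the same protein:
#' * `group3_lea`: GRAVY below threshold AND charge-hydropathy call
#'   unfolded AND enough period-11 lysine runs AND (if required) no
#'   cysteine or tryptophan;
#' * `lea_like`: GRAVY below threshold AND unfolded;
#' * `hydrophilic_novel`: GRAVY below threshold OR percent disorder above
#'   threshold;
#' * `not_lea_like`: none of the above.
#'
#' @param profile a `"physchem_profile"`.
#' @param uversky a `"uversky_point"`.
#' @param foldindex a `"foldindex_profile"`.
#' @param k11 result of [k11_summary()].
#' @param criteria a `"lea_criteria"` object.
#' @return list of class `"lea_classification"` with `label` and
#'   `evidence` (data.frame of criterion, value, satisfied).
#' @export
classify_lea <- function(profile, uversky, foldindex, k11,
                         criteria = lea_criteria()) {
  hydrophilic <- profile$gravy < criteria$gravy_max
  unfolded <- uversky$classification == "unfolded"
  disordered <- foldindex$percent_disorder > criteria$disorder_min_percent
  k11_ok <- k11$n_lysine_runs >= criteria$min_k11_lysine_runs
  no_cw <- !(profile$has_cys || profile$has_trp)
  label <- if (hydrophilic && unfolded && k11_ok &&
               (no_cw || !criteria$forbid_cys_trp)) {
    "group3_lea"
  } else if (hydrophilic && unfolded) {
    "lea_like"
  } else if (hydrophilic || disordered) {
    "hydrophilic_novel"
  } else {
    "not_lea_like"
  }
  evidence <- data.frame(
    criterion = c("gravy_below_threshold", "uversky_unfolded",
                  "percent_disorder_above_threshold", "k11_lysine_runs",
                  "no_cys_trp", "compositional_clustering"),
    value = c(profile$gravy, uversky$h - uversky$h_boundary,
              foldindex$percent_disorder, k11$n_lysine_runs,
              as.numeric(no_cw), NA_real_),
    satisfied = c(hydrophilic, unfolded, disordered, k11_ok, no_cw, NA)
  )
  evidence$note <- c("", "", "", "", "", "not evaluated")
  structure(list(label = label, evidence = evidence),
            class = "lea_classification")
}

#' Flag a protein as hydrophilic-novel from summary values
#'
#' `TRUE` iff GRAVY is strictly below the hydrophilicity threshold OR
#' percent disorder is strictly above the disorder threshold.
#'
#' @param gravy GRAVY score.
#' @param percent_disorder percent of residues called disordered.
#' @param criteria a `"lea_criteria"`.
#' @return logical (vectorised over its first two arguments).
#' @export
flag_hydrophilic_novel <- function(gravy, percent_disorder,
                                   criteria = lea_criteria()) {
  gravy < criteria$gravy_max | percent_disorder > criteria$disorder_min_percent
}

#' Printed parameters of the twelve novel dehydration-induced ESTs
#'
#' Predicted protein length, pI, GRAVY and percent disorder as printed
#' for the twelve novel *A. avenae* ESTs (no database match) recovered in
#' the dehydration-enrichment screen; used as a standing regression input
#' for [flag_hydrophilic_novel()].
#'
#' @return data.frame with columns `accession`, `n_aa`, `pi`, `gravy`,
#'   `percent_disorder`.
#' @export
novel_est_profiles <- function() {
  data.frame(
    accession = c("GR463919", "GR463920", "GR463921", "GR463922",
                  "GR463923", "GR463924", "GR463925", "GR463926",
                  "GR463927", "GR463928", "GR463929", "EF026246"),
    n_aa = c(179L, 98L, 88L, 168L, 144L, 35L, 143L, 140L, 122L, 37L, 59L, 61L),
    pi = c(9.28, 10.51, 4.36, 11.13, 6.78, 6.69, 9.82, 9.64, 10.91, 6.33,
           4.17, 6.35),
    gravy = c(-1.16, -0.87, 0.01, -0.55, 0.20, -0.13, -0.08, -0.97, -0.30,
              0.28, 0.99, -2.32),
    percent_disorder = c(75, 39, 78, 39, 16, 37, 22, 51, 37, 46, 0, 20)
  )
}

#' Characterise a batch of ESTs
#'
#' Runs the full per-EST pipeline: polyA trimming, spliced-leader
#' detection and removal, longest-ORF extraction, physicochemical
#' profiling, disorder prediction, K11 periodicity and LEA
#' classification. Per-record failures become rows with a non-`"ok"`
#' `status`; the batch never aborts.
#'
#' @param ests named character vector or `DNAStringSet` of EST sequences
#'   (mRNA sense), or a FASTA file path.
#' @param criteria a `"lea_criteria"`.
#' @param catalogue spliced-leader catalogue.
#' @param readthrough_uga UGA read-through allowance for ORF finding.
#' @param min_orf_aa minimum ORF protein length (residues) to profile;
#'   shorter or absent ORFs get status `"no ORF"` (default 20).
#' @param foldindex_window window for [foldindex_profile()].
#' @return data.frame, one row per EST, in input order: `id`, `status`,
#'   `sl_name`, `sl_mismatches`, `length_with_sl`, `length_no_sl`,
#'   `polya_len`, `orf_aa`, `mr`, `pi`, `gravy`, `mean_scaled_hydropathy`,
#'   `mean_net_charge`, `uversky_class`, `percent_disorder`,
#'   `k11_lysine_runs`, `label`.
#' @export
characterise <- function(ests, criteria = lea_criteria(),
                         catalogue = load_default_catalogue(),
                         readthrough_uga = 0L, min_orf_aa = 20L,
                         foldindex_window = 51L) {
  if (is.character(ests) && length(ests) == 1 && file.exists(ests)) {
    ests <- read_fasta(ests, mode = "dna")
  }
  seqs <- if (is.character(ests)) ests else as.character(ests)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    row <- list(
      id = ids[i], status = "ok", sl_name = NA_character_,
      sl_mismatches = NA_integer_, length_with_sl = NA_integer_,
      length_no_sl = NA_integer_, polya_len = NA_integer_,
      orf_aa = NA_integer_, mr = NA_real_, pi = NA_real_, gravy = NA_real_,
      mean_scaled_hydropathy = NA_real_, mean_net_charge = NA_real_,
      uversky_class = NA_character_, percent_disorder = NA_real_,
      k11_lysine_runs = NA_integer_, label = NA_character_
    )
    tryCatch({
      tr <- suppressWarnings(trim_polya(seqs[[i]]))
      row$polya_len <- tr$polya_len
      row$length_with_sl <- nchar(tr$trimmed)
      body <- tr$trimmed
      sl <- detect_sl(body, catalogue = catalogue)
      if (!is.null(sl)) {
        row$sl_name <- sl$name
        row$sl_mismatches <- sl$mismatches
        body <- suppressMessages(strip_sl(body, sl))
      }
      row$length_no_sl <- nchar(body)
      orf <- find_longest_orf(body, readthrough_uga = readthrough_uga)
      if (is.null(orf) || nchar(orf$protein) < min_orf_aa) {
        row$status <- "no ORF"
        return(row)
      }
      prot <- orf$protein
      prof <- suppressWarnings(physchem_profile(prot))
      uv <- uversky_classify(prof$mean_scaled_hydropathy,
                             prof$mean_net_charge)
      fi <- foldindex_profile(prot, window = foldindex_window)
      k11 <- k11_summary(prot)
      cls <- classify_lea(prof, uv, fi, k11, criteria)
      row$orf_aa <- prof$length
      row$mr <- prof$mr
      row$pi <- round(prof$pi, 2)
      row$gravy <- prof$gravy
      row$mean_scaled_hydropathy <- prof$mean_scaled_hydropathy
      row$mean_net_charge <- prof$mean_net_charge
      row$uversky_class <- uv$classification
      row$percent_disorder <- fi$percent_disorder
      row$k11_lysine_runs <- k11$n_lysine_runs
      row$label <- cls$label
      row
    }, error = function(e) {
      row$status <- paste0("error: ", conditionMessage(e))
      row
    })
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  if (is.null(out)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 17),
      c("id", "status", "sl_name", "sl_mismatches", "length_with_sl",
        "length_no_sl", "polya_len", "orf_aa", "mr", "pi", "gravy",
        "mean_scaled_hydropathy", "mean_net_charge", "uversky_class",
        "percent_disorder", "k11_lysine_runs", "label")))
  }
  rownames(out) <- NULL
  out
}
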