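# Seeded generators for proteins and ESTs with known ground truth, so
# every pipeline stage can be validated without external data. All
# generators draw from R's RNG; when `seed` is given the previous RNG
# state is restored afterwards, making each call a pure function of
# (spec, seed). Generated records sit strictly inside the classifier
# thresholds they target (GRAVY margin 0.2, disorder margin 5 points),
# so classification recovery is exact, never borderline.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# hydrophilic background (no K, C, W) biased to charged residues
.LEA_POOL <- c(E = 0.20, D = 0.20, Q = 0.10, N = 0.10, R = 0.30,
               S = 0.04, T = 0.03, G = 0.03)
.GLOB_POOL <- c(I = 0.20, L = 0.20, V = 0.20, F = 0.10, A = 0.20, M = 0.10)

.sample_residues <- function(n, pool) {
  sample(names(pool), n, replace = TRUE, prob = pool)
}

#' Generate a LEA-like protein with planted K11 runs
#'
#' Builds a hydrophilic, charge-rich protein containing exactly
#' `n_k11_runs` maximal period-11 lysine chains of length 3 (interlaced
#' phases, as observed in Group 3 LEA proteins); lysine occurs nowhere
#' else, so the planted chains are maximal by construction. The
#' background is resampled (bounded retries) until the protein's GRAVY
#' is below `hydrophilic_bias`, its charge-hydropathy classification is
#' unfolded with margin, and its windowed percent disorder exceeds 55.
#'
#' @param length protein length in residues.
#' @param n_k11_runs number of period-11 lysine chains to plant
#'   (default 2; requires `length >= 26 + 2*n_k11_runs`).
#' @param hydrophilic_bias GRAVY ceiling (default -1.0, comfortably
#'   below the -0.43 classification threshold).
#' @param include_cys_trp plant one cysteine and one tryptophan, which
#'   disqualifies the Group 3 call (default `FALSE`).
#' @param seed integer seed, or `NULL` to draw from the current RNG
#'   stream.
#' @return residue string.
#' @export
make_lea_like_protein <- function(length, n_k11_runs = 2L,
                                  hydrophilic_bias = -1.0,
                                  include_cys_trp = FALSE, seed = NULL) {
  if (n_k11_runs > 0 && length < 26 + 2 * n_k11_runs) {
    stop("length ", length, " too short for ", n_k11_runs,
         " period-11 runs (need >= ", 26 + 2 * n_k11_runs, ")")
  }
  if (n_k11_runs > 11) stop("at most 11 distinct-phase period-11 runs")
  .with_seed(seed, {
    k_pos <- integer(0)
    if (n_k11_runs > 0) {
      starts <- 4L + 2L * (seq_len(n_k11_runs) - 1L)
      k_pos <- as.vector(outer(starts, c(0L, 11L, 22L), `+`))
    }
    for (try in 1:100) {
      res <- .sample_residues(length, .LEA_POOL)
      res[k_pos] <- "K"
      if (include_cys_trp) {
        free <- setdiff(seq_len(length), k_pos)
        res[free[1]] <- "C"
        res[free[2]] <- "W"
      }
      p <- paste(res, collapse = "")
      uv <- uversky_coordinates(p)
      fi <- foldindex_profile(p)
      if (gravy(p) < hydrophilic_bias &&
          uv$h < (uv$r + 1.151) / 2.785 - 0.02 &&
          fi$percent_disorder > 55) {
        return(p)
      }
    }
    stop("could not satisfy the protein spec in 100 attempts")
  })
}

#' Generate a globular (hydrophobic, folded) protein
#'
#' Composition biased to hydrophobic residues; resampled until GRAVY is
#' above +0.2 and the charge-hydropathy classification is folded with
#' margin, giving a clean negative control for the LEA classifier.
#'
#' @param length protein length (>= 20).
#' @param seed integer seed or `NULL`.
#' @return residue string.
#' @export
make_globular_protein <- function(length, seed = NULL) {
  stopifnot(length >= 20)
  .with_seed(seed, {
    for (try in 1:100) {
      p <- paste(.sample_residues(length, .GLOB_POOL), collapse = "")
      uv <- uversky_coordinates(p)
      fi <- foldindex_profile(p)
      if (gravy(p) > 0.2 && uv$h > (uv$r + 1.151) / 2.785 + 0.02 &&
          fi$percent_disorder < 45) {
        return(p)
      }
    }
    stop("could not satisfy the protein spec in 100 attempts")
  })
}

# Back-translate a protein (possibly containing U) to a CDS plus TAA
# stop, sampling synonymous codons uniformly. U maps to TGA.
.back_translate <- function(protein) {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  code <- Biostrings::GENETIC_CODE
  cds <- vapply(res, function(aa) {
    if (aa == "U") return("TGA")
    opts <- names(code)[code == aa]
    if (length(opts) == 0) stop("cannot back-translate residue ", aa)
    opts <- gsub("U", "T", opts)  # GENETIC_CODE keys are DNA already; safe
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1))
  paste(c(cds, "TAA"), collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Assemble a synthetic EST with known ground truth
#'
#' Concatenates spliced leader (optional), 5' UTR, an ATG-initiated CDS
#' back-translated from `protein` (U residues become internal TGA
#' codons) terminated by TAA, 3' UTR and a polyA tail. UTRs are
#' resampled (bounded retries) until the longest ORF of the assembled,
#' polyA-trimmed, SL-stripped sequence is exactly the planted one and
#' polyA trimming recovers exactly `polya_len`.
#'
#' @param protein residue string for the encoded protein (no initiator
#'   M is added: supply it as the first residue).
#' @param sl_name catalogue leader name or `NULL` for no leader.
#' @param utr5_len,utr3_len UTR lengths in bases.
#' @param polya_len polyA tail length (0 for none).
#' @param seed integer seed or `NULL`.
#' @param catalogue spliced-leader catalogue for `sl_name` lookup.
#' @return list with `sequence` (character) and `truth`: a one-row
#'   data.frame with `sl_name`, `polya_len`, `orf_start`, `orf_end`
#'   (1-based on the polyA-trimmed sequence, SL included), `protein`,
#'   `uga_readthroughs`.
#' @export
make_est <- function(protein, sl_name = "SL1c", utr5_len = 20L,
                     utr3_len = 30L, polya_len = 15L, seed = NULL,
                     catalogue = load_default_catalogue()) {
  stopifnot(substr(protein, 1, 1) == "M")
  sl <- ""
  if (!is.null(sl_name) && !is.na(sl_name)) {
    sl <- catalogue$sequence[catalogue$name == sl_name]
    if (length(sl) != 1) stop("unknown catalogue leader: ", sl_name)
  }
  n_u <- sum(strsplit(protein, "", fixed = TRUE)[[1]] == "U")
  .with_seed(seed, {
    cds <- .back_translate(protein)
    for (try in 1:100) {
      utr5 <- if (utr5_len > 0) .random_dna(utr5_len) else ""
      utr3 <- if (utr3_len > 0) .random_dna(utr3_len) else ""
      # keep the polyA boundary unambiguous
      if (utr3_len > 0 && substr(utr3, utr3_len, utr3_len) == "A") next
      body <- paste0(sl, utr5, cds, utr3)
      full <- paste0(body, strrep("A", polya_len))
      tr <- suppressWarnings(trim_polya(full))
      if (tr$polya_len != polya_len || tr$trimmed != body) next
      stripped <- if (nzchar(sl)) substr(body, nchar(sl) + 1L, nchar(body))
        else body
      orf <- find_longest_orf(stripped, readthrough_uga = n_u)
      exp_start <- utr5_len + 1L
      if (is.null(orf) || orf$protein != protein ||
          orf$start != exp_start) next
      off <- nchar(sl)
      truth <- data.frame(
        sl_name = if (nzchar(sl)) sl_name else NA_character_,
        polya_len = as.integer(polya_len),
        orf_start = as.integer(off + exp_start),
        orf_end = as.integer(off + orf$end),
        protein = protein,
        uga_readthroughs = as.integer(n_u),
        stringsAsFactors = FALSE
      )
      return(list(sequence = full, truth = truth))
    }
    stop("could not assemble an EST satisfying its own ground truth")
  })
}

# A decoy record: random sequence with no substantial ORF, no leader,
# no polyA tail.
.make_decoy <- function(length = 200L, min_orf_aa = 20L,
                        catalogue = load_default_catalogue()) {
  for (try in 1:500) {
    s <- .random_dna(length)
    if (suppressWarnings(trim_polya(s))$polya_len != 0) next
    if (!is.null(detect_sl(s, catalogue = catalogue))) next
    orf <- find_longest_orf(s)
    if (!is.null(orf) && nchar(orf$protein) >= min_orf_aa) next
    return(s)
  }
  stop("could not generate a decoy without a spurious ORF")
}

#' Generate a mixed EST collection with a ground-truth manifest
#'
#' Simulates `n` ESTs as a seeded mixture of LEA-like records (Group 3
#' hallmarks, leader SL1c), globular-protein records (random catalogue
#' leader) and no-ORF decoys, together with a manifest giving the truth
#' for every record. Two calls with the same arguments produce identical
#' sequences and manifests.
#'
#' @param n number of records.
#' @param class_weights named numeric vector over `lea`, `globular`,
#'   `decoy`, summing to 1.
#' @param seed integer seed (mandatory: the manifest is only meaningful
#'   for a reproducible draw).
#' @param fasta_path,manifest_path optional output files (FASTA and TSV).
#' @return list with `sequences` (named character vector) and `manifest`
#'   (data.frame: `id`, `class`, `sl_name`, `polya_len`, `orf_start`,
#'   `orf_end`, `protein`, `expected_label`, `expected_status`, `seed`).
#' @export
make_est_collection <- function(n,
                                class_weights = c(lea = 0.4, globular = 0.3,
                                                  decoy = 0.3),
                                seed,
                                fasta_path = NULL, manifest_path = NULL) {
  stopifnot(n > 0, abs(sum(class_weights) - 1) < 1e-8)
  cls_names <- c("lea", "globular", "decoy")
  stopifnot(all(names(class_weights) %in% cls_names))
  .with_seed(seed, {
    classes <- sample(names(class_weights), n, replace = TRUE,
                      prob = class_weights)
    cat <- load_default_catalogue()
    aav <- cat$name[cat$organism == "Aphelenchus avenae"]
    seqs <- character(n)
    man <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("synth%04d", i)
      if (classes[i] == "lea") {
        len <- sample(80:120, 1)
        prot <- paste0("M", make_lea_like_protein(len - 1L, n_k11_runs = 2L))
        est <- make_est(prot, sl_name = "SL1c",
                        polya_len = sample(10:25, 1))
        seqs[i] <- est$sequence
        man[[i]] <- cbind(data.frame(id = id, class = "lea"), est$truth,
                          expected_label = "group3_lea",
                          expected_status = "ok")
      } else if (classes[i] == "globular") {
        len <- sample(100:150, 1)
        prot <- paste0("M", make_globular_protein(len - 1L))
        est <- make_est(prot, sl_name = sample(aav, 1),
                        polya_len = sample(10:25, 1))
        seqs[i] <- est$sequence
        man[[i]] <- cbind(data.frame(id = id, class = "globular"), est$truth,
                          expected_label = "not_lea_like",
                          expected_status = "ok")
      } else {
        seqs[i] <- .make_decoy()
        man[[i]] <- data.frame(
          id = id, class = "decoy", sl_name = NA_character_,
          polya_len = 0L, orf_start = NA_integer_, orf_end = NA_integer_,
          protein = NA_character_, uga_readthroughs = NA_integer_,
          expected_label = NA_character_, expected_status = "no ORF")
      }
    }
    names(seqs) <- sprintf("synth%04d", seq_len(n))
    manifest <- do.call(rbind, man)
    manifest$seed <- seed
    rownames(manifest) <- NULL
    if (!is.null(fasta_path)) write_fasta(seqs, fasta_path, mode = "dna")
    if (!is.null(manifest_path)) {
      utils::write.table(manifest, manifest_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(sequences = seqs, manifest = manifest)
  })
}
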