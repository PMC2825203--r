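# Per-protein physicochemical scalars: GRAVY, molecular weight, net
# charge / isoelectric point, and the two charge-hydropathy plot
# coordinates.

.residue_vector <- function(p) {
  s <- .as_seq_string(p)
  if (!nzchar(s)) stop("empty protein sequence")
  strsplit(s, "", fixed = TRUE)[[1]]
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of per-residue hydropathy values, by default on the
#' Eisenberg consensus scale. Unknown residues (`X`) are excluded from
#' both numerator and denominator. Strongly negative values flag the
#' extreme hydrophilicity typical of LEA proteins (the conventional
#' hydrophilicity cutoff used downstream is -0.43, the GRAVY of bovine
#' serum albumin).
#'
#' @param p protein sequence (character or `AAString`).
#' @param scale a named hydropathy vector from [hydropathy_scale()].
#' @return numeric GRAVY score.
#' @export
gravy <- function(p, scale = hydropathy_scale("eisenberg")) {
  res <- .residue_vector(p)
  res <- res[res != "X"]
  if (length(res) == 0) stop("protein contains only X residues")
  vals <- scale[res]
  if (anyNA(vals)) {
    stop("residue(s) without a hydropathy value: ",
         paste(unique(res[is.na(vals)]), collapse = ", "))
  }
  mean(vals)
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water; selenocysteine (`U`)
#' uses its own average mass. Unknown residues are an error because the
#' mass is undefined.
#'
#' @param p protein sequence.
#' @return mass in Da.
#' @export
molecular_weight <- function(p) {
  res <- .residue_vector(p)
  if (any(res == "X")) {
    stop("cannot compute mass with X at position(s): ",
         paste(which(res == "X"), collapse = ", "))
  }
  vals <- .RESIDUE_MASS[res]
  if (anyNA(vals)) {
    stop("unknown residue(s): ", paste(unique(res[is.na(vals)]), collapse = ", "))
  }
  sum(vals) + .WATER_MASS
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum over ionisable side chains (D, E, C, Y, H,
#' K, R) and the two termini.
#'
#' @param p protein sequence.
#' @param pH pH in \[0, 14\].
#' @param pka pKa table from [pka_table()], or a table name.
#' @return signed net charge in elementary charges.
#' @export
net_charge <- function(p, pH = 7, pka = pka_table("EMBOSS")) {
  stopifnot(pH >= 0, pH <= 14)
  if (is.character(pka)) pka <- pka_table(pka)
  res <- .residue_vector(p)
  pos_frac <- function(pka_val) 1 / (1 + 10^(pH - pka_val))
  neg_frac <- function(pka_val) -1 / (1 + 10^(pka_val - pH))
  q <- pos_frac(pka$nterm) + neg_frac(pka$cterm)
  for (r in names(pka$pos)) q <- q + sum(res == r) * pos_frac(pka$pos[[r]])
  for (r in names(pka$neg)) q <- q + sum(res == r) * neg_frac(pka$neg[[r]])
  q
}

#' Isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge is zero, located by
#' bisection on \[0, 14\].
#'
#' @inheritParams net_charge
#' @param tol bisection half-interval at termination (default 1e-4 pH
#'   units, well inside the 0.01 the result is reported to).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(p, pka = pka_table("EMBOSS"), tol = 1e-4) {
  if (is.character(pka)) pka <- pka_table(pka)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(p, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Window-averaged rescaled Kyte-Doolittle hydropathy per residue; windows
# are truncated at the sequence ends. X residues are dropped within each
# window.
.windowed_h <- function(res, window, scale) {
  n <- length(res)
  h <- (scale[res] + 4.5) / 9
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    w <- h[max(1L, i - half):min(n, i + half)]
    mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Charge-hydropathy plot coordinates
#'
#' Computes the two coordinates of a charge-hydropathy (Uversky) plot:
#' the mean scaled hydropathy \eqn{\langle H \rangle} - per-residue
#' Kyte-Doolittle values rescaled to \[0,1\] by \eqn{(h+4.5)/9}, smoothed
#' with a centred window truncated at the ends, then averaged - and the
#' mean net charge \eqn{\langle R \rangle = |(\#K+\#R)-(\#D+\#E)|/length}
#' at neutral pH.
#'
#' @param p protein sequence.
#' @param window smoothing window in residues (default 5); shrunk with a
#'   warning when the protein is shorter.
#' @return list with `h` and `r`.
#' @export
uversky_coordinates <- function(p, window = 5L) {
  res <- .residue_vector(p)
  n <- length(res)
  if (n < window) {
    warning("protein shorter than window; using window = ", n)
    window <- n
  }
  kd <- hydropathy_scale("kyte-doolittle")
  h <- mean(.windowed_h(res, window, kd))
  r <- abs((sum(res == "K") + sum(res == "R")) -
             (sum(res == "D") + sum(res == "E"))) / n
  list(h = unname(h), r = unname(r))
}

#' Full physicochemical profile of a protein
#'
#' Convenience wrapper collecting length, molecular weight, pI, GRAVY,
#' charge-hydropathy coordinates and Cys/Trp presence into one object.
#'
#' @inheritParams uversky_coordinates
#' @param pka pKa table or name for the pI.
#' @return list of class `"physchem_profile"` with fields `length`, `mr`,
#'   `pi`, `gravy`, `mean_scaled_hydropathy`, `mean_net_charge`,
#'   `has_cys`, `has_trp`.
#' @export
physchem_profile <- function(p, window = 5L, pka = pka_table("EMBOSS")) {
  res <- .residue_vector(p)
  uv <- uversky_coordinates(p, window = window)
  mr <- if (any(res == "X")) NA_real_ else molecular_weight(p)
  structure(list(
    length = length(res),
    mr = mr,
    pi = isoelectric_point(p, pka = pka),
    gravy = gravy(p),
    mean_scaled_hydropathy = uv$h,
    mean_net_charge = uv$r,
    has_cys = any(res == "C"),
    has_trp = any(res == "W")
  ), class = "physchem_profile")
}
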