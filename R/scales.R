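# Embedded physicochemical reference tables. Residue keys are one-letter
# codes; U (selenocysteine) is given the cysteine hydropathy by default and
# its own average mass. X (unknown) carries no entry and is handled by the
# callers that tolerate it.

.EISENBERG <- c(
  A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
  Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
  L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
  S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08
)

.KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Average (not monoisotopic) residue masses in Da; water added per chain.
.RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326,
  U = 150.0388
)
.WATER_MASS <- 18.01524

# Side-chain and terminal pKa sets. Sign: positive groups listed under
# `pos`, acidic under `neg`.
.PKA_SETS <- list(
  EMBOSS = list(
    nterm = 8.6, cterm = 3.6,
    pos = c(K = 10.8, R = 12.5, H = 6.5),
    neg = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  ),
  Lehninger = list(
    nterm = 9.69, cterm = 2.34,
    pos = c(K = 10.53, R = 12.48, H = 6.0),
    neg = c(D = 3.65, E = 4.25, C = 8.33, Y = 10.07)
  )
)

#' Retrieve a hydropathy scale by name
#'
#' Two scales are embedded: `"eisenberg"`, the Eisenberg consensus scale
#' used for GRAVY, and `"kyte-doolittle"`, used (rescaled to \[0,1\]) for
#' charge-hydropathy plot coordinates and FoldIndex-style profiles.
#' Selenocysteine (U) is mapped to the cysteine value unless `u_as` names
#' a different residue.
#'
#' @param name scale name, case-insensitive.
#' @param u_as residue whose hydropathy is reused for U (default `"C"`).
#' @return named numeric vector over the 20 standard residues plus U,
#'   with attributes `name`.
#' @export
hydropathy_scale <- function(name = c("eisenberg", "kyte-doolittle"),
                             u_as = "C") {
  name <- match.arg(tolower(name[1]), c("eisenberg", "kyte-doolittle"))
  vals <- switch(name, eisenberg = .EISENBERG, `kyte-doolittle` = .KYTE_DOOLITTLE)
  stopifnot(u_as %in% names(vals))
  vals <- c(vals, U = unname(vals[u_as]))
  attr(vals, "name") <- name
  vals
}

#' Retrieve a pKa table by name
#'
#' @param name `"EMBOSS"` (default throughout the package) or
#'   `"Lehninger"`.
#' @return list with elements `nterm`, `cterm`, `pos`, `neg`.
#' @export
pka_table <- function(name = "EMBOSS") {
  if (!name %in% names(.PKA_SETS)) {
    stop("unknown pKa table '", name, "'; available: ",
         paste(names(.PKA_SETS), collapse = ", "))
  }
  .PKA_SETS[[name]]
}
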