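## The 20 standard amino acids, one-letter codes.
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Kyte-Doolittle hydropathy scale.
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

## Residue groups behind the composition indices.
AA_ACIDIC <- c("D", "E")
AA_CHARGED <- c("D", "E", "H", "K", "R")
AA_POLAR_UNCHARGED <- c("C", "N", "Q", "S", "T", "Y")
AA_AROMATIC <- c("F", "W", "Y")

#' Names of the ten thermal-adaptation indices
#'
#' Counts of glycine, proline, serine, acidic (D,E), charged (D,E,H,K,R) and
#' polar uncharged (C,N,Q,S,T,Y) residues, plus the aliphatic index (Ikai),
#' aromaticity, GRAVY hydropathy and isoelectric point.
#'
#' @return character vector of length 10
#' @export
thermalIndexNames <- function() {
  c("n_gly", "n_pro", "n_ser", "n_acidic", "n_charged", "n_polar_uncharged",
    "aliphatic_index", "aromaticity", "gravy", "isoelectric_point")
}

#' Sanitize a protein sequence for index computation
#'
#' Uppercases, strips gap characters (- and .), terminal stops (*), and drops
#' ambiguous or non-standard letters (B, Z, X, U, O and anything outside the
#' 20-letter alphabet). Dropped residues are excluded from every index and
#' from length denominators.
#'
#' @param sequence amino-acid string
#' @return list with `sequence` (cleaned string) and `n_dropped`
#' @export
sanitizeSequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single string")
  s <- toupper(sequence)
  s <- gsub("[-.*[:space:]]", "", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  keep <- chars %in% AA_ALPHABET20
  list(sequence = paste(chars[keep], collapse = ""),
       n_dropped = sum(!keep))
}

#' Bjellqvist pKa scale used for isoelectric-point calculation
#'
#' The ProtParam-style constants: side-chain pKas for K, R, H (positive) and
#' D, E, C, Y (negative), default terminal pKas, and residue-specific
#' terminal overrides. A user-supplied scale with the same structure can be
#' passed to [isoelectricPoint()].
#'
#' @return list with elements `positive`, `negative`, `nterm_default`,
#'   `cterm_default`, `nterm_by_residue`, `cterm_by_residue`
#' @export
bjellqvistScale <- function() {
  list(positive = c(K = 10.0, R = 12.0, H = 5.98),
       negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
       nterm_default = 7.5, cterm_default = 3.55,
       nterm_by_residue = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36,
                            T = 6.82, V = 7.44, E = 7.7),
       cterm_by_residue = c(D = 4.55, E = 4.75))
}

## Net charge of a sanitized sequence at a given pH.
netCharge <- function(counts, first, last, pH, scale) {
  nterm_pk <- if (first %in% names(scale$nterm_by_residue))
    scale$nterm_by_residue[[first]] else scale$nterm_default
  cterm_pk <- if (last %in% names(scale$cterm_by_residue))
    scale$cterm_by_residue[[last]] else scale$cterm_default
  pos_pk <- c(scale$positive, nterm = nterm_pk)
  pos_n <- c(counts[names(scale$positive)], nterm = 1)
  neg_pk <- c(scale$negative, cterm = cterm_pk)
  neg_n <- c(counts[names(scale$negative)], cterm = 1)
  sum(pos_n / (1 + 10^(pH - pos_pk))) - sum(neg_n / (1 + 10^(neg_pk - pH)))
}

#' Isoelectric point by bisection
#'
#' Solves net charge = 0 on pH in \[0, 14\] by bisection with the Bjellqvist
#' pKa scale, to |net charge| < 1e-4 (matching the ProtParam convention).
#'
#' @param sequence amino-acid string (sanitized internally)
#' @param scale pKa scale, see [bjellqvistScale()]
#' @return isoelectric point, pH units
#' @export
isoelectricPoint <- function(sequence, scale = bjellqvistScale()) {
  s <- sanitizeSequence(sequence)$sequence
  if (!nzchar(s)) stop("no standard residues left after sanitization")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET20))
  counts <- stats::setNames(as.numeric(counts), AA_ALPHABET20)
  first <- chars[1]; last <- chars[length(chars)]
  lo <- 0; hi <- 14
  charge_lo <- netCharge(counts, first, last, lo, scale)
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    q <- netCharge(counts, first, last, mid, scale)
    if (abs(q) < 1e-4) break
    # charge decreases monotonically with pH
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Compute the ten thermal-adaptation indices of a protein sequence
#'
#' Residue counts are raw (not length-normalized). Aromaticity is the
#' fraction of F, W and Y. GRAVY is the mean Kyte-Doolittle hydropathy over
#' all residues. The aliphatic index follows Ikai:
#' X_Ala + 2.9 * X_Val + 3.9 * (X_Ile + X_Leu), with X in mole percent.
#' The isoelectric point uses bisection on the Bjellqvist pKa scale.
#'
#' @param sequence amino-acid string; sanitized with [sanitizeSequence()]
#' @param pka_scale pKa scale for the isoelectric point
#' @return named numeric vector over [thermalIndexNames()]
#' @examples
#' computeIndices(strrep("G", 100))[["gravy"]]  # -0.4
#' @export
computeIndices <- function(sequence, pka_scale = bjellqvistScale()) {
  san <- sanitizeSequence(sequence)
  s <- san$sequence
  if (!nzchar(s))
    stop("empty sequence (or nothing left after sanitization)")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  len <- length(chars)
  counts <- table(factor(chars, levels = AA_ALPHABET20))
  counts <- stats::setNames(as.numeric(counts), AA_ALPHABET20)
  molpct <- 100 * counts / len
  c(n_gly = counts[["G"]],
    n_pro = counts[["P"]],
    n_ser = counts[["S"]],
    n_acidic = sum(counts[AA_ACIDIC]),
    n_charged = sum(counts[AA_CHARGED]),
    n_polar_uncharged = sum(counts[AA_POLAR_UNCHARGED]),
    aliphatic_index = molpct[["A"]] + 2.9 * molpct[["V"]] +
      3.9 * (molpct[["I"]] + molpct[["L"]]),
    aromaticity = sum(counts[AA_AROMATIC]) / len,
    gravy = sum(KD_HYDROPATHY[chars]) / len,
    isoelectric_point = isoelectricPoint(s, pka_scale))
}
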