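# Physicochemical annotation of candidate peptides: average molecular
# weight, GRAVY (Kyte-Doolittle), Henderson-Hasselbalch net charge at
# a chosen pH, and theoretical pI by bisection of the charge curve.

# Kyte-Doolittle hydropathy scale
.KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
               Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
               L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
               S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# average residue masses (Da), water 18.0153 Da
.AVG_MASS <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
               V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
               I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
               K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
               F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.WATER_MASS <- 18.0153

#' Ionizable-group pKa presets
#'
#' Two presets reflecting the two annotation tools the panel mirrors:
#' \code{"protparam"} is the Bjellqvist set used for theoretical pI
#' (C-terminus 3.55, Asp 4.05, Glu 4.45, Cys 9.0, Tyr 10.0, His 5.98,
#' Lys 10.0, Arg 12.0, and a residue-specific N-terminal pKa);
#' \code{"protcalc"} is a generic set used for net charge at a given
#' pH (N-term 8.0, C-term 3.1, Asp/Glu 4.4, Cys 8.5, Tyr 10.0, His
#' 6.5, Lys 10.0, Arg 12.0).
#'
#' @param preset \code{"protcalc"} or \code{"protparam"}.
#' @return A \code{pka_set} list with elements \code{nTerm},
#'   \code{cTerm}, \code{side} (named vector over D,E,C,Y,H,K,R) and
#'   optionally \code{nTermByResidue}.
#' @export
pkaSet <- function(preset = c("protcalc", "protparam")) {
  preset <- match.arg(preset)
  if (preset == "protcalc") {
    structure(list(name = "protcalc", nTerm = 8.0, cTerm = 3.1,
                   side = c(D = 4.4, E = 4.4, C = 8.5, Y = 10.0,
                            H = 6.5, K = 10.0, R = 12.0),
                   nTermByResidue = NULL),
              class = "pka_set")
  } else {
    structure(list(name = "protparam", nTerm = 7.5, cTerm = 3.55,
                   side = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
                            H = 5.98, K = 10.0, R = 12.0),
                   nTermByResidue = c(A = 7.59, M = 7.0, S = 6.93,
                                      P = 8.36, T = 6.82, V = 7.44,
                                      E = 7.7)),
              class = "pka_set")
  }
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy values over all
#' residues; positive values indicate hydrophobic peptides.
#'
#' @param sequence peptide string (20-letter alphabet).
#' @return GRAVY value in \[-4.5, 4.5\].
#' @examples
#' gravy("DDSMAATGL")  # 0.044
#' @export
gravy <- function(sequence) {
  if (nchar(sequence) == 0L) stop("empty sequence")
  .checkAAAlphabet(sequence)
  mean(.KD_SCALE[strsplit(sequence, "")[[1]]])
}

#' Average molecular weight of a free peptide
#'
#' Sum of average residue masses plus one water (condensation
#' identity: concatenating peptides removes one water per bond).
#'
#' @param sequence peptide string.
#' @return Mass in Da.
#' @examples
#' molecularWeight("G")  # 75.07, free glycine
#' @export
molecularWeight <- function(sequence) {
  if (nchar(sequence) == 0L) stop("empty sequence")
  .checkAAAlphabet(sequence)
  sum(.AVG_MASS[strsplit(sequence, "")[[1]]]) + .WATER_MASS
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups: the N-terminus and
#' K/R/H side chains contribute \code{+1/(1+10^(pH-pKa))}; the
#' C-terminus and D/E/C/Y side chains contribute
#' \code{-1/(1+10^(pKa-pH))}. Strictly decreasing in pH.
#'
#' @param sequence peptide string.
#' @param pH pH in (0, 14); default 7.0.
#' @param pka a [pkaSet()]; default \code{"protcalc"}, which matches
#'   net-charge-at-pH-7 annotation conventions.
#' @return Net charge in elementary charges.
#' @examples
#' netCharge("DEEEVDI")  # about -5.1
#' @export
netCharge <- function(sequence, pH = 7.0, pka = pkaSet("protcalc")) {
  if (nchar(sequence) == 0L) stop("empty sequence")
  stopifnot(pH > 0, pH < 14, inherits(pka, "pka_set"))
  .checkAAAlphabet(sequence)
  res <- strsplit(sequence, "")[[1]]
  nTerm <- pka$nTerm
  if (!is.null(pka$nTermByResidue) && res[1] %in% names(pka$nTermByResidue))
    nTerm <- pka$nTermByResidue[[res[1]]]
  pos <- 1 / (1 + 10^(pH - nTerm))
  neg <- 1 / (1 + 10^(pka$cTerm - pH))
  for (r in res) {
    if (r %in% c("K", "R", "H"))
      pos <- pos + 1 / (1 + 10^(pH - pka$side[[r]]))
    else if (r %in% c("D", "E", "C", "Y"))
      neg <- neg + 1 / (1 + 10^(pka$side[[r]] - pH))
  }
  pos - neg
}

#' Theoretical isoelectric point
#'
#' Bisection of the net-charge curve over pH in \[0, 14\] until
#' \code{|charge| < tol}, using the Bjellqvist ("protparam") pKa set
#' by default — the convention of theoretical-pI annotation tools.
#'
#' @param sequence peptide string.
#' @param pka a [pkaSet()]; default \code{"protparam"}.
#' @param tol convergence tolerance on |charge| (default 1e-4).
#' @param maxIter maximum bisection iterations (default 200).
#' @return pI in pH units.
#' @examples
#' isoelectricPoint("DDSMAATGL")  # about 3.56
#' @export
isoelectricPoint <- function(sequence, pka = pkaSet("protparam"),
                             tol = 1e-4, maxIter = 200L) {
  lo <- 0; hi <- 14
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    ch <- netCharge(sequence, mid, pka)
    if (abs(ch) < tol) return(mid)
    if (ch > 0) lo <- mid else hi <- mid
  }
  stop("pI bisection did not converge within ", maxIter, " iterations")
}

#' Physicochemical profile table for candidate peptides
#'
#' The candidate annotation panel: average molecular weight,
#' theoretical pI (Bjellqvist set), GRAVY, and net charge at
#' \code{pH} (generic set). The \code{toxicity} column is an
#' annotation hook for an external toxicity predictor and is emitted
#' empty.
#'
#' @param sequences character vector of peptides.
#' @param pH pH for the net-charge column (default 7.0).
#' @param pkaCharge,pkaPI [pkaSet()]s for charge and pI.
#' @return data.frame with columns \code{sequence}, \code{mw},
#'   \code{pI}, \code{gravy}, \code{charge}, \code{toxicity}.
#' @export
physChemProfile <- function(sequences, pH = 7.0,
                            pkaCharge = pkaSet("protcalc"),
                            pkaPI = pkaSet("protparam")) {
  data.frame(
    sequence = sequences,
    mw = vapply(sequences, molecularWeight, numeric(1)),
    pI = vapply(sequences, isoelectricPoint, numeric(1), pka = pkaPI),
    gravy = vapply(sequences, gravy, numeric(1)),
    charge = vapply(sequences, netCharge, numeric(1), pH = pH,
                    pka = pkaCharge),
    toxicity = NA_character_,
    stringsAsFactors = FALSE, row.names = NULL)
}
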