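#' Physical and chemical constants used throughout ginsannot
#'
#' Monoisotopic atomic masses (IUPAC 2021), the electron mass, and the
#' negative-mode adduct and glycosyl-residue tables that drive all m/z
#' arithmetic in the package. All masses are in Dalton.
#'
#' @name ginsannot-constants
#' @keywords internal
NULL

# IUPAC 2021 monoisotopic masses of the most abundant isotope, Da.
ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  O = 15.9949146221,
  N = 14.0030740052,
  S = 31.97207069
)

ELECTRON_MASS <- 0.00054858
# mass of H minus an electron: what [M-H]- removes
PROTON_MASS <- 1.007276

#' Supported negative-mode adducts
#'
#' Mass deltas include the electron mass (anion convention):
#' `[M-H]-` removes a proton (-1.007276 Da); `[M+HCOO]-` attaches a
#' formate anion (+44.998203 Da). Both are singly charged.
#'
#' @return Data frame with columns `name`, `mass_delta` (Da), `charge`.
#' @examples
#' adduct_table()
#' @export
adduct_table <- function() {
  data.frame(
    name = c("[M-H]-", "[M+HCOO]-"),
    mass_delta = c(-PROTON_MASS,
                   ATOMIC_MASS[["C"]] + ATOMIC_MASS[["H"]] +
                     2 * ATOMIC_MASS[["O"]] + ELECTRON_MASS),
    charge = c(-1L, -1L),
    stringsAsFactors = FALSE
  )
}

# neutral formic acid, lost when a formate precursor collapses to [M-H]-
FORMIC_ACID_MASS <- 46.0054793

#' Glycosyl residue deltas
#'
#' Neutral-loss building blocks of the ginsenoside ladder: residues are
#' given as the anhydro (condensed) form actually lost in a glycosidic
#' cleavage, e.g. anhydrohexose C6H10O5 = 162.05282 Da. Deoxyhexose
#' (rhamnose) and pentose (arabinose/xylose) are included because several
#' ginsenosides (Rg2, F4, Rb3, Rc, Ra1) carry them.
#'
#' @return Data frame with columns `name`, `formula`, `mass` (Da).
#' @examples
#' residue_table()
#' @export
residue_table <- function() {
  fml <- c(
    Hexose        = "C6H10O5",
    Deoxyhexose   = "C6H10O4",
    Pentose       = "C5H8O4",
    HexuronicAcid = "C6H8O6",
    Malonyl       = "C3H2O3",
    Water         = "H2O"
  )
  data.frame(
    name = names(fml),
    formula = unname(fml),
    mass = vapply(fml, function(f) monoisotopic_mass(parse_formula(f)),
                  numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Aglycone classes
#'
#' The three sapogenin skeletons of Panax ginsenosides with the
#' theoretical m/z of their deprotonated diagnostic ions:
#' protopanaxadiol (PPD, C30H52O3), protopanaxatriol (PPT, C30H52O4),
#' oleanolic acid (OLE, C30H48O3).
#'
#' @return Data frame with columns `class_name`, `formula`,
#'   `diagnostic_mz` (theoretical `[M-H]-`).
#' @examples
#' aglycone_table()
#' @export
aglycone_table <- function() {
  fml <- c(PPD = "C30H52O3", PPT = "C30H52O4", OLE = "C30H48O3")
  data.frame(
    class_name = names(fml),
    formula = unname(fml),
    diagnostic_mz = vapply(fml, function(f) {
      adduct_mz(monoisotopic_mass(parse_formula(f)), "[M-H]-")
    }, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}
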