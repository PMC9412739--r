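#' Load the packaged ginsenoside library
#'
#' Reads the curated record table shipped with the package: the 21
#' compounds of the fermented-ginseng marker table (with retention time,
#' measured precursor m/z, MS/MS fragments and PPD/PPT classification as
#' printed) plus additional compounds named in the profiling narrative
#' (aglycones, Ro, Re, Rg1, Rc, malonyl-Rb1, ...) whose compositions are
#' derived from standard ginsenoside chemistry and flagged
#' `source = "text"`.
#'
#' Every record is checked on load against the composition invariant
#' `formula == aglycone + sum(residues) - dehydration * H2O`
#' (element-wise, exact); a violation is a load error naming the record.
#' A negative dehydration count denotes hydration (ring-opened or
#' dihydro forms such as 20(S)-Rf2).
#'
#' @param path Optional path to an alternative library CSV with the same
#'   columns as the packaged one.
#' @return Data frame of class `ginsenoside_library`, one row per record,
#'   with parsed `formula` string, residue-count columns, theoretical
#'   adduct m/z columns `mz_mh` (`[M-H]-`) and `mz_formate`, and
#'   `fragments` as a list column of numeric vectors.
#' @examples
#' lib <- load_library()
#' subset(lib, name == "Rb1")
#' @export
load_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ginsenosides.csv", package = "ginsannot")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("ginsenoside library fixture not found")
  }
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "rt", "measured_mz", "formula", "fragments", "class",
              "hexose", "deoxyhexose", "pentose", "hexuronic_acid",
              "malonyl", "dehydration", "source")
  missing_cols <- setdiff(needed, names(lib))
  if (length(missing_cols)) {
    stop("library fixture lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- character(0)
  for (i in seq_len(nrow(lib))) {
    ok <- tryCatch(
      record_balances(lib$formula[i], lib$class[i],
                      hex = lib$hexose[i], dhex = lib$deoxyhexose[i],
                      pen = lib$pentose[i], hexa = lib$hexuronic_acid[i],
                      mal = lib$malonyl[i], dehyd = lib$dehydration[i]),
      error = function(e) FALSE)
    if (!isTRUE(ok)) bad <- c(bad, lib$name[i])
  }
  if (length(bad)) {
    stop("library records fail the composition invariant: ",
         paste(bad, collapse = ", "))
  }
  mass <- vapply(lib$formula, function(f) monoisotopic_mass(parse_formula(f)),
                 numeric(1), USE.NAMES = FALSE)
  lib$neutral_mass <- mass
  lib$mz_mh <- adduct_mz(mass, "[M-H]-")
  lib$mz_formate <- adduct_mz(mass, "[M+HCOO]-")
  lib$n_residues <- lib$hexose + lib$deoxyhexose + lib$pentose +
    lib$hexuronic_acid + lib$malonyl
  lib$fragments <- lapply(lib$fragments, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  class(lib) <- c("ginsenoside_library", "data.frame")
  lib
}

# exact element bookkeeping: formula == aglycone + residues - dehyd*H2O
record_balances <- function(formula, class_name, hex, dhex, pen, hexa, mal,
                            dehyd) {
  agl <- aglycone_table()
  i <- match(class_name, agl$class_name)
  if (is.na(i)) stop("unknown aglycone class: ", class_name)
  expect <- unclass(parse_formula(agl$formula[i]))
  res <- residue_table()
  resf <- function(nm) unclass(parse_formula(res$formula[res$name == nm]))
  expect <- expect + hex * resf("Hexose") + dhex * resf("Deoxyhexose") +
    pen * resf("Pentose") + hexa * resf("HexuronicAcid") +
    mal * resf("Malonyl") - dehyd * resf("Water")
  identical(unname(expect), unname(as.integer(unclass(parse_formula(formula)))))
}

#' Residue composition of a library record as a named count vector
#' @param record One row of a `ginsenoside_library`.
#' @return Named integer vector over the residue names plus `dehydration`.
#' @export
residue_counts <- function(record) {
  c(Hexose = record$hexose, Deoxyhexose = record$deoxyhexose,
    Pentose = record$pentose, HexuronicAcid = record$hexuronic_acid,
    Malonyl = record$malonyl, dehydration = record$dehydration)
}

#' Library candidates for a precursor m/z
#'
#' Returns every record whose theoretical m/z under any of the supported
#' negative-mode adducts falls within `tol_ppm` of the query, sorted by
#' |ppm|. Isomers (equal formula) are all returned.
#'
#' @param mz Query precursor m/z.
#' @param library A `ginsenoside_library` (default: packaged).
#' @param adducts Adduct names to consider.
#' @param tol_ppm MS1 tolerance, ppm (> 0); default 10.
#' @return Data frame with the matching records plus `adduct` and `ppm`
#'   columns; zero rows when nothing matches.
#' @examples
#' candidates_for_mass(829.4957)$name
#' @export
candidates_for_mass <- function(mz, library = load_library(),
                                adducts = c("[M-H]-", "[M+HCOO]-"),
                                tol_ppm = 10) {
  stopifnot(tol_ppm > 0, length(mz) == 1L, mz > 0)
  out <- do.call(rbind, lapply(adducts, function(ad) {
    theo <- adduct_mz(library$neutral_mass, ad)
    ppm <- ppm_deviation(mz, theo)
    keep <- abs(ppm) <= tol_ppm
    if (!any(keep)) return(NULL)
    cbind(library[keep, , drop = FALSE],
          data.frame(adduct = ad, ppm = ppm[keep], theoretical_mz = theo[keep]))
  }))
  if (is.null(out)) {
    out <- cbind(library[0, , drop = FALSE],
                 data.frame(adduct = character(0), ppm = numeric(0),
                            theoretical_mz = numeric(0)))
  }
  out[order(abs(out$ppm), out$n_residues, out$name), , drop = FALSE]
}
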