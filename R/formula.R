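#' Parse a Hill-notation elemental formula
#'
#' Supported elements are C, H, O, N, S. A formula is stored as a named
#' integer vector of element counts (class `elemental_formula`); counts
#' are nonnegative and at least one must be positive.
#'
#' @param text Formula string, e.g. `"C48H82O18"`.
#' @return An `elemental_formula` object.
#' @examples
#' parse_formula("C48H82O18")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text)) {
    stop("formula must be a single non-empty string")
  }
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text)) {
    stop("cannot parse formula: ", text)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  counts <- stats::setNames(integer(length(ATOMIC_MASS)), names(ATOMIC_MASS))
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Z][a-z]?", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(ATOMIC_MASS)) {
      stop("unknown element symbol: ", el)
    }
    if (n <= 0L) stop("zero count not allowed for element ", el)
    counts[el] <- counts[el] + n
  }
  as_formula(counts)
}

as_formula <- function(counts) {
  counts <- counts[names(ATOMIC_MASS)]
  counts[is.na(counts)] <- 0L
  names(counts) <- names(ATOMIC_MASS)
  if (any(counts < 0L)) stop("negative element count")
  if (all(counts == 0L)) stop("empty formula")
  structure(as.integer(counts), names = names(ATOMIC_MASS),
            class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  # Hill order for C-containing compounds: C, H, then alphabetical
  ord <- if (x[["C"]] > 0L) c("C", "H", "N", "O", "S")
         else sort(names(ATOMIC_MASS))
  parts <- vapply(ord, function(el) {
    n <- x[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  paste(parts, collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula>", format(x), "\n")
  invisible(x)
}

#' Element-wise formula arithmetic
#'
#' Addition and subtraction of formulas. Subtraction that would drive any
#' element negative, or empty a formula completely, is an error.
#'
#' @param f1,f2 `elemental_formula` objects.
#' @return An `elemental_formula`.
#' @examples
#' formula_add(parse_formula("C6H10O5"), parse_formula("H2O"))
#' @export
formula_add <- function(f1, f2) {
  as_formula(unclass(f1) + unclass(f2))
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f1, f2) {
  as_formula(unclass(f1) - unclass(f2))
}

#' Monoisotopic mass of a formula
#'
#' Sum of element counts times IUPAC monoisotopic atomic masses.
#'
#' @param f An `elemental_formula` or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C6H10O5")  # anhydrohexose, 162.05282
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  sum(unclass(f) * ATOMIC_MASS)
}

#' Adduct m/z from a neutral mass
#'
#' @param neutral_mass Neutral monoisotopic mass, Da (> 0).
#' @param adduct Adduct name, one of `"[M-H]-"`, `"[M+HCOO]-"`.
#' @return m/z of the singly charged anion.
#' @examples
#' adduct_mz(monoisotopic_mass("C48H82O18"), "[M+HCOO]-")  # 991.5483
#' @export
adduct_mz <- function(neutral_mass, adduct = "[M-H]-") {
  if (!is.numeric(neutral_mass) || any(neutral_mass <= 0)) {
    stop("neutral mass must be positive")
  }
  tab <- adduct_table()
  i <- match(adduct, tab$name)
  if (is.na(i)) stop("unsupported adduct: ", adduct)
  (neutral_mass + tab$mass_delta[i]) / abs(tab$charge[i])
}

#' Recover the neutral mass from an adduct m/z
#'
#' @param mz Observed m/z.
#' @inheritParams adduct_mz
#' @return Neutral mass, Da.
#' @export
neutral_mass <- function(mz, adduct = "[M-H]-") {
  tab <- adduct_table()
  i <- match(adduct, tab$name)
  if (is.na(i)) stop("unsupported adduct: ", adduct)
  mz * abs(tab$charge[i]) - tab$mass_delta[i]
}

#' Signed parts-per-million deviation
#'
#' `1e6 * (observed - theoretical) / theoretical`; the conventional
#' high-resolution MS identification bound is |ppm| < 10.
#'
#' @param observed,theoretical m/z values.
#' @return Signed ppm deviation.
#' @examples
#' ppm_deviation(991.5483, 991.54832)
#' @export
ppm_deviation <- function(observed, theoretical) {
  1e6 * (observed - theoretical) / theoretical
}

#' @rdname ppm_deviation
#' @param tol_ppm Tolerance in ppm.
#' @export
within_ppm <- function(observed, theoretical, tol_ppm = 10) {
  abs(ppm_deviation(observed, theoretical)) <= tol_ppm
}
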