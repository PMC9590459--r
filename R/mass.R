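# Monoisotopic masses and adduct m/z. Positive adducts subtract the electron
# mass; this is required to reproduce quadrupole-TOF EIC targets to the
# printed 4 decimals.

MONO_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
               O = 15.9949146196, S = 31.97207100, P = 30.97376163,
               Na = 22.9897692809, K = 38.96370668, Cl = 34.96885268,
               F = 18.99840322, Fe = 55.9349375, Si = 27.9769265325,
               Br = 78.9183371, I = 126.904473)
ELECTRON_MASS <- 0.00054857990907
PROTON_MASS <- MONO_MASS[["H"]] - ELECTRON_MASS

#' Parse a molecular formula string
#'
#' @param x Formula like `"C30H50O2"` (element symbols with optional counts),
#'   or an already-named numeric vector of element counts.
#' @return Named integer vector of element counts, class `MolecularFormula`.
#' @export
molecular_formula <- function(x) {
  if (is.numeric(x)) {
    counts <- x
  } else {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
    toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
    if (sum(nchar(toks)) != nchar(x)) stop("cannot parse formula: ", x)
    el <- gsub("[0-9]", "", toks)
    ct <- as.integer(ifelse(grepl("[0-9]", toks), gsub("[A-Za-z]", "", toks), 1L))
    counts <- tapply(ct, el, sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  if (length(counts) == 0L || sum(counts) <= 0) {
    stop("formula must contain at least one atom")
  }
  unknown <- setdiff(names(counts), names(MONO_MASS))
  if (length(unknown) > 0L) {
    stop("element(s) without a monoisotopic mass: ",
         paste(unknown, collapse = ", "))
  }
  if (any(counts < 0)) stop("negative element counts")
  structure(counts, class = "MolecularFormula")
}

#' Monoisotopic mass of a molecular formula
#'
#' @param f Formula string or [molecular_formula()] object.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(f) {
  if (!inherits(f, "MolecularFormula")) f <- molecular_formula(f)
  sum(MONO_MASS[names(f)] * as.numeric(f))
}

#' Adduct m/z for a singly charged ion
#'
#' `[M+H]+ = M + m(H) - m(e)`, `[M-H]- = M - m(H) + m(e)`,
#' `[M+Na]+ = M + m(Na) - m(e)`.
#'
#' @param f Formula string or [molecular_formula()] object.
#' @param adduct One of `"[M+H]+"`, `"[M-H]-"`, `"[M+Na]+"`.
#' @return m/z value (Da per unit charge).
#' @export
adduct_mz <- function(f, adduct = c("[M+H]+", "[M-H]-", "[M+Na]+")) {
  adduct <- match.arg(adduct)
  M <- monoisotopic_mass(f)
  switch(adduct,
         "[M+H]+" = M + MONO_MASS[["H"]] - ELECTRON_MASS,
         "[M-H]-" = M - MONO_MASS[["H"]] + ELECTRON_MASS,
         "[M+Na]+" = M + MONO_MASS[["Na"]] - ELECTRON_MASS)
}
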