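# Shared alphabet definitions. State order is fixed package-wide: the 20
# standard residues alphabetically by one-letter code, then the gap, so that
# Potts parameter blocks and PSSM columns can be indexed consistently.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP <- "-"
AA21 <- c(AA20, GAP)

#' Amino-acid alphabet used throughout the package
#'
#' @param gap logical; include the gap character as a 21st symbol.
#' @return Character vector of one-letter residue codes.
#' @export
aa_alphabet <- function(gap = FALSE) if (gap) AA21 else AA20

# Map a character vector of residues to integer states 1..21 (gap = 21).
# Anything outside the alphabet (X, B, Z, ., *) is mapped to the gap state.
aa_index <- function(x) {
  idx <- match(x, AA21)
  idx[is.na(idx)] <- 21L
  idx
}

# Split a sequence string into single characters.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Normalize one aligned row: uppercase, '.' to '-', unknowns to gap.
normalize_row <- function(s) {
  ch <- seq_chars(toupper(s))
  ch[ch == "."] <- GAP
  ch[!(ch %in% AA21)] <- GAP
  paste(ch, collapse = "")
}
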