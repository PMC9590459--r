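#' Position-specific scoring matrix from a weighted alignment
#'
#' Per column `i` and residue `a`, the estimated probability is
#' `p_i(a) = (weighted count of a + alpha * background(a)) /
#' (weighted non-gap total + alpha)` and the score is
#' `log2(p_i(a) / background(a))` (bits). Gaps are excluded from the counts;
#' an all-gap column gets all-zero scores with a warning.
#'
#' @param aln An [alignment()] object.
#' @param w Optional [compute_weights()] result; default is
#'   `compute_weights(aln)`.
#' @param alpha Pseudocount weight (> 0), mixing the background into the
#'   observed frequencies; default 1.
#' @param background Length-20 probability vector over [aa_alphabet()];
#'   default uniform 1/20.
#' @return Object of class `PSSM`: list with `scores` (`L x 20`, columns
#'   named by residue), `probs`, `background`, `pseudocount_alpha`.
#' @export
compute_pssm <- function(aln, w = NULL, alpha = 1,
                         background = rep(1 / 20, 20)) {
  stopifnot(inherits(aln, "Alignment"))
  if (is.null(w)) w <- compute_weights(aln)
  stopifnot(inherits(w, "SequenceWeights"))
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (length(background) != 20L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("background must be 20 positive probabilities summing to 1")
  }
  st <- aln$states
  L <- aln$L
  counts <- matrix(0, L, 20L)
  for (a in 1:20) counts[, a] <- colSums((st == a) * w$weights)
  tot <- rowSums(counts)
  probs <- (counts + alpha * matrix(background, L, 20L, byrow = TRUE)) /
    (tot + alpha)
  scores <- log2(sweep(probs, 2L, background, "/"))
  if (any(tot == 0)) {
    warning(sprintf("column(s) %s are entirely gaps; scores set to 0",
                    paste(which(tot == 0), collapse = ", ")))
    scores[tot == 0, ] <- 0
    probs[tot == 0, ] <- matrix(background, sum(tot == 0), 20L, byrow = TRUE)
  }
  colnames(scores) <- colnames(probs) <- AA20
  structure(list(scores = scores, probs = probs, background = background,
                 pseudocount_alpha = alpha, L = L),
            class = "PSSM")
}

#' @export
print.PSSM <- function(x, ...) {
  cat(sprintf("PSSM: %d positions x 20 residues (bits, alpha = %g)\n",
              x$L, x$pseudocount_alpha))
  invisible(x)
}

#' Substitutions with positive PSSM support
#'
#' Lists every (position, residue) cell with a strictly positive score whose
#' residue differs from the target sequence at that position — the candidate
#' substitutions favored by family conservation. Sorted by descending score,
#' ties by (position, residue).
#'
#' @param pssm A [compute_pssm()] result.
#' @param target Target sequence (string or character vector) of length `L`.
#' @return data.frame with columns `position`, `from`, `to`, `score`.
#' @export
positive_substitutions <- function(pssm, target) {
  stopifnot(inherits(pssm, "PSSM"))
  tgt <- if (length(target) == 1L) seq_chars(target) else target
  if (length(tgt) != pssm$L) {
    stop(sprintf("target length %d does not match PSSM length %d",
                 length(tgt), pssm$L))
  }
  if (!all(tgt %in% AA20)) stop("target contains non-residue characters")
  pos <- which(pssm$scores > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) {
    return(data.frame(position = integer(), from = character(),
                      to = character(), score = numeric()))
  }
  res <- data.frame(position = pos[, 1L],
                    from = tgt[pos[, 1L]],
                    to = AA20[pos[, 2L]],
                    score = pssm$scores[pos])
  res <- res[res$from != res$to, , drop = FALSE]
  res <- res[order(-res$score, res$position, res$to), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a PSSM as TSV
#'
#' Columns: `position`, `native` (target residue) and the 20 residue scores.
#'
#' @param pssm A [compute_pssm()] result.
#' @param target Target sequence of length `L`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, target, path) {
  stopifnot(inherits(pssm, "PSSM"))
  tgt <- if (length(target) == 1L) seq_chars(target) else target
  df <- data.frame(position = seq_len(pssm$L), native = tgt,
                   pssm$scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
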