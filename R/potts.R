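# Pairwise Markov random field (Potts model) over alignment columns, fitted
# by L2-regularized pseudolikelihood. The objective is convex, so a
# quasi-Newton optimizer from zero initialization gives a reproducible
# optimum. Couplings are stored once per unordered pair i < j; the (j, i)
# view is the transpose.

#' Fit a Potts model to an alignment by regularized pseudolikelihood
#'
#' Minimizes the weighted negative log-pseudolikelihood
#' `sum_s w_s sum_i -log P(x_i^s | x_-i^s; h, J)` plus the L2 penalties
#' `lambda_h * ||h||^2 + lambda_J * ||J||^2` (each unordered pair counted
#' once). Sites condition on all other columns, with the coupling matrix
#' shared between the two conditionals of a pair (symmetric
#' pseudolikelihood).
#'
#' @param aln An [alignment()] object with at least 2 columns.
#' @param w Optional [compute_weights()] result; default
#'   `compute_weights(aln)`.
#' @param lambda_h L2 strength on fields; default 0.01.
#' @param lambda_J L2 strength on couplings; default `0.2 * (L - 1)`, the
#'   usual pseudolikelihood-DCA scaling.
#' @param max_iter Maximum L-BFGS iterations; default 500.
#' @param tol Convergence tolerance on the projected gradient infinity norm;
#'   default 1e-3.
#' @param alphabet `"full"` fits all 21 states (20 residues + gap as an
#'   ordinary state); `"observed"` restricts to the states present in the
#'   alignment — the fast projection used for recovery tests on synthetic
#'   reduced-alphabet data.
#' @return Object of class `PottsModel`: `states` (characters modelled),
#'   `q`, `h` (`L x q`), `J` (`q x q x n_pairs`, pairs in `pairs`),
#'   `pairs` (2-column matrix, i < j), regularization, `neff`, and
#'   convergence diagnostics (`converged`, `grad_norm`, `niter`, `value`).
#' @export
fit_potts <- function(aln, w = NULL, lambda_h = 0.01,
                      lambda_J = 0.2 * (aln$L - 1),
                      max_iter = 500, tol = 1e-3,
                      alphabet = c("full", "observed")) {
  stopifnot(inherits(aln, "Alignment"))
  alphabet <- match.arg(alphabet)
  if (aln$L < 2L) stop("Potts model needs at least 2 alignment columns")
  if (is.null(w)) w <- compute_weights(aln)
  stopifnot(inherits(w, "SequenceWeights"))
  if (w$neff <= 0) stop("neff must be positive")

  L <- aln$L
  N <- aln$N
  if (alphabet == "observed") {
    obs <- sort(unique(as.vector(aln$states)))
    states <- AA21[obs]
    X <- matrix(match(aln$states, obs), N, L)
  } else {
    states <- AA21
    X <- aln$states
  }
  q <- length(states)
  Lq <- L * q
  wts <- w$weights

  # One-hot design matrix, N x (L*q)
  Z <- Matrix::sparseMatrix(i = rep(seq_len(N), L),
                            j = as.vector(t(t(X) + (seq_len(L) - 1L) * q)),
                            x = 1, dims = c(N, Lq))

  pairs <- t(utils::combn(L, 2L))
  npair <- nrow(pairs)
  # Flat (column-major) indices into the Lq x Lq interaction matrix V for the
  # upper (i-block rows, j-block cols) and mirrored lower image of each J_ij
  # element, in the storage order of the J parameter vector (a fastest).
  a <- rep(seq_len(q), times = q)       # row state within block i
  b <- rep(seq_len(q), each = q)        # col state within block j
  iofs <- (pairs[, 1L] - 1L) * q
  jofs <- (pairs[, 2L] - 1L) * q
  r_up <- outer(a, iofs, "+"); c_up <- outer(b, jofs, "+")
  idx_up <- as.vector((c_up - 1) * Lq + r_up)
  r_lo <- outer(b, jofs, "+"); c_lo <- outer(a, iofs, "+")
  idx_lo <- as.vector((c_lo - 1) * Lq + r_lo)

  nh <- Lq
  nJ <- npair * q * q
  obs_idx <- cbind(seq_len(N), 0L)  # filled per block below
  blk_cols <- lapply(seq_len(L), function(i) ((i - 1L) * q + 1L):(i * q))

  fg <- function(par) {
    h <- par[seq_len(nh)]
    Jv <- par[nh + seq_len(nJ)]
    V <- numeric(Lq * Lq)
    V[idx_up] <- Jv
    V[idx_lo] <- Jv
    dim(V) <- c(Lq, Lq)
    M <- as.matrix(Z %*% V) + matrix(h, N, Lq, byrow = TRUE)
    D <- matrix(0, N, Lq)
    nll <- 0
    for (i in seq_len(L)) {
      cols <- blk_cols[[i]]
      Mi <- M[, cols, drop = FALSE]
      mx <- Mi[cbind(seq_len(N), max.col(Mi, ties.method = "first"))]
      E <- exp(Mi - mx)
      Se <- rowSums(E)
      lse <- mx + log(Se)
      sel <- Mi[cbind(seq_len(N), X[, i])]
      nll <- nll + sum(wts * (lse - sel))
      P <- E / Se
      Pi <- P * wts
      Pi[cbind(seq_len(N), X[, i])] <- Pi[cbind(seq_len(N), X[, i])] - wts
      D[, cols] <- Pi
    }
    G <- as.matrix(Matrix::crossprod(Z, D))
    gh <- colSums(D) + 2 * lambda_h * h
    gJ <- G[idx_up] + G[idx_lo] + 2 * lambda_J * Jv
    list(value = nll + lambda_h * sum(h^2) + lambda_J * sum(Jv^2),
         grad = c(gh, gJ))
  }

  env <- new.env()
  f <- function(par) { r <- fg(par); env$grad <- r$grad; r$value }
  g <- function(par) env$grad
  opt <- stats::optim(rep(0, nh + nJ), fn = f, gr = g, method = "L-BFGS-B",
                      control = list(maxit = max_iter, pgtol = tol,
                                     factr = 0, lmm = 8))
  grad_norm <- max(abs(fg(opt$par)$grad))
  converged <- grad_norm < tol
  if (!converged) {
    warning(sprintf(
      "pseudolikelihood fit stopped before convergence (grad inf-norm %.3g >= tol %.3g)",
      grad_norm, tol))
  }
  h <- matrix(opt$par[seq_len(nh)], L, q, byrow = TRUE)
  colnames(h) <- states
  J <- array(opt$par[nh + seq_len(nJ)], dim = c(q, q, npair),
             dimnames = list(states, states, NULL))
  structure(list(states = states, q = q, L = L, h = h, J = J, pairs = pairs,
                 lambda_h = lambda_h, lambda_J = lambda_J, neff = w$neff,
                 converged = converged, grad_norm = grad_norm,
                 niter = opt$counts[["function"]], value = opt$value),
            class = "PottsModel")
}

#' @export
print.PottsModel <- function(x, ...) {
  cat(sprintf(
    "PottsModel: L = %d, q = %d, neff = %.1f, %sconverged (grad %.2g)\n",
    x$L, x$q, x$neff, if (x$converged) "" else "NOT ", x$grad_norm))
  invisible(x)
}

pair_index <- function(model, i, j) {
  which(model$pairs[, 1L] == min(i, j) & model$pairs[, 2L] == max(i, j))
}

#' Coupling matrix of a position pair
#'
#' Returns the `q x q` coupling block `J_ij`; for `i > j` the transpose of
#' the stored `J_ji`.
#'
#' @param model A [fit_potts()] result.
#' @param i,j Distinct positions in `1..L`.
#' @return `q x q` numeric matrix (rows: states at `i`; cols: states at `j`).
#' @export
potts_coupling <- function(model, i, j) {
  stopifnot(inherits(model, "PottsModel"), i != j,
            i >= 1, j >= 1, i <= model$L, j <= model$L)
  Jm <- model$J[, , pair_index(model, i, j)]
  if (i < j) Jm else t(Jm)
}

# Zero-sum (Ising) gauge for a coupling block: double-centering.
zero_sum_gauge <- function(B) {
  B - outer(rowMeans(B), rep(1, ncol(B))) -
    outer(rep(1, nrow(B)), colMeans(B)) + mean(B)
}

#' Frobenius-norm coupling scores with average product correction
#'
#' `S_ij` is the Frobenius norm of the non-gap block of `J_ij` after the
#' zero-sum gauge transformation. The APC-corrected map is
#' `S_apc_ij = S_ij - (Sbar_i * Sbar_j) / Sbar` with `Sbar_i` the mean of
#' row `i` excluding the diagonal and `Sbar` the mean over all off-diagonal
#' entries; it removes the background connectivity that uniformly inflates
#' high-entropy columns.
#'
#' @param model A [fit_potts()] result.
#' @return Object of class `CouplingScores`: `S` and `S_apc`, both `L x L`
#'   symmetric with zero diagonal.
#' @export
coupling_scores <- function(model) {
  stopifnot(inherits(model, "PottsModel"))
  L <- model$L
  keep <- model$states != GAP
  S <- matrix(0, L, L)
  for (p in seq_len(nrow(model$pairs))) {
    B <- zero_sum_gauge(model$J[keep, keep, p])
    v <- sqrt(sum(B^2))
    S[model$pairs[p, 1L], model$pairs[p, 2L]] <- v
    S[model$pairs[p, 2L], model$pairs[p, 1L]] <- v
  }
  S_apc <- apc_correct(S)
  structure(list(S = S, S_apc = S_apc), class = "CouplingScores")
}

# Average product correction of a symmetric zero-diagonal score matrix.
apc_correct <- function(S) {
  L <- nrow(S)
  if (L < 2L) return(S * 0)
  row_mean <- rowSums(S) / (L - 1)
  all_mean <- sum(S) / (L * (L - 1))
  A <- if (all_mean > 0) S - outer(row_mean, row_mean) / all_mean else S * 0
  diag(A) <- 0
  A
}

#' @export
print.CouplingScores <- function(x, ...) {
  cat(sprintf("CouplingScores: %d x %d (max APC %.3f)\n",
              nrow(x$S), ncol(x$S), max(x$S_apc)))
  invisible(x)
}

#' Top co-evolving position pairs
#'
#' @param scores A [coupling_scores()] result.
#' @param k Number of pairs to return (>= 1). If `k` exceeds the number of
#'   pairs, all pairs are returned with a warning.
#' @return data.frame `i`, `j` (`i < j`), `score`, sorted by descending APC
#'   score, ties broken by `(i, j)` lexicographic.
#' @export
top_pairs <- function(scores, k) {
  stopifnot(inherits(scores, "CouplingScores"))
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("k must be >= 1")
  L <- nrow(scores$S_apc)
  ut <- which(upper.tri(scores$S_apc), arr.ind = TRUE)
  df <- data.frame(i = ut[, 1L], j = ut[, 2L],
                   score = scores$S_apc[ut])
  if (k > nrow(df)) {
    warning(sprintf("k = %d exceeds the %d available pairs; returning all",
                    k, nrow(df)))
    k <- nrow(df)
  }
  df <- df[order(-df$score, df$i, df$j), , drop = FALSE]
  df <- df[seq_len(k), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Substitutions favored by co-evolution
#'
#' For each of the top `k_pairs` coupled pairs `(i, j)`, scans both
#' directions: at position `i` the residue `a` maximizing
#' `J_ij(a, target[j]) + h_i(a)` over the 20 residues, and symmetrically at
#' `j`. A proposal is reported when the best residue differs from the target
#' and its objective gain over the target residue is positive.
#'
#' @param model A [fit_potts()] result.
#' @param scores Matching [coupling_scores()] result.
#' @param target Target sequence of length `L`.
#' @param k_pairs Number of top APC pairs to scan; default `ceiling(1.5 * L)`.
#' @return data.frame `position`, `from`, `to`, `partner_position`,
#'   `coupling_gain`, sorted by descending gain (ties by position, partner).
#' @export
coevolved_substitutions <- function(model, scores, target,
                                    k_pairs = ceiling(1.5 * model$L)) {
  stopifnot(inherits(model, "PottsModel"), inherits(scores, "CouplingScores"))
  tgt <- if (length(target) == 1L) seq_chars(target) else target
  if (length(tgt) != model$L) {
    stop(sprintf("target length %d does not match model length %d",
                 length(tgt), model$L))
  }
  tp <- suppressWarnings(top_pairs(scores, k_pairs))
  keep <- which(model$states != GAP)
  tstate <- match(tgt, model$states)
  out <- list()
  propose <- function(pos, partner) {
    si <- tstate[pos]; sj <- tstate[partner]
    if (is.na(si) || is.na(sj)) return(NULL)
    Jm <- potts_coupling(model, pos, partner)
    val <- Jm[keep, sj] + model$h[pos, keep]
    best <- which.max(val)
    cur <- which(keep == si)
    if (length(cur) == 0L) return(NULL)
    gain <- val[best] - val[cur]
    if (keep[best] == si || gain <= 0) return(NULL)
    data.frame(position = pos, from = tgt[pos],
               to = model$states[keep[best]],
               partner_position = partner, coupling_gain = gain)
  }
  for (r in seq_len(nrow(tp))) {
    out[[length(out) + 1L]] <- propose(tp$i[r], tp$j[r])
    out[[length(out) + 1L]] <- propose(tp$j[r], tp$i[r])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(position = integer(), from = character(),
                      to = character(), partner_position = integer(),
                      coupling_gain = numeric()))
  }
  df <- do.call(rbind, out)
  df <- df[order(-df$coupling_gain, df$position, df$partner_position), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a coupling map as TSV
#'
#' @param scores A [coupling_scores()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_couplings <- function(scores, path) {
  stopifnot(inherits(scores, "CouplingScores"))
  ut <- which(upper.tri(scores$S), arr.ind = TRUE)
  df <- data.frame(i = ut[, 1L], j = ut[, 2L], raw = scores$S[ut],
                   apc = scores$S_apc[ut])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
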