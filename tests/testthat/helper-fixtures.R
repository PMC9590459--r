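# Shared fixtures and independent oracles. Oracles deliberately use a
# different code path (plain loops, table(), closed forms) from the package.

WT60 <- paste(rep("MKTLISAGCDEFHNPQRVWYMKTLISAGCDEFHNPQRVWYMKTLISAGCDEFHNPQRVWY",
                  1), collapse = "")

tiny_aln <- function(rows, ids = sprintf("s%d", seq_along(rows))) {
  alignment(ids, rows)
}

write_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# Brute-force PSSM oracle: explicit count loops, log2 odds.
oracle_pssm <- function(rows, weights, alpha, background) {
  chars <- lapply(rows, function(r) strsplit(r, "")[[1]])
  L <- length(chars[[1]])
  aa <- enzdesign::aa_alphabet()
  sc <- matrix(0, L, 20)
  for (i in seq_len(L)) {
    cnt <- setNames(numeric(20), aa)
    tot <- 0
    for (s in seq_along(chars)) {
      ch <- chars[[s]][i]
      if (ch %in% aa) {
        cnt[ch] <- cnt[ch] + weights[s]
        tot <- tot + weights[s]
      }
    }
    for (a in seq_along(aa)) {
      p <- (cnt[a] + alpha * background[a]) / (tot + alpha)
      sc[i, a] <- log2(p / background[a])
    }
  }
  colnames(sc) <- aa
  sc
}

# Hand-applied APC on a symmetric zero-diagonal matrix.
oracle_apc <- function(S) {
  L <- nrow(S)
  A <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      si <- mean(S[i, -i]); sj <- mean(S[j, -j])
      sbar <- mean(S[row(S) != col(S)])
      A[i, j] <- S[i, j] - si * sj / sbar
    }
  }
  A
}

# Monte-Carlo SASA oracle for one atom among occluders: rejection sampling
# of uniform points on the expanded sphere.
oracle_mc_sasa <- function(center, radius, others, other_radii, n = 1e6,
                           seed = 42) {
  set.seed(seed)
  z <- stats::rnorm(n); y <- stats::rnorm(n); x <- stats::rnorm(n)
  nrm <- sqrt(x^2 + y^2 + z^2)
  px <- center[1] + radius * x / nrm
  py <- center[2] + radius * y / nrm
  pz <- center[3] + radius * z / nrm
  acc <- rep(TRUE, n)
  for (m in seq_len(nrow(others))) {
    d2 <- (px - others[m, 1])^2 + (py - others[m, 2])^2 + (pz - others[m, 3])^2
    acc <- acc & d2 >= other_radii[m]^2
  }
  4 * pi * radius^2 * mean(acc)
}

# Empirical mutual information between two alignment columns.
oracle_mi <- function(aln, i, j) {
  tab <- table(substr(aln$rows, i, i), substr(aln$rows, j, j))
  p <- tab / sum(tab)
  pi_ <- rowSums(p); pj <- colSums(p)
  s <- 0
  for (a in seq_len(nrow(p))) {
    for (b in seq_len(ncol(p))) {
      if (p[a, b] > 0) s <- s + p[a, b] * log(p[a, b] / (pi_[a] * pj[b]))
    }
  }
  s
}

# Hand-built Potts model object for coevolved_substitutions oracles.
fake_potts <- function(L, states, h, Jlist) {
  pairs <- t(utils::combn(L, 2))
  q <- length(states)
  J <- array(0, dim = c(q, q, nrow(pairs)),
             dimnames = list(states, states, NULL))
  for (nm in names(Jlist)) {
    ij <- as.integer(strsplit(nm, ",")[[1]])
    p <- which(pairs[, 1] == ij[1] & pairs[, 2] == ij[2])
    J[, , p] <- Jlist[[nm]]
  }
  structure(list(states = states, q = q, L = L, h = h, J = J, pairs = pairs,
                 lambda_h = 0.01, lambda_J = 0.2 * (L - 1), neff = 1,
                 converged = TRUE, grad_norm = 0, niter = 0, value = 0),
            class = "PottsModel")
}

# Random single/multi-substitution variant on a base sequence.
random_variant <- function(base, n_subs, rng_positions = NULL) {
  chars <- strsplit(base, "")[[1]]
  pos <- sample(if (is.null(rng_positions)) seq_along(chars) else
    rng_positions, n_subs)
  subs <- data.frame(position = pos, from = chars[pos],
                     to = vapply(chars[pos], function(f)
                       sample(setdiff(enzdesign::aa_alphabet(), f), 1),
                       character(1)))
  name <- paste(sprintf("%s%d%s", subs$from, subs$position, subs$to)[
    order(subs$position)], collapse = "-")
  list(name = name, subs = subs[order(subs$position), ])
}

# VariantSet built directly from named scores for clustering tests.
variant_set_from <- function(base, names_, scores = NULL) {
  vars <- lapply(seq_along(names_), function(i) {
    v <- parse_variant_name(names_[i], base)
    v$score <- if (is.null(scores)) 0 else scores[i]
    v
  })
  structure(list(variants = vars, base = base, table = data.frame()),
            class = "VariantSet")
}
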