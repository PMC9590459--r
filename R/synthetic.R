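# Seeded generators for every input the pipeline consumes: Potts-sampled
# alignments with planted couplings and conserved columns, toy helix
# structures with a placed ligand atom, and Gaussian-peak chromatograms.
# All are pure functions of their arguments plus the seed.

#' Sample a synthetic alignment from a known Potts model
#'
#' Single-chain Gibbs sampling from a Potts model with zero fields except at
#' `conserved` columns (field `conserved_strength` on a per-column target
#' state) and diagonal couplings `J(a, b) = beta * 1[a == b]` on the planted
#' pairs, which favor identical states and are disjoint from the conserved
#' columns. The reduced alphabet uses the first `q` residue letters, so the
#' result is a valid [alignment()].
#'
#' @param L Columns; default 30.
#' @param N Sequences; default 2000.
#' @param q Alphabet size (2-20); default 8, the fast projection used for
#'   recovery tests.
#' @param n_pairs Number of planted coupled pairs; default 10 (ignored when
#'   `pairs` is given).
#' @param beta Planted coupling strength (>= 0); default 1.
#' @param conserved Integer vector of conserved column indices; default none.
#' @param conserved_strength Field strength at conserved columns; default 2.
#' @param seed RNG seed.
#' @param burn_in Burn-in sweeps; default 1000.
#' @param thin Sweeps between retained samples; default 10.
#' @param pairs Optional explicit 2-column matrix of planted pairs.
#' @return List: `alignment` (an [alignment()]), `truth` (list with `pairs`,
#'   `beta`, `conserved`, `conserved_states`, `h`, `seed`).
#' @export
sample_potts_msa <- function(L = 30, N = 2000, q = 8, n_pairs = 10,
                             beta = 1.0, conserved = integer(0),
                             conserved_strength = 2.0, seed = 1,
                             burn_in = 1000, thin = 10, pairs = NULL) {
  if (beta < 0) stop("beta must be non-negative")
  if (q < 2 || q > 20) stop("q must be in 2..20")
  set.seed(as.integer(seed))
  letters_q <- AA20[seq_len(q)]

  if (is.null(pairs)) {
    avail <- setdiff(seq_len(L), conserved)
    if (n_pairs > 0) {
      if (length(avail) < 2 * n_pairs) {
        stop("not enough free columns for the requested planted pairs")
      }
      picked <- sample(avail, 2 * n_pairs)
      pairs <- matrix(picked, ncol = 2)
      pairs <- t(apply(pairs, 1, sort))
    } else {
      pairs <- matrix(integer(0), ncol = 2)
    }
  } else {
    pairs <- as.matrix(pairs)
    if (length(intersect(as.vector(pairs), conserved)) > 0L) {
      stop("planted pairs must be disjoint from conserved columns")
    }
  }

  h <- matrix(0, L, q)
  conserved_states <- integer(0)
  if (length(conserved) > 0L) {
    conserved_states <- sample(q, length(conserved), replace = TRUE)
    h[cbind(conserved, conserved_states)] <- conserved_strength
  }
  # partner lookup: each position's coupled partners
  partners <- vector("list", L)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    partners[[i]] <- c(partners[[i]], j)
    partners[[j]] <- c(partners[[j]], i)
  }

  x <- sample(q, L, replace = TRUE)
  rows <- matrix(0L, N, L)
  got <- 0L
  sweep_no <- 0L
  next_keep <- burn_in + 1L
  while (got < N) {
    sweep_no <- sweep_no + 1L
    for (i in seq_len(L)) {
      logits <- h[i, ]
      for (j in partners[[i]]) {
        # diagonal coupling: bonus beta for matching the partner's state
        logits[x[j]] <- logits[x[j]] + beta
      }
      pr <- exp(logits - max(logits))
      x[i] <- sample.int(q, 1L, prob = pr)
    }
    if (sweep_no >= next_keep) {
      got <- got + 1L
      rows[got, ] <- x
      next_keep <- sweep_no + thin
    }
  }
  aln <- alignment(sprintf("synth_%04d", seq_len(N)),
                   apply(rows, 1L, function(r)
                     paste(letters_q[r], collapse = "")))
  list(alignment = aln,
       truth = list(pairs = pairs, beta = beta, conserved = conserved,
                    conserved_states = conserved_states,
                    conserved_residues = letters_q[conserved_states],
                    h = h, q = q, seed = seed))
}

#' Build a toy helix structure with an optional ligand atom
#'
#' An ideal alpha-helix trace (rise 1.5 A, twist 100 degrees per residue,
#' radius 2.3 A) of poly-alanine with CA and outward-pointing CB
#' pseudo-atoms, plus one HETATM iron ligand placed `ligand_offset` A
#' radially outward from a chosen residue's CB. End residues are more
#' exposed than mid-helix ones, and the ligand defines a pocket
#' neighborhood, which is all the environment classifier needs.
#'
#' @param n_residues Helix length (>= 4); default 20.
#' @param ligand_resno Residue the ligand is anchored to (`NA` for no
#'   ligand); default 10.
#' @param ligand_offset Distance (A) from that residue's CB; default 5.
#' @return A `Structure` (writable with [write_pdb()]).
#' @export
make_toy_structure <- function(n_residues = 20, ligand_resno = 10,
                               ligand_offset = 5.0) {
  if (n_residues < 4) stop("helix needs at least 4 residues")
  rise <- 1.5; twist <- 100 * pi / 180; radius <- 2.3
  i <- seq_len(n_residues)
  ang <- (i - 1) * twist
  ca <- cbind(radius * cos(ang), radius * sin(ang), (i - 1) * rise)
  # CB 1.53 A from CA, radially outward
  cb <- cbind((radius + 1.53) * cos(ang), (radius + 1.53) * sin(ang),
              (i - 1) * rise)
  atoms <- data.frame(
    serial = seq_len(2L * n_residues),
    name = rep(c("CA", "CB"), n_residues),
    resname = "ALA", chain = "A",
    resno = rep(i, each = 2L),
    x = as.vector(rbind(ca[, 1L], cb[, 1L])),
    y = as.vector(rbind(ca[, 2L], cb[, 2L])),
    z = as.vector(rbind(ca[, 3L], cb[, 3L])),
    element = "C", is_ligand = FALSE)
  if (!is.na(ligand_resno)) {
    if (ligand_resno < 1 || ligand_resno > n_residues) {
      stop("ligand_resno outside the helix")
    }
    a0 <- ang[ligand_resno]
    lig <- c((radius + 1.53 + ligand_offset) * cos(a0),
             (radius + 1.53 + ligand_offset) * sin(a0),
             (ligand_resno - 1) * rise)
    atoms <- rbind(atoms, data.frame(
      serial = 2L * n_residues + 1L, name = "FE", resname = "HEM",
      chain = "A", resno = n_residues + 1L,
      x = lig[1L], y = lig[2L], z = lig[3L],
      element = "FE", is_ligand = TRUE))
  }
  structure(list(atoms = atoms, ligand_codes = "HEM"), class = "Structure")
}

#' Simulate a spectra series of Gaussian chromatographic peaks
#'
#' Scans on a uniform retention-time grid; each peak contributes a
#' Gaussian-in-time intensity `A * exp(-(t - rt)^2 / (2 sigma^2))` at its
#' m/z. Gaussian noise of standard deviation `noise_sd` is added per peak
#' entry and clipped at zero.
#'
#' @param peaks data.frame with columns `rt` (min), `mz`, `amplitude`,
#'   `sigma` (min, > 0).
#' @param rt_range Time range `c(from, to)` in minutes; default `c(0, 20)`.
#' @param scans_per_min Scan rate; default 60.
#' @param noise_sd Noise standard deviation; default 0.
#' @param seed RNG seed; default 1.
#' @return A `SpectraSeries`.
#' @export
make_chromatogram <- function(peaks, rt_range = c(0, 20), scans_per_min = 60,
                              noise_sd = 0, seed = 1) {
  need <- c("rt", "mz", "amplitude", "sigma")
  if (!all(need %in% names(peaks))) {
    stop("peaks must have columns rt, mz, amplitude, sigma")
  }
  if (any(peaks$sigma <= 0)) stop("peak sigma must be positive")
  set.seed(as.integer(seed))
  times <- seq(rt_range[1L], rt_range[2L], by = 1 / scans_per_min)
  scans <- lapply(times, function(t) {
    ints <- peaks$amplitude * exp(-(t - peaks$rt)^2 / (2 * peaks$sigma^2))
    if (noise_sd > 0) ints <- ints + stats::rnorm(length(ints), 0, noise_sd)
    list(rt = t, mz = peaks$mz, intensity = pmax(0, ints))
  })
  spectra_series(scans)
}
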