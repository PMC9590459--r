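# Candidate enumeration from the two evidence streams (conservation PSSM and
# co-evolution couplings), PAM30-derived variant distances, deterministic
# average-linkage clustering, and per-cluster representative selection.

#' PAM30 similarity matrix (20 x 20)
#'
#' NCBI PAM30 restricted to the 20 standard residues, taken from the
#' Biostrings data set.
#'
#' @return Integer matrix with residue one-letter row/column names.
#' @export
pam30_matrix <- function() {
  e <- new.env()
  utils::data("PAM30", package = "Biostrings", envir = e)
  m <- e$PAM30[AA20, AA20]
  storage.mode(m) <- "double"
  m
}

#' Enumerate single-substitution candidate variants
#'
#' Builds one variant per evidence record on top of `base_variant`'s
#' sequence, merging duplicates (same position and target residue) across
#' the two streams. Each candidate is annotated with its burial class and
#' pocket flag from `env` and scored as `-(PSSM score) - (coupling gain)`
#' (missing terms 0; lower is better). `filter` optionally restricts to
#' surface or pocket positions.
#'
#' @param base_variant A `Variant` (candidates are built on the sequence it
#'   produces).
#' @param pssm_subs [positive_substitutions()] output (may be `NULL`).
#' @param coev_subs [coevolved_substitutions()] output (may be `NULL`).
#' @param env Optional [classify_residues()] output; positions without
#'   environment data get class `"unknown"` with a warning.
#' @param filter One of `"all"`, `"surface"`, `"pocket"`.
#' @return Object of class `VariantSet`: list with `variants` (list of
#'   `Variant`), `base` (the sequence candidates apply to), and a summary
#'   `table`.
#' @export
enumerate_candidates <- function(base_variant, pssm_subs = NULL,
                                 coev_subs = NULL, env = NULL,
                                 filter = c("all", "surface", "pocket")) {
  stopifnot(inherits(base_variant, "Variant"))
  filter <- match.arg(filter)
  seq0 <- apply_variant(base_variant)
  chars <- seq_chars(seq0)

  recs <- list()
  add <- function(position, to, prov, pssm_score = 0, coup_gain = 0) {
    key <- sprintf("%d|%s", position, to)
    if (chars[position] == to) return()
    if (is.null(recs[[key]])) {
      recs[[key]] <<- list(position = position, from = chars[position],
                           to = to, provenance = prov,
                           pssm_score = pssm_score, coupling_gain = coup_gain)
    } else {
      recs[[key]]$provenance <<- union(recs[[key]]$provenance, prov)
      recs[[key]]$pssm_score <<- max(recs[[key]]$pssm_score, pssm_score)
      recs[[key]]$coupling_gain <<- max(recs[[key]]$coupling_gain, coup_gain)
    }
  }
  if (!is.null(pssm_subs) && nrow(pssm_subs) > 0L) {
    for (r in seq_len(nrow(pssm_subs))) {
      add(pssm_subs$position[r], pssm_subs$to[r], "pssm",
          pssm_score = pssm_subs$score[r])
    }
  }
  if (!is.null(coev_subs) && nrow(coev_subs) > 0L) {
    for (r in seq_len(nrow(coev_subs))) {
      add(coev_subs$position[r], coev_subs$to[r], "coevolution",
          coup_gain = coev_subs$coupling_gain[r])
    }
  }
  if (length(recs) == 0L) {
    return(structure(list(variants = list(), base = seq0,
                          table = data.frame()), class = "VariantSet"))
  }
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(position = r$position, from = r$from, to = r$to,
               provenance = paste(sort(r$provenance), collapse = ","),
               score = -(r$pssm_score) - (r$coupling_gain))
  }))
  df <- df[order(df$position, df$to), , drop = FALSE]
  rownames(df) <- NULL

  if (!is.null(env)) {
    m <- match(df$position, env$residue_number)
    df$burial_class <- ifelse(is.na(m), "unknown",
                              env$burial_class[m])
    df$pocket <- ifelse(is.na(m), FALSE, env$pocket[m])
    if (anyNA(m)) {
      warning(sprintf("no environment data for position(s) %s; class 'unknown'",
                      paste(unique(df$position[is.na(m)]), collapse = ", ")))
    }
  } else {
    df$burial_class <- "unknown"
    df$pocket <- FALSE
  }
  keep <- switch(filter,
                 all = rep(TRUE, nrow(df)),
                 surface = df$burial_class == "surface",
                 pocket = df$pocket)
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  variants <- lapply(seq_len(nrow(df)), function(r) {
    v <- new_variant(seq0,
                     data.frame(position = df$position[r], from = df$from[r],
                                to = df$to[r]),
                     provenance = strsplit(df$provenance[r], ",")[[1]],
                     score = df$score[r])
    v
  })
  df$name <- vapply(variants, `[[`, character(1), "name")
  structure(list(variants = variants, base = seq0,
                 table = df[, c("name", setdiff(names(df), "name"))]),
            class = "VariantSet")
}

#' @export
print.VariantSet <- function(x, ...) {
  cat(sprintf("VariantSet: %d candidate variants\n", length(x$variants)))
  invisible(x)
}

#' PAM30-derived distance between two variants
#'
#' Over the union of mutated positions, with `x` the residue of `a` at the
#' position and `y` that of `b`, the distance is
#' `sum (s(x,x) + s(y,y) - 2 s(x,y)) / 2` using the PAM30 similarities `s`.
#' Zero for identical variants and symmetric; the triangle inequality is not
#' guaranteed by this construction.
#'
#' @param a,b `Variant`s sharing the same base sequence.
#' @param matrix 20 x 20 similarity matrix; default [pam30_matrix()].
#' @return Non-negative scalar.
#' @export
variant_distance <- function(a, b, matrix = pam30_matrix()) {
  stopifnot(inherits(a, "Variant"), inherits(b, "Variant"))
  if (!identical(a$base, b$base)) {
    stop("variants have different base sequences")
  }
  pos <- sort(union(a$substitutions$position, b$substitutions$position))
  if (length(pos) == 0L) return(0)
  ca <- seq_chars(apply_variant(a))
  cb <- seq_chars(apply_variant(b))
  x <- ca[pos]; y <- cb[pos]
  sum((matrix[cbind(x, x)] + matrix[cbind(y, y)] - 2 * matrix[cbind(x, y)]) / 2)
}

#' Pairwise distance matrix of a variant set
#'
#' @param vs A `VariantSet`.
#' @param matrix Similarity matrix passed to [variant_distance()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
variant_distance_matrix <- function(vs, matrix = pam30_matrix()) {
  stopifnot(inherits(vs, "VariantSet"))
  n <- length(vs$variants)
  D <- base::matrix(0, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        D[i, j] <- D[j, i] <- variant_distance(vs$variants[[i]],
                                               vs$variants[[j]], matrix)
      }
    }
  }
  D
}

#' Agglomerative average-linkage clustering of variants
#'
#' Deterministic bottom-up clustering on the PAM30 distance matrix, cut at
#' `k` clusters. The distance between clusters is the mean over all cross
#' pairs; merge ties are broken by the smallest (cluster-id, cluster-id)
#' pair, where a cluster's id is its smallest member index. Output labels
#' are numbered 1..k in order of each cluster's smallest member.
#'
#' @param vs A `VariantSet`.
#' @param k Number of clusters, `1 <= k <= |variants|`; default 8.
#' @param linkage Linkage criterion; only `"average"` is implemented.
#' @param distance Optional precomputed distance matrix; default
#'   [variant_distance_matrix()] with PAM30.
#' @return Object of class `ClusterAssignment`: `variants`, `k`, `labels`,
#'   `distance`, `representatives` (filled by
#'   [select_representatives()], initially `NULL`).
#' @export
cluster_variants <- function(vs, k = 8, linkage = "average",
                             distance = NULL) {
  stopifnot(inherits(vs, "VariantSet"))
  linkage <- match.arg(linkage, "average")
  n <- length(vs$variants)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n) {
    stop(sprintf("k must be between 1 and %d", n))
  }
  if (is.null(distance)) distance <- variant_distance_matrix(vs)
  stopifnot(nrow(distance) == n, ncol(distance) == n)
  members <- as.list(seq_len(n))
  while (length(members) > k) {
    m <- length(members)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        d <- mean(distance[members[[i]], members[[j]]])
        id <- c(min(members[[i]][1L], members[[j]][1L]),
                max(members[[i]][1L], members[[j]][1L]))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (id[1L] < best$id[1L] ||
              (id[1L] == best$id[1L] && id[2L] < best$id[2L])))) {
          best <- list(i = i, j = j, d = d, id = id)
        }
      }
    }
    members[[best$i]] <- sort(c(members[[best$i]], members[[best$j]]))
    members[[best$j]] <- NULL
  }
  ord <- order(vapply(members, `[`, integer(1), 1L))
  members <- members[ord]
  labels <- integer(n)
  for (c in seq_along(members)) labels[members[[c]]] <- c
  structure(list(variants = vs$variants, base = vs$base, k = as.integer(k),
                 labels = labels, distance = distance,
                 representatives = NULL),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d variants in %d clusters\n",
              length(x$variants), x$k))
  invisible(x)
}

#' Lowest-scored representative of each cluster
#'
#' Within each cluster, the variant with the minimal score (lower = better);
#' ties go to the lexicographically smallest canonical name. Exactly `k`
#' representatives are returned.
#'
#' @param ca A [cluster_variants()] result.
#' @return List of `k` `Variant`s, in cluster-label order.
#' @export
select_representatives <- function(ca) {
  stopifnot(inherits(ca, "ClusterAssignment"))
  lapply(seq_len(ca$k), function(c) {
    idx <- which(ca$labels == c)
    sc <- vapply(ca$variants[idx], `[[`, numeric(1), "score")
    sc[is.na(sc)] <- 0
    nm <- vapply(ca$variants[idx], `[[`, character(1), "name")
    best <- idx[order(sc, nm)][1L]
    ca$variants[[best]]
  })
}

#' Write a variant report as TSV
#'
#' One row per candidate: canonical name, net substitutions, provenance,
#' burial class, pocket flag, score, cluster label and representative flag.
#'
#' @param vs A `VariantSet`.
#' @param ca Optional matching [cluster_variants()] result.
#' @param path Output path.
#' @return The report data.frame, invisibly.
#' @export
write_variant_report <- function(vs, ca = NULL, path) {
  stopifnot(inherits(vs, "VariantSet"))
  df <- vs$table
  if (!is.null(ca)) {
    df$cluster <- ca$labels
    reps <- select_representatives(ca)
    rep_names <- vapply(reps, `[[`, character(1), "name")
    df$representative <- df$name %in% rep_names
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
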