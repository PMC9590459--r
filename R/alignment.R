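#' Construct a multiple sequence alignment object
#'
#' An `Alignment` holds `N` aligned rows of identical length `L` over the
#' 21-letter alphabet (20 residues plus the gap `-`). Characters outside the
#' alphabet are mapped to the gap during normalization.
#'
#' @param ids Character vector of sequence identifiers.
#' @param rows Character vector of aligned sequences (same length as `ids`).
#' @return An object of class `Alignment` with fields `ids`, `rows`, `L`, `N`
#'   and an integer state matrix `states` (`N x L`, gap = 21).
#' @export
alignment <- function(ids, rows) {
  if (length(rows) == 0L) stop("empty alignment: no rows")
  if (length(ids) != length(rows)) stop("ids and rows differ in length")
  rows <- vapply(rows, normalize_row, character(1), USE.NAMES = FALSE)
  lens <- nchar(rows)
  if (any(lens != lens[1L])) {
    stop(sprintf("alignment rows have unequal lengths (%s)",
                 paste(unique(lens), collapse = ", ")))
  }
  if (lens[1L] < 1L) stop("empty alignment: zero columns")
  states <- t(vapply(rows, function(r) aa_index(seq_chars(r)),
                     integer(lens[1L])))
  dimnames(states) <- NULL
  structure(list(ids = as.character(ids), rows = rows,
                 L = lens[1L], N = length(rows), states = states),
            class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns\n", x$N, x$L))
  invisible(x)
}

#' Read a multiple sequence alignment from file
#'
#' Supports FASTA, A3M (lowercase characters are insert states relative to the
#' master sequence and are removed, so all rows share the master length) and
#' Stockholm (`# ` annotation lines ignored, `//` terminates). After
#' normalization all characters outside the 21-letter alphabet become gaps.
#'
#' @param path Path to the alignment file.
#' @param format One of `"fasta"`, `"a3m"`, `"stockholm"`.
#' @return An [alignment()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "a3m", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  switch(format,
         fasta = read_fasta_aln(path, strip_inserts = FALSE),
         a3m = read_fasta_aln(path, strip_inserts = TRUE),
         stockholm = read_stockholm_aln(path))
}

read_fasta_aln <- function(path, strip_inserts) {
  if (strip_inserts) {
    # Biostrings rejects ragged rows, so parse A3M by hand.
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty alignment file: ", path)
    hdr <- grepl("^>", lines)
    if (!hdr[1L]) stop("not FASTA/A3M: first line is not a header")
    ids <- sub("^>\\s*", "", lines[hdr])
    ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
    grp <- cumsum(hdr)
    rows <- vapply(split(lines[!hdr], grp[!hdr]),
                   paste, character(1), collapse = "")
    rows <- gsub("[a-z.]", "", rows)  # drop insert states
    alignment(ids, rows)
  } else {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("FASTA parse error: ",
                                             conditionMessage(e)))
    if (length(set) == 0L) stop("empty alignment file: ", path)
    ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
    alignment(ids, as.character(set))
  }
}

read_stockholm_aln <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^#", lines) & !grepl("^//", lines)]
  lines <- lines[!grepl("^# STOCKHOLM", lines)]
  if (length(lines) == 0L) stop("empty alignment file: ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("Stockholm parse error near: ", lines[which(bad)[1L]])
  ids <- vapply(parts, `[`, character(1), 1L)
  seqs <- vapply(parts, `[`, character(1), 2L)
  # Interleaved blocks: concatenate rows sharing an id, preserving first-seen order.
  uid <- unique(ids)
  rows <- vapply(uid, function(i) paste(seqs[ids == i], collapse = ""),
                 character(1))
  alignment(uid, rows)
}

#' Write an alignment as FASTA
#'
#' @param aln An [alignment()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "Alignment"))
  writeLines(as.vector(rbind(paste0(">", aln$ids), aln$rows)), path)
  invisible(path)
}

#' Redundancy-based sequence weights
#'
#' The weight of a row is the reciprocal of the number of rows (itself
#' included) whose fractional identity to it is at least
#' `identity_threshold`. Identity of row *t* to row *s* is counted over the
#' non-gap columns of *s*. `neff`, the effective sequence count, is the sum
#' of the weights.
#'
#' @param aln An [alignment()] object.
#' @param identity_threshold Fraction in (0, 1]; default 0.8, the usual
#'   co-evolution convention.
#' @return An object of class `SequenceWeights`: list with `weights` (one per
#'   row) and `neff`.
#' @export
compute_weights <- function(aln, identity_threshold = 0.8) {
  stopifnot(inherits(aln, "Alignment"))
  if (!is.numeric(identity_threshold) || length(identity_threshold) != 1L ||
      identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be a single number in (0, 1]")
  }
  st <- aln$states
  N <- aln$N
  nongap <- st != 21L
  n_nongap <- rowSums(nongap)
  counts <- integer(N)
  for (s in seq_len(N)) {
    cols <- nongap[s, ]
    if (!any(cols)) { counts[s] <- N; next }  # all-gap row matches everything trivially
    eq <- st[, cols, drop = FALSE] ==
      matrix(st[s, cols], nrow = N, ncol = sum(cols), byrow = TRUE)
    counts[s] <- sum(rowSums(eq) / sum(cols) >= identity_threshold)
  }
  w <- 1 / counts
  structure(list(weights = w, neff = sum(w)), class = "SequenceWeights")
}

#' @export
print.SequenceWeights <- function(x, ...) {
  cat(sprintf("SequenceWeights: N = %d, neff = %.2f\n",
              length(x$weights), x$neff))
  invisible(x)
}
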