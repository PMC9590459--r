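# Variant nomenclature and composition. A variant is a set of substitutions
# against a base sequence, written in the field's hyphenated form
# ("L48F-S49A-..."); alias prefixes ("V1-K352I") compose on a named base
# variant with replacement semantics: a later substitution at an
# already-mutated position replaces it, and the net from-residue is always
# taken from the original base.

SUB_TOKEN_RE <- "^([A-Z])([0-9]+)([A-Z])$"

parse_sub_token <- function(tok) {
  m <- regmatches(tok, regexec(SUB_TOKEN_RE, tok))[[1]]
  if (length(m) == 0L) return(NULL)
  list(from = m[2], position = as.integer(m[3]), to = m[4])
}

sub_string <- function(subs) {
  if (nrow(subs) == 0L) return("")
  subs <- subs[order(subs$position), , drop = FALSE]
  paste(sprintf("%s%d%s", subs$from, subs$position, subs$to), collapse = "-")
}

new_variant <- function(base, subs, display_name = NULL,
                        provenance = character(0), score = NA_real_) {
  subs <- subs[order(subs$position), , drop = FALSE]
  rownames(subs) <- NULL
  name <- sub_string(subs)
  structure(list(name = name,
                 display_name = if (is.null(display_name)) name else display_name,
                 base = base, substitutions = subs,
                 provenance = provenance, score = score),
            class = "Variant")
}

#' @export
print.Variant <- function(x, ...) {
  cat(sprintf("Variant %s (%d substitutions%s)\n",
              if (nzchar(x$display_name)) x$display_name else "<wild type>",
              nrow(x$substitutions),
              if (is.na(x$score)) "" else sprintf(", score %.3f", x$score)))
  invisible(x)
}

#' Parse a hyphenated variant name
#'
#' Accepts substitution tokens like `L48F` and optional alias prefixes
#' resolvable through `aliases` (e.g. `"V1-K352I"` where `V1` names another
#' variant string). Tokens are applied left to right: each `from` residue
#' must match the current sequence at that position, so a token at an
#' already-mutated position replaces the earlier substitution and the net
#' change keeps the original base residue as `from` (composing `K352I` onto
#' a base carrying `T352K` yields a net `T352I`).
#'
#' @param name Variant name string, tokens joined by `-`. The empty string
#'   denotes the unchanged base.
#' @param base Base (wild-type) sequence, string or character vector.
#' @param aliases Named character vector or list mapping alias names to
#'   variant name strings (themselves parsed against `base`).
#' @return A `Variant`: canonical `name` (net substitutions sorted by
#'   position), `display_name` (as given), `base`, `substitutions`
#'   data.frame (`position`, `from`, `to`).
#' @export
parse_variant_name <- function(name, base, aliases = NULL) {
  base_chars <- if (length(base) == 1L) seq_chars(base) else base
  cur <- base_chars
  toks <- if (nzchar(name)) strsplit(name, "-", fixed = TRUE)[[1]] else character(0)
  for (tok in toks) {
    sub <- parse_sub_token(tok)
    if (is.null(sub)) {
      if (!is.null(aliases) && tok %in% names(aliases)) {
        av <- parse_variant_name(as.character(aliases[[tok]]), base_chars,
                                 aliases = aliases)
        cur2 <- seq_chars(apply_variant(av, cur_base_override = cur))
        cur <- cur2
        next
      }
      stop(sprintf("unknown token '%s': not a substitution and no alias defined",
                   tok))
    }
    if (sub$from == sub$to) {
      stop(sprintf("invalid substitution '%s': from and to residues are equal",
                   tok))
    }
    if (!(sub$from %in% AA20) || !(sub$to %in% AA20)) {
      stop(sprintf("invalid substitution '%s': residues must be amino acids",
                   tok))
    }
    if (sub$position < 1L || sub$position > length(cur)) {
      stop(sprintf("substitution '%s' outside sequence of length %d",
                   tok, length(cur)))
    }
    if (cur[sub$position] != sub$from) {
      stop(sprintf(
        "substitution '%s' conflicts with residue '%s' at position %d",
        tok, cur[sub$position], sub$position))
    }
    cur[sub$position] <- sub$to
  }
  new_variant(paste(base_chars, collapse = ""),
              diff_sequences(base_chars, cur), display_name = name)
}

# Apply an alias variant's substitutions to an arbitrary current sequence
# (used during left-to-right composition). Checks from-residues against the
# sequence the alias was parsed on, not the running sequence, because an
# alias is a completed variant of the base.
apply_variant_chars <- function(v, chars) {
  s <- v$substitutions
  for (r in seq_len(nrow(s))) chars[s$position[r]] <- s$to[r]
  chars
}

#' Apply a variant to its base sequence
#'
#' @param v A `Variant`.
#' @param base Optional base sequence; defaults to the one stored in `v`
#'   (must equal it at every substituted position).
#' @param cur_base_override Internal; applies the substitutions onto an
#'   arbitrary character vector without from-residue checks.
#' @return The mutated sequence as a single string.
#' @export
apply_variant <- function(v, base = NULL, cur_base_override = NULL) {
  stopifnot(inherits(v, "Variant"))
  if (!is.null(cur_base_override)) {
    return(paste(apply_variant_chars(v, cur_base_override), collapse = ""))
  }
  chars <- seq_chars(if (is.null(base)) v$base else
    if (length(base) == 1L) base else paste(base, collapse = ""))
  s <- v$substitutions
  for (r in seq_len(nrow(s))) {
    if (chars[s$position[r]] != s$from[r]) {
      stop(sprintf("base residue '%s' at %d does not match variant's '%s'",
                   chars[s$position[r]], s$position[r], s$from[r]))
    }
  }
  paste(apply_variant_chars(v, chars), collapse = "")
}

#' Substitution set between two equal-length sequences
#'
#' @param base,mutated Sequences (strings or character vectors).
#' @return data.frame `position`, `from`, `to`, sorted by position.
#' @export
diff_sequences <- function(base, mutated) {
  b <- if (length(base) == 1L) seq_chars(base) else base
  m <- if (length(mutated) == 1L) seq_chars(mutated) else mutated
  if (length(b) != length(m)) stop("sequences differ in length")
  d <- which(b != m)
  data.frame(position = d, from = b[d], to = m[d])
}

#' Add beneficial substitutions to a variant
#'
#' Composes further substitutions (validated against the sequence the
#' variant produces) and returns the combined variant. The display name is
#' the variant's display name with the new tokens appended; the canonical
#' name is the net substitution set against the original base, with
#' replacement semantics at already-mutated positions.
#'
#' @param base_variant A `Variant`.
#' @param beneficial Character vector of substitution tokens (e.g.
#'   `c("C343Y")`) or a data.frame with `position`, `from`, `to`.
#' @return The combined `Variant`.
#' @export
combine_substitutions <- function(base_variant, beneficial) {
  stopifnot(inherits(base_variant, "Variant"))
  toks <- if (is.data.frame(beneficial)) {
    sprintf("%s%d%s", beneficial$from, beneficial$position, beneficial$to)
  } else as.character(beneficial)
  if (length(toks) == 0L) return(base_variant)
  cur <- seq_chars(apply_variant(base_variant))
  for (tok in toks) {
    sub <- parse_sub_token(tok)
    if (is.null(sub)) stop("invalid substitution token: ", tok)
    if (sub$from == sub$to) stop("invalid substitution (from = to): ", tok)
    if (cur[sub$position] != sub$from) {
      stop(sprintf(
        "substitution '%s' conflicts with residue '%s' at position %d",
        tok, cur[sub$position], sub$position))
    }
    cur[sub$position] <- sub$to
  }
  new_variant(base_variant$base, diff_sequences(seq_chars(base_variant$base), cur),
              display_name = paste(c(base_variant$display_name, toks),
                                   collapse = "-"),
              provenance = base_variant$provenance)
}
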