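#' Tokenize a repetitive domain into repeat motifs
#'
#' Greedy left-to-right scan using the field's convention for these
#' repeats: most motifs begin with a proline and end with several
#' glutamines, so a token runs from its start through the last residue of
#' the next maximal glutamine run (run length >= 1; a single terminal Q is
#' allowed but such short-run variants are flagged). Tokens not beginning
#' with P are flagged as variants (typically single-substitution
#' derivatives such as P->S/T/L); leading residues before any motif form a
#' variant prefix token. Concatenating the tokens always reproduces the
#' input exactly.
#'
#' @param domain Repetitive-domain residue string (or protein `prl_seq`).
#' @param motif_sets Optional class template (the `motif_sets` of a
#'   [prolamin_grammar()]); when given, `canonical` means an exact template
#'   match rather than just beginning with P.
#' @return List of `prl_motif_token`: `residues`, `start` (0-based offset
#'   in the domain), `canonical`, `variant_of` (template string or NA).
#' @examples
#' toks <- tokenize_repeats("PLPQQPFPQQ")
#' vapply(toks, function(t) t$residues, "")
#' @export
tokenize_repeats <- function(domain, motif_sets = NULL) {
  if (is_seq(domain)) domain <- domain$residues
  if (!is.character(domain) || !nzchar(domain)) {
    stop("empty repeat domain", call. = FALSE)
  }
  chars <- strsplit(domain, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  template_rx <- if (!is.null(motif_sets)) motif_template_regex(motif_sets)
  tokens <- list()
  s <- 1L
  while (s <= n) {
    q <- which(chars[s:n] == "Q")
    if (!length(q)) {
      e <- n
    } else {
      qstart <- s + q[1L] - 1L
      e <- qstart
      while (e < n && chars[e + 1L] == "Q") e <- e + 1L
    }
    res <- paste(chars[s:e], collapse = "")
    canonical <- if (is.null(template_rx)) {
      startsWith(res, "P")
    } else {
      grepl(template_rx, res)
    }
    variant_of <- NA_character_
    if (!canonical && !is.null(motif_sets)) {
      variant_of <- nearest_template(res, motif_sets)
    } else if (!canonical && startsWith(res, "P")) {
      variant_of <- "P-initial, non-template"
    }
    tokens[[length(tokens) + 1L]] <- structure(
      list(
        residues = res, start = s - 1L, canonical = canonical,
        variant_of = variant_of
      ),
      class = "prl_motif_token"
    )
    s <- e + 1L
  }
  tokens
}

motif_template_regex <- function(motif_sets) {
  parts <- vapply(motif_sets, function(set) {
    if (length(set) == 1L && nchar(set) == 1L) {
      set
    } else if (all(nchar(set) == 1L)) {
      paste0("[", paste(set, collapse = ""), "]")
    } else {
      # a set of Q-run alternatives like QQ/QQQ
      lens <- sort(nchar(set))
      sprintf("Q{%d,%d}", lens[1L], lens[length(lens)])
    }
  }, "")
  paste0("^", paste(parts, collapse = ""), "$")
}

# closest exact template form within one substitution (equal length), or NA
nearest_template <- function(res, motif_sets) {
  forms <- Reduce(
    function(acc, set) {
      unlist(lapply(acc, function(a) paste0(a, set)))
    },
    motif_sets,
    accumulate = FALSE, init = ""
  )
  rc <- strsplit(res, "", fixed = TRUE)[[1L]]
  for (f in forms) {
    if (nchar(f) != length(rc)) next
    fc <- strsplit(f, "", fixed = TRUE)[[1L]]
    if (sum(fc != rc) <= 1L) {
      return(f)
    }
  }
  NA_character_
}

token_strings <- function(tokens) vapply(tokens, function(t) t$residues, "")

#' Summarize a motif list into a class signature
#'
#' Splits each token into its non-Q prefix and terminal glutamine run,
#' takes the modal prefix length, and reports the residue set observed at
#' each prefix position together with the observed Q-run length range --
#' e.g. P-[LF]-P-Q{2-3} for delta-gliadin/gamma-3 hordein repeats.
#'
#' @param tokens List from [tokenize_repeats()] (>= 3 tokens).
#' @return List: `position_sets` (list of character vectors),
#'   `q_range` (c(min, max)), `pattern` (display string).
#' @export
motif_signature <- function(tokens) {
  if (length(tokens) < 3L) {
    stop("need at least 3 tokens for a signature", call. = FALSE)
  }
  res <- token_strings(tokens)
  qlen <- nchar(sub("^.*?(Q*)$", "\\1", res))
  prefix <- substr(res, 1L, nchar(res) - qlen)
  use <- qlen >= 1L
  if (!any(use)) stop("no Q-terminated tokens", call. = FALSE)
  plen <- nchar(prefix[use])
  modal <- as.integer(names(which.max(table(plen))))
  sel <- use & nchar(prefix) == modal
  mat <- do.call(rbind, strsplit(prefix[sel], "", fixed = TRUE))
  position_sets <- lapply(seq_len(modal), function(j) sort(unique(mat[, j])))
  q_range <- range(qlen[sel])
  pattern <- paste0(
    paste(vapply(position_sets, function(s) {
      if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
    }, ""), collapse = "-"),
    sprintf("-Q{%d-%d}", q_range[1L], q_range[2L])
  )
  list(position_sets = position_sets, q_range = q_range, pattern = pattern)
}

tokens_match <- function(a, b, max_mismatch) {
  if (nchar(a) != nchar(b)) {
    return(FALSE)
  }
  if (a == b) {
    return(TRUE)
  }
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(ac != bc) <= max_mismatch
}

#' Align two motif lists (conserved vs missing repeats)
#'
#' Longest order-preserving matching between two token lists, where two
#' tokens match if they have equal length and differ in at most
#' `max_mismatch` residues (default 1: the single-substitution variants
#' seen between orthologous repeat domains). Unmatched indices on either
#' side are the repeat differences (motifs missing from the other domain).
#'
#' @param a,b Token lists from [tokenize_repeats()].
#' @param max_mismatch Residue differences tolerated within a matched pair.
#' @return A `prl_motif_alignment`: `pairs` (2-column matrix of 1-based
#'   indices into a and b), `unmatched_a`, `unmatched_b`, `conservation`
#'   (pairs / max(|a|, |b|)).
#' @export
align_motif_lists <- function(a, b, max_mismatch = 1L) {
  if (!length(a) || !length(b)) stop("empty token list", call. = FALSE)
  sa <- token_strings(a)
  sb <- token_strings(b)
  n <- length(sa)
  m <- length(sb)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      L[i + 1L, j + 1L] <- if (tokens_match(sa[i], sb[j], max_mismatch)) {
        L[i, j] + 1L
      } else {
        max(L[i, j + 1L], L[i + 1L, j])
      }
    }
  }
  # symmetric traceback: ties between dropping a[i] and b[j] resolve by
  # string order, so swapping the inputs transposes the result exactly
  pairs <- NULL
  i <- n
  j <- m
  while (i > 0L && j > 0L) {
    if (tokens_match(sa[i], sb[j], max_mismatch) &&
      L[i + 1L, j + 1L] == L[i, j] + 1L) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1L
      j <- j - 1L
    } else if (L[i, j + 1L] > L[i + 1L, j]) {
      i <- i - 1L
    } else if (L[i, j + 1L] < L[i + 1L, j]) {
      j <- j - 1L
    } else if (sa[i] > sb[j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  matched_a <- if (is.null(pairs)) integer(0) else pairs[, 1L]
  matched_b <- if (is.null(pairs)) integer(0) else pairs[, 2L]
  structure(
    list(
      pairs = if (is.null(pairs)) {
        matrix(integer(0), 0L, 2L,
          dimnames = list(NULL, c("a", "b"))
        )
      } else {
        `dimnames<-`(pairs, list(NULL, c("a", "b")))
      },
      unmatched_a = setdiff(seq_len(n), matched_a),
      unmatched_b = setdiff(seq_len(m), matched_b),
      conservation = nrow(if (is.null(pairs)) matrix(0, 0, 2) else pairs) /
        max(n, m)
    ),
    class = "prl_motif_alignment"
  )
}

#' Cysteines inside a repeat domain
#'
#' Some repetitive domains carry cysteines (seen in gamma-gliadins,
#' 75S gamma-secalins and gamma-hordeins); the delta-gliadin repeats carry
#' none. Positions agree with a plain scan of the concatenated domain.
#'
#' @param tokens List from [tokenize_repeats()].
#' @return Integer vector of 0-based C positions within the domain.
#' @export
find_repeat_cysteines <- function(tokens) {
  unlist(lapply(tokens, function(t) {
    hit <- which(strsplit(t$residues, "", fixed = TRUE)[[1L]] == "C")
    if (length(hit)) t$start + hit - 1L else integer(0)
  }))
}
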