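#' Build a prolamin class panel
#'
#' A panel holds one or more representative sequences per class plus the
#' assignment thresholds. Assignment-by-identity replaces the original
#' screen's co-assembly check: a query belongs to a class only if it aligns
#' to that class well and to no other class nearly as well.
#'
#' @param entries Named list mapping class name to a `prl_seq` or a list of
#'   `prl_seq` representatives. At least two distinct classes.
#' @param min_identity Identity floor for classification (default 0.85 for
#'   DNA panels).
#' @param min_overlap Minimum aligned query bases (default 60).
#' @param margin Minimum identity gap between best and second-best class.
#' @return A `prl_panel`.
#' @export
class_panel <- function(entries, min_identity = 0.85, min_overlap = 60L,
                        margin = 0.05) {
  if (length(entries) < 2L || is.null(names(entries)) ||
    any(!nzchar(names(entries)))) {
    stop("panel needs >= 2 named classes", call. = FALSE)
  }
  entries <- lapply(entries, function(e) if (is_seq(e)) list(e) else e)
  kinds <- unique(unlist(lapply(entries, function(cl) {
    vapply(cl, function(s) s$kind, "")
  })))
  if (length(kinds) != 1L) {
    stop("panel representatives mix alphabets", call. = FALSE)
  }
  structure(
    list(
      entries = entries, kind = kinds, min_identity = min_identity,
      min_overlap = as.integer(min_overlap), margin = margin
    ),
    class = "prl_panel"
  )
}

#' Assign one query to a prolamin class
#'
#' Locally aligns the query against every panel representative; the
#' per-class score is the best identity achieved over at least
#' `min_overlap` aligned query bases. The query is labelled with the best
#' class only if its identity reaches `min_identity` and beats the
#' second-best class by at least `margin`; otherwise it is
#' `"unclassified"` (below the floor, or ambiguous between classes).
#'
#' @param query A `prl_seq` matching the panel alphabet.
#' @param panel A [class_panel()].
#' @return A `prl_class_assignment`: `query`, `label`, `best_identity`,
#'   `best_overlap`, `second_identity`, `scores` (per-class identity).
#' @export
assign_class <- function(query, panel) {
  stopifnot(inherits(panel, "prl_panel"))
  if (!length(panel$entries)) stop("empty panel", call. = FALSE)
  if (query$kind != panel$kind) {
    stop("query kind does not match panel", call. = FALSE)
  }
  classes <- sort(names(panel$entries))
  scores <- stats::setNames(rep(NA_real_, length(classes)), classes)
  overlaps <- stats::setNames(rep(0L, length(classes)), classes)
  for (cls in classes) {
    for (rep_seq in panel$entries[[cls]]) {
      al <- align_local(query, rep_seq)
      if (al$score <= 0) next
      ov <- al$matches + al$mismatches
      if (ov < panel$min_overlap) next
      if (is.na(scores[cls]) || al$identity > scores[cls]) {
        scores[cls] <- al$identity
        overlaps[cls] <- ov
      }
    }
  }
  ranked <- order(-ifelse(is.na(scores), -Inf, scores), classes)
  best <- ranked[1L]
  second <- if (length(ranked) > 1L) scores[ranked[2L]] else NA_real_
  label <- "unclassified"
  if (!is.na(scores[best]) &&
    scores[best] >= panel$min_identity &&
    overlaps[best] >= panel$min_overlap &&
    (is.na(second) || scores[best] - second >= panel$margin)) {
    label <- classes[best]
  }
  structure(
    list(
      query = query$id, label = label,
      best_identity = unname(scores[best]),
      best_overlap = unname(overlaps[best]),
      second_identity = unname(second),
      scores = scores
    ),
    class = "prl_class_assignment"
  )
}

#' Screen a collection of queries against a class panel
#'
#' @param queries List of `prl_seq`.
#' @param panel A [class_panel()].
#' @return List with `assignments` (data frame: query, label,
#'   best_identity, best_overlap, second_identity) and `counts` (named
#'   vector per class plus `unclassified`; sums to the query count).
#' @export
screen <- function(queries, panel) {
  rows <- lapply(queries, function(q) {
    a <- assign_class(q, panel)
    data.frame(
      query = a$query, label = a$label,
      best_identity = a$best_identity, best_overlap = a$best_overlap,
      second_identity = a$second_identity, stringsAsFactors = FALSE
    )
  })
  assignments <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      query = character(0), label = character(0),
      best_identity = numeric(0), best_overlap = integer(0),
      second_identity = numeric(0)
    )
  }
  levels <- c(sort(names(panel$entries)), "unclassified")
  counts <- table(factor(assignments$label, levels = levels))
  list(assignments = assignments, counts = c(counts))
}
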