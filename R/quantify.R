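#' Estimate gene copy number from matching read counts
#'
#' With N matching reads of mean length R bases over a target of L bases
#' at c-fold genome coverage, one gene copy is expected to attract
#' `c * L / R` reads (or `c * (L + R) / R` with the Lander-Waterman edge
#' correction, counting reads that merely overlap the target). The copy
#' total is `N / reads_per_copy` and is split evenly across the `G`
#' genomes of a polyploid. The uncorrected form is the default: it is the
#' crude estimate the screening arithmetic uses.
#'
#' @param n_reads Matching read count N.
#' @param mean_read_len Mean matching read length R, bases.
#' @param target_len Target span L (coding region plus immediate flanks).
#' @param coverage Genome coverage c, fold.
#' @param n_genomes Genome count G (3 for hexaploid wheat, 1 for a
#'   diploid).
#' @param edge_corrected Use the (L + R) form.
#' @return A `prl_copy_estimate`: inputs plus `reads_per_copy`,
#'   `copies_total`, `copies_per_genome`.
#' @examples
#' estimate_copy_number(69, 400, 1000, 5, 3)$copies_per_genome # 1.84
#' @export
estimate_copy_number <- function(n_reads, mean_read_len, target_len,
                                 coverage, n_genomes = 1L,
                                 edge_corrected = FALSE) {
  vals <- c(n_reads, mean_read_len, target_len, coverage, n_genomes)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all parameters must be positive", call. = FALSE)
  }
  span <- if (edge_corrected) target_len + mean_read_len else target_len
  reads_per_copy <- coverage * span / mean_read_len
  copies_total <- n_reads / reads_per_copy
  structure(
    list(
      n_reads = n_reads, mean_read_len = mean_read_len,
      target_len = target_len, coverage = coverage, n_genomes = n_genomes,
      edge_corrected = edge_corrected,
      reads_per_copy = reads_per_copy,
      copies_total = copies_total,
      copies_per_genome = copies_total / n_genomes
    ),
    class = "prl_copy_estimate"
  )
}

#' @export
print.prl_copy_estimate <- function(x, ...) {
  cat(sprintf(
    "<copy estimate> N=%g reads / %.2f reads per copy = %.2f copies (%.2f per genome over %d genome%s)%s\n",
    x$n_reads, x$reads_per_copy, x$copies_total, x$copies_per_genome,
    x$n_genomes, if (x$n_genomes > 1) "s" else "",
    if (x$edge_corrected) " [edge-corrected]" else ""
  ))
  invisible(x)
}

#' Count ESTs per gene consensus
#'
#' Each EST is assigned to the gene consensus it matches best by local
#' alignment identity, provided that identity reaches `min_identity` and
#' leads the second-best gene by at least `margin`; otherwise the EST is
#' ambiguous and excluded from the counts (but reported).
#'
#' @param ests List of DNA `prl_seq` (or `prl_est`).
#' @param genes Named list of DNA `prl_seq` consensi (>= 2).
#' @param min_identity Identity floor.
#' @param margin Required lead over the runner-up (default 0.01:
#'   orthologous gene copies differ by only ~2%, so the margin that
#'   separates them is necessarily small).
#' @param min_overlap Minimum aligned EST bases.
#' @return List: `counts` (named integer, one per gene), `ambiguous`
#'   (EST ids), `assignments` (data frame).
#' @export
count_ests <- function(ests, genes, min_identity = 0.85, margin = 0.01,
                       min_overlap = 60L) {
  if (length(genes) < 2L || is.null(names(genes))) {
    stop("need >= 2 named gene consensi", call. = FALSE)
  }
  panel <- class_panel(genes,
    min_identity = min_identity,
    min_overlap = min_overlap, margin = margin
  )
  seqs <- lapply(ests, function(e) if (inherits(e, "prl_est")) e$seq else e)
  sc <- screen(seqs, panel)
  labs <- names(genes)
  counts <- stats::setNames(integer(length(labs)), labs)
  tab <- table(factor(sc$assignments$label, levels = labs))
  counts[labs] <- as.integer(tab)
  list(
    counts = counts,
    ambiguous = sc$assignments$query[sc$assignments$label == "unclassified"],
    assignments = sc$assignments
  )
}

#' Upper tail of the chi-square distribution
#'
#' Survival function P(X >= x) for X ~ chi-square(df). For df = 2 this is
#' exactly exp(-x/2).
#'
#' @param x Statistic (>= 0).
#' @param df Degrees of freedom (integer >= 1).
#' @return Probability in [0, 1].
#' @export
chi2_upper_tail <- function(x, df) {
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  df <- as.integer(df)
  if (any(df < 1L)) stop("df must be >= 1", call. = FALSE)
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Chi-square goodness-of-fit test on EST counts
#'
#' Tests an observed count vector against expected proportions (uniform by
#' default: equal expression across genomes), with
#' `chi2 = sum((O - E)^2 / E)`, `df = k - 1`, and an upper-tail p-value.
#' Expected cells below 1 trigger a warning but the statistic is still
#' computed.
#'
#' @param observed Non-negative count vector (>= 2 categories, total > 0).
#' @param expected_proportions Optional proportions (normalized if needed).
#' @return A `prl_gof`: `chi2`, `df`, `p`, `observed`, `expected`.
#' @examples
#' gof_chisq(c(9, 4, 18))$p # ~0.0077
#' @export
gof_chisq <- function(observed, expected_proportions = NULL) {
  observed <- as.numeric(observed)
  k <- length(observed)
  if (k < 2L) stop("need >= 2 categories", call. = FALSE)
  if (any(observed < 0) || sum(observed) <= 0) {
    stop("observed must be non-negative with positive total", call. = FALSE)
  }
  props <- if (is.null(expected_proportions)) {
    rep(1 / k, k)
  } else {
    expected_proportions / sum(expected_proportions)
  }
  if (length(props) != k) stop("proportion length mismatch", call. = FALSE)
  expected <- sum(observed) * props
  if (any(expected < 1)) {
    warning("expected cell count below 1; chi-square approximation is weak")
  }
  chi2 <- sum((observed - expected)^2 / expected)
  df <- k - 1L
  structure(
    list(
      chi2 = chi2, df = df, p = chi2_upper_tail(chi2, df),
      observed = observed, expected = expected
    ),
    class = "prl_gof"
  )
}

#' @export
print.prl_gof <- function(x, ...) {
  cat(sprintf(
    "<goodness of fit> chi2 = %.3f, df = %d, p = %.4g\n", x$chi2, x$df, x$p
  ))
  invisible(x)
}
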