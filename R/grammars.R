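#' Prolamin class grammars
#'
#' A grammar is the structural recipe for one prolamin class: signal peptide
#' length, length ranges for the non-repetitive domains (I, III, IV, V), the
#' repeat motif template for domain II, the allowed motif count range, and
#' the cysteine layout (counts in domains III and V).
#'
#' Motif templates follow the field's shorthand: the wheat delta-gliadins and
#' barley gamma-3 hordeins use P-L/F-P-Q(2-3); alpha-gliadins P-F/Y-P-Q(3-5);
#' LMW glutenins P-F-P/S-Q(2-5); the gamma-type prolamins (gamma-gliadins,
#' gamma-secalins, gamma-1/2 hordeins) a composite P-F-(P-Q1-2)-P-Q-Q; the
#' omega-gliadins are repeat-rich but cysteine-free.
#'
#' `motif_sets` is a list of per-position alternatives; each motif is built
#' by drawing one string from each position set and concatenating, so the
#' final element carries the glutamine run.
#'
#' @param class One of `"delta"`, `"gamma3"`, `"gamma"`, `"alpha"`,
#'   `"lmw"`, `"omega"`.
#' @return A `prl_grammar` list: `name`, `signal_len`, `domain_len_ranges`,
#'   `motif_sets`, `n_repeats_range`, `cys_layout` (c(III, V)).
#' @examples
#' g <- prolamin_grammar("delta")
#' sum(g$cys_layout) # 8 conserved cysteines
#' @export
prolamin_grammar <- function(class = c(
                               "delta", "gamma3", "gamma", "alpha",
                               "lmw", "omega"
                             )) {
  class <- match.arg(class)
  qs <- function(lo, hi) {
    vapply(lo:hi, function(k) paste(rep("Q", k), collapse = ""), "")
  }
  base <- list(
    signal_len = 19L,
    domain_len_ranges = list(
      I = c(9L, 14L), III = c(40L, 55L), IV = c(38L, 48L), V = c(34L, 44L)
    ),
    n_repeats_range = c(8L, 14L)
  )
  recipe <- switch(class,
    delta = list(
      motif_sets = list("P", c("L", "F"), "P", qs(2, 3)),
      cys_layout = c(III = 6L, V = 2L)
    ),
    gamma3 = list(
      motif_sets = list("P", c("L", "F"), "P", qs(2, 3)),
      cys_layout = c(III = 6L, V = 2L)
    ),
    gamma = list(
      motif_sets = list("P", "F", "P", qs(1, 2), "P", "Q", "Q"),
      cys_layout = c(III = 6L, V = 2L)
    ),
    alpha = list(
      motif_sets = list("P", c("F", "Y"), "P", qs(3, 5)),
      cys_layout = c(III = 4L, V = 2L)
    ),
    lmw = list(
      motif_sets = list("P", "F", c("P", "S"), qs(2, 5)),
      cys_layout = c(III = 6L, V = 2L)
    ),
    omega = list(
      motif_sets = list("P", c("F", "Q"), "P", qs(2, 4)),
      cys_layout = c(III = 0L, V = 0L)
    )
  )
  g <- c(list(name = class), base, recipe)
  stopifnot(g$signal_len > 0L, all(g$cys_layout >= 0L))
  if (class == "delta") stopifnot(sum(g$cys_layout) == 8L)
  structure(g, class = "prl_grammar")
}

#' @export
print.prl_grammar <- function(x, ...) {
  motif <- paste(vapply(x$motif_sets, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "-")
  cat(sprintf(
    "<grammar %s> SIG %d aa, motif %s, repeats %d-%d, cys III/V %d/%d\n",
    x$name, x$signal_len, motif, x$n_repeats_range[1], x$n_repeats_range[2],
    x$cys_layout[["III"]], x$cys_layout[["V"]]
  ))
  invisible(x)
}

## Residue pools for the non-repetitive domains. P is excluded outside the
## repeat domain and C appears only at the planted layout positions: this
## keeps domain boundaries identifiable (motif matches cannot leak across
## them) and the cysteine census exactly equal to the layout.
SIG_POOL <- c("A", "F", "I", "L", "S", "T", "V")
DOM1_POOL <- c("D", "E", "H", "M", "N", "R", "S", "T", "V", "W")
DOM3_POOL <- c(
  "A", "D", "E", "G", "H", "I", "K", "L", "M", "N", "R", "S", "T",
  "V", "W", "Y", "F", "Q"
)
DOM4_POOL <- c("E", "G", "I", "L", "S", "T", "V", "F")
DOM5_POOL <- c(
  "A", "D", "E", "G", "H", "I", "L", "M", "N", "S", "T", "V", "Y",
  "W", "F", "Q"
)

sample_motif <- function(motif_sets) {
  paste(vapply(motif_sets, function(s) {
    if (length(s) == 1L) s else sample(s, 1L)
  }, ""), collapse = "")
}
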