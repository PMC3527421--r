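## Diverge a functional ortholog under purifying selection: substitution
## draws that would create a premature stop are re-drawn (a expressed,
## functional copy cannot carry one). Deterministic for a fixed seed.
diverge_intact <- function(gene, rate, seed, id, genome = gene$genome) {
  for (k in 0:99) {
    d <- diverge(gene, rate, seed + k * 131L, id = id, genome = genome)
    if (d$status == "intact") {
      return(d)
    }
  }
  stop("could not draw an intact ortholog at rate ", rate, call. = FALSE)
}

#' Simulate the hexaploid delta-gliadin locus
#'
#' Three genome orthologs (A, B, D) at ~2% pairwise divergence descend
#' from one ancestral delta-gliadin; the A copy is inactivated by two
#' tandem in-frame premature stop codons, and a more diverged (~8%)
#' D-genome paralog is a pseudogene carrying one in-frame stop, a 1-bp
#' deletion and an 11-bp deletion (both frameshifts). Defect positions sit
#' in the non-repetitive domains so they are unambiguous under alignment.
#' Expression weights default to the Chinese Spring pattern: the
#' premature-stop A copy and the pseudogene are silent; B and D express at
#' 4:13.
#'
#' @param seed Integer seed.
#' @param ortholog_rate Per-base divergence of each ortholog from the
#'   ancestor (default 0.01, i.e. ~2% pairwise).
#' @param paralog_rate Divergence of the pseudogene paralog (default
#'   0.08).
#' @param n_repeats Repeat motifs in the ancestral domain II.
#' @param weights Expression weights for the B and D orthologs.
#' @return List: `genes` (deltaA, deltaB, deltaD, deltaD_psi), `ancestor`,
#'   `grammar`, `true_copies`.
#' @export
scenario_hexaploid <- function(seed = 1L, ortholog_rate = 0.01,
                               paralog_rate = 0.08, n_repeats = 10L,
                               weights = c(B = 4, D = 13)) {
  grammar <- prolamin_grammar("delta")
  anc <- build_gene(grammar, n_repeats, seed = seed, id = "delta_anc")
  dA <- diverge_intact(anc, ortholog_rate, seed + 11L, id = "deltaA", genome = "A")
  dB <- diverge_intact(anc, ortholog_rate, seed + 12L, id = "deltaB", genome = "B")
  dD <- diverge_intact(anc, ortholog_rate, seed + 13L, id = "deltaD", genome = "D")
  dB$expression_weight <- weights[["B"]]
  dD$expression_weight <- weights[["D"]]

  dA <- pseudogenize(dA, tandem_stop_defects(dA), seed = seed + 14L, id = "deltaA")
  psi <- diverge(anc, paralog_rate, seed + 15L, id = "deltaD_psi", genome = "D")
  psi <- pseudogenize(psi, pseudogene_defects(psi),
    seed = seed + 16L,
    id = "deltaD_psi"
  )
  list(
    genes = list(dA, dB, dD, psi), ancestor = anc, grammar = grammar,
    true_copies = 4L
  )
}

#' Simulate the diploid (D-genome ancestor) locus
#'
#' One intact delta-gliadin plus the shared frameshift pseudogene: the
#' two distinct sequences of the diploid screen.
#'
#' @inheritParams scenario_hexaploid
#' @return List: `genes` (deltaD_dip intact, deltaD_psi pseudogene),
#'   `ancestor`, `grammar`, `true_copies`.
#' @export
scenario_diploid <- function(seed = 1L, ortholog_rate = 0.01,
                             paralog_rate = 0.08, n_repeats = 10L) {
  grammar <- prolamin_grammar("delta")
  anc <- build_gene(grammar, n_repeats, seed = seed, id = "delta_anc")
  dD <- diverge_intact(anc, ortholog_rate, seed + 13L, id = "deltaD_dip", genome = "D")
  psi <- diverge(anc, paralog_rate, seed + 15L, id = "deltaD_psi", genome = "D")
  psi <- pseudogenize(psi, pseudogene_defects(psi),
    seed = seed + 16L,
    id = "deltaD_psi"
  )
  list(
    genes = list(dD, psi), ancestor = anc, grammar = grammar,
    true_copies = 2L
  )
}

# two tandem in-frame premature stops, early in domain III
tandem_stop_defects <- function(gene) {
  iii <- gene$domain_map["III", "start"]
  p <- 3L * (iii + 5L)
  list(
    defect("premature_stop", dna_position = p),
    defect("premature_stop", dna_position = p + 3L)
  )
}

# one in-frame stop (domain I), a 1-bp deletion (domain III) and an 11-bp
# deletion (domain V), the deletions placed away from glutamine runs
pseudogene_defects <- function(gene) {
  dm <- gene$domain_map
  list(
    defect("premature_stop", dna_position = 3L * (dm["I", "start"] + 4L)),
    defect("deletion", dna_position = 3L * (dm["III", "start"] + 12L) + 1L, length = 1L),
    defect("deletion", dna_position = 3L * (dm["V", "start"] + 8L), length = 11L)
  )
}

#' Simulate two cultivars with contrasting delta-gliadin expression
#'
#' Both cultivars carry the same three orthologs, but alleles differ: in
#' Chinese Spring the A copy carries the tandem stops (silent) and B:D
#' express at 4:13; in Recital all copies are structurally intact but B is
#' silent and A:D express at 9:5. EST totals default to the per-cultivar
#' identification counts (17 and 14).
#'
#' @param seed Integer seed.
#' @param n_ests Named vector of EST totals per cultivar.
#' @return List of two cultivar entries, each with `genes` and `ests`,
#'   plus `grammar`.
#' @export
scenario_expression <- function(seed = 1L,
                                n_ests = c(chinese_spring = 17L, recital = 14L)) {
  hex <- scenario_hexaploid(seed)
  cs_genes <- hex$genes[1:3] # deltaA (stops), deltaB w=4, deltaD w=13

  anc <- hex$ancestor
  rec_A <- diverge_intact(anc, 0.01, seed + 11L, id = "deltaA", genome = "A")
  rec_B <- diverge_intact(anc, 0.01, seed + 12L, id = "deltaB", genome = "B")
  rec_D <- diverge_intact(anc, 0.01, seed + 13L, id = "deltaD", genome = "D")
  rec_A$expression_weight <- 9
  rec_B$expression_weight <- 0 # silent or lowly expressed; undetermined
  rec_D$expression_weight <- 5

  list(
    chinese_spring = list(
      genes = cs_genes,
      ests = sample_ests(cs_genes, n_ests[["chinese_spring"]], seed = seed + 21L)
    ),
    recital = list(
      genes = list(rec_A, rec_B, rec_D),
      ests = sample_ests(list(rec_A, rec_B, rec_D), n_ests[["recital"]],
        seed = seed + 22L
      )
    ),
    grammar = hex$grammar
  )
}

#' Simulate a gamma-type prolamin family with a delta/gamma-3 stem
#'
#' Evolves one ancestral gamma-type gene along a fixed species/class tree:
#' a stem lineage splits into the delta-gliadin/gamma-3 hordein clade
#' before the wheat-barley speciation, a sister stem carries the
#' gamma-gliadins/hordeins/secalins, and a strongly diverged alpha-gliadin
#' serves as outgroup. Substitution-only evolution keeps all proteins
#' colinear, so the repeat-stripped sequences form an ungapped aligned
#' block with the ancestor's domain map.
#'
#' @param seed Integer seed.
#' @param stem_rate Divergence on each stem branch.
#' @param terminal_rate Divergence on each leaf branch.
#' @param outgroup_rate Divergence of the alpha outgroup.
#' @return List: `genes`, `groups` (`dg3`, `gamma`), `outgroup`,
#'   `domain_map`, `stripped` (list of repeat-stripped proteins).
#' @export
simulate_prolamin_family <- function(seed = 1L, stem_rate = 0.05,
                                     terminal_rate = 0.025,
                                     outgroup_rate = 0.18) {
  grammar <- prolamin_grammar("gamma")
  anc <- build_gene(grammar, 10L, seed = seed, id = "gamma_anc")
  stem_dg3 <- diverge(anc, stem_rate, seed + 31L, id = "stem_dg3")
  stem_g <- diverge(anc, stem_rate, seed + 32L, id = "stem_gamma")
  leaves <- list(
    diverge(stem_dg3, terminal_rate, seed + 41L, id = "delta_wheat1"),
    diverge(stem_dg3, terminal_rate, seed + 42L, id = "delta_wheat2"),
    diverge(stem_dg3, terminal_rate, seed + 43L, id = "gamma3_hordein"),
    diverge(stem_g, terminal_rate, seed + 44L, id = "gamma_gliadin"),
    diverge(stem_g, terminal_rate, seed + 45L, id = "gamma_hordein"),
    diverge(stem_g, terminal_rate, seed + 46L, id = "gamma_secalin"),
    diverge(anc, outgroup_rate, seed + 47L, id = "alpha_outgroup")
  )
  stripped <- lapply(leaves, function(g) {
    p <- seq_record(g$id, g$protein$residues, "protein")
    strip_repeats(p, anc$domain_map)
  })
  list(
    genes = leaves,
    groups = list(
      dg3 = c("delta_wheat1", "delta_wheat2", "gamma3_hordein"),
      gamma = c("gamma_gliadin", "gamma_hordein", "gamma_secalin")
    ),
    outgroup = "alpha_outgroup",
    domain_map = anc$domain_map,
    stripped = stripped
  )
}

#' Build a multi-class panel of representative sequences
#'
#' One grammar-built representative per prolamin class, as coding DNA (or
#' protein), for classification screens.
#'
#' @param classes Class names (see [prolamin_grammar()]).
#' @param seed Integer seed.
#' @param kind `"dna"` or `"protein"` representatives.
#' @return A [class_panel()].
#' @export
build_class_panel <- function(classes = c(
                                "delta", "gamma3", "gamma", "alpha",
                                "lmw", "omega"
                              ),
                              seed = 100L, kind = c("dna", "protein"), ...) {
  kind <- match.arg(kind)
  entries <- lapply(seq_along(classes), function(i) {
    g <- build_gene(prolamin_grammar(classes[i]), 10L,
      seed = seed + i,
      id = paste0(classes[i], "_rep")
    )
    if (kind == "dna") g$dna else g$protein
  })
  names(entries) <- classes
  class_panel(entries, ...)
}
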