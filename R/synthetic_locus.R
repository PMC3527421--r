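#' Describe an inactivating defect
#'
#' @param type `"premature_stop"`, `"deletion"` or `"insertion"`.
#' @param dna_position 0-based offset into the coding DNA. For a premature
#'   stop this is the first base of the codon that is overwritten with TAA.
#' @param length Bases inserted/deleted (ignored for stops).
#' @return A `prl_defect` list.
#' @export
defect <- function(type = c("premature_stop", "deletion", "insertion"),
                   dna_position, length = 1L) {
  type <- match.arg(type)
  dna_position <- as.integer(dna_position)
  length <- as.integer(length)
  if (dna_position < 0L) stop("defect position must be >= 0", call. = FALSE)
  if (type != "premature_stop" && length < 1L) {
    stop("indel length must be >= 1", call. = FALSE)
  }
  structure(
    list(type = type, dna_position = dna_position, length = length),
    class = "prl_defect"
  )
}

is_frameshift <- function(d) {
  d$type %in% c("deletion", "insertion") && d$length %% 3L != 0L
}

status_from_defects <- function(defects) {
  if (!length(defects)) {
    "intact"
  } else if (any(vapply(defects, is_frameshift, TRUE))) {
    "pseudogene"
  } else if (any(vapply(defects, function(d) d$type == "premature_stop", TRUE))) {
    "inactivated"
  } else {
    "intact"
  }
}

domain_matrix <- function(lens) {
  # lens: named vector SIG, I, II, III, IV, V
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  m <- cbind(start = as.integer(starts), end = as.integer(ends))
  rownames(m) <- names(lens)
  m
}

new_gene <- function(id, genome, dna, protein, domain_map, status, defects,
                     expression_weight, grammar_name, n_repeats) {
  structure(
    list(
      id = id, genome = genome, dna = dna, protein = protein,
      domain_map = domain_map, status = status, defects = defects,
      expression_weight = expression_weight, grammar_name = grammar_name,
      n_repeats = n_repeats
    ),
    class = "prl_gene"
  )
}

#' @export
print.prl_gene <- function(x, ...) {
  cat(sprintf(
    "<prl_gene %s> genome %s, %s, %d aa / %d bp, %d defect(s), weight %g\n",
    x$id, x$genome, x$status, nchar(x$protein$residues),
    nchar(x$dna$residues), length(x$defects), x$expression_weight
  ))
  invisible(x)
}

#' Build a prolamin gene from a class grammar
#'
#' Constructs the protein domain by domain (SIG, I, II = `n_repeats` repeat
#' motifs, III, IV, V), plants the grammar's cysteine layout (the last
#' residue of domain III and the first residue of domain V are cysteines,
#' the remainder of each layout scattered inside the domain), makes domain
#' IV glutamine-rich (about a third Q), and back-translates with random
#' synonymous codons (glutamine CAA:CAG at 2:1). The coding DNA carries a
#' terminal stop codon. Deterministic for a fixed seed.
#'
## Each class has one canonical protein scaffold, drawn from a fixed
## class-keyed RNG stream: members of a prolamin class share their
## non-repetitive domains, and that within-class similarity is what the
## classification screen relies on. The user seed governs the synonymous
## codon draws (and hence DNA-level variation between same-class genes).
CLASS_SCAFFOLD_SEED <- c(
  delta = 7101L, gamma3 = 7102L, gamma = 7103L, alpha = 7104L,
  lmw = 7105L, omega = 7106L
)

#' @param grammar A `prl_grammar`.
#' @param n_repeats Motif count for domain II; must lie in the grammar's
#'   range.
#' @param seed Integer seed; governs the synonymous codon draws, so two
#'   same-class genes with different seeds encode the same canonical
#'   protein through different DNA.
#' @param id,genome Identifiers stored on the record.
#' @return A `prl_gene` with ground-truth `domain_map` (0-based half-open
#'   protein coordinates), `status = "intact"` and `expression_weight = 1`.
#' @examples
#' g <- build_gene(prolamin_grammar("delta"), 10, seed = 1)
#' sum(strsplit(g$protein$residues, "")[[1]] == "C") # 8
#' @export
build_gene <- function(grammar, n_repeats = 10L, seed = 1L,
                       id = paste0(grammar$name, "_", seed), genome = "U") {
  stopifnot(inherits(grammar, "prl_grammar"))
  n_repeats <- as.integer(n_repeats)
  rng <- grammar$n_repeats_range
  if (n_repeats < rng[1] || n_repeats > rng[2]) {
    stop(
      "n_repeats ", n_repeats, " outside grammar range [", rng[1], ", ",
      rng[2], "]",
      call. = FALSE
    )
  }
  scaffold_seed <- CLASS_SCAFFOLD_SEED[[grammar$name]] + n_repeats
  with_seed(scaffold_seed, {
    pick_len <- function(dom) {
      r <- grammar$domain_len_ranges[[dom]]
      sample(r[1]:r[2], 1L)
    }
    sig <- paste0(
      "M",
      paste(sample(SIG_POOL, grammar$signal_len - 1L, TRUE), collapse = "")
    )
    dom1 <- paste(sample(DOM1_POOL, pick_len("I"), TRUE), collapse = "")
    dom2 <- paste(
      vapply(seq_len(n_repeats), function(i) sample_motif(grammar$motif_sets), ""),
      collapse = ""
    )
    n3 <- pick_len("III")
    c3 <- grammar$cys_layout[["III"]]
    dom3 <- sample(DOM3_POOL, n3, TRUE)
    dom3[1L] <- sample(setdiff(DOM3_POOL, "Q"), 1L) # motif runs cannot leak in
    if (c3 > 0L) {
      # last residue is a cysteine; the rest scattered strictly inside
      at <- c(sort(sample(2:(n3 - 1L), c3 - 1L)), n3)
      dom3[at] <- "C"
    }
    dom3 <- paste(dom3, collapse = "")
    n4 <- pick_len("IV")
    nq <- max(1L, round(n4 * 0.35))
    dom4 <- sample(DOM4_POOL, n4, TRUE)
    dom4[sample(seq_len(n4), nq)] <- "Q"
    dom4 <- paste(dom4, collapse = "")
    n5 <- pick_len("V")
    c5 <- grammar$cys_layout[["V"]]
    dom5 <- sample(DOM5_POOL, n5, TRUE)
    dom5[1L] <- sample(setdiff(DOM5_POOL, "Q"), 1L)
    if (c5 > 0L) {
      at <- c(1L, if (c5 > 1L) sort(sample(2:(n5 - 1L), c5 - 1L)))
      dom5[at] <- "C"
    }
    dom5 <- paste(dom5, collapse = "")

    lens <- c(
      SIG = nchar(sig), I = nchar(dom1), II = nchar(dom2),
      III = nchar(dom3), IV = nchar(dom4), V = nchar(dom5)
    )
    protein <- seq_record(
      paste0(id, "_aa"),
      paste0(sig, dom1, dom2, dom3, dom4, dom5), "protein"
    )
    cds <- reverse_translate(protein) # canonical codons, class stream
    canonical <- paste0(cds$residues, sample(c("TAA", "TGA", "TAG"), 1L))
    dna <- with_seed(seed, {
      seq_record(id, synonymous_jitter(canonical, protein$residues), "dna")
    })
    new_gene(
      id = id, genome = genome, dna = dna, protein = protein,
      domain_map = domain_matrix(lens), status = "intact",
      defects = list(), expression_weight = 1,
      grammar_name = grammar$name, n_repeats = n_repeats
    )
  })
}

## Re-draw a fraction of codons synonymously (draws from the current RNG
## state). Same-class genes built under different seeds thus share their
## canonical codons except for scattered silent differences -- the
## within-class DNA identity a sequence screen relies on -- while the
## encoded protein is untouched.
synonymous_jitter <- function(dna, protein, rate = 0.1) {
  codons <- substring(dna, seq(1L, nchar(dna) - 2L, 3L), seq(3L, nchar(dna), 3L))
  aas <- c(strsplit(protein, "", fixed = TRUE)[[1L]], "*")
  hit <- which(stats::runif(length(codons)) < rate)
  for (i in hit) {
    aa <- aas[i]
    opts <- if (aa == "*") CODON_BY_AA[["*"]] else CODON_BY_AA[[aa]]
    if (is.null(opts) || length(opts) < 2L) next
    codons[i] <- if (aa == "Q") {
      sample(c("CAA", "CAG"), 1L, prob = c(2, 1))
    } else {
      sample(opts, 1L)
    }
  }
  paste(codons, collapse = "")
}

refresh_protein <- function(gene) {
  # Notional translation of the (possibly edited) coding DNA; the final
  # codon position (the nominal stop) is excluded, so protein length is
  # stable even if divergence hits the stop codon. Internal stops stay
  # visible as '*'.
  n <- nchar(gene$dna$residues)
  cds <- seq_record(gene$id, substr(gene$dna$residues, 1L, n - 3L), "dna")
  aa <- translate_dna(cds)$residues
  gene$protein <- seq_record(paste0(gene$id, "_aa"), aa, "protein")
  gene
}

#' Diverge a gene by random substitutions
#'
#' Each coding base is substituted independently with probability
#' `sub_rate`; the protein is re-derived and substitutions that create an
#' in-frame premature stop are recorded as defects (the transcript of such
#' a copy is treated as unstable: expression weight drops to 0). The
#' ground-truth domain map is unchanged because substitutions do not move
#' boundaries.
#'
#' @param gene A `prl_gene`.
#' @param sub_rate Per-base substitution probability in [0, 0.25).
#' @param seed Integer seed.
#' @param id,genome New identifiers (default: keep, suffix id).
#' @return A `prl_gene`.
#' @export
diverge <- function(gene, sub_rate, seed,
                    id = paste0(gene$id, "_div"), genome = gene$genome) {
  stopifnot(inherits(gene, "prl_gene"))
  if (!is.numeric(sub_rate) || sub_rate < 0 || sub_rate >= 0.25) {
    stop("sub_rate must be in [0, 0.25)", call. = FALSE)
  }
  with_seed(seed, {
    mut <- mutate_dna_string(gene$dna$residues, sub_rate)
    out <- gene
    out$id <- id
    out$genome <- genome
    out$dna <- seq_record(id, mut$residues, "dna")
    out <- refresh_protein(out)
    ncod <- nchar(out$protein$residues)
    stops <- which(strsplit(out$protein$residues, "")[[1L]] == "*")
    stops <- stops[stops < ncod - 4L] # premature = before the final 5 codons
    out$defects <- lapply(stops, function(i) {
      defect("premature_stop", dna_position = (i - 1L) * 3L, length = 3L)
    })
    out$status <- status_from_defects(out$defects)
    out$expression_weight <-
      if (out$status == "intact") gene$expression_weight else 0
    out
  })
}

#' Apply a defect catalogue to a gene
#'
#' Premature stops overwrite a codon with TAA; deletions remove bases;
#' insertions add random bases (seeded). Defects are applied from the
#' highest position down so that the stated 0-based coordinates all refer
#' to the input DNA. Status follows the defect list: any frameshift
#' (indel length not divisible by 3) makes a pseudogene; stops alone make
#' an inactivated gene. Either way the expression weight drops to 0.
#'
#' @param gene A `prl_gene`.
#' @param defects List of [defect()] objects (empty list = no-op).
#' @param seed Seed for insertion base draws.
#' @param id New gene id.
#' @return A `prl_gene`.
#' @export
pseudogenize <- function(gene, defects, seed = 1L,
                         id = paste0(gene$id, "_psi")) {
  stopifnot(inherits(gene, "prl_gene"))
  if (!length(defects)) {
    return(gene)
  }
  n <- nchar(gene$dna$residues)
  spans <- lapply(defects, function(d) {
    len <- if (d$type == "insertion") 1L else if (d$type == "premature_stop") 3L else d$length
    c(d$dna_position, d$dna_position + len)
  })
  if (any(vapply(spans, function(s) s[2] > n, TRUE))) {
    stop("defect position outside gene", call. = FALSE)
  }
  ord <- order(vapply(spans, `[`, 0, 1L))
  for (k in seq_along(ord)[-1L]) {
    if (spans[[ord[k]]][1] < spans[[ord[k - 1L]]][2]) {
      stop("overlapping defects", call. = FALSE)
    }
  }
  with_seed(seed, {
    s <- gene$dna$residues
    for (d in defects[order(-vapply(defects, function(d) d$dna_position, 0L))]) {
      p <- d$dna_position
      s <- switch(d$type,
        premature_stop = paste0(
          substr(s, 1L, p), "TAA",
          substr(s, p + 4L, nchar(s))
        ),
        deletion = paste0(
          substr(s, 1L, p),
          substr(s, p + d$length + 1L, nchar(s))
        ),
        insertion = paste0(
          substr(s, 1L, p), random_dna(d$length),
          substr(s, p + 1L, nchar(s))
        )
      )
    }
    out <- gene
    out$id <- id
    out$dna <- seq_record(id, s, "dna")
    out <- refresh_protein(out)
    out$defects <- defects
    out$status <- status_from_defects(defects)
    out$expression_weight <- 0
    out
  })
}

#' Simulate shotgun reads over a set of gene units
#'
#' Emulates a low-coverage pyrosequencing screen: each gene's unit is its
#' coding region plus `flank` bp of random flanking DNA on each side; read
#' starts are uniform over the unit, read lengths are normal
#' (`read_len[1]` mean, `read_len[2]` sd) truncated at the unit end, reads
#' shorter than `min_len` are discarded, and surviving reads receive
#' independent substitution errors at `error_rate`. The per-gene read count
#' is Poisson with mean `coverage * span / read_len[1]`. All reads are on
#' the coding strand.
#'
#' @param genes List of `prl_gene`.
#' @param coverage Fold coverage (> 0).
#' @param read_len `c(mean, sd)` in bases; mean must be >= `min_len`.
#' @param min_len Minimum retained read length (default 100).
#' @param error_rate Per-base substitution error probability.
#' @param flank Flanking bases simulated on each side of the coding region.
#' @param seed Integer seed.
#' @return List of `prl_read`: `id`, `dna` (`prl_seq`),
#'   `true_source = list(gene, start)` (0-based start in the unit),
#'   `length`.
#' @export
simulate_reads <- function(genes, coverage, read_len = c(450, 80),
                           min_len = 100L, error_rate = 0.005,
                           flank = 200L, seed = 1L) {
  if (!is.numeric(coverage) || coverage <= 0) {
    stop("coverage must be > 0", call. = FALSE)
  }
  if (read_len[1] < min_len) {
    stop("mean read length below min_len", call. = FALSE)
  }
  with_seed(seed, {
    reads <- list()
    for (gene in genes) {
      unit <- paste0(
        if (flank > 0L) random_dna(flank) else "",
        gene$dna$residues,
        if (flank > 0L) random_dna(flank) else ""
      )
      span <- nchar(unit)
      n <- stats::rpois(1L, coverage * span / read_len[1])
      if (n == 0L) next
      starts <- sample.int(span, n, replace = TRUE) - 1L
      lens <- pmax(1L, round(stats::rnorm(n, read_len[1], read_len[2])))
      ends <- pmin(starts + lens, span)
      keep <- which(ends - starts >= min_len)
      for (j in seq_along(keep)) {
        k <- keep[j]
        raw <- substr(unit, starts[k] + 1L, ends[k])
        if (error_rate > 0) raw <- mutate_dna_string(raw, error_rate)$residues
        rid <- sprintf("%s_r%03d", gene$id, j)
        reads[[length(reads) + 1L]] <- structure(
          list(
            id = rid, dna = seq_record(rid, raw, "dna"),
            true_source = list(gene = gene$id, start = starts[k]),
            length = ends[k] - starts[k]
          ),
          class = "prl_read"
        )
      }
    }
    reads
  })
}

#' Sample ESTs from expressed genes
#'
#' Draws `n` single-pass partial transcripts. A gene is chosen with
#' probability proportional to its expression weight (weight-0 genes --
#' premature-stop carriers and pseudogenes -- are never sampled), then a
#' fragment of uniform length in `len_range` is anchored at the 5' or 3'
#' end of the coding sequence with probability `p5` / `1 - p5`.
#'
#' @param genes List of `prl_gene`; at least one must have positive weight.
#' @param n Number of ESTs.
#' @param seed Integer seed.
#' @param len_range EST length range in bases (clipped to the CDS length).
#' @param p5 Probability of 5'-anchoring.
#' @return List of `prl_est`: `seq` (`prl_seq`), `source` (gene id),
#'   `anchor` ("5p"/"3p").
#' @export
sample_ests <- function(genes, n, seed = 1L, len_range = c(200L, 700L),
                        p5 = 0.5) {
  w <- vapply(genes, function(g) g$expression_weight, 0)
  if (all(w <= 0)) stop("all expression weights are zero", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    picks <- sample.int(length(genes), n, replace = TRUE, prob = w)
    lapply(seq_len(n), function(i) {
      gene <- genes[[picks[i]]]
      cds <- gene$dna$residues
      len <- min(sample(len_range[1]:len_range[2], 1L), nchar(cds))
      five <- stats::runif(1L) < p5
      s <- if (five) {
        substr(cds, 1L, len)
      } else {
        substr(cds, nchar(cds) - len + 1L, nchar(cds))
      }
      eid <- sprintf("est_%03d", i)
      structure(
        list(
          seq = seq_record(eid, s, "dna"), source = gene$id,
          anchor = if (five) "5p" else "3p"
        ),
        class = "prl_est"
      )
    })
  })
}
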