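# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, direct table lookup, quadrature) that never
# calls the package code paths it is checking.

# exhaustive affine-gap global alignment score by recursive enumeration;
# a gap run of length L costs gap_open + L * gap_extend; N scores 0
oracle_global_score <- function(a, b, match = 2, mismatch = -3,
                                gap_open = -5, gap_extend = -2) {
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  subst <- function(x, y) {
    if (x == "N" || y == "N") 0 else if (x == y) match else mismatch
  }
  rec <- function(i, j, last) {
    if (i > length(ac) && j > length(bc)) {
      return(0)
    }
    best <- -Inf
    if (i <= length(ac) && j <= length(bc)) {
      best <- max(best, subst(ac[i], bc[j]) + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= length(ac)) {
      cost <- gap_extend + if (last == "a") 0 else gap_open
      best <- max(best, cost + rec(i + 1L, j, "a"))
    }
    if (j <= length(bc)) {
      cost <- gap_extend + if (last == "b") 0 else gap_open
      best <- max(best, cost + rec(i, j + 1L, "b"))
    }
    best
  }
  rec(1L, 1L, "m")
}

# best local score = best global score over all substring pairs, floor 0
oracle_local_score <- function(a, b, ...) {
  best <- 0
  na <- nchar(a)
  nb <- nchar(b)
  for (i in seq_len(na)) {
    for (j in i:na) {
      for (k in seq_len(nb)) {
        for (l in k:nb) {
          best <- max(best, oracle_global_score(
            substr(a, i, j), substr(b, k, l), ...
          ))
        }
      }
    }
  }
  best
}

# direct codon-table translation (table typed out independently)
ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_translate <- function(dna) {
  n <- (nchar(dna) %/% 3L) * 3L
  cods <- substring(dna, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  paste(vapply(cods, function(cd) {
    if (grepl("N", cd, fixed = TRUE)) "X" else unname(ORACLE_CODONS[cd])
  }, ""), collapse = "")
}

# length of the longest order-preserving matching by full enumeration
oracle_lcs_length <- function(sa, sb, match_fn) {
  rec <- function(i, j) {
    if (i > length(sa) || j > length(sb)) {
      return(0L)
    }
    best <- max(rec(i + 1L, j), rec(i, j + 1L))
    if (match_fn(sa[i], sb[j])) best <- max(best, 1L + rec(i + 1L, j + 1L))
    best
  }
  rec(1L, 1L)
}

# all edge bipartitions of a phylo tree by direct edge traversal
oracle_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  below <- function(node) {
    if (node <= n_tip) {
      return(tree$tip.label[node])
    }
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) sort(below(tree$edge[e, 2])))
}

# chi-square upper tail by quadrature of the hand-written density
oracle_chisq_sf <- function(x, df) {
  dens <- function(t) {
    t^(df / 2 - 1) * exp(-t / 2) / (2^(df / 2) * gamma(df / 2))
  }
  stats::integrate(dens, x, Inf, rel.tol = 1e-12)$value
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

read_sources <- function(contig) {
  unique(sub("_r[0-9]+$", "", contig$members$id))
}
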