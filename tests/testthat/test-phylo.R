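test_that("repeat stripping removes exactly domain II and is idempotent", {
  g <- build_gene(prolamin_grammar("delta"), 10, seed = 5)
  s <- strip_repeats(g$protein, g$domain_map)
  ii <- g$domain_map["II", ]
  expect_identical(
    nchar(s$residues),
    unname(nchar(g$protein$residues) - (ii["end"] - ii["start"]))
  )
  # stripping a stripped sequence with an empty-II map changes nothing
  dm2 <- g$domain_map
  dm2["II", ] <- c(dm2["II", "start"], dm2["II", "start"])
  expect_identical(strip_repeats(s, dm2)$residues, s$residues)
})

test_that("p-distances reflect planted substitutions", {
  ident <- lapply(1:3, function(i) {
    seq_record(paste0("s", i), "MKTAEDVHWRSMKTAEDVHWRS", "protein")
  })
  m <- p_distance_matrix(ident)
  expect_true(all(m$d == 0))

  opp <- list(
    seq_record("a", strrep("A", 12), "dna"),
    seq_record("c", strrep("C", 12), "dna"),
    seq_record("g", strrep("G", 12), "dna")
  )
  expect_true(all(p_distance_matrix(opp)$d[upper.tri(diag(3))] == 1))

  # planted k substitutions over L sites
  set.seed(30)
  base <- random_dna_str(200)
  plant <- function(k) {
    ch <- strsplit(base, "")[[1]]
    at <- sample(200, k)
    for (i in at) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  seqs <- list(
    seq_record("ref", base, "dna"),
    seq_record("k10", plant(10), "dna"),
    seq_record("k40", plant(40), "dna")
  )
  d <- p_distance_matrix(seqs)$d
  expect_equal(d["ref", "k10"], 10 / 200, tolerance = 1e-9)
  expect_equal(d["ref", "k40"], 40 / 200, tolerance = 1e-9)

  # input order only permutes labels
  d2 <- p_distance_matrix(seqs[c(2, 3, 1)])$d
  expect_identical(d2["ref", "k10"], d["ref", "k10"])

  expect_error(p_distance_matrix(ident[1:2]), "at least 3")
  short <- lapply(1:3, function(i) seq_record(paste0("t", i), "ACG", "dna"))
  expect_error(p_distance_matrix(short), "unreliable")
})

test_that("neighbor joining recovers additive trees and roots correctly", {
  # distances generated by ((A:1,B:2):1,(C:3,D:1)): AB|CD is the true split
  d <- matrix(
    c(
      0, 3, 5, 3,
      3, 0, 6, 4,
      5, 6, 0, 4,
      3, 4, 4, 0
    ), 4, 4,
    dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  )
  # oracle: check which of the three splits satisfies the four-point
  # condition, by direct enumeration
  four_point <- function(p) {
    s1 <- d[p[1], p[2]] + d[p[3], p[4]]
    s2 <- d[p[1], p[3]] + d[p[2], p[4]]
    s3 <- d[p[1], p[4]] + d[p[2], p[3]]
    s1 <= s2 && s1 <= s3 && abs(s2 - s3) < 1e-9
  }
  splits <- list(
    c("A", "B", "C", "D"), c("A", "C", "B", "D"), c("A", "D", "B", "C")
  )
  truth <- splits[[which(vapply(splits, four_point, TRUE))]]
  expect_identical(truth[1:2], c("A", "B"))

  tr <- nj_tree(d, outgroup = "C")
  expect_true(monophyly_check(tr, c("A", "B"))$monophyletic)
  expect_false(monophyly_check(tr, c("A", "C"))$monophyletic)

  # three taxa give the unique topology
  tr3 <- nj_tree(d[1:3, 1:3], outgroup = "C")
  expect_identical(sort(tr3$tip.label), c("A", "B", "C"))
  expect_true(all(tr3$edge.length >= 0))
  expect_error(nj_tree(d[1:2, 1:2], "A"), "at least 3")
  expect_error(nj_tree(d, "Z"), "not among labels")
})

test_that("monophyly agrees with brute-force bipartition listing", {
  expect_true(monophyly_check(ape::rtree(5), "t1")$monophyletic)
  tr <- ape::rtree(7)
  expect_true(monophyly_check(tr, tr$tip.label)$monophyletic)
  expect_error(monophyly_check(tr, "nope"), "unknown label")

  set.seed(31)
  for (rep in 1:5) {
    tr <- ape::rtree(sample(4:8, 1))
    parts <- oracle_bipartitions(tr)
    tips <- tr$tip.label
    for (k in 1:6) {
      s <- sample(tips, sample(seq_along(tips), 1))
      want <- any(vapply(parts, function(p) {
        setequal(p, s) || setequal(p, setdiff(tips, s))
      }, TRUE)) || length(s) == length(tips)
      got <- monophyly_check(tr, s)$monophyletic
      expect_identical(got, want, info = paste(rep, paste(s, collapse = ",")))
    }
  }
})

test_that("diagnostic residues find exactly the planted columns", {
  blk <- c(
    a1 = "MKTAEDVHWRSM", a2 = "MKTAEDVHWRSM",
    b1 = "MKTAEDVHWRSM", b2 = "MKTAEDVHWRSM"
  )
  none <- diagnostic_residues(blk, c("a1", "a2"), c("b1", "b2"))
  expect_identical(nrow(none$columns), 0L)

  # plant 5 group-a-exclusive columns
  ch <- strsplit(blk, "")
  for (j in c(2, 4, 6, 8, 10)) {
    ch$a1[j] <- "W"
    ch$a2[j] <- "W"
  }
  blk2 <- vapply(ch, paste, "", collapse = "")
  da <- diagnostic_residues(blk2, c("a1", "a2"), c("b1", "b2"))
  got_a <- da$columns$column[da$columns$group == "a"]
  expect_identical(sort(got_a), c(1L, 3L, 5L, 7L, 9L))

  # group-exclusive indel block
  ch$b1[3:5] <- "-"
  ch$b2[3:5] <- "-"
  blk3 <- vapply(ch, paste, "", collapse = "")
  di <- diagnostic_residues(blk3, c("a1", "a2"), c("b1", "b2"))
  expect_identical(di$indel_blocks$start, 2L)
  expect_identical(di$indel_blocks$end, 5L)
  expect_identical(di$indel_blocks$gapped_in, "b")

  expect_error(
    diagnostic_residues(c(x = "AB", y = "ABC"), "x", "y"), "ragged"
  )
  expect_error(
    diagnostic_residues(blk, c("a1", "b1"), c("b1", "b2")), "overlap"
  )
})

test_that("simulated stem lineages produce trees with the expected clade", {
  fam <- simulate_prolamin_family(seed = 3)
  tr <- nj_tree(p_distance_matrix(fam$stripped), fam$outgroup)
  chk <- monophyly_check(tr, fam$groups$dg3)
  expect_true(chk$monophyletic)
  expect_false(any(fam$groups$gamma %in% chk$clade))

  blk <- stats::setNames(
    vapply(fam$stripped, function(s) s$residues, ""),
    vapply(fam$stripped, function(s) s$id, "")
  )
  dr <- diagnostic_residues(blk, fam$groups$dg3, fam$groups$gamma)
  expect_gt(nrow(dr$columns), 0L)
})

test_that("genome assignment counts mismatches and glutamine-codon indels", {
  base <- build_gene(prolamin_grammar("delta"), 10, seed = 11, id = "q")
  plant <- function(s, k, seed) {
    set.seed(seed)
    ch <- strsplit(s, "")[[1]]
    for (j in sample(length(ch), k)) {
      ch[j] <- setdiff(c("A", "C", "G", "T"), ch[j])[1]
    }
    paste(ch, collapse = "")
  }
  refs <- list(
    A = seq_record("A", plant(base$dna$residues, 6, 1), "dna"),
    B = seq_record("B", plant(base$dna$residues, 17, 2), "dna"),
    D = seq_record("D", plant(base$dna$residues, 31, 3), "dna")
  )
  ga <- assign_genome(base$dna, refs)
  expect_identical(ga$assigned, "A")
  expect_identical(unname(ga$mismatch_counts), c(6L, 17L, 31L))

  # identical reference: zero mismatches
  refs$A <- base$dna
  expect_identical(
    unname(assign_genome(base$dna, refs)$mismatch_counts["A"]), 0L
  )

  # tie -> ambiguous
  tie <- list(X = base$dna, Y = base$dna)
  amb <- assign_genome(base$dna, tie)
  expect_identical(amb$assigned, "ambiguous")
  expect_identical(sort(amb$tied), c("X", "Y"))
})

test_that("a glutamine codon lost from a poly-Q run is one codon event", {
  flank5 <- "ATGGCTACTGGTCTTAGAGATCCTATG"
  flank3 <- "GGTCATTTGAGAGCTCCTGGTCTTATG"
  ref <- seq_record("ref", paste0(flank5, strrep("CAA", 6), flank3), "dna")
  qry <- seq_record("q", paste0(flank5, strrep("CAA", 5), flank3), "dna")
  other <- seq_record("o", prolaminr:::with_seed(7, {
    paste(sample(c("A", "C", "G", "T"), nchar(ref$residues), TRUE), collapse = "")
  }), "dna")
  ga <- assign_genome(qry, list(R = ref, O = other))
  expect_identical(ga$assigned, "R")
  expect_identical(unname(ga$mismatch_counts["R"]), 0L)
  expect_identical(unname(ga$codon_indel_counts["R"]), 1L)
  expect_identical(unname(ga$other_gap_bases["R"]), 0L)
})
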