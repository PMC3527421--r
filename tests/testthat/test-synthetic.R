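test_that("built genes obey their grammar", {
  grammar <- prolamin_grammar("delta")
  g <- build_gene(grammar, 10, seed = 5)
  chars <- strsplit(g$protein$residues, "")[[1]]
  expect_identical(sum(chars == "C"), 8L)
  expect_identical(g$status, "intact")
  expect_identical(g$defects, list())

  # domain map tiles the protein in canonical order
  dm <- g$domain_map
  expect_identical(rownames(dm), c("SIG", "I", "II", "III", "IV", "V"))
  expect_identical(dm[1, "start"], 0L)
  expect_identical(unname(dm[-1, "start"]), unname(dm[-6, "end"]))
  expect_identical(unname(dm[6, "end"]), length(chars))

  # determinism and the seed's role: same seed -> identical record; a
  # different seed re-draws codons only
  expect_identical(build_gene(grammar, 10, seed = 5), g)
  g2 <- build_gene(grammar, 10, seed = 6, id = g$id)
  expect_identical(g2$protein$residues, g$protein$residues)
  expect_false(identical(g2$dna$residues, g$dna$residues))

  # coding DNA really encodes the protein
  expect_identical(
    translate_dna(g$dna)$residues, paste0(g$protein$residues, "*")
  )
  expect_error(build_gene(grammar, 50, seed = 1), "outside grammar range")
})

test_that("the repeat domain re-tokenizes into the built motif count", {
  g <- build_gene(prolamin_grammar("delta"), 10, seed = 5)
  ii <- g$domain_map["II", ]
  dom <- substr(g$protein$residues, ii["start"] + 1, ii["end"])
  toks <- tokenize_repeats(dom)
  expect_length(toks, 10L)
  expect_true(all(vapply(toks, function(t) t$canonical, TRUE)))
})

test_that("divergence substitutes at the requested rate", {
  g <- build_gene(prolamin_grammar("delta"), 10, seed = 5)
  expect_identical(diverge(g, 0, 9)$dna$residues, g$dna$residues)
  expect_identical(diverge(g, 0.02, 9), diverge(g, 0.02, 9))

  n <- nchar(g$dna$residues)
  rate <- 0.02
  mm <- vapply(1:10, function(s) {
    d <- diverge(g, rate, s)
    sum(strsplit(d$dna$residues, "")[[1]] != strsplit(g$dna$residues, "")[[1]])
  }, 0)
  sigma <- sqrt(n * rate * (1 - rate))
  expect_lt(abs(mean(mm) - n * rate), 4 * sigma / sqrt(10))
  expect_error(diverge(g, 0.3, 1), "sub_rate")
})

test_that("divergence records stop-creating substitutions as defects", {
  g <- build_gene(prolamin_grammar("delta"), 10, seed = 5)
  hit <- FALSE
  for (s in 1:40) {
    d <- diverge(g, 0.05, s)
    if (length(d$defects)) {
      hit <- TRUE
      expect_identical(d$status, "inactivated")
      expect_identical(d$expression_weight, 0)
      for (df in d$defects) expect_identical(df$type, "premature_stop")
      break
    }
  }
  expect_true(hit)
})

test_that("pseudogenization applies the defect catalogue and sets status", {
  g <- build_gene(prolamin_grammar("delta"), 10, seed = 5)
  p <- 3 * (g$domain_map["III", "start"] + 5)
  stops <- list(
    defect("premature_stop", p), defect("premature_stop", p + 3)
  )
  inact <- pseudogenize(g, stops, seed = 2)
  expect_identical(inact$status, "inactivated")
  expect_length(inact$defects, 2L)
  expect_identical(inact$expression_weight, 0)

  full <- pseudogenize(g, list(
    defect("premature_stop", 3 * (g$domain_map["I", "start"] + 4)),
    defect("deletion", 3 * (g$domain_map["III", "start"] + 12) + 1, 1),
    defect("deletion", 3 * (g$domain_map["V", "start"] + 8), 11)
  ), seed = 2)
  expect_identical(full$status, "pseudogene")
  # 1 and 11 are both indivisible by 3: frameshifts
  fs <- vapply(full$defects, prolaminr:::is_frameshift, TRUE)
  expect_identical(sum(fs), 2L)
  expect_identical(nchar(full$dna$residues), nchar(g$dna$residues) - 12L)

  expect_identical(pseudogenize(g, list(), seed = 1), g)
  expect_error(
    pseudogenize(g, list(defect("deletion", 10, 5), defect("deletion", 12, 2))),
    "overlapping"
  )
})

test_that("read simulation matches coverage accounting", {
  g <- build_gene(prolamin_grammar("delta"), 10, seed = 5)
  span <- nchar(g$dna$residues) + 400
  counts <- vapply(1:20, function(s) {
    length(simulate_reads(list(g), coverage = 5, seed = s))
  }, 0)
  # lengths < 100 are discarded, so the retained count sits slightly
  # below coverage * span / mean; 15% tolerance covers both effects
  expect_lt(abs(mean(counts) - 5 * span / 450) / (5 * span / 450), 0.15)

  rd <- simulate_reads(list(g), coverage = 5, seed = 3)
  expect_true(all(vapply(rd, function(r) r$length, 0) >= 100))

  clean <- simulate_reads(list(g), coverage = 3, error_rate = 0, seed = 4)
  # error-free reads are exact substrings of their unit; check against
  # the coding region for reads fully inside it
  for (r in clean) {
    s <- r$true_source$start
    if (s >= 200 && s + r$length <= 200 + nchar(g$dna$residues)) {
      expect_identical(
        r$dna$residues,
        substr(g$dna$residues, s - 200 + 1, s - 200 + r$length)
      )
    }
  }
  expect_error(simulate_reads(list(g), coverage = 0), "coverage")
  expect_error(
    simulate_reads(list(g), coverage = 1, read_len = c(80, 10)),
    "min_len"
  )
})

test_that("interior depth converges to the requested coverage", {
  g <- build_gene(prolamin_grammar("delta"), 10, seed = 5)
  span <- nchar(g$dna$residues) + 400
  rd <- simulate_reads(list(g), coverage = 20, seed = 11)
  depth <- integer(span)
  for (r in rd) {
    s <- r$true_source$start
    depth[(s + 1):(s + r$length)] <- depth[(s + 1):(s + r$length)] + 1L
  }
  # away from the edges (where truncation and the minimum read length
  # thin the pileup) mean depth approaches the nominal coverage
  interior <- depth[350:(span - 500)]
  expect_lt(abs(mean(interior) - 20) / 20, 0.15)
})

test_that("EST sampling respects expression weights", {
  g <- build_gene(prolamin_grammar("delta"), 10, seed = 5)
  silent <- pseudogenize(
    g, list(defect("premature_stop", 3 * (g$domain_map["III", "start"] + 5))),
    id = "gA"
  )
  gB <- diverge(g, 0.01, 21, id = "gB")
  gD <- diverge(g, 0.01, 22, id = "gD")
  gB$expression_weight <- 1
  gD$expression_weight <- 1
  ests <- sample_ests(list(silent, gB, gD), 100, seed = 7)
  expect_length(ests, 100L)
  src <- vapply(ests, function(e) e$source, "")
  expect_identical(sum(src == "gA"), 0L)

  gD$expression_weight <- 3
  ests2 <- sample_ests(list(gB, gD), 100, seed = 8)
  nD <- sum(vapply(ests2, function(e) e$source, "") == "gD")
  expect_lt(abs(nD - 75), 4 * sqrt(100 * 0.75 * 0.25))

  gB$expression_weight <- 0
  gD$expression_weight <- 0
  expect_error(sample_ests(list(gB, gD), 10, seed = 1), "weights are zero")
})

test_that("class scaffolds give within-class DNA identity, not between", {
  d1 <- build_gene(prolamin_grammar("delta"), 10, seed = 31)
  d2 <- build_gene(prolamin_grammar("delta"), 10, seed = 32)
  a1 <- build_gene(prolamin_grammar("alpha"), 10, seed = 33)
  within <- align_local(d1$dna, d2$dna)$identity
  expect_gt(within, 0.9)
  between <- align_local(d1$dna, a1$dna)
  expect_true(between$score == 0 || between$identity < within)
})
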