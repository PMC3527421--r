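delta <- prolamin_grammar("delta")

test_that("an unmodified copy of the reference is intact", {
  g <- build_gene(delta, 10, seed = 5)
  rep <- detect_defects(g$dna, g)
  expect_identical(rep$status, "intact")
  expect_length(rep$defects, 0L)
  expect_identical(rep$protein$residues, g$protein$residues)
})

test_that("tandem premature stops are recovered with positions", {
  g <- build_gene(delta, 10, seed = 5)
  p <- 3L * (g$domain_map["III", "start"] + 5L)
  inact <- pseudogenize(
    g, list(defect("premature_stop", p), defect("premature_stop", p + 3L))
  )
  rep <- detect_defects(inact$dna, g)
  expect_identical(rep$status, "inactivated")
  expect_length(rep$defects, 2L)
  expect_identical(
    vapply(rep$defects, function(d) d$type, ""),
    c("premature_stop", "premature_stop")
  )
  expect_identical(
    vapply(rep$defects, function(d) d$dna_position, 0L),
    c(p, p + 3L)
  )
  # ORF ends at the first stop
  expect_lt(nchar(rep$protein$residues), nchar(g$protein$residues))
})

test_that("the stop + 1 bp + 11 bp catalogue round-trips exactly", {
  for (s in c(5, 23)) {
    g <- build_gene(delta, 10, seed = s)
    cat_def <- list(
      defect("premature_stop", 3 * (g$domain_map["I", "start"] + 4)),
      defect("deletion", 3 * (g$domain_map["III", "start"] + 12) + 1, 1),
      defect("deletion", 3 * (g$domain_map["V", "start"] + 8), 11)
    )
    psi <- pseudogenize(g, cat_def, seed = s + 1)
    rep <- detect_defects(psi$dna, g)
    expect_identical(rep$status, "pseudogene")
    expect_identical(
      sort(vapply(rep$defects, function(d) d$type, "")),
      c("deletion", "deletion", "premature_stop")
    )
    planted <- sort(vapply(cat_def, function(d) d$dna_position, 0L))
    found <- sort(vapply(rep$defects, function(d) d$dna_position, 0L))
    expect_true(all(abs(planted - found) <= 3L))
    fs <- Filter(function(d) isTRUE(d$frameshift), rep$defects)
    expect_identical(sort(vapply(fs, function(d) d$length, 0L)), c(1L, 11L))
  }
})

test_that("status is a pure function of the defect list", {
  f <- prolaminr:::status_from_defects
  stop1 <- defect("premature_stop", 30)
  del3 <- defect("deletion", 60, 3)
  del1 <- defect("deletion", 90, 1)
  expect_identical(f(list()), "intact")
  expect_identical(f(list(stop1)), "inactivated")
  expect_identical(f(list(del3, stop1)), "inactivated") # in-frame indel
  expect_identical(f(list(del1)), "pseudogene")
  expect_identical(f(list(stop1, del1)), "pseudogene")
  expect_identical(f(list(del1, stop1)), f(list(stop1, del1)))
})

test_that("non-homologous queries are rejected", {
  g <- build_gene(delta, 10, seed = 5)
  set.seed(6)
  junk <- seq_record("junk", random_dna_str(600), "dna")
  expect_error(detect_defects(junk, g), "not homologous")
})

test_that("domain segmentation recovers the generator ground truth", {
  for (s in c(5, 12)) {
    for (cls in c("delta", "lmw", "gamma3")) {
      gr <- prolamin_grammar(cls)
      g <- build_gene(gr, 10, seed = s)
      dm <- segment_domains(g$protein, gr)
      expect_identical(dm, g$domain_map, info = paste(cls, s))
      # idempotent on the same input
      expect_identical(segment_domains(g$protein, gr), dm)
    }
  }
})

test_that("repeat-free proteins degrade to SIG + I with a warning", {
  p <- seq_record("plain", strrep("MKTAEDVHWRS", 8), "protein")
  expect_warning(dm <- segment_domains(p, delta), "no repetitive window")
  expect_identical(unname(dm["SIG", ]), c(0L, 19L))
  expect_identical(unname(dm["I", "end"]), nchar(p$residues))
  expect_identical(unname(dm["II", "start"]), unname(dm["II", "end"]))
})

test_that("domain IV is glutamine-rich", {
  g <- build_gene(delta, 10, seed = 5)
  iv <- g$domain_map["IV", ]
  chars <- strsplit(substr(g$protein$residues, iv["start"] + 1, iv["end"]), "")[[1]]
  tab <- table(chars)
  expect_identical(names(which.max(tab)), "Q")
})

test_that("cysteine census counts, parity and polymer flag", {
  g <- build_gene(delta, 10, seed = 5)
  cen <- census_cysteines(g$protein, g$domain_map)
  expect_identical(cen$count, 8L)
  expect_identical(cen$parity, "even")
  expect_false(cen$polymer_flag)
  expect_length(cen$per_domain$III, 6L)
  expect_length(cen$per_domain$V, 2L)
  expect_length(cen$per_domain$II, 0L)

  om <- build_gene(prolamin_grammar("omega"), 10, seed = 5)
  cen_o <- census_cysteines(om$protein, om$domain_map)
  expect_identical(cen_o$count, 0L)

  # inject one repeat-domain cysteine into a gamma gene
  gg <- build_gene(prolamin_grammar("gamma"), 10, seed = 5)
  chars <- strsplit(gg$protein$residues, "")[[1]]
  chars[gg$domain_map["II", "start"] + 3] <- "C"
  mut <- seq_record("gmut", paste(chars, collapse = ""), "protein")
  cen_g <- census_cysteines(mut, gg$domain_map)
  expect_identical(cen_g$count, 9L)
  expect_identical(cen_g$parity, "odd")
  expect_true(cen_g$polymer_flag)
})
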