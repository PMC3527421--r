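test_that("copy-number arithmetic reproduces the screening estimates", {
  cs <- estimate_copy_number(69, 400, 1000, 5, 3)
  expect_equal(cs$copies_per_genome, 69 / (5 * 1000 / 400) / 3)
  expect_equal(round(cs$copies_per_genome, 2), 1.84)
  expect_gte(cs$copies_per_genome, 1)
  expect_lte(cs$copies_per_genome, 2)

  at <- estimate_copy_number(10, 400, 1000, 3, 1)
  expect_equal(at$copies_per_genome, 10 / 7.5)
  expect_gte(at$copies_per_genome, 1)
  expect_lte(at$copies_per_genome, 2)

  # definitional identity: N = c L / R reads -> exactly one copy
  one <- estimate_copy_number(5 * 1000 / 400, 400, 1000, 5, 1)
  expect_equal(one$copies_per_genome, 1)

  expect_error(estimate_copy_number(0, 400, 1000, 5, 3), "positive")
  expect_error(estimate_copy_number(10, -1, 1000, 5, 3), "positive")
})

test_that("the estimator is linear in reads, inverse in coverage, and the
           edge correction only lowers it", {
  for (n in c(10, 40, 69)) {
    for (cv in c(2, 5, 8)) {
      e <- estimate_copy_number(n, 400, 1000, cv, 1)
      expect_equal(e$copies_total, n * 400 / (cv * 1000))
      ec <- estimate_copy_number(n, 400, 1000, cv, 1, edge_corrected = TRUE)
      expect_lt(ec$copies_total, e$copies_total)
    }
  }
})

test_that("simulated single-copy loci recover about one copy per genome", {
  ok <- 0L
  for (s in 1:20) {
    sc <- scenario_hexaploid(seed = s)
    genes <- sc$genes[1:3] # one copy per genome
    rd <- simulate_reads(genes, coverage = 5, seed = s + 400)
    span <- mean(vapply(genes, function(g) nchar(g$dna$residues), 0)) + 400
    est <- estimate_copy_number(
      n_reads = length(rd), mean_read_len = 450, target_len = span,
      coverage = 5, n_genomes = 3
    )
    if (est$copies_per_genome >= 0.6 && est$copies_per_genome <= 1.6) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 18L)
})

test_that("EST counting assigns by identity with an ortholog-scale margin", {
  sc <- scenario_hexaploid(seed = 2)
  genes <- sc$genes[1:3]
  cons <- stats::setNames(
    lapply(genes, function(g) g$dna),
    vapply(genes, function(g) g$id, "")
  )
  # exact substring of deltaD counts to deltaD
  est <- seq_record("e1", substr(genes[[3]]$dna$residues, 31, 430), "dna")
  ec <- count_ests(list(est), cons)
  expect_identical(unname(ec$counts["deltaD"]), 1L)

  # an EST equally near two identical consensi is ambiguous and excluded
  twin <- stats::setNames(
    list(genes[[3]]$dna, genes[[3]]$dna), c("X", "Y")
  )
  amb <- count_ests(list(est), twin)
  expect_identical(sum(amb$counts), 0L)
  expect_identical(amb$ambiguous, "e1")

  # silenced gene never collects counts
  ex <- scenario_expression(seed = 2)
  cs_genes <- ex$chinese_spring$genes
  cons_cs <- stats::setNames(
    lapply(cs_genes, function(g) g$dna),
    vapply(cs_genes, function(g) g$id, "")
  )
  cc <- count_ests(ex$chinese_spring$ests, cons_cs)
  expect_identical(unname(cc$counts["deltaA"]), 0L)
  expect_identical(sum(cc$counts) + length(cc$ambiguous), 17L)
  expect_gt(unname(cc$counts["deltaD"]), unname(cc$counts["deltaB"]))
})

test_that("the goodness-of-fit test reproduces the pooled EST example", {
  g <- gof_chisq(c(9, 4, 18))
  expect_equal(g$chi2, sum((c(9, 4, 18) - 31 / 3)^2 / (31 / 3)))
  expect_equal(g$chi2, 9.741935, tolerance = 1e-6)
  expect_identical(g$df, 2L)
  expect_gte(g$p, 0.0076)
  expect_lte(g$p, 0.0077)

  flat <- gof_chisq(c(10, 10, 10))
  expect_identical(flat$chi2, 0)
  expect_identical(flat$p, 1)

  # cross-check against the standard test
  ref <- suppressWarnings(stats::chisq.test(c(9, 4, 18)))
  expect_equal(g$chi2, unname(ref$statistic))
  expect_equal(g$p, ref$p.value)

  expect_warning(gof_chisq(c(1, 0, 1)), "below 1")
  expect_error(gof_chisq(c(5)), "categories")
  expect_error(gof_chisq(c(0, 0)), "positive total")
})

test_that("the survival function matches closed form and quadrature", {
  expect_identical(chi2_upper_tail(0, 1), 1)
  expect_identical(chi2_upper_tail(0, 5), 1)
  # df = 2 closed form exp(-x/2)
  for (x in c(0.5, 2, 9.742, 20)) {
    expect_equal(chi2_upper_tail(x, 2), exp(-x / 2), tolerance = 1e-12)
  }
  expect_equal(chi2_upper_tail(9.742, 2), 0.00766, tolerance = 1e-3)
  # quadrature of the hand-written density, df 1..6
  for (df in 1:6) {
    for (x in c(0.7, 3.3, 11)) {
      expect_equal(
        chi2_upper_tail(x, df), oracle_chisq_sf(x, df), tolerance = 1e-8
      )
    }
  }
  # monotone decreasing in the statistic
  xs <- seq(0, 30, by = 0.5)
  expect_true(all(diff(chi2_upper_tail(xs, 3)) <= 0))
  expect_error(chi2_upper_tail(3, 0), "df")
  expect_error(chi2_upper_tail(-1, 2), ">= 0")
})
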