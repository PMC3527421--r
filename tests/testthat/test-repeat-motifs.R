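delta_sets <- prolamin_grammar("delta")$motif_sets

# independent tokenizer: cut after every maximal Q run
oracle_tokens <- function(s) {
  marked <- gsub("(Q+)(?!Q)", "\\1|", s, perl = TRUE)
  toks <- strsplit(marked, "|", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

test_that("tokenization follows the P...Q-run convention", {
  toks <- tokenize_repeats("PLPQQPFPQQ", delta_sets)
  expect_identical(
    vapply(toks, function(t) t$residues, ""), c("PLPQQ", "PFPQQ")
  )
  expect_true(all(vapply(toks, function(t) t$canonical, TRUE)))
  expect_identical(vapply(toks, function(t) t$start, 0L), c(0L, 5L))

  var <- tokenize_repeats("PLPQQSFPQQ", delta_sets)
  expect_identical(
    vapply(var, function(t) t$residues, ""), c("PLPQQ", "SFPQQ")
  )
  expect_false(var[[2]]$canonical)
  expect_identical(var[[2]]$variant_of, "PFPQQ") # P -> S substitution
})

test_that("tokenization is lossless and matches the regex-scan oracle", {
  set.seed(20)
  for (i in 1:50) {
    s <- paste(
      sample(c("P", "Q", "L", "F", "S", "T"), sample(5:40, 1), replace = TRUE),
      collapse = ""
    )
    toks <- tokenize_repeats(s)
    expect_identical(
      paste(vapply(toks, function(t) t$residues, ""), collapse = ""), s
    )
    expect_identical(vapply(toks, function(t) t$residues, ""), oracle_tokens(s))
  }
  expect_error(tokenize_repeats(""), "empty")
})

test_that("motif signatures recover the class patterns", {
  sig_of <- function(class, n = 40, seed = 21) {
    sets <- prolamin_grammar(class)$motif_sets
    dom <- with_seed(seed, paste(
      vapply(1:n, function(i) prolaminr:::sample_motif(sets), ""),
      collapse = ""
    ))
    motif_signature(tokenize_repeats(dom, sets))
  }
  expect_identical(sig_of("delta")$pattern, "P-[FL]-P-Q{2-3}")
  expect_identical(sig_of("alpha")$pattern, "P-[FY]-P-Q{3-5}")
  expect_identical(sig_of("lmw")$pattern, "P-F-[PS]-Q{2-5}")
  expect_error(
    motif_signature(tokenize_repeats("PLPQQ")), "at least 3"
  )
})

test_that("motif alignment marks conserved and missing repeats", {
  # distinct Q-run lengths make every motif unique, so the matching
  # between the two lists is unambiguous
  units <- paste0("PLP", strrep("Q", 1:8))
  a <- tokenize_repeats(paste(units, collapse = ""))
  ident <- align_motif_lists(a, a)
  expect_identical(ident$conservation, 1)
  expect_identical(nrow(ident$pairs), length(a))

  b <- a[-c(3, 6)] # two internal motifs deleted
  al <- align_motif_lists(a, b)
  expect_identical(al$unmatched_a, c(3L, 6L))
  expect_length(al$unmatched_b, 0L)
  expect_equal(al$conservation, 6 / 8)
})

test_that("motif alignment length agrees with exhaustive enumeration", {
  match_fn <- function(x, y) {
    nchar(x) == nchar(y) &&
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]) <= 1
  }
  set.seed(23)
  pool <- c("PLPQQ", "PFPQQ", "PLPQQQ", "SFPQQ", "PFPQ", "PQQ")
  for (i in 1:10) {
    sa <- sample(pool, sample(2:6, 1), replace = TRUE)
    sb <- sample(pool, sample(2:6, 1), replace = TRUE)
    mk <- function(ss) {
      lapply(seq_along(ss), function(k) {
        structure(
          list(
            residues = ss[k], start = 0L, canonical = TRUE,
            variant_of = NA_character_
          ),
          class = "prl_motif_token"
        )
      })
    }
    al <- align_motif_lists(mk(sa), mk(sb))
    expect_identical(
      nrow(al$pairs), oracle_lcs_length(sa, sb, match_fn),
      info = paste(paste(sa, collapse = ","), "|", paste(sb, collapse = ","))
    )
  }
})

test_that("motif alignment is symmetric under argument swap", {
  dom1 <- with_seed(24, paste(
    vapply(1:6, function(i) prolaminr:::sample_motif(delta_sets), ""),
    collapse = ""
  ))
  dom2 <- with_seed(25, paste(
    vapply(1:5, function(i) prolaminr:::sample_motif(delta_sets), ""),
    collapse = ""
  ))
  a <- tokenize_repeats(dom1)
  b <- tokenize_repeats(dom2)
  ab <- align_motif_lists(a, b)
  ba <- align_motif_lists(b, a)
  expect_identical(unname(ab$pairs[, 1]), unname(ba$pairs[, 2]))
  expect_identical(unname(ab$pairs[, 2]), unname(ba$pairs[, 1]))
  expect_identical(ab$unmatched_a, ba$unmatched_b)
  expect_identical(ab$unmatched_b, ba$unmatched_a)
  expect_identical(ab$conservation, ba$conservation)
  expect_gte(ab$conservation, 0)
  expect_lte(ab$conservation, 1)
})

test_that("repeat cysteines are found exactly where a string scan finds C", {
  g <- build_gene(prolamin_grammar("delta"), 10, seed = 5)
  ii <- g$domain_map["II", ]
  dom <- substr(g$protein$residues, ii["start"] + 1, ii["end"])
  expect_length(find_repeat_cysteines(tokenize_repeats(dom)), 0L)

  injected <- paste0(substr(dom, 1, 7), "C", substr(dom, 9, nchar(dom)))
  toks <- tokenize_repeats(injected)
  pos <- find_repeat_cysteines(toks)
  scan <- which(strsplit(injected, "")[[1]] == "C") - 1L
  expect_identical(pos, scan)
  expect_identical(pos, 7L)
})
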