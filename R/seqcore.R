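#' @import methods
#' @importFrom stats setNames
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M", "F",
  "P", "S", "T", "W", "Y", "V", "X", "*"
)

#' Create a sequence record
#'
#' Lightweight container used throughout the package: an id, the residue
#' string (uppercase), and the alphabet kind. DNA is restricted to A/C/G/T/N;
#' protein to the 20 amino acids plus X (unknown) and `*` (stop). Ambiguity
#' codes beyond N are rejected rather than silently remapped.
#'
#' @param id Single non-empty string.
#' @param residues Non-empty residue string; lowercase accepted, stored
#'   uppercase.
#' @param kind `"dna"` or `"protein"`.
#' @return An object of class `prl_seq` with fields `id`, `residues`, `kind`.
#' @examples
#' seq_record("g1", "ATGCAACAA", "dna")
#' @export
seq_record <- function(id, residues, kind = c("dna", "protein")) {
  kind <- match.arg(kind)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("seq_record: 'id' must be a single non-empty string", call. = FALSE)
  }
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues)) {
    stop("seq_record: empty sequence for id '", id, "'", call. = FALSE)
  }
  residues <- toupper(residues)
  alpha <- if (kind == "dna") DNA_ALPHABET else AA_ALPHABET
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), alpha)
  if (length(bad)) {
    stop(
      "seq_record: characters outside the ", kind, " alphabet for id '", id,
      "': ", paste(bad, collapse = " "), call. = FALSE
    )
  }
  structure(list(id = id, residues = residues, kind = kind),
    class = "prl_seq"
  )
}

#' @export
print.prl_seq <- function(x, ...) {
  n <- nchar(x$residues)
  head <- substr(x$residues, 1L, 50L)
  cat(sprintf(
    "<prl_seq %s> %s, %d residues\n  %s%s\n", x$kind, x$id, n, head,
    if (n > 50L) "..." else ""
  ))
  invisible(x)
}

seq_len_res <- function(x) nchar(x$residues)

is_seq <- function(x) inherits(x, "prl_seq")

check_same_kind <- function(a, b) {
  if (!is_seq(a) || !is_seq(b)) {
    stop("expected prl_seq objects", call. = FALSE)
  }
  if (a$kind != b$kind) {
    stop("mixed alphabets: '", a$kind, "' vs '", b$kind, "'", call. = FALSE)
  }
  invisible(TRUE)
}

## Substitution matrices with N/X scored 0 against everything (identity-
## neutral columns, also neutral in the DP score).
dna_submat <- function(match, mismatch) {
  m <- matrix(mismatch, 5L, 5L, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

protein_submat <- function(match, mismatch) {
  m <- matrix(mismatch, 22L, 22L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(m) <- match
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

#' Default alignment scoring
#'
#' blastn-like DNA scoring (match +2, mismatch -3, gap open -5, gap extend
#' -2) and flat protein scoring (+1/-1, gap -2 per residue). A gap run of
#' length L costs `gap_open + L * gap_extend`. N (DNA) and X (protein) are
#' score- and identity-neutral.
#'
#' @param kind `"dna"` or `"protein"`.
#' @return List with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
default_scoring <- function(kind = c("dna", "protein")) {
  kind <- match.arg(kind)
  if (kind == "dna") {
    list(match = 2, mismatch = -3, gap_open = -5, gap_extend = -2)
  } else {
    list(match = 1, mismatch = -1, gap_open = 0, gap_extend = -2)
  }
}

alignment_stats <- function(ga, gb, kind) {
  ca <- strsplit(ga, "", fixed = TRUE)[[1L]]
  cb <- strsplit(gb, "", fixed = TRUE)[[1L]]
  gap_a <- ca == "-"
  gap_b <- cb == "-"
  neutral_chr <- if (kind == "dna") "N" else "X"
  neutral <- (ca == neutral_chr | cb == neutral_chr) & !gap_a & !gap_b
  both <- !gap_a & !gap_b & !neutral
  matches <- sum(both & ca == cb)
  mismatches <- sum(both & ca != cb)
  gap_runs <- function(g) {
    if (!length(g)) return(0L)
    sum(g & !c(FALSE, g[-length(g)]))
  }
  list(
    matches = matches,
    mismatches = mismatches,
    gap_opens = gap_runs(gap_a) + gap_runs(gap_b),
    gap_residues = sum(gap_a) + sum(gap_b),
    identity = if (matches + mismatches > 0) {
      matches / (matches + mismatches)
    } else {
      NA_real_
    }
  )
}

new_alignment <- function(ga, gb, score, kind) {
  st <- alignment_stats(ga, gb, kind)
  structure(
    c(list(gapped_a = ga, gapped_b = gb, score = score, kind = kind), st),
    class = "prl_alignment"
  )
}

#' @export
print.prl_alignment <- function(x, ...) {
  cat(sprintf(
    "<alignment> score %.1f, identity %.3f (%d match / %d mismatch, %d gap opens)\n",
    x$score, x$identity, x$matches, x$mismatches, x$gap_opens
  ))
  invisible(x)
}

pw_align <- function(a, b, scoring, type) {
  check_same_kind(a, b)
  if (!nzchar(a$residues) || !nzchar(b$residues)) {
    stop("empty sequence in alignment", call. = FALSE)
  }
  if (!is.list(scoring) || scoring$match <= scoring$mismatch) {
    stop("scoring must satisfy match > mismatch", call. = FALSE)
  }
  if (a$kind == "dna") {
    submat <- dna_submat(scoring$match, scoring$mismatch)
    xa <- Biostrings::DNAString(a$residues)
    xb <- Biostrings::DNAString(b$residues)
  } else {
    submat <- protein_submat(scoring$match, scoring$mismatch)
    xa <- Biostrings::AAString(a$residues)
    xb <- Biostrings::AAString(b$residues)
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = xa, subject = xb, type = type,
    substitutionMatrix = submat,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
  )
  pa
}

#' Optimal global pairwise alignment
#'
#' End-to-end (Needleman-Wunsch) alignment under affine gap scoring; a gap
#' run of length L costs `gap_open + L * gap_extend`. Deterministic for
#' fixed inputs. N/X columns count neither as matches nor mismatches.
#'
#' @param a,b `prl_seq` objects of the same kind.
#' @param scoring Scoring list as from [default_scoring()].
#' @return A `prl_alignment`: gapped strings, `score`, `matches`,
#'   `mismatches`, `gap_opens`, `gap_residues`, `identity`.
#' @examples
#' al <- align_global(seq_record("a", "ACGT", "dna"), seq_record("b", "ACGA", "dna"))
#' al$mismatches
#' @export
align_global <- function(a, b, scoring = default_scoring(a$kind)) {
  pa <- pw_align(a, b, scoring, "global")
  new_alignment(
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)),
    Biostrings::score(pa), a$kind
  )
}

#' Best local pairwise alignment
#'
#' Smith-Waterman alignment under the same scoring conventions as
#' [align_global()]. If no positive-scoring pair of substrings exists the
#' result is the empty alignment with score 0.
#'
#' @inheritParams align_global
#' @return A `prl_alignment`; additionally `start_a`/`start_b` give the
#'   0-based offsets of the aligned region in each input.
#' @export
align_local <- function(a, b, scoring = default_scoring(a$kind)) {
  pa <- pw_align(a, b, scoring, "local")
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    al <- new_alignment("", "", 0, a$kind)
    al$start_a <- NA_integer_
    al$start_b <- NA_integer_
    return(al)
  }
  al <- new_alignment(
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)),
    sc, a$kind
  )
  al$start_a <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  al$start_b <- Biostrings::start(Biostrings::subject(pa)) - 1L
  al
}

#' Read a multi-record FASTA file
#'
#' Residues are uppercased on read; duplicate ids get a numeric suffix with
#' a warning; zero-length records are an error. The id is the header token
#' before the first whitespace.
#'
#' @param path FASTA file.
#' @param kind `"dna"` or `"protein"`.
#' @return List of `prl_seq`.
#' @export
read_fasta <- function(path, kind = c("dna", "protein")) {
  kind <- match.arg(kind)
  xs <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(xs) == 0L)) {
    stop("read_fasta: empty record in '", path, "'", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(xs))
  if (anyDuplicated(ids)) {
    warning("read_fasta: duplicate ids in '", path, "', suffixing")
    ids <- make.unique(ids, sep = "_")
  }
  mapply(function(id, s) seq_record(id, s, kind),
    ids, as.character(xs),
    SIMPLIFY = FALSE, USE.NAMES = FALSE
  )
}

#' Write sequence records as FASTA
#'
#' @param seqs List of `prl_seq` (or a single one).
#' @param path Output file.
#' @param wrap Line width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap = 60L) {
  if (is_seq(seqs)) seqs <- list(seqs)
  xs <- Biostrings::BStringSet(vapply(seqs, function(s) s$residues, ""))
  names(xs) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(xs, path, width = as.integer(wrap))
  invisible(path)
}

#' Translate DNA in a fixed frame
#'
#' Standard genetic code; internal stops are emitted as `*`; a trailing
#' partial codon is dropped; any codon containing N translates to X.
#'
#' @param dna A DNA `prl_seq`.
#' @param frame 0, 1 or 2 (0-based offset into the sequence).
#' @return A protein `prl_seq` (id suffixed with `_aa`).
#' @examples
#' translate_dna(seq_record("x", "ATGCAACAA", "dna"))$residues # "MQQ"
#' @export
translate_dna <- function(dna, frame = 0L) {
  stopifnot(is_seq(dna), dna$kind == "dna")
  frame <- as.integer(frame)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  n <- seq_len_res(dna)
  if (n < 3L + frame) stop("sequence too short to translate", call. = FALSE)
  ncod <- (n - frame) %/% 3L
  sub <- substr(dna$residues, frame + 1L, frame + 3L * ncod)
  aa <- Biostrings::translate(Biostrings::DNAString(sub),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  )
  seq_record(paste0(dna$id, "_aa"), as.character(aa), "protein")
}

#' Reverse-translate a protein with random synonymous codons
#'
#' Used by the locus simulator: each residue gets a codon drawn from the
#' standard-code synonymous set. Glutamine uses CAA:CAG at `q_caa_weight:1`
#' (default 2:1), mirroring the CAA bias of prolamin polyglutamine runs.
#' Stops (`*`) become a uniformly drawn stop codon. Draws from the current
#' RNG state.
#'
#' @param protein A protein `prl_seq`.
#' @param q_caa_weight Relative weight of CAA vs CAG for glutamine.
#' @return A DNA `prl_seq` (id suffixed with `_dna`).
#' @export
reverse_translate <- function(protein, q_caa_weight = 2) {
  stopifnot(is_seq(protein), protein$kind == "protein")
  chars <- strsplit(protein$residues, "", fixed = TRUE)[[1L]]
  codons <- vapply(chars, function(aa) {
    if (aa == "Q") {
      sample(c("CAA", "CAG"), 1L, prob = c(q_caa_weight, 1))
    } else if (aa == "X") {
      "NNN"
    } else {
      opts <- CODON_BY_AA[[aa]]
      if (is.null(opts)) stop("no codon for residue ", aa, call. = FALSE)
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }
  }, "")
  seq_record(paste0(protein$id, "_dna"), paste(codons, collapse = ""), "dna")
}

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

CODON_BY_AA <- split(names(GENETIC_CODE_TABLE), GENETIC_CODE_TABLE)

#' Run an expression with a temporary RNG seed
#'
#' Seeds the Mersenne-Twister RNG, runs `expr`, and restores the caller's
#' RNG state, so seeded simulators do not disturb the session stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna_string <- function(s, rate) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
  }
  list(residues = paste(chars, collapse = ""), positions = hit)
}
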