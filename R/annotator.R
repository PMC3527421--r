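#' Detect inactivating defects against an intact reference
#'
#' Globally aligns query coding DNA to the reference coding DNA. Indels
#' whose length is not divisible by 3 are recorded as frameshifts; the
#' query is then translated codon-by-codon in the reference frame (each
#' reference codon reads the query bases aligned to its three positions,
#' so the frame is restored after every indel region and downstream stops
#' are not cascaded artifacts of a shift). A stop strictly before the final
#' five codons of the reference ORF is a premature stop. Positions are
#' reported in 0-based reference coordinates, so a defect catalogue applied
#' by [pseudogenize()] is recovered on the same scale.
#'
#' Status follows the defect list alone: any frameshift makes a
#' `pseudogene`; premature stops without frameshifts make an `inactivated`
#' gene; otherwise `intact`.
#'
#' @param dna Query coding DNA (`prl_seq`).
#' @param reference An intact `prl_gene` (or a DNA `prl_seq` of its CDS).
#' @return A `prl_status_report`: `status`, `defects` (list of [defect()]
#'   plus a `frameshift` flag on indels), `orf_span` (0-based half-open
#'   query coordinates through the first stop), `protein` (translation
#'   through the first stop), `full_translation` (notional reference-frame
#'   translation), `identity`.
#' @export
detect_defects <- function(dna, reference) {
  ref_dna <- if (inherits(reference, "prl_gene")) reference$dna else reference
  stopifnot(is_seq(dna), dna$kind == "dna", ref_dna$kind == "dna")
  # query aligned end-to-end, reference ends free: a truncated query (a
  # terminated contig) then maps onto the matching reference window
  # without phantom terminal indels
  sc <- default_scoring("dna")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(dna$residues),
    subject = Biostrings::DNAString(ref_dna$residues),
    type = "global-local",
    substitutionMatrix = dna_submat(sc$match, sc$mismatch),
    gapOpening = -sc$gap_open, gapExtension = -sc$gap_extend
  )
  al <- new_alignment(
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)),
    Biostrings::score(pa), "dna"
  )
  ref_offset <- Biostrings::start(Biostrings::subject(pa)) - 1L
  # homology gate: at least half of the query bases must match the
  # reference (identity over aligned columns alone stays deceptively high
  # for unrelated DNA once the aligner has gapped it)
  if (is.na(al$identity) || al$matches / seq_len_res(dna) < 0.5) {
    stop("query is not homologous to the reference (identity < 0.5)",
      call. = FALSE
    )
  }
  qc <- strsplit(al$gapped_a, "", fixed = TRUE)[[1L]]
  rc <- strsplit(al$gapped_b, "", fixed = TRUE)[[1L]]
  ncol_al <- length(qc)
  # coordinate maps: 0-based position of each column's base in query/ref
  qpos <- cumsum(qc != "-") - 1L
  rpos <- cumsum(rc != "-") - 1L + ref_offset

  defects <- list()
  # gap runs in the query row = deletions; in the reference row =
  # insertions. Runs touching either alignment end are truncation (an
  # incomplete query or reference), not indel defects, and are skipped.
  gap_runs <- function(gapped) {
    r <- rle(gapped == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & starts > 1L & ends < length(gapped)
    cbind(start = starts[keep], end = ends[keep])
  }
  for (run in split(gap_runs(qc), row(gap_runs(qc)))) {
    d <- defect("deletion", dna_position = rpos[run[1]], length = run[2] - run[1] + 1L)
    d$frameshift <- is_frameshift(d)
    defects[[length(defects) + 1L]] <- d
  }
  for (run in split(gap_runs(rc), row(gap_runs(rc)))) {
    pos <- if (run[1] > 1L) rpos[run[1] - 1L] + 1L else ref_offset
    d <- defect("insertion", dna_position = pos, length = run[2] - run[1] + 1L)
    d$frameshift <- is_frameshift(d)
    defects[[length(defects) + 1L]] <- d
  }

  # reference-frame translation: reference codon k reads the query bases
  # aligned to reference positions 3k, 3k+1, 3k+2
  nref <- seq_len_res(ref_dna)
  ncod <- nref %/% 3L
  qbase_at_ref <- rep(NA_character_, nref)
  qpos_at_ref <- rep(NA_integer_, nref)
  keep <- rc != "-" & qc != "-"
  qbase_at_ref[rpos[keep] + 1L] <- qc[keep]
  qpos_at_ref[rpos[keep] + 1L] <- qpos[keep]
  aa <- character(ncod)
  first_stop_cod <- NA_integer_
  for (k in seq_len(ncod)) {
    cod <- qbase_at_ref[(3L * k - 2L):(3L * k)]
    if (anyNA(cod)) {
      aa[k] <- "-"
      next
    }
    codon <- paste(cod, collapse = "")
    aa[k] <- if (grepl("N", codon, fixed = TRUE)) {
      "X"
    } else {
      unname(GENETIC_CODE_TABLE[codon])
    }
    if (identical(aa[k], "*") && is.na(first_stop_cod)) first_stop_cod <- k
  }
  premature <- which(aa == "*" & seq_len(ncod) < ncod - 5L)
  for (k in premature) {
    d <- defect("premature_stop", dna_position = 3L * (k - 1L))
    d$frameshift <- FALSE
    defects[[length(defects) + 1L]] <- d
  }
  defects <- defects[order(vapply(defects, function(d) d$dna_position, 0L))]

  orf_end <- if (length(premature)) {
    qpos_at_ref[3L * premature[1L]] + 1L
  } else {
    seq_len_res(dna)
  }
  if (is.na(orf_end)) orf_end <- seq_len_res(dna)
  aa_clean <- aa[aa != "-"]
  stop_at <- match("*", aa_clean)
  prot_through_stop <- paste(
    aa_clean[seq_len(if (is.na(stop_at)) length(aa_clean) else stop_at - 1L)],
    collapse = ""
  )
  structure(
    list(
      status = status_from_defects(defects),
      defects = defects,
      orf_span = c(0L, orf_end),
      protein = if (nzchar(prot_through_stop)) {
        seq_record(paste0(dna$id, "_orf"), prot_through_stop, "protein")
      } else {
        NULL
      },
      full_translation = seq_record(
        paste0(dna$id, "_aa"),
        paste(gsub("-", "X", aa, fixed = TRUE), collapse = ""), "protein"
      ),
      identity = al$identity
    ),
    class = "prl_status_report"
  )
}

#' @export
print.prl_status_report <- function(x, ...) {
  cat(sprintf(
    "<status %s> %d defect(s): %s\n", x$status, length(x$defects),
    if (length(x$defects)) {
      paste(vapply(x$defects, function(d) {
        sprintf(
          "%s@%d%s", d$type, d$dna_position,
          if (isTRUE(d$frameshift)) "(fs)" else ""
        )
      }, ""), collapse = ", ")
    } else {
      "none"
    }
  ))
  invisible(x)
}

MOTIF_REGEX <- "P[A-Z]{1,3}Q{1,6}"

#' Segment a prolamin protein into domains
#'
#' SIG is the grammar's fixed signal-peptide length. Domain II (the
#' repetitive domain) is located as the longest contiguous run of repeat
#' motif matches, screened by a sliding-window motif density (window 15,
#' threshold 0.6) and refined to motif boundaries. Domain I is whatever
#' lies between SIG and II. Domains III-V are anchored on the grammar's
#' cysteine layout: III runs from the end of II through its last layout
#' cysteine, V starts at the next cysteine and runs to the end, and the
#' glutamine-rich domain IV is the gap between them. With no repetitive
#' window the map degenerates (SIG and I only, with a warning).
#'
#' @param protein A protein `prl_seq`.
#' @param grammar The class [prolamin_grammar()].
#' @return 6 x 2 integer matrix (rows SIG, I, II, III, IV, V; columns
#'   start, end), 0-based half-open protein coordinates.
#' @export
segment_domains <- function(protein, grammar,
                            window = 15L, min_density = 0.6) {
  stopifnot(is_seq(protein), protein$kind == "protein")
  n <- seq_len_res(protein)
  sig <- min(grammar$signal_len, n)
  if (n <= sig) stop("protein shorter than the signal peptide", call. = FALSE)
  s <- protein$residues

  m <- gregexpr(MOTIF_REGEX, s)[[1L]]
  covered <- rep(FALSE, n)
  hits <- NULL
  if (m[1L] != -1L) {
    len <- attr(m, "match.length")
    keep <- m > sig # motifs begin after the signal peptide
    hits <- cbind(start = as.integer(m[keep]), len = len[keep])
    for (i in seq_len(nrow(hits))) {
      covered[hits[i, 1]:(hits[i, 1] + hits[i, 2] - 1L)] <- TRUE
    }
  }
  dens_ok <- FALSE
  if (n >= window) {
    cs <- cumsum(c(0L, covered))
    dens <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
    dens_ok <- any(dens >= min_density)
  }
  if (is.null(hits) || nrow(hits) == 0L || !dens_ok) {
    warning("no repetitive window found; domains II-V are empty")
    lens <- c(SIG = sig, I = n - sig, II = 0L, III = 0L, IV = 0L, V = 0L)
    return(domain_matrix(lens))
  }

  # longest contiguous chain of adjacent motif matches
  ends <- hits[, 1] + hits[, 2]
  chain <- c(0L, cumsum(hits[-1L, 1] != ends[-nrow(hits)]))
  best <- as.integer(names(which.max(tapply(hits[, 2], chain, sum))))
  sel <- which(chain == best)
  ii_start <- unname(hits[sel[1L], 1]) - 1L # to 0-based
  ii_end <- unname(ends[sel[length(sel)]]) - 1L

  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  cys <- which(chars == "C") - 1L
  cys <- cys[cys >= ii_end]
  n3 <- grammar$cys_layout[["III"]]
  n5 <- grammar$cys_layout[["V"]]
  if (n3 + n5 == 0L) {
    lens <- c(
      SIG = sig, I = ii_start - sig, II = ii_end - ii_start,
      III = 0L, IV = 0L, V = n - ii_end
    )
    return(domain_matrix(lens))
  }
  if (length(cys) < n3 + 1L) {
    stop("too few cysteines after the repetitive domain for this grammar",
      call. = FALSE
    )
  }
  iii_end <- cys[n3] + 1L
  v_start <- cys[n3 + 1L]
  lens <- c(
    SIG = sig, I = ii_start - sig, II = ii_end - ii_start,
    III = iii_end - ii_end, IV = v_start - iii_end, V = n - v_start
  )
  domain_matrix(lens)
}

#' Census cysteines by domain
#'
#' Counts cysteines and reports their 0-based positions per domain. An odd
#' total flags a candidate for intermolecular disulfide bonding (a gluten
#' polymer chain extender/terminator); the conserved even count of the
#' delta-gliadins leaves no cysteine free for such bonds.
#'
#' @param protein A protein `prl_seq`.
#' @param domains Domain matrix from [segment_domains()] (or a gene's
#'   ground-truth `domain_map`).
#' @return List: `count`, `positions` (0-based), `per_domain` (named list),
#'   `parity` ("even"/"odd"), `polymer_flag` (TRUE iff odd).
#' @export
census_cysteines <- function(protein, domains) {
  stopifnot(is_seq(protein), protein$kind == "protein")
  chars <- strsplit(protein$residues, "", fixed = TRUE)[[1L]]
  pos <- which(chars == "C") - 1L
  per <- lapply(rownames(domains), function(d) {
    pos[pos >= domains[d, "start"] & pos < domains[d, "end"]]
  })
  names(per) <- rownames(domains)
  n <- length(pos)
  list(
    count = n, positions = pos, per_domain = per,
    parity = if (n %% 2L == 0L) "even" else "odd",
    polymer_flag = n %% 2L == 1L
  )
}
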