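#' Remove the repetitive domain from a protein
#'
#' Fast-changing tandem repeats mislead alignment (proline/glutamine
#' prevalence creates false matches), so trees are built on the
#' concatenation of SIG + I + III + IV + V only. Stripping is idempotent.
#'
#' @param protein A protein `prl_seq`.
#' @param domains Domain matrix ([segment_domains()] or ground truth).
#' @return A protein `prl_seq` without domain II.
#' @export
strip_repeats <- function(protein, domains) {
  stopifnot(is_seq(protein), protein$kind == "protein")
  s <- protein$residues
  ii <- domains["II", ]
  if (ii["end"] <= ii["start"]) {
    return(protein)
  }
  out <- paste0(substr(s, 1L, ii["start"]), substr(s, ii["end"] + 1L, nchar(s)))
  seq_record(protein$id, out, protein$kind)
}

#' Pairwise p-distance matrix
#'
#' Globally aligns every pair and takes the fraction of differing residues
#' among comparable columns (both non-gap, neither N/X). Any pair with
#' fewer than 10 comparable columns is an error (unreliable distance).
#'
#' @param seqs List of `prl_seq` (>= 3, same kind).
#' @return A `prl_distmat`: `labels`, `d` (symmetric matrix, zero
#'   diagonal).
#' @export
p_distance_matrix <- function(seqs) {
  if (length(seqs) < 3L) stop("need at least 3 sequences", call. = FALSE)
  labels <- vapply(seqs, function(s) s$id, "")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- align_global(seqs[[i]], seqs[[j]])
      comparable <- al$matches + al$mismatches
      if (comparable < 10L) {
        stop(
          "unreliable distance: only ", comparable,
          " comparable columns between '", labels[i], "' and '",
          labels[j], "'",
          call. = FALSE
        )
      }
      d[i, j] <- d[j, i] <- al$mismatches / comparable
    }
  }
  structure(list(labels = labels, d = d), class = "prl_distmat")
}

#' Neighbor-joining tree rooted on an outgroup
#'
#' Standard neighbor-joining agglomeration on a distance matrix, rooted on
#' the outgroup's pendant edge. Negative branch-length estimates are
#' clamped to zero with a warning.
#'
#' @param m A `prl_distmat` (or a plain symmetric matrix with dimnames).
#' @param outgroup A leaf label.
#' @return An [ape::ape-package] `phylo` object (rooted).
#' @export
nj_tree <- function(m, outgroup) {
  d <- if (inherits(m, "prl_distmat")) m$d else m
  if (nrow(d) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (!outgroup %in% rownames(d)) {
    stop("outgroup '", outgroup, "' not among labels", call. = FALSE)
  }
  tr <- ape::nj(d)
  tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

tree_clades <- function(tree) {
  # tip-label sets of every edge bipartition (rooted clades incl. tips)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  clades <- lapply(pp, function(idx) labs[idx])
  c(clades, as.list(labs))
}

#' Test whether a label set forms a clade
#'
#' Root-independent: true iff some edge bipartition of the tree separates
#' exactly the given labels from the rest. Also reports the smallest clade
#' (of the rooted tree) containing all the labels.
#'
#' @param tree A `phylo` object.
#' @param labels Character vector of tip labels.
#' @return List: `monophyletic` (logical), `clade` (tip labels of the
#'   smallest containing clade).
#' @export
monophyly_check <- function(tree, labels) {
  tips <- tree$tip.label
  unknown <- setdiff(labels, tips)
  if (length(unknown)) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  labels <- unique(labels)
  clades <- tree_clades(tree)
  is_split <- any(vapply(clades, function(cl) {
    setequal(cl, labels) || setequal(cl, setdiff(tips, labels))
  }, TRUE))
  containing <- Filter(function(cl) all(labels %in% cl), c(clades, list(tips)))
  smallest <- containing[[which.min(lengths(containing))]]
  list(monophyletic = is_split, clade = sort(smallest))
}

#' Clade-diagnostic residues in an aligned block
#'
#' A column is diagnostic for group A iff a single residue is shared by
#' every member of A and occurs in no member of B (and symmetrically for
#' B). Group-exclusive indel blocks are maximal runs of columns gapped in
#' all of one group and none of the other.
#'
#' @param block Named character vector (or list of `prl_seq`) of aligned
#'   sequences, all the same length; `-` marks gaps.
#' @param group_a,group_b Disjoint sets of sequence names.
#' @return List: `columns` (data frame: column (0-based), group, residue),
#'   `indel_blocks` (data frame: start, end (0-based half-open), group,
#'   gapped_in).
#' @export
diagnostic_residues <- function(block, group_a, group_b) {
  if (is.list(block)) {
    block <- stats::setNames(
      vapply(block, function(s) s$residues, ""),
      vapply(block, function(s) s$id, "")
    )
  }
  if (length(unique(nchar(block))) != 1L) {
    stop("ragged alignment", call. = FALSE)
  }
  if (length(intersect(group_a, group_b))) {
    stop("groups overlap", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), names(block))
  if (length(missing)) {
    stop("sequences not in block: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  mat <- do.call(rbind, strsplit(block[c(group_a, group_b)], "", fixed = TRUE))
  rownames(mat) <- c(group_a, group_b)
  ncols <- ncol(mat)
  a <- mat[group_a, , drop = FALSE]
  b <- mat[group_b, , drop = FALSE]

  cols <- list()
  for (j in seq_len(ncols)) {
    ua <- unique(a[, j])
    ub <- unique(b[, j])
    if (length(ua) == 1L && ua != "-" && !(ua %in% ub)) {
      cols[[length(cols) + 1L]] <- data.frame(
        column = j - 1L, group = "a", residue = ua, stringsAsFactors = FALSE
      )
    }
    if (length(ub) == 1L && ub != "-" && !(ub %in% ua)) {
      cols[[length(cols) + 1L]] <- data.frame(
        column = j - 1L, group = "b", residue = ub, stringsAsFactors = FALSE
      )
    }
  }
  columns <- if (length(cols)) {
    do.call(rbind, cols)
  } else {
    data.frame(
      column = integer(0), group = character(0), residue = character(0)
    )
  }

  gap_a <- apply(a == "-", 2L, all) & !apply(b == "-", 2L, any)
  gap_b <- apply(b == "-", 2L, all) & !apply(a == "-", 2L, any)
  run_blocks <- function(flag, grp) {
    if (!any(flag)) {
      return(NULL)
    }
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(
      start = starts[r$values] - 1L, end = ends[r$values],
      group = grp, gapped_in = grp, stringsAsFactors = FALSE
    )
  }
  blocks <- rbind(run_blocks(gap_a, "a"), run_blocks(gap_b, "b"))
  if (is.null(blocks)) {
    blocks <- data.frame(
      start = integer(0), end = integer(0), group = character(0),
      gapped_in = character(0)
    )
  }
  list(columns = columns, indel_blocks = blocks)
}

#' Assign a query sequence to a genome by mismatch counting
#'
#' Globally aligns the query over its span to every reference (query ends
#' are free in the reference), counts base mismatches per reference, and
#' assigns the query to the reference with the fewest. In-frame 3-base
#' indels whose absent bases form a glutamine codon (CAA/CAG) inside a run
#' of three or more glutamine codons are tallied separately as
#' polyglutamine codon events, not as mismatches or plain gaps: repeat-run
#' slippage is scored as a single codon-level event.
#'
#' @param query A DNA `prl_seq` (e.g. a partial cDNA or diploid consensus).
#' @param refs Named list of DNA `prl_seq` (>= 2), names = genome labels.
#' @return A `prl_genome_assignment`: `query`, `mismatch_counts`,
#'   `codon_indel_counts`, `other_gap_bases`, `aligned_span`, `assigned`
#'   (label, or `"ambiguous"` with `tied` labels on a tie).
#' @export
assign_genome <- function(query, refs) {
  if (length(refs) < 2L || is.null(names(refs))) {
    stop("need >= 2 named references", call. = FALSE)
  }
  labels <- names(refs)
  mism <- stats::setNames(integer(length(refs)), labels)
  qindel <- stats::setNames(integer(length(refs)), labels)
  gapb <- stats::setNames(integer(length(refs)), labels)
  span <- stats::setNames(integer(length(refs)), labels)
  for (lab in labels) {
    sc <- default_scoring("dna")
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(query$residues),
      subject = Biostrings::DNAString(refs[[lab]]$residues),
      type = "global-local",
      substitutionMatrix = dna_submat(sc$match, sc$mismatch),
      gapOpening = -sc$gap_open, gapExtension = -sc$gap_extend
    )
    ga <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    gb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    both <- ga != "-" & gb != "-" & ga != "N" & gb != "N"
    mism[lab] <- sum(both & ga != gb)
    span[lab] <- sum(ga != "-")
    # classify gap runs
    res <- classify_gap_runs(ga, gb)
    qindel[lab] <- res$codon_indels
    gapb[lab] <- res$other_gap_bases
  }
  best <- min(mism)
  winners <- labels[mism == best]
  structure(
    list(
      query = query$id, mismatch_counts = mism,
      codon_indel_counts = qindel, other_gap_bases = gapb,
      aligned_span = span,
      assigned = if (length(winners) == 1L) winners else "ambiguous",
      tied = if (length(winners) > 1L) winners else NULL
    ),
    class = "prl_genome_assignment"
  )
}

# A 3-base gap whose absent bases read CAA/CAG, sitting inside a run of
# >= 3 glutamine codons of the ungapped strand, is one codon event.
classify_gap_runs <- function(ga, gb) {
  codon_indels <- 0L
  other <- 0L
  for (side in 1:2) {
    g <- if (side == 1L) ga else gb
    o <- if (side == 1L) gb else ga
    r <- rle(g == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    oseq <- paste(o[o != "-"], collapse = "")
    qruns <- gregexpr("(CAA|CAG){3,}", oseq)[[1L]]
    for (k in which(r$values)) {
      len <- r$lengths[k]
      if (len == 3L) {
        # 0-based position of the absent bases in the ungapped strand;
        # the aligner may slide a gap within a glutamine-codon run, so
        # the test is containment in a (CAA|CAG){3,} run, not the
        # phase of the gap itself
        opos <- sum(o[seq_len(starts[k] - 1L)] != "-")
        # two bases of slack on each side: the repeat context lets the
        # aligner slide the gap slightly off the run's codon phase
        in_qrun <- qruns[1L] != -1L && any(
          opos + 1L >= qruns - 2L &
            opos + 3L <= qruns + attr(qruns, "match.length") + 1L
        )
        if (in_qrun) {
          codon_indels <- codon_indels + 1L
          next
        }
      }
      other <- other + len
    }
  }
  list(codon_indels = codon_indels, other_gap_bases = other)
}

#' @export
print.prl_genome_assignment <- function(x, ...) {
  cat(sprintf(
    "<genome assignment %s> -> %s | mismatches: %s | Q-codon indels: %s\n",
    x$query, x$assigned,
    paste(sprintf("%s=%d", names(x$mismatch_counts), x$mismatch_counts),
      collapse = " "
    ),
    paste(sprintf("%s=%d", names(x$codon_indel_counts), x$codon_indel_counts),
      collapse = " "
    )
  ))
  invisible(x)
}
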