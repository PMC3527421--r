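#' Assembler configuration
#'
#' Defaults formalize the manual read-set separation of the source screen:
#' 98% identity over at least 40 bp joins a read to a growing cluster, so
#' ~2% ortholog divergence separates copies while sub-percent sequencing
#' noise does not. `min_reads` is the reporting floor: a consensus must be
#' supported by at least two overlapping reads, otherwise the read is left
#' unplaced.
#'
#' @param min_identity Join threshold on overlap identity.
#' @param min_overlap Minimum overlap with the cluster consensus, bases.
#' @param max_rounds Maximum eviction/re-placement rounds in [assemble()].
#' @param min_reads Minimum supporting reads for a reported contig.
#' @param mismatch_floor Absolute mismatch allowance on short overlaps
#'   (noise tolerance; see Details).
#' @return Named list of settings.
#' @export
assembler_config <- function(min_identity = 0.98, min_overlap = 40L,
                             max_rounds = 5L, min_reads = 2L,
                             mismatch_floor = 2L) {
  stopifnot(min_identity > 0, min_identity <= 1, min_overlap >= 1)
  list(
    min_identity = min_identity, min_overlap = as.integer(min_overlap),
    max_rounds = as.integer(max_rounds), min_reads = as.integer(min_reads),
    mismatch_floor = as.integer(mismatch_floor)
  )
}

BASES <- c("A", "C", "G", "T", "N")

read_chars <- function(r) {
  s <- if (inherits(r, "prl_read")) r$dna$residues else r$residues
  strsplit(s, "", fixed = TRUE)[[1L]]
}

read_id <- function(r) if (inherits(r, "prl_read")) r$id else r$id

## A cluster is a plain list: seed_read, ids, offsets (0-based column of
## each read's first base), lens, votes (5 x L integer matrix, rows BASES),
## cons (char vector, length L). Layouts are gapless: reads are placed at
## integer offsets, which is exact for substitution-only divergence.
new_cluster <- function(id, chars) {
  L <- length(chars)
  votes <- matrix(0L, 5L, L, dimnames = list(BASES, NULL))
  votes[cbind(match(chars, BASES), seq_len(L))] <- 1L
  list(
    seed_read = id, ids = id, offsets = 0L, lens = L,
    votes = votes, cons = chars
  )
}

majority_base <- function(votes_col) {
  acgt <- votes_col[1:4]
  if (all(acgt == 0L)) {
    return("N")
  }
  BASES[which.max(acgt)] # ties resolve to the first base in A,C,G,T order
}

recompute_cons <- function(cl, cols) {
  for (j in cols) cl$cons[j] <- majority_base(cl$votes[, j])
  cl
}

## Candidate placement offsets of a read against the cluster consensus via
## shared k-mer seeding; returns offsets ordered by supporting probe count.
candidate_offsets <- function(cl, chars, k = 14L, stride = 17L, top = 4L) {
  lr <- length(chars)
  if (lr < k) {
    return(integer(0))
  }
  cons_str <- paste(cl$cons, collapse = "")
  probes <- unique(c(seq(1L, lr - k + 1L, by = stride), lr - k + 1L))
  offs <- integer(0)
  for (p in probes) {
    kmer <- paste(chars[p:(p + k - 1L)], collapse = "")
    hit <- gregexpr(kmer, cons_str, fixed = TRUE)[[1L]]
    if (hit[1L] != -1L) offs <- c(offs, hit - p)
  }
  if (!length(offs)) {
    return(integer(0))
  }
  tab <- sort(table(offs), decreasing = TRUE)
  utils::head(as.integer(names(tab)), top)
}

overlap_identity <- function(cl, chars, off) {
  L <- length(cl$cons)
  lr <- length(chars)
  s <- max(0L, off)
  e <- min(L, off + lr)
  if (e - s <= 0L) {
    return(list(ov = 0L, identity = NA_real_, mismatches = NA_integer_))
  }
  rseg <- chars[(s - off + 1L):(e - off)]
  cseg <- cl$cons[(s + 1L):e]
  comp <- rseg != "N" & cseg != "N"
  m <- sum(comp & rseg == cseg)
  mm <- sum(comp & rseg != cseg)
  list(
    ov = e - s, identity = if (m + mm > 0L) m / (m + mm) else NA_real_,
    mismatches = mm,
    s = s, e = e, rseg = rseg, cseg = cseg, comp = comp
  )
}

## Mismatch acceptance: the identity ratio sets the allowance on long
## overlaps, but a short overlap against a depth-1 consensus carries
## read + seed error noise (~1% combined), so a flat ratio would reject
## legitimate joins there. A small absolute floor (default 2, the ~99th
## percentile of the noise mismatch count on sub-200 bp overlaps) keeps
## noise from blocking joins while true 2% copy divergence still separates
## through the ratio and the diagnostic-column conflict test.
accept_overlap <- function(ov, config) {
  if (ov$ov < config$min_overlap || is.na(ov$identity)) {
    return(FALSE)
  }
  comparable <- sum(ov$comp)
  allowed <- max(
    config$mismatch_floor,
    (1 - config$min_identity) * comparable
  )
  ov$mismatches <= allowed
}

## Diagnostic-column conflict: adding this read would create columns where
## two different bases each have >= 2 supporting reads -- the signature of
## two distinguishable read sets collapsed into one. A single such column
## can arise from two coincident sequencing errors, so the trigger requires
## the pattern at two or more columns: true copy divergence marks many
## columns consistently, coincident errors mark one.
has_conflict <- function(cl, ov, min_cols = 2L) {
  if (ov$ov == 0L) {
    return(FALSE)
  }
  cols <- (ov$s + 1L):ov$e
  dis <- which(ov$comp & ov$rseg != ov$cseg)
  n_hit <- 0L
  for (i in dis) {
    j <- cols[i]
    b <- ov$rseg[i]
    if (b == "N") next
    support <- cl$votes[b, j] + 1L
    other <- max(cl$votes[setdiff(BASES[1:4], b), j])
    if (support >= 2L && other >= 2L) {
      n_hit <- n_hit + 1L
      if (n_hit >= min_cols) {
        return(TRUE)
      }
    }
  }
  FALSE
}

add_read_at <- function(cl, id, chars, off) {
  lr <- length(chars)
  if (off < 0L) {
    pad <- -off
    cl$votes <- cbind(
      matrix(0L, 5L, pad, dimnames = list(BASES, NULL)),
      cl$votes
    )
    cl$cons <- c(rep("N", pad), cl$cons)
    cl$offsets <- cl$offsets + pad
    off <- 0L
  }
  L <- length(cl$cons)
  if (off + lr > L) {
    pad <- off + lr - L
    cl$votes <- cbind(
      cl$votes,
      matrix(0L, 5L, pad, dimnames = list(BASES, NULL))
    )
    cl$cons <- c(cl$cons, rep("N", pad))
  }
  cols <- (off + 1L):(off + lr)
  idx <- cbind(match(chars, BASES), cols)
  cl$votes[idx] <- cl$votes[idx] + 1L
  cl$ids <- c(cl$ids, id)
  cl$offsets <- c(cl$offsets, off)
  cl$lens <- c(cl$lens, lr)
  recompute_cons(cl, cols)
}

## Best acceptable placement of a read on one cluster (no mutation):
## list(off, identity) or NULL.
## Mismatches at columns where the consensus base is established by >= 2
## reads: real copy divergence shows here, single-read noise does not.
established_mismatches <- function(cl, ov) {
  cols <- (ov$s + 1L):ov$e
  dis <- which(ov$comp & ov$rseg != ov$cseg)
  n <- 0L
  for (k in dis) {
    if (cl$votes[ov$cseg[k], cols[k]] >= 2L) n <- n + 1L
  }
  n
}

eval_join <- function(cl, chars, config) {
  best <- NULL
  L <- length(cl$cons)
  lr <- length(chars)
  for (off in candidate_offsets(cl, chars)) {
    ov <- overlap_identity(cl, chars, off)
    if (!accept_overlap(ov, config)) next
    if (has_conflict(cl, ov)) next
    # a read EXTENDING the layout commits the cluster to new sequence on
    # the evidence of one overlap; when that overlap is short the identity
    # ratio cannot tell ~2% copy divergence from read noise, so short
    # extension joins must be clean at every established column (the
    # two-independent-reads, 100%-match extension standard applied at the
    # membership level). Long overlaps are discriminative on their own.
    if ((off < 0L || off + lr > L) && ov$ov < 150L &&
      established_mismatches(cl, ov) > 0L) {
      next
    }
    if (is.null(best) || ov$identity > best$identity) {
      best <- list(off = off, identity = ov$identity)
    }
  }
  best
}

## Place a read on the best-identity qualifying cluster (ties keep the
## earlier cluster in size/seed order); returns the updated cluster list
## or NULL if nothing qualifies.
place_read <- function(clusters, id, chars, config) {
  if (!length(clusters)) {
    return(NULL)
  }
  ord <- order(
    -vapply(clusters, function(cl) length(cl$ids), 0L),
    vapply(clusters, function(cl) cl$seed_read, "")
  )
  best_ci <- 0L
  best <- NULL
  for (ci in ord) {
    cand <- eval_join(clusters[[ci]], chars, config)
    if (!is.null(cand) &&
      (is.null(best) || cand$identity > best$identity)) {
      best <- cand
      best_ci <- ci
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  clusters[[best_ci]] <- add_read_at(clusters[[best_ci]], id, chars, best$off)
  clusters[[best_ci]]$.chars[[id]] <- chars
  clusters
}

rebuild_cluster <- function(cl) {
  # rebuild votes/consensus directly from the stored gapless layout
  base <- min(cl$offsets)
  L <- max(cl$offsets + cl$lens) - base
  votes <- matrix(0L, 5L, L, dimnames = list(BASES, NULL))
  for (i in seq_along(cl$ids)) {
    chars <- cl$.chars[[cl$ids[i]]]
    cols <- (cl$offsets[i] - base + 1L):(cl$offsets[i] - base + cl$lens[i])
    idx <- cbind(match(chars, BASES), cols)
    votes[idx] <- votes[idx] + 1L
  }
  cl$offsets <- cl$offsets - base
  cl$votes <- votes
  cl$cons <- vapply(seq_len(L), function(j) majority_base(votes[, j]), "")
  cl$seed_read <- cl$ids[which.max(cl$lens)]
  cl
}

## Consensus-level conflict between two clusters at a given donor offset:
## columns where both clusters have an established (>= 2 reads) majority
## base and the bases differ. Majority consensus absorbs single-read
## errors, so even one such column is evidence of two distinguishable
## copies and blocks the merge.
consensus_conflict <- function(acc, don, off, min_cols = 1L) {
  La <- length(acc$cons)
  Ld <- length(don$cons)
  s <- max(0L, off)
  e <- min(La, off + Ld)
  if (e <= s) {
    return(FALSE)
  }
  a_cols <- (s + 1L):e
  d_cols <- (s - off + 1L):(e - off)
  a_top <- apply(acc$votes[1:4, a_cols, drop = FALSE], 2L, max)
  d_top <- apply(don$votes[1:4, d_cols, drop = FALSE], 2L, max)
  both <- a_top >= 2L & d_top >= 2L
  if (!any(both)) {
    return(FALSE)
  }
  differ <- acc$cons[a_cols] != don$cons[d_cols]
  sum(both & differ) >= min_cols
}

## Split a cluster using another cluster's consensus as a witness. At the
## columns where both clusters hold established, discordant majorities,
## every member reveals which copy it came from: members siding with the
## witness form one block, members siding with their own consensus the
## other. A pure cluster has no members on the witness side and is left
## untouched; only a genuinely mixed (chimeric) layout separates.
split_by_witness <- function(acc, don, off, junction_max = 150L) {
  La <- length(acc$cons)
  Ld <- length(don$cons)
  s <- max(0L, off)
  e <- min(La, off + Ld)
  if (e <= s) {
    return(NULL)
  }
  a_cols <- (s + 1L):e
  d_top <- apply(
    don$votes[1:4, (s - off + 1L):(e - off), drop = FALSE], 2L, max
  )
  witnessed <- a_cols[d_top >= 2L]
  if (length(witnessed) < 2L) {
    return(NULL)
  }
  don_at <- don$cons[witnessed - off]
  mism <- integer(length(acc$ids))
  for (i in seq_along(acc$ids)) {
    p <- witnessed - acc$offsets[i]
    inside <- p >= 1L & p <= acc$lens[i]
    if (!any(inside)) next
    mism[i] <- sum(acc$.chars[[acc$ids[i]]][p[inside]] != don_at[inside])
  }
  conflict <- which(mism >= 2L)
  rest <- setdiff(seq_along(acc$ids), conflict)
  if (!length(conflict) || !length(rest)) {
    return(NULL)
  }
  # only split at a thin junction: if any conflicting read overlaps a
  # non-conflicting one deeply they are fragments of one copy (a foreign
  # read could never have joined across a deep overlap), so leave intact
  st <- acc$offsets
  en <- acc$offsets + acc$lens
  junction <- 0L
  for (ci in conflict) {
    for (ri in rest) {
      junction <- max(junction, min(en[ci], en[ri]) - max(st[ci], st[ri]))
    }
  }
  if (junction >= junction_max) {
    return(NULL)
  }
  part1 <- drop_members(acc, conflict)
  part2 <- drop_members(acc, rest)
  c(
    if (!is.null(part1)) split_components(part1),
    if (!is.null(part2)) split_components(part2)
  )
}

drop_members <- function(cl, idx) {
  if (!length(idx)) {
    return(cl)
  }
  cl$ids <- cl$ids[-idx]
  cl$offsets <- cl$offsets[-idx]
  cl$lens <- cl$lens[-idx]
  cl$.chars <- cl$.chars[cl$ids]
  if (!length(cl$ids)) {
    return(NULL)
  }
  rebuild_cluster(cl)
}

## Merge acceptance with noise-aware allowance. Columns established on
## both sides (>= 2 reads each) are majority-corrected, so mismatches
## there reflect copy divergence and get the identity-ratio allowance.
## Columns thin on either side still carry raw read error, so they get a
## Poisson upper quantile of the expected noise count. Without this, two
## fragments of one copy meeting across low-depth ends are kept apart by
## their own sequencing errors.
accept_merge <- function(acc, don, ov, off, config, noise_rate = 0.01) {
  if (ov$ov < config$min_overlap || is.na(ov$identity)) {
    return(FALSE)
  }
  a_cols <- (ov$s + 1L):ov$e
  d_cols <- (ov$s - off + 1L):(ov$e - off)
  a_top <- apply(acc$votes[1:4, a_cols, drop = FALSE], 2L, max)
  d_top <- apply(don$votes[1:4, d_cols, drop = FALSE], 2L, max)
  estab <- sum(a_top >= 2L & d_top >= 2L)
  thin <- sum(ov$comp) - estab
  allowed <- max(
    config$mismatch_floor,
    (1 - config$min_identity) * estab +
      stats::qpois(0.995, noise_rate * max(0L, thin))
  )
  ov$mismatches <= allowed
}

## One merge pass: try to fold each cluster (smallest first) into a larger
## one whose consensus it matches. This is the reassembly step: consensus
## vs consensus comparison averages out read errors that can keep two
## fragments of the same copy apart at the read level. A merge blocked by
## established discordant columns triggers relocation: the acceptor
## members that side with those columns are re-placed into whichever other
## cluster accepts them (a chimeric block fits its true copy elsewhere; a
## pure cluster's members fit nowhere else and nothing moves).
merge_pass <- function(clusters, config) {
  if (length(clusters) < 2L) {
    return(list(clusters = clusters, merged = FALSE))
  }
  sizes <- vapply(clusters, function(cl) length(cl$ids), 0L)
  for (di in order(sizes, vapply(clusters, function(cl) cl$seed_read, ""))) {
    don <- clusters[[di]]
    # evaluate every possible acceptor and keep the best-identity merge:
    # a thin overlap with a near-identical copy must not outrank a deeper,
    # cleaner overlap with the cluster's true continuation
    best <- NULL
    best_ai <- 0L
    blocked <- list()
    for (ai in order(-sizes, vapply(clusters, function(cl) cl$seed_read, ""))) {
      if (ai == di || sizes[ai] < sizes[di]) next
      acc <- clusters[[ai]]
      for (off in candidate_offsets(acc, don$cons)) {
        ov <- overlap_identity(acc, don$cons, off)
        if (ov$ov < config$min_overlap) next
        if (consensus_conflict(acc, don, off)) {
          blocked[[length(blocked) + 1L]] <- list(ai = ai, off = off)
          next
        }
        if (!accept_merge(acc, don, ov, off, config)) next
        if (is.null(best) || ov$identity > best$identity) {
          best <- list(off = off, identity = ov$identity)
          best_ai <- ai
        }
      }
    }
    if (!is.null(best)) {
      acc <- clusters[[best_ai]]
      acc$ids <- c(acc$ids, don$ids)
      acc$offsets <- c(acc$offsets, don$offsets + best$off)
      acc$lens <- c(acc$lens, don$lens)
      acc$.chars <- c(acc$.chars, don$.chars)
      clusters[[best_ai]] <- rebuild_cluster(acc)
      clusters[[di]] <- NULL
      return(list(clusters = clusters, merged = TRUE))
    }
    for (bl in blocked) {
      pieces <- split_by_witness(clusters[[bl$ai]], don, bl$off)
      if (!is.null(pieces)) {
        clusters[[bl$ai]] <- NULL
        clusters <- c(clusters, pieces)
        return(list(clusters = clusters, merged = TRUE))
      }
    }
  }
  list(clusters = clusters, merged = FALSE)
}

## Flag members that no longer belong to their cluster. Three tests:
## (1) the overlap acceptance rule against the matured consensus;
## (2) contradiction of the established (>= 2 other reads) consensus base
##     at three or more columns;
## (3) membership of the minority side at two or more established conflict
##     columns (two bases with >= 2 votes each) -- the distinguishable-
##     read-set trigger applied inside a cluster. Two such columns backed
##     by the same reads mark true copy divergence; coincident sequencing
##     errors do not repeat across columns for the same read pair.
mismatching_members <- function(cl, config) {
  n <- length(cl$ids)
  bad <- logical(n)
  minority_hits <- integer(n)
  cnt2 <- colSums(cl$votes[1:4, , drop = FALSE] >= 2L)
  for (j in which(cnt2 >= 2L)) {
    v <- cl$votes[1:4, j]
    estab <- which(v >= 2L)
    minority <- estab[v[estab] < max(v[estab])]
    if (!length(minority)) minority <- estab[length(estab)] # tie: later base
    min_bases <- BASES[minority]
    for (i in seq_len(n)) {
      p <- j - cl$offsets[i]
      if (p >= 1L && p <= cl$lens[i] &&
        cl$.chars[[cl$ids[i]]][p] %in% min_bases) {
        minority_hits[i] <- minority_hits[i] + 1L
      }
    }
  }
  for (i in seq_len(n)) {
    ov <- overlap_identity(cl, cl$.chars[[cl$ids[i]]], cl$offsets[i])
    if (is.na(ov$identity)) next
    cols <- (ov$s + 1L):ov$e
    dis <- which(ov$comp & ov$rseg != ov$cseg)
    n_estab <- 0L
    for (k in dis) {
      if (cl$votes[ov$cseg[k], cols[k]] >= 2L) n_estab <- n_estab + 1L
    }
    bad[i] <- !accept_overlap(ov, config) || n_estab >= 3L ||
      minority_hits[i] >= 2L
  }
  # never evict the whole cluster
  if (all(bad)) bad[which.max(cl$lens)] <- FALSE
  bad
}

## Split a cluster whose members no longer form one connected layout.
split_components <- function(cl) {
  o <- order(cl$offsets, cl$ids)
  st <- cl$offsets[o]
  en <- st + cl$lens[o]
  comp <- integer(length(o))
  cur <- 1L
  reach <- en[1L]
  comp[1L] <- 1L
  for (k in seq_along(o)[-1L]) {
    if (st[k] < reach) {
      comp[k] <- cur
      reach <- max(reach, en[k])
    } else {
      cur <- cur + 1L
      comp[k] <- cur
      reach <- en[k]
    }
  }
  if (cur == 1L) {
    return(list(cl))
  }
  lapply(seq_len(cur), function(cc) {
    sel <- o[comp == cc]
    sub <- list(
      seed_read = cl$ids[sel][which.max(cl$lens[sel])],
      ids = cl$ids[sel], offsets = cl$offsets[sel], lens = cl$lens[sel],
      votes = NULL, cons = NULL, .chars = cl$.chars[cl$ids[sel]]
    )
    rebuild_cluster(sub)
  })
}

order_clusters <- function(clusters) {
  if (!length(clusters)) {
    return(clusters)
  }
  sizes <- vapply(clusters, function(cl) length(cl$ids), 0L)
  seeds <- vapply(clusters, function(cl) cl$seed_read, "")
  clusters[order(-sizes, seeds)]
}

#' Separate reads into distinguishable read sets
#'
#' Greedy agglomeration: the longest unassigned read seeds a cluster; a
#' read joins an existing cluster if its best gapless placement overlaps
#' the cluster consensus by at least `min_overlap` bases with identity at
#' least `min_identity` and does not create a diagnostic-column conflict (a
#' column where two different bases would each be supported by two or more
#' reads). Reads that fit nowhere seed new clusters. Output is sorted by
#' cluster size (ties by seed read id).
#'
#' @param reads List of `prl_read` (or DNA `prl_seq`).
#' @param config An [assembler_config()].
#' @return List of cluster objects (fields `seed_read`, `ids`, `offsets`,
#'   `lens`, `votes`, `cons`).
#' @export
cluster_reads <- function(reads, config = assembler_config()) {
  if (!length(reads)) stop("no reads supplied", call. = FALSE)
  chars <- lapply(reads, read_chars)
  ids <- vapply(reads, read_id, "")
  names(chars) <- ids
  lens <- lengths(chars)
  if (max(lens) < config$min_overlap) {
    stop("min_overlap exceeds every read length", call. = FALSE)
  }
  clusters <- list()
  for (i in order(-lens, ids)) {
    res <- place_read(clusters, ids[i], chars[[i]], config)
    if (!is.null(res)) {
      clusters <- res
    } else {
      ncl <- new_cluster(ids[i], chars[[i]])
      ncl$.chars <- chars[ids[i]]
      clusters[[length(clusters) + 1L]] <- ncl
    }
  }
  order_clusters(clusters)
}

#' Build a terminated consensus for one read cluster
#'
#' Inside the anchor span (the region covered by an EST-like anchor
#' sequence, when one is supplied) the consensus is the per-column majority
#' with ties emitted as N. Beyond the anchor the consensus is extended one
#' column at a time only while at least two reads support a single base at
#' that column (the two-independent-reads, 100%-match extension rule); when
#' the rule first fails the end is marked `extension_failed`, and an end
#' reached with the rule still holding is `input_exhausted`. Without an
#' anchor the deepest column seeds the extension.
#'
#' @param cluster A cluster from [cluster_reads()].
#' @param anchor Optional DNA `prl_seq` anchoring the trusted span.
#' @param id Contig id.
#' @return A `prl_contig`: `consensus` (`prl_seq`), `depth`, `members`
#'   (data frame id/offset/length), `left_terminated`, `right_terminated`,
#'   `anchor_span` (0-based half-open, contig coordinates; NULL without
#'   anchor).
#' @export
build_consensus <- function(cluster, anchor = NULL, id = "contig_1") {
  if (any(cluster$offsets < 0L)) stop("negative offsets in layout", call. = FALSE)
  depth <- colSums(cluster$votes)
  L <- length(depth)
  top <- apply(cluster$votes[1:4, , drop = FALSE], 2L, max)
  n_top <- colSums(cluster$votes[1:4, , drop = FALSE] ==
    rep(top, each = 4L)) # how many bases tie at the max
  extendable <- top >= 2L & n_top == 1L

  span <- NULL
  if (!is.null(anchor)) {
    achars <- strsplit(anchor$residues, "", fixed = TRUE)[[1L]]
    offs <- candidate_offsets(cluster, achars)
    if (length(offs)) {
      o <- offs[1L]
      span <- c(max(0L, o), min(L, o + length(achars)))
      if (span[2] <= span[1]) span <- NULL
    }
    if (is.null(span)) {
      warning("anchor could not be placed on cluster; ignoring it")
    }
  }
  if (is.null(span)) {
    j <- which.max(depth)
    span <- c(j - 1L, j)
    anchored <- FALSE
  } else {
    anchored <- TRUE
  }

  # trim anchor span to covered columns
  covered <- which(depth > 0L)
  span[1] <- max(span[1], min(covered) - 1L)
  span[2] <- min(span[2], max(covered))

  left <- span[1] # 0-based start of contig
  left_term <- "input_exhausted"
  while (left > 0L) {
    if (!extendable[left]) {
      left_term <- "extension_failed"
      break
    }
    left <- left - 1L
  }
  right <- span[2]
  right_term <- "input_exhausted"
  while (right < L) {
    if (!extendable[right + 1L]) {
      right_term <- "extension_failed"
      break
    }
    right <- right + 1L
  }

  cols <- (left + 1L):right
  cons <- character(length(cols))
  for (k in seq_along(cols)) {
    j <- cols[k]
    inside_anchor <- anchored && (j - 1L) >= span[1] && (j - 1L) < span[2]
    acgt <- cluster$votes[1:4, j]
    if (all(acgt == 0L)) {
      cons[k] <- "N"
    } else if (inside_anchor) {
      mx <- max(acgt)
      cons[k] <- if (sum(acgt == mx) > 1L) "N" else BASES[which.max(acgt)]
    } else {
      cons[k] <- BASES[which.max(acgt)] # unique by the extension rule
    }
  }

  members <- data.frame(
    id = cluster$ids, offset = cluster$offsets - left,
    length = cluster$lens, stringsAsFactors = FALSE
  )
  structure(
    list(
      id = id,
      consensus = seq_record(id, paste(cons, collapse = ""), "dna"),
      depth = as.integer(depth[cols]),
      members = members,
      left_terminated = left_term,
      right_terminated = right_term,
      anchor_span = if (anchored) c(span[1] - left, span[2] - left) else NULL
    ),
    class = "prl_contig"
  )
}

#' @export
print.prl_contig <- function(x, ...) {
  cat(sprintf(
    "<contig %s> %d bp, %d reads, depth %.1fx, ends %s/%s\n",
    x$id, nchar(x$consensus$residues), nrow(x$members), mean(x$depth),
    x$left_terminated, x$right_terminated
  ))
  invisible(x)
}

#' Assemble reads into terminated consensus contigs
#'
#' Runs [cluster_reads()], then up to `max_rounds` eviction rounds: any
#' member whose overlap identity to its cluster consensus has fallen below
#' `min_identity` is removed (reiterative removal of mismatching reads),
#' clusters are rebuilt, and evicted reads are re-placed greedily (possibly
#' seeding new clusters). Iteration stops at a fixed point. Clusters with
#' fewer than `min_reads` members are reported as unplaced reads, not
#' contigs: a reported consensus requires multiple overlapping reads.
#'
#' @param reads List of `prl_read` / DNA `prl_seq`. Empty list gives an
#'   empty result.
#' @param anchors Optional list of DNA `prl_seq` (EST-like anchors); each
#'   contig uses the first anchor that places on it.
#' @param config An [assembler_config()].
#' @return List with `contigs` (list of `prl_contig`, largest first),
#'   `unplaced` (read ids), `rounds` (eviction rounds run), `clusters`.
#' @export
assemble <- function(reads, anchors = NULL, config = assembler_config()) {
  if (!length(reads)) {
    return(list(
      contigs = list(), unplaced = character(0), rounds = 0L,
      clusters = list()
    ))
  }
  merge_until_stable <- function(cls, max_iter = 40L) {
    for (it in seq_len(max_iter)) {
      mp <- merge_pass(cls, config)
      cls <- mp$clusters
      if (!mp$merged) break
    }
    cls
  }

  clusters <- merge_until_stable(cluster_reads(reads, config))
  all_chars <- do.call(c, lapply(clusters, function(cl) cl$.chars))

  rounds <- 0L
  repeat {
    if (rounds >= config$max_rounds) break
    evicted <- character(0)
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      if (length(cl$ids) <= 1L) next
      bad <- mismatching_members(cl, config)
      if (any(bad)) {
        evicted <- c(evicted, cl$ids[bad])
        cl$ids <- cl$ids[!bad]
        cl$offsets <- cl$offsets[!bad]
        cl$lens <- cl$lens[!bad]
        cl$.chars <- cl$.chars[cl$ids]
        clusters[[ci]] <- if (length(cl$ids)) rebuild_cluster(cl) else NULL
      }
    }
    clusters <- Filter(Negate(is.null), clusters)
    # evictions can disconnect a layout; split remnants into connected
    # components so the merge pass can reunite them with their true set
    clusters <- do.call(c, lapply(clusters, split_components))
    rounds <- rounds + 1L
    if (!length(evicted)) break
    # re-place evicted reads, longest first
    ev_len <- vapply(evicted, function(id) length(all_chars[[id]]), 0L)
    for (id in evicted[order(-ev_len, evicted)]) {
      chars <- all_chars[[id]]
      res <- place_read(clusters, id, chars, config)
      if (!is.null(res)) {
        clusters <- res
      } else {
        ncl <- new_cluster(id, chars)
        ncl$.chars <- all_chars[id]
        clusters[[length(clusters) + 1L]] <- ncl
      }
    }
    clusters <- merge_until_stable(clusters)
  }

  clusters <- merge_until_stable(clusters)

  # final sweep: disband 2-read splinters and re-place their reads
  # individually against the matured clusters (reads whose thin overlap
  # once failed against a seed-stage consensus usually fit now); reads
  # that still fit nowhere re-form their pair
  small <- which(vapply(clusters, function(cl) length(cl$ids), 0L) == 2L)
  if (length(small) && length(clusters) > length(small)) {
    loose <- clusters[small]
    clusters <- clusters[-small]
    for (cl in loose) {
      ord <- order(-cl$lens, cl$ids)
      placed <- logical(2L)
      for (k in ord) {
        res <- place_read(clusters, cl$ids[k], cl$.chars[[cl$ids[k]]], config)
        if (!is.null(res)) {
          clusters <- res
          placed[k] <- TRUE
        }
      }
      if (!all(placed)) {
        keep <- which(!placed)
        remnant <- drop_members(cl, which(placed))
        if (!is.null(remnant)) {
          clusters[[length(clusters) + 1L]] <- remnant
        }
      }
    }
    clusters <- merge_until_stable(clusters)
  }
  clusters <- order_clusters(clusters)
  keep <- vapply(clusters, function(cl) length(cl$ids) >= config$min_reads, TRUE)
  contigs <- vector("list", sum(keep))
  ki <- 0L
  for (ci in which(keep)) {
    ki <- ki + 1L
    anchor <- NULL
    if (!is.null(anchors)) {
      for (a in anchors) {
        achars <- strsplit(a$residues, "", fixed = TRUE)[[1L]]
        if (length(candidate_offsets(clusters[[ci]], achars))) {
          anchor <- a
          break
        }
      }
    }
    contigs[[ki]] <- build_consensus(
      clusters[[ci]],
      anchor = anchor,
      id = sprintf("contig_%02d", ki)
    )
  }
  unplaced <- unlist(lapply(clusters[!keep], function(cl) cl$ids))
  list(
    contigs = contigs,
    unplaced = if (is.null(unplaced)) character(0) else unplaced,
    rounds = rounds, clusters = clusters
  )
}
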