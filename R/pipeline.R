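#' Pipeline configuration
#'
#' Bundles the stage settings and the seed; every output writer stamps the
#' seed and a hash of this configuration so a run can be reproduced
#' byte-for-byte.
#'
#' @param seed Integer seed used by every stochastic stage.
#' @param coverage Read-simulation fold coverage.
#' @param read_len `c(mean, sd)` read length, bases.
#' @param min_read_len Minimum retained read length.
#' @param error_rate Per-base read substitution error.
#' @param flank Simulated flanking bases per side.
#' @param assembler An [assembler_config()].
#' @param classifier Thresholds for [class_panel()].
#' @param target_len Target span L for the copy-number estimate.
#' @param n_genomes Genome count G for the copy-number estimate.
#' @param est_margin Identity margin for per-gene EST assignment.
#' @return A named list of settings.
#' @export
pipeline_config <- function(seed = 1L, coverage = 5, read_len = c(450, 80),
                            min_read_len = 100L, error_rate = 0.005,
                            flank = 200L,
                            assembler = assembler_config(),
                            classifier = list(
                              min_identity = 0.85,
                              min_overlap = 60L, margin = 0.05
                            ),
                            target_len = 1000, n_genomes = 3L,
                            est_margin = 0.01) {
  list(
    seed = as.integer(seed), coverage = coverage, read_len = read_len,
    min_read_len = as.integer(min_read_len), error_rate = error_rate,
    flank = as.integer(flank), assembler = assembler,
    classifier = classifier, target_len = target_len,
    n_genomes = as.integer(n_genomes), est_margin = est_margin
  )
}

# small FNV-1a over the deparsed configuration; enough to fingerprint a run
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647 # keep within bitwXor's integer range
  }
  sprintf("%08x", h)
}

output_header <- function(config) {
  sprintf(
    "# prolaminr %s | seed %d | config %s",
    as.character(utils::packageVersion("prolaminr")),
    config$seed, config_hash(config)
  )
}

#' Write a table with a reproducibility header
#'
#' Tab-separated output preceded by a `#` header line recording package
#' version, seed and configuration hash.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param config A [pipeline_config()].
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, config = pipeline_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  utils::write.table(df, con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Extract the region of a contig matching a reference
#'
#' Local alignment against the reference CDS trims away flanking sequence
#' so defect detection sees coding DNA only.
#'
#' @param contig_seq DNA `prl_seq` (e.g. a contig consensus with flanks).
#' @param reference An intact `prl_gene` or DNA `prl_seq`.
#' @return DNA `prl_seq`, the matched span of `contig_seq`.
#' @export
trim_to_reference <- function(contig_seq, reference) {
  ref_dna <- if (inherits(reference, "prl_gene")) reference$dna else reference
  al <- align_local(contig_seq, ref_dna)
  if (al$score <= 0) stop("contig does not match the reference", call. = FALSE)
  matched <- gsub("-", "", al$gapped_a, fixed = TRUE)
  seq_record(contig_seq$id, matched, "dna")
}

#' Run the discovery pipeline on a read set
#'
#' The end-to-end emulation of the screen: assemble the reads into
#' distinguishable contigs, classify each consensus against the class
#' panel, annotate gene status against the intact reference, build a
#' repeat-stripped NJ tree of the discovered proteins plus panel
#' representatives, estimate copy number from the matching read count, and
#' (when ESTs are supplied) count per-gene ESTs and test the distribution.
#'
#' @param reads List of `prl_read` / DNA `prl_seq`.
#' @param panel A [class_panel()] of DNA representatives.
#' @param reference Intact reference `prl_gene` for defect calls.
#' @param grammar The focal class [prolamin_grammar()].
#' @param config A [pipeline_config()].
#' @param ests Optional EST list for the expression stage.
#' @param anchors Optional anchor sequences for consensus building.
#' @return A `prl_discovery` list: `contigs`, `classes`, `status`,
#'   `tree`, `copy_estimate`, `expression`, `summary`.
#' @export
discover_pipeline <- function(reads, panel, reference, grammar,
                              config = pipeline_config(), ests = NULL,
                              anchors = NULL) {
  if (!length(reads)) {
    stop("discovery failed at stage 'assemble': empty read set",
      call. = FALSE
    )
  }
  asm <- tryCatch(
    assemble(reads, anchors = anchors, config = config$assembler),
    error = function(e) {
      stop("discovery failed at stage 'assemble': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  contigs <- asm$contigs
  consensi <- lapply(contigs, function(ct) ct$consensus)

  cls <- tryCatch(
    screen(consensi, panel),
    error = function(e) {
      stop("discovery failed at stage 'classify': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )

  status <- lapply(consensi, function(cs) {
    tryCatch(
      {
        trimmed <- trim_to_reference(cs, reference)
        detect_defects(trimmed, reference)
      },
      error = function(e) NULL
    )
  })
  names(status) <- vapply(contigs, function(ct) ct$id, "")

  # repeat-stripped NJ tree over discovered ORFs + panel proteins
  tree <- NULL
  prots <- list()
  for (i in seq_along(status)) {
    rep_st <- status[[i]]
    if (is.null(rep_st) || is.null(rep_st$protein)) next
    if (seq_len_res(rep_st$protein) < grammar$signal_len + 30L) next
    p <- seq_record(names(status)[i], rep_st$protein$residues, "protein")
    dm <- tryCatch(suppressWarnings(segment_domains(p, grammar)),
      error = function(e) NULL
    )
    if (is.null(dm)) next
    prots[[length(prots) + 1L]] <- strip_repeats(p, dm)
  }
  outgroup_id <- NULL
  if (length(prots) >= 2L) {
    panel_classes <- setdiff(names(panel$entries), grammar$name)
    for (cn in panel_classes[seq_len(min(2L, length(panel_classes)))]) {
      g <- build_gene(prolamin_grammar(cn), 10L,
        seed = config$seed + 900L,
        id = paste0(cn, "_panel")
      )
      dm <- g$domain_map
      labelled <- seq_record(g$id, g$protein$residues, "protein")
      prots[[length(prots) + 1L]] <- strip_repeats(labelled, dm)
      outgroup_id <- g$id # last added, most external class used as root
    }
    tree <- tryCatch(
      nj_tree(p_distance_matrix(prots), outgroup_id),
      error = function(e) NULL
    )
  }

  mean_len <- mean(vapply(reads, function(r) {
    if (inherits(r, "prl_read")) r$length else seq_len_res(r)
  }, 0))
  copy <- estimate_copy_number(
    n_reads = length(reads), mean_read_len = mean_len,
    target_len = config$target_len, coverage = config$coverage,
    n_genomes = config$n_genomes
  )

  expression <- NULL
  if (!is.null(ests) && length(contigs) >= 2L) {
    labs <- vapply(contigs, function(ct) ct$id, "")
    cons_named <- stats::setNames(consensi, labs)
    ec <- count_ests(ests, cons_named,
      min_identity = config$classifier$min_identity,
      margin = config$est_margin
    )
    gof <- if (sum(ec$counts) > 0) gof_chisq(ec$counts) else NULL
    expression <- c(ec, list(gof = gof))
  }

  statuses <- vapply(status, function(s) {
    if (is.null(s)) "unalignable" else s$status
  }, "")
  summary <- list(
    n_contigs = length(contigs),
    n_unplaced = length(asm$unplaced),
    class_counts = cls$counts,
    status_counts = table(statuses),
    copies_per_genome = copy$copies_per_genome,
    monophyly = NULL,
    expression_p = if (!is.null(expression) && !is.null(expression$gof)) {
      expression$gof$p
    } else {
      NA_real_
    }
  )
  structure(
    list(
      contigs = contigs, unplaced = asm$unplaced, classes = cls,
      status = status, tree = tree, copy_estimate = copy,
      expression = expression, summary = summary, config = config
    ),
    class = "prl_discovery"
  )
}

#' @export
print.prl_discovery <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<discovery> %d contig(s), %d unplaced read(s)\n", s$n_contigs,
    s$n_unplaced
  ))
  cat("  classes: ", paste(sprintf(
    "%s=%d", names(s$class_counts),
    s$class_counts
  ), collapse = " "), "\n")
  cat("  status:  ", paste(sprintf(
    "%s=%d", names(s$status_counts),
    s$status_counts
  ), collapse = " "), "\n")
  cat(sprintf("  copies/genome: %.2f\n", s$copies_per_genome))
  if (!is.na(s$expression_p)) {
    cat(sprintf("  expression chi-square p: %.4g\n", s$expression_p))
  }
  invisible(x)
}

#' Write contigs and their layout report
#'
#' FASTA of consensus sequences plus a tab-separated layout (read id,
#' contig id, offset, length) with a reproducibility header; a
#' `run_info.txt` sidecar records version, seed and config hash for the
#' formats that cannot carry comments.
#'
#' @param contigs List of `prl_contig`.
#' @param dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return `dir`, invisibly.
#' @export
write_contigs <- function(contigs, dir, config = pipeline_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(lapply(contigs, function(ct) ct$consensus),
    file.path(dir, "contigs.fasta")
  )
  layout <- do.call(rbind, lapply(contigs, function(ct) {
    cbind(contig = ct$id, ct$members)
  }))
  if (is.null(layout)) {
    layout <- data.frame(
      contig = character(0), id = character(0),
      offset = integer(0), length = integer(0)
    )
  }
  write_report_tsv(layout, file.path(dir, "layout.tsv"), config)
  writeLines(output_header(config), file.path(dir, "run_info.txt"))
  invisible(dir)
}
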