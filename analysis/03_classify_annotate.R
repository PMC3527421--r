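#!/usr/bin/env Rscript

# Stage 3: classify the assembled consensi against a six-class prolamin
# panel and annotate gene status (intact / inactivated / pseudogene)
# against the intact D ortholog. The hexaploid locus should show one
# tandem-stop inactivated copy and one frameshift pseudogene.

suppressPackageStartupMessages(library(prolaminr))

seed <- 3L
cfg <- pipeline_config(seed = seed)
out <- "results/03_classify_annotate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

hex <- scenario_hexaploid(seed = seed)
reference <- hex$genes[[3]] # intact deltaD
panel <- build_class_panel()

contigs <- read_fasta("results/02_assemble/hexaploid/contigs.fasta", "dna")
cls <- screen(contigs, panel)
write_report_tsv(cls$assignments, file.path(out, "classes.tsv"), cfg)
cat("class counts:\n")
print(cls$counts)

rows <- lapply(contigs, function(cs) {
  rep <- tryCatch(
    detect_defects(trim_to_reference(cs, reference), reference),
    error = function(e) NULL
  )
  if (is.null(rep)) {
    return(data.frame(
      contig = cs$id, status = "unalignable", defects = "", cysteines = NA
    ))
  }
  defects <- paste(vapply(rep$defects, function(d) {
    sprintf(
      "%s@%d%s", d$type, d$dna_position,
      if (isTRUE(d$frameshift)) "(fs)" else ""
    )
  }, ""), collapse = "; ")
  cys <- if (!is.null(rep$protein) && rep$status == "intact") {
    dm <- tryCatch(suppressWarnings(segment_domains(rep$protein, hex$grammar)),
      error = function(e) NULL
    )
    if (is.null(dm)) NA else census_cysteines(rep$protein, dm)$count
  } else {
    NA
  }
  data.frame(
    contig = cs$id, status = rep$status, defects = defects, cysteines = cys
  )
})
status <- do.call(rbind, rows)
write_report_tsv(status, file.path(out, "status.tsv"), cfg)
cat("\ngene status calls:\n")
print(status, row.names = FALSE)
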