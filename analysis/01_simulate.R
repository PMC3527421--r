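#!/usr/bin/env Rscript

# Stage 1: simulate the study systems and write them out.
#
# Builds the hexaploid locus (three delta-gliadin orthologs at ~2%
# divergence, the A copy inactivated by two tandem premature stops, plus
# an ~8%-diverged D-genome frameshift pseudogene), the diploid D-ancestor
# locus, 5x shotgun reads over both, and the two cultivars' EST samples
# (17 and 14 ESTs with the Chinese Spring / Recital expression patterns).

suppressPackageStartupMessages(library(prolaminr))

seed <- 3L
cfg <- pipeline_config(seed = seed)
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

hex <- scenario_hexaploid(seed = seed)
dip <- scenario_diploid(seed = seed)
expr <- scenario_expression(seed = seed)

reads_hex <- simulate_reads(hex$genes, coverage = 5, seed = seed + 1000L)
reads_dip <- simulate_reads(dip$genes, coverage = 5, seed = seed + 2000L)

write_fasta(lapply(hex$genes, function(g) g$dna), file.path(out, "genes_hexaploid.fasta"))
write_fasta(lapply(dip$genes, function(g) g$dna), file.path(out, "genes_diploid.fasta"))
write_fasta(lapply(reads_hex, function(r) r$dna), file.path(out, "reads_hexaploid.fasta"))
write_fasta(lapply(reads_dip, function(r) r$dna), file.path(out, "reads_diploid.fasta"))
for (cv in c("chinese_spring", "recital")) {
  write_fasta(
    lapply(expr[[cv]]$ests, function(e) e$seq),
    file.path(out, paste0("ests_", cv, ".fasta"))
  )
}

truth <- do.call(rbind, lapply(c(hex$genes, dip$genes), function(g) {
  data.frame(
    id = g$id, genome = g$genome, status = g$status,
    n_defects = length(g$defects),
    expression_weight = g$expression_weight,
    cds_len = nchar(g$dna$residues)
  )
}))
write_report_tsv(truth, file.path(out, "ground_truth.tsv"), cfg)

cat(sprintf(
  "simulated %d hexaploid genes (%d reads), %d diploid genes (%d reads)\n",
  length(hex$genes), length(reads_hex), length(dip$genes), length(reads_dip)
))
cat(sprintf(
  "EST samples: Chinese Spring %d, Recital %d\n",
  length(expr$chinese_spring$ests), length(expr$recital$ests)
))
cat("outputs in", out, "\n")
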