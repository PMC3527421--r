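#!/usr/bin/env Rscript

# Stage 2: separate the simulated reads into distinguishable read sets and
# build terminated consensus contigs. The hexaploid locus should resolve
# into four distinguishable sequences and the diploid locus into two.

suppressPackageStartupMessages(library(prolaminr))

seed <- 3L
cfg <- pipeline_config(seed = seed)
out <- "results/02_assemble"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (which in c("hexaploid", "diploid")) {
  reads <- read_fasta(
    file.path("results/01_simulate", paste0("reads_", which, ".fasta")), "dna"
  )
  asm <- assemble(reads)
  write_contigs(asm$contigs, file.path(out, which), cfg)
  cat(sprintf(
    "%s: %d reads -> %d contigs (%d unplaced, %d eviction rounds)\n",
    which, length(reads), length(asm$contigs), length(asm$unplaced),
    asm$rounds
  ))
  for (ct in asm$contigs) {
    cat(sprintf(
      "  %s: %d bp, %d reads, mean depth %.1f, ends %s/%s\n",
      ct$id, nchar(ct$consensus$residues), nrow(ct$members),
      mean(ct$depth), ct$left_terminated, ct$right_terminated
    ))
  }
}
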