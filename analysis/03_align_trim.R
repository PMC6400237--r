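#!/usr/bin/env Rscript
# Align the accepted genes of each class, remove gap-rich columns with the
# class gap thresholds (0.5 linkers, 0.75 globins), and trim residues 5'
# of the majority start methionine. Expects 02_screen.R outputs.

library(hblhb)

in_dir <- "results/screen"
out_dir <- "results/align"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

gts <- c(linker = 0.5, ex_globin = 0.75)
for (cls in names(gts)) {
  seqs <- read_fasta(file.path(in_dir, paste0(cls, "_genes.fasta")),
                     type = "AA")
  msa <- progressive_msa(seqs)
  trimmed <- trim_to_start(trim_columns(msa, gts[[cls]]))
  write_msa(trimmed, file.path(out_dir, paste0(cls, "_aln.fasta")))
  cat(sprintf("%s: %d sequences, %d -> %d columns (gt %.2f + start trim)\n",
              cls, length(msa), nchar(msa[[1]]), nchar(trimmed[[1]]),
              gts[[cls]]))
}
cat("Trimmed alignments written under", out_dir, "\n")
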