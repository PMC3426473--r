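#!/usr/bin/env Rscript
# Step 2 — place ortholog exons on the draft.
#
# Reads the step-1 artifacts back from disk (the same files a real audit
# would receive), extracts every transcript's exon sequences from the
# reference genome, places them on the draft by seeded local alignment,
# and writes the per-exon placement table. On an uncorrupted draft every
# exon places uniquely at identity 1; deviations from that are the raw
# material for steps 3-4.

suppressMessages(library(exonaudit))

indir <- "results/survey"
truth_seq <- read_fasta(file.path(indir, "truth.fa"))
models <- read_gff3(file.path(indir, "truth.gff3"))
draft <- assembly_from_files(indir)

chains <- map_transcripts(models, truth_seq, draft)
tab <- chains_to_table(chains)
utils::write.table(tab, file.path(indir, "exon_placements.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("%d exons: %d placed, %d ambiguous, %d unplaced",
                nrow(tab), sum(tab$status == "placed"),
                sum(tab$status == "ambiguous"),
                sum(tab$status == "unplaced")))
split_genes <- unique(tab$gene_id[ave(tab$target, tab$gene_id,
  FUN = function(x) length(unique(x[!is.na(x)]))) > 1])
message(sprintf("%d gene(s) place on more than one sequence: %s",
                length(split_genes), paste(split_genes, collapse = ", ")))
message("wrote ", file.path(indir, "exon_placements.tsv"))
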