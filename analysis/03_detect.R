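#!/usr/bin/env Rscript
# Step 3 — detect sequencing-error effects and misassemblies.
#
# Re-reads the survey artifacts, rebuilds the exon chains (mapping is
# cheap and keeps this script self-contained), and runs every detector:
# frameshifts, premature stops, missing exons / sub-exon sequence,
# spurious and truncated draft models, split genes, orientation flips,
# order anomalies, unintegrated contigs and chimeric contigs. Writes the
# findings table and the per-contig chimerism diagnoses.

suppressMessages(library(exonaudit))

indir <- "results/survey"
truth_seq <- read_fasta(file.path(indir, "truth.fa"))
models <- read_gff3(file.path(indir, "truth.gff3"))
draft_models <- read_gff3(file.path(indir, "draft.gff3"))
draft <- assembly_from_files(indir)
synteny <- read_synteny(file.path(indir, "synteny.tsv"))

chains <- map_transcripts(models, truth_seq, draft)
col <- collect_findings(chains, draft, draft_models, truth_seq, models,
                        synteny)

ft <- findings_table(col$findings)
utils::write.table(ft, file.path(indir, "findings.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
ctg <- do.call(rbind, lapply(col$contig_diagnoses, function(d) {
  data.frame(contig_id = d$contig_id, verdict = d$verdict,
             evidence_absent = d$evidence_absent,
             breakpoint_lo = if (is.null(d$breakpoint_interval))
               NA_integer_ else d$breakpoint_interval[1L],
             breakpoint_hi = if (is.null(d$breakpoint_interval))
               NA_integer_ else d$breakpoint_interval[2L],
             stringsAsFactors = FALSE)
}))
utils::write.table(ctg, file.path(indir, "contig_diagnoses.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("%d findings over %d genes:", nrow(ft),
                length(unique(ft$gene_id))))
print(table(ft$kind))
message(sprintf("%d contig(s) called chimeric",
                sum(ctg$verdict == "chimeric")))
message("wrote findings.tsv, contig_diagnoses.tsv")
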