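#!/usr/bin/env Rscript
# Step 4 — classify every gene into the six survey categories.
#
# Consumes the step-3 findings table plus the draft annotation: a gene
# missing from the draft GFF3 is none_annotated; a premature stop marks
# the protein underivable; otherwise the finding kinds decide between
# wrong, incomplete, unclear and complete/correct. Writes per-gene
# verdicts and the category summary (counts and integer percentages).

suppressMessages(library(exonaudit))

indir <- "results/survey"
models <- read_gff3(file.path(indir, "truth.gff3"))
draft_models <- read_gff3(file.path(indir, "draft.gff3"))
ft <- utils::read.delim(file.path(indir, "findings.tsv"),
                        stringsAsFactors = FALSE, quote = "")
findings <- lapply(seq_len(nrow(ft)), function(i) {
  finding(ft$gene_id[i], ft$kind[i])
})

verdicts <- classify_genes(models, draft_models, findings)
summ <- summarize_verdicts(verdicts)

utils::write.table(verdicts, file.path(indir, "verdicts.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
summary_tab <- data.frame(category = names(summ$counts),
                          count = unname(summ$counts),
                          percent = unname(summ$percentages))
utils::write.table(summary_tab, file.path(indir, "survey_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("%d genes classified:", summ$total))
print(summary_tab)
message("wrote verdicts.tsv, survey_summary.tsv")
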