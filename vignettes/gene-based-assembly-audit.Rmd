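---
title: "Auditing draft assemblies through conserved gene structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing draft assemblies through conserved gene structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonaudit)
```

## The method

A draft genome is audited gene by gene. For every ortholog transcript we
extract each exon's sequence from the reference genome, place it on the
draft independently by local alignment, and read the placements back in
transcription order as an *exon chain*. Two comparative assumptions make
the chain informative. First, coding sequence is conserved enough between
close relatives (here, simulated truth vs. its own corrupted draft; in
real use, e.g. human mRNA vs. a macaque draft) that a true exon of 30 bp
or more aligns at high identity. Second, exon order along the chromosome
is highly conserved among vertebrates, so a chain whose placements
violate transcription order, strand consistency, or the synteny-expected
chromosome indicts the assembly, not the gene.

The detectors read the chain at three levels:

* **Within placed exons** (`detect_frameshift`, `detect_premature_stop`,
  `detect_missing_subsequence`): signed indel lengths are summed over the
  CDS portion of each placed exon; any prefix sum not divisible by 3 is a
  frameshift, even when a later indel restores the frame, because the
  protein is corrupted over the interior span. The draft CDS is
  reconstructed base by base through each exon alignment and translated;
  an internal stop that the ortholog CDS lacks at or before that codon is
  a premature stop, and when draft and ortholog CDS are length-matched
  and the stop codon differs by one base, that base is named. Query
  positions that are unaligned, deleted, or aligned opposite N carry no
  sequence support; a contiguous unsupported block of ≥ 15 bp is missing
  sub-exon sequence.
* **Across the chain** (`detect_missing_exon`, `diagnose_chain`,
  `check_unintegrated`): unplaced exons are missing, and when the
  flanking placed exons bracket an N run the absence is `gap_explained` —
  the sequence most likely sits in the unsequenced gap. Chains spanning
  two chromosomes (or a chromosome plus unlocalized scaffolds of the
  expected chromosome) are split; minority-strand exons are orientation
  flips; same-target, same-strand placements out of monotonic order by
  more than one exon span are order anomalies. A misplaced block on a
  single-contig scaffold whose expected chromosome equals the chain's
  primary target is an unintegrated contig.
* **Across genes per contig** (`diagnose_contigs`,
  `detect_spurious_exon`): placements are resolved to contigs through the
  placement table and grouped by each gene's synteny-expected chromosome.
  Two groups on disjoint contig intervals make the contig chimeric, with
  the breakpoint interval between the innermost conflicting placements;
  interleaved conflicts are routed to `AMBIGUOUS_PLACEMENT` instead of a
  chimera call. Separately, the draft's own gene models are audited
  against the chains: a model exon with reciprocal overlap < 0.1 to every
  ortholog-supported placement, next to a supported neighbour, is a
  spurious exon; supported placements at the chain termini absent from
  the model are a model truncation.

`classify_gene` folds a gene's findings into one of six survey
categories under a fixed severity precedence: `none_annotated` (no draft
model) > `no_protein_derived` (no CDS translates to completion — the
pseudogene-mislabel signature) > `wrong` (spurious sequence: spurious
exon, split, chimera, flip, order anomaly, or frameshift with a surviving
ORF) > `incomplete` (pure truncation: missing exon/subsequence, truncated
model) > `unclear` (ambiguity-only evidence) > `complete_correct`. The
precedence is this package's codification — the boundary cases it
resolves were decided by the severity the categories imply: any invented
sequence outranks pure truncation. `summarize_verdicts` reports raw
counts plus integer percentages (rounded half-up) and never forces
percentages to sum to 100.

## Alignment and placement parameters

`local_align` is a Smith–Waterman local alignment with Gotoh affine gaps
(Rcpp): match +2, mismatch −3, gap of length L costs 5 + 2L — BLASTN-like
values, since the method is a stand-in for aligning mRNAs with BLAST at
default parameters. Two numerical choices matter:

* **N is absence, not disagreement.** In scoring, N in the target is
  always a mismatch (never a match), so placements shrink at assembly
  gaps rather than bridging them. In the derived statistics, columns
  opposite N are excluded from identity and from coverage *support*: a
  30 bp N block inside an otherwise perfect exon leaves identity ≈ 1 (the
  exon is correctly placed) while the block itself surfaces as missing
  subsequence. Block boundaries are alignment-dependent to about ±5 bp,
  which the tests allow for.
* **Deterministic traceback.** Ties prefer diagonal, then up, then left,
  and the best cell with the smallest end position wins, so placements
  are reproducible to the base.

Placement gates: `min_identity = 0.85` over non-N aligned columns and
`min_coverage = 0.80` of the exon length, chosen so that single-base
errors and small indels still place an exon while unrelated sequence
(e.g. a decoy intronic exon) does not. Exons under 20 bp are reported
unplaced-short and excluded from anomaly evidence — too little signal.
Equal-scoring candidates make a placement `ambiguous` (exact ties by
default; a score margin is configurable for real data), and ambiguous
exons are excluded from anomaly evidence but kept in the report. The
candidate search is an exact 11-mer seed prefilter (stride 8, plus the
final offset, both strands) followed by windowed alignment; clusters
supported by a single seed are dropped when the exon offers six or more,
since at genome scale a lone 11-mer hit is almost surely random. An
adjacent-exon distance bound of 1 Mb (`max_intron`) flags biologically
implausible chains on real data; the simulated chromosomes never
approach it.

## What the simulator emulates

`generate_truth` builds a compact vertebrate-like gene complement:
by default 50 genes on 2 chromosomes, 4–8 exons of 90–260 bp per gene,
introns of 1–4 kb (so genes span 3.4–20 kb), intergenic spacers of
0.5–3 kb, GC 0.45, strands assigned at random. Every CDS is ATG-initiated,
stop-terminated, free of internal stops, and every intron carries GT..AG
splice dinucleotides. Coding sequence is sampled codon-wise from the 61
sense codons with per-base GC weighting; the genetic code is data
(`genetic_code_table()`), not logic. UTRs of 0–45/0–90 bp exercise the
CDS-offset bookkeeping. These sizes were chosen so a gene typically
spans several contigs of the draft tiling — the property that makes
contig-level defects visible in exon chains — while keeping a full
survey replicate to a few seconds.

`derive_draft` cuts each chromosome into 5–15 kb contigs (cut points
snapped out of exons; real exons are rarely cut mid-exon at this scale,
and the snap keeps one exon = one contig interval), reassembles them with
100-N gaps, and injects defects. Contig-level defects are assigned first
and claim every gene with an exon on the moved contig; the moved contig
must carry a strict subset of each such gene's exons (preferring contigs
with a middle exon), otherwise the defect would be invisible to an
exon-order audit. Sequence-level defects then draw from untouched genes:
stop-creating substitutions at an interior codon one base away from a
stop; 1–2 bp CDS indels placed ≥ 25 bp inside an exon's coding portion;
whole-exon N replacement with a 10 bp margin plus a decoy model exon
sampled N-free from the gene's own intron, length-matched within 20%;
30 bp central N blocks in exons ≥ 140 bp (smaller exons would lose the
side-anchored alignment altogether and read as a missing exon instead).
Chimeric fusions join a prefix of one chromosome's contig to a suffix of
another's, both breakpoints ≥ 20 bp clear of any exon; the trimmed ends
are genuinely lost sequence and are logged as such. Every record carries
its draft-coordinate locus, the finding kinds it should trigger, and the
survey category it implies — for frameshifts that category is computed
at injection time by translating the edited CDS, since a shifted frame
only usually (not always) hits a downstream stop.

One root seed drives everything; per-gene randomness runs in substreams
keyed on the gene id, so a record is reproducible regardless of spec
ordering. The reference annotation used by the mapper is the truth
annotation itself, making the synteny map the identity — real-data use
swaps in a real ortholog annotation and a real correspondence table
without code changes.

What the simulator does **not** emulate: read-level sequencing error
(the audit targets the assembly, not reads), repeat families and
segmental duplications (so ambiguous placements are rarer than on real
genomes), heterozygosity, and biological pseudogenes. Passing tests
therefore demonstrate that the detectors recover the defect classes they
model under clean mappability — not that real-genome precision would be
1.0, where repeats and true biology add ambiguity the thresholds can
only partly absorb. The simulator also cannot say whether a chimeric
contig arose in assembly or from a chimeric clone; all fusions are
logged as one class.

## Degenerate inputs and tie-breaks

A chain with no placed exons yields an empty diagnosis with a note, not
an error. Genes split across targets skip CDS reconstruction (no
premature-stop call) and defer to the misassembly detectors. The primary
target is the plurality of placed exons, ties broken by the synteny
expectation, then lexicographically. Majority strand ties break to `+`.
An empty verdict set is an error for `summarize_verdicts`; a gene with a
draft model but no protein cannot be expressed (`classify_gene`
validates the combination). Contigs without exon evidence are reported
consistent with an `evidence_absent` flag rather than silently passing.

## Problem sizes

The shipped configuration — 50 genes, ~0.8 Mb of genome, one defect per
affected gene, 20 replicate seeds for the recovery tables — runs the
full acceptance suite in a few minutes on one CPU and gives every defect
class at least 20 scored instances across replicates. All counts scale
through `sim_config()` / `defect_spec()` if more replication is wanted.

## Known limitations

* Spliced alignment is per-exon, not splice-aware: micro-exons (< 20 bp)
  are invisible, and exon boundaries are trusted from the ortholog
  annotation.
* Premature-stop attribution assumes the ortholog CDS is the correct
  frame; a mis-annotated ortholog would propagate.
* `unclear` is operationalized as ambiguity-only evidence; a manual
  survey's judgment of "unclear" may not coincide.
* The breakpoint interval of a chimeric contig is only as tight as the
  innermost flanking exons; intergenic fusions far from any exon widen
  it.
* Findings are reported, never auto-corrected: proposing a repaired
  assembly is out of scope.
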