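# Hand-built fixtures for detector unit tests: fabricated placements and
# chains let the order/strand/overlap logic be exercised without running
# the aligner.

# A placed-exon entry as map_transcripts() produces, with just enough
# fields for the detectors. Aligned strings default to a perfect
# alignment of the given length.
fake_placed <- function(exon, target, start, end, strand = "+",
                        qstart = 0L, exon_len = end - start,
                        aligned_query = NULL, aligned_target = NULL,
                        indels = NULL, identity = 1, score = NULL) {
  n <- end - start
  if (is.null(aligned_query)) aligned_query <- strrep("A", n)
  if (is.null(aligned_target)) aligned_target <- aligned_query
  if (is.null(indels)) {
    indels <- data.frame(qpos = integer(), tpos = integer(),
                         length = integer(), kind = character(),
                         stringsAsFactors = FALSE)
  }
  list(exon = exon, status = "placed", target = target,
       target_start = start, target_end = end, strand = strand,
       score = score %||% (2 * n), identity = identity,
       coverage = (nchar(gsub("-", "", aligned_query))) / exon_len,
       qstart = qstart,
       qend = qstart + nchar(gsub("-", "", aligned_query)),
       exon_len = exon_len, indels = indels,
       aligned_query = aligned_query, aligned_target = aligned_target)
}

fake_unplaced <- function(exon, reason = NULL) {
  out <- list(exon = exon, status = "unplaced")
  if (!is.null(reason)) out$reason <- reason
  out
}

# Chain over a fabricated (+ strand) model: exon lengths inferred from
# the entries; reference-side coordinates are arbitrary.
fake_chain <- function(gene_id, entries, seq_name = "ref1",
                       exon_lens = NULL, cds_span = NULL) {
  if (is.null(exon_lens)) {
    exon_lens <- vapply(entries, function(e) {
      if (!is.null(e$exon_len)) e$exon_len else 100L
    }, integer(1L))
  }
  starts <- cumsum(c(0L, utils::head(exon_lens, -1L) + 500L))
  exons <- cbind(starts, starts + exon_lens)
  if (is.null(cds_span)) cds_span <- c(0L, sum(exon_lens))
  model <- transcript_model(gene_id, paste0(gene_id, ".t1"), seq_name,
                            "+", exons, cds_span)
  structure(list(transcript_id = paste0(gene_id, ".t1"),
                 gene_id = gene_id, model = model, exons = entries),
            class = "exon_chain")
}

# Minimal draft assembly providing roles and (optionally) placements for
# fabricated chains; sequences are placeholders of the requested lengths.
fake_draft <- function(roles, lengths = NULL, placements = NULL) {
  nms <- names(roles)
  if (is.null(lengths)) lengths <- setNames(rep(100000L, length(nms)), nms)
  seqs <- vapply(nms, function(nm) strrep("A", lengths[[nm]]),
                 character(1L))
  if (is.null(placements)) {
    placements <- exonaudit:::empty_placements()
  }
  assembly(seqs, roles, placements)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small simulated bundles, cached per option set so several tests can
# share one pipeline run.
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

small_config <- function(seed = 42L, n_genes = 10L) {
  sim_config(n_genes = n_genes, n_chromosomes = 2L, seed = seed)
}
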