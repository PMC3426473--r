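# Cached simulated bundles exercising one defect class each.
one_defect_run <- function(cls, n = 2L, seed = 55L) {
  cached_run(paste0("one_", cls, "_", seed),
             run_pipeline(small_config(seed = seed, n_genes = 12L),
                          defect_specs = list(defect_spec(cls, n))))
}

finding_df <- function(b) findings_table(b$findings)

test_that("frameshift arithmetic follows cumulative net mod 3", {
  ind <- function(qpos, len, kind) {
    data.frame(qpos = qpos, tpos = qpos + 1000L, length = len,
               kind = kind, stringsAsFactors = FALSE)
  }
  # one 1-bp insertion -> frameshift
  ch <- fake_chain("g1", list(
    fake_placed(1L, "chr1", 1000L, 1101L,
                indels = ind(50L, 1L, "ins"))))
  f <- detect_frameshift(ch)
  expect_length(f, 1L)
  expect_identical(f[[1L]]$kind, "FRAMESHIFT")

  # one 3-bp deletion -> frame preserved
  ch2 <- fake_chain("g2", list(
    fake_placed(1L, "chr1", 1000L, 1097L,
                indels = ind(50L, 3L, "del"))))
  expect_length(detect_frameshift(ch2), 0L)

  # +2 then +1 in one exon: net 0 mod 3 at the exon end, but the span
  # between the indels is out of frame and is reported
  ch3 <- fake_chain("g3", list(
    fake_placed(1L, "chr1", 1000L, 1103L,
                indels = rbind(ind(30L, 2L, "ins"), ind(70L, 1L, "ins")))))
  f3 <- detect_frameshift(ch3)
  expect_length(f3, 1L)
  expect_true(f3[[1L]]$payload$restored)
  expect_equal(f3[[1L]]$payload$first_indel$qpos, 30L)

  # indel outside the CDS portion is ignored
  ch4 <- fake_chain("g4", list(
    fake_placed(1L, "chr1", 1000L, 1101L,
                indels = ind(95L, 1L, "ins"))),
    cds_span = c(0L, 90L))
  expect_length(detect_frameshift(ch4), 0L)
})

test_that("injected frameshifts are detected and divergence matches", {
  b <- one_defect_run("FRAMESHIFT_INDEL", 3L)
  ft <- finding_df(b)
  for (i in seq_len(nrow(b$defects))) {
    g <- b$defects$gene_id[i]
    expect_true(any(ft$gene_id == g & ft$kind == "FRAMESHIFT"))
    # oracle: the reconstructed draft CDS diverges from the truth protein
    # within one codon of the reported indel
    ch <- b$chains[[g]]
    dcds <- exonaudit:::reconstruct_draft_cds(ch)
    m <- Filter(function(m) m$gene_id == g, b$truth$models)[[1L]]
    tcds <- cds_sequence(b$truth$assembly, m)
    dp <- translate_cds(substr(dcds, 1L, nchar(dcds) - nchar(dcds) %% 3L))
    tp <- translate_cds(tcds)
    div <- which(utf8ToInt(dp$protein)[seq_len(min(nchar(dp$protein),
                                                   nchar(tp$protein)))] !=
                   utf8ToInt(tp$protein)[seq_len(min(nchar(dp$protein),
                                                     nchar(tp$protein)))])
    first_div <- if (length(div)) div[1L] else
      min(nchar(dp$protein), nchar(tp$protein)) + 1L
    pl <- jsonlite::fromJSON(b$defects$payload[i])
    expect_lte(abs((first_div - 1L) - pl$cds_offset %/% 3L), 1L)
  }
})

test_that("premature stops are found at the injected codon", {
  b <- one_defect_run("STOP_SUBSTITUTION", 3L)
  ft <- finding_df(b)
  for (i in seq_len(nrow(b$defects))) {
    g <- b$defects$gene_id[i]
    hit <- b$findings[vapply(b$findings, function(f)
      f$gene_id == g && f$kind == "PREMATURE_STOP", logical(1L))]
    expect_length(hit, 1L)
    pl <- jsonlite::fromJSON(b$defects$payload[i])
    expect_equal(hit[[1L]]$payload$codon_index, pl$codon_index)
    expect_identical(hit[[1L]]$payload$substitution$alt, pl$alt)
  }
  # the verdicts mark these genes protein-less
  expect_true(all(b$verdicts$category[
    b$verdicts$gene_id %in% b$defects$gene_id] == "no_protein_derived"))
})

test_that("gap-deleted exons are missing and gap-explained", {
  b <- one_defect_run("EXON_GAP", 3L)
  ft <- finding_df(b)
  for (i in seq_len(nrow(b$defects))) {
    g <- b$defects$gene_id[i]
    me <- b$findings[vapply(b$findings, function(f)
      f$gene_id == g && f$kind == "MISSING_EXON", logical(1L))]
    expect_length(me, 1L)
    expect_true(me[[1L]]$payload$gap_explained)
    pl <- jsonlite::fromJSON(b$defects$payload[i])
    expect_equal(me[[1L]]$payload$exon, pl$exon)
    # the decoy model exon is flagged spurious
    expect_true(any(ft$gene_id == g & ft$kind == "SPURIOUS_EXON"))
  }
})

test_that("an exon deleted without an N run is not gap-explained", {
  ch <- fake_chain("g1", list(
    fake_placed(1L, "chr1", 1000L, 1100L),
    fake_unplaced(2L),
    fake_placed(3L, "chr1", 1400L, 1500L)))
  no_gaps <- data.frame(seq = character(), start = integer(),
                        end = integer())
  f <- detect_missing_exon(ch, no_gaps)
  expect_length(f, 1L)
  expect_false(f[[1L]]$payload$gap_explained)
  with_gap <- data.frame(seq = "chr1", start = 1200L, end = 1320L)
  f2 <- detect_missing_exon(ch, with_gap)
  expect_true(f2[[1L]]$payload$gap_explained)
})

test_that("partial exon gaps surface as missing subsequence of ~30 bp", {
  b <- one_defect_run("PARTIAL_EXON_GAP", 3L)
  for (i in seq_len(nrow(b$defects))) {
    g <- b$defects$gene_id[i]
    ms <- b$findings[vapply(b$findings, function(f)
      f$gene_id == g && f$kind == "MISSING_SUBSEQUENCE", logical(1L))]
    expect_length(ms, 1L)
    pl <- jsonlite::fromJSON(b$defects$payload[i])
    expect_equal(ms[[1L]]$payload$exon, pl$exon)
    expect_lte(abs(ms[[1L]]$payload$length - pl$len), 5L)
    expect_lte(abs(ms[[1L]]$payload$block_start - pl$offset), 5L)
  }
})

test_that("sub-threshold coverage shortfalls are not reported", {
  # full coverage -> nothing
  ch <- fake_chain("g1", list(fake_placed(1L, "chr1", 1000L, 1100L)))
  expect_length(detect_missing_subsequence(ch), 0L)
  # a 10-bp N block is below the 15-bp floor
  aq <- strrep("A", 100L)
  at <- paste0(strrep("A", 45L), strrep("N", 10L), strrep("A", 45L))
  ch2 <- fake_chain("g2", list(
    fake_placed(1L, "chr1", 1000L, 1100L, aligned_query = aq,
                aligned_target = at)))
  expect_length(detect_missing_subsequence(ch2), 0L)
  # a 20-bp N block is reported
  at3 <- paste0(strrep("A", 40L), strrep("N", 20L), strrep("A", 40L))
  ch3 <- fake_chain("g3", list(
    fake_placed(1L, "chr1", 1000L, 1100L, aligned_query = aq,
                aligned_target = at3)))
  f3 <- detect_missing_subsequence(ch3)
  expect_length(f3, 1L)
  expect_equal(f3[[1L]]$payload$length, 20L)
})

test_that("model exons with partial support route to ambiguous, not spurious", {
  # model exon 2 overlaps its placement by half: not spurious
  ch <- fake_chain("g1", list(
    fake_placed(1L, "chr1", 1000L, 1100L),
    fake_placed(2L, "chr1", 1500L, 1600L),
    fake_placed(3L, "chr1", 2000L, 2100L)))
  dm <- transcript_model("g1", "g1.t1", "chr1", "+",
                         cbind(c(1000L, 1550L, 2000L),
                               c(1100L, 1650L, 2100L)),
                         c(0L, 300L))
  f <- detect_spurious_exon(list(dm), list(g1 = ch))
  kinds <- vapply(f, `[[`, "", "kind")
  expect_identical(kinds, "AMBIGUOUS_PLACEMENT")

  # no overlap at all, neighbours supported: spurious
  dm2 <- transcript_model("g1", "g1.t1", "chr1", "+",
                          cbind(c(1000L, 1700L, 2000L),
                                c(1100L, 1800L, 2100L)),
                          c(0L, 300L))
  f2 <- detect_spurious_exon(list(dm2), list(g1 = ch))
  kinds2 <- vapply(f2, `[[`, "", "kind")
  expect_identical(kinds2, "SPURIOUS_EXON")
  expect_equal(f2[[1L]]$payload$model_exon, 2L)

  # model identical to the placements: silence
  dm3 <- transcript_model("g1", "g1.t1", "chr1", "+",
                          cbind(c(1000L, 1500L, 2000L),
                                c(1100L, 1600L, 2100L)),
                          c(0L, 300L))
  expect_length(detect_spurious_exon(list(dm3), list(g1 = ch)), 0L)
})

test_that("truncated models are caught from unmatched terminal placements", {
  b <- one_defect_run("MODEL_TRUNCATION", 3L)
  ft <- finding_df(b)
  for (g in b$defects$gene_id) {
    expect_true(any(ft$gene_id == g & ft$kind == "MODEL_TRUNCATION"))
    expect_identical(
      b$verdicts$category[b$verdicts$gene_id == g], "incomplete")
  }
})

test_that("the identity draft yields zero findings of any kind", {
  b <- cached_run("clean10",
                  run_pipeline(small_config(seed = 19L),
                               defect_specs = list()))
  expect_length(b$findings, 0L)
  expect_true(all(b$verdicts$category == "complete_correct"))
})
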