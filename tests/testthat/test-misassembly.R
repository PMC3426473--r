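id_synteny <- function(chroms) synteny_map(chroms, chroms)

test_that("a gene split across a chromosome and expected-chromosome scaffolds", {
  # exons 1-2 on the expected chromosome; 3-5 on a wrong chromosome;
  # 6-8 on two unlocalized scaffolds — the layout of a split gene whose
  # misplaced block sits off the synteny expectation
  draft <- fake_draft(c(chr4 = "chromosome", chrX = "chromosome",
                        scafA = "unlocalized_scaffold",
                        scafB = "unlocalized_scaffold"))
  ch <- fake_chain("gS", list(
    fake_placed(1L, "chr4", 1000L, 1100L),
    fake_placed(2L, "chr4", 2000L, 2100L),
    fake_placed(3L, "chrX", 5000L, 5100L),
    fake_placed(4L, "chrX", 6000L, 6100L),
    fake_placed(5L, "chrX", 7000L, 7100L),
    fake_placed(6L, "scafA", 900L, 1000L),
    fake_placed(7L, "scafB", 2900L, 3000L),
    fake_placed(8L, "scafB", 3500L, 3600L)), seq_name = "chr4")
  d <- diagnose_chain(ch, draft, id_synteny(c("chr4", "chrX")))
  kinds <- vapply(d$anomalies, `[[`, "", "kind")
  expect_setequal(kinds, c("SPLIT_CHROMOSOME", "SPLIT_UNLOCALIZED"))
  expect_identical(d$synteny_expected_target, "chr4")
  sc <- d$anomalies[[which(kinds == "SPLIT_CHROMOSOME")]]
  expect_setequal(sc$payload$misplaced_exons, 3:5)
})

test_that("even with one chromosome in use, scaffold evidence splits the gene", {
  # every chromosome-placed exon on the wrong chromosome, the rest on a
  # scaffold of the expected one
  draft <- fake_draft(c(chr4 = "chromosome", chrX = "chromosome",
                        scafA = "unlocalized_scaffold"))
  ch <- fake_chain("gS", list(
    fake_placed(1L, "chrX", 5000L, 5100L),
    fake_placed(2L, "chrX", 6000L, 6100L),
    fake_placed(3L, "scafA", 900L, 1000L)), seq_name = "chr4")
  kinds <- vapply(diagnose_chain(ch, draft,
                                 id_synteny(c("chr4", "chrX")))$anomalies,
                  `[[`, "", "kind")
  expect_true("SPLIT_CHROMOSOME" %in% kinds)
})

test_that("strand minorities and order violations are called", {
  draft <- fake_draft(c(chr1 = "chromosome"))
  syn <- id_synteny("chr1")
  # exon 9 on the opposite strand
  entries <- lapply(1:10, function(i)
    fake_placed(i, "chr1", i * 1000L, i * 1000L + 100L))
  entries[[9L]]$strand <- "-"
  d <- diagnose_chain(fake_chain("gF", entries, seq_name = "chr1"),
                      draft, syn)
  kinds <- vapply(d$anomalies, `[[`, "", "kind")
  expect_identical(kinds, "ORIENTATION_FLIP")
  expect_equal(d$anomalies[[1L]]$payload$exons, 9L)

  # consistent chain: silence
  d2 <- diagnose_chain(fake_chain("gC", lapply(1:6, function(i)
    fake_placed(i, "chr1", i * 1000L, i * 1000L + 100L)),
    seq_name = "chr1"), draft, syn)
  expect_length(d2$anomalies, 0L)

  # exons swapped by more than a span: order anomaly
  entries3 <- lapply(1:4, function(i)
    fake_placed(i, "chr1", i * 1000L, i * 1000L + 100L))
  entries3[[2L]]$target_start <- 3500L
  entries3[[2L]]$target_end <- 3600L
  d3 <- diagnose_chain(fake_chain("gO", entries3, seq_name = "chr1"),
                       draft, syn)
  kinds3 <- vapply(d3$anomalies, `[[`, "", "kind")
  expect_true("ORDER_ANOMALY" %in% kinds3)

  # overlapping tandem placements within one exon span are tolerated
  entries4 <- lapply(1:3, function(i)
    fake_placed(i, "chr1", i * 1000L, i * 1000L + 100L))
  entries4[[2L]]$target_start <- 970L   # 30 bp before exon 1 start + span
  entries4[[2L]]$target_end <- 1070L
  d4 <- diagnose_chain(fake_chain("gT", entries4, seq_name = "chr1"),
                       draft, syn)
  expect_length(d4$anomalies, 0L)

  # adjacent exons over 1 Mb apart: distance variant
  entries5 <- list(fake_placed(1L, "chr1", 1000L, 1100L),
                   fake_placed(2L, "chr1", 1500000L, 1500100L))
  draft5 <- fake_draft(c(chr1 = "chromosome"),
                       lengths = c(chr1 = 2000000L))
  d5 <- diagnose_chain(fake_chain("gD", entries5, seq_name = "chr1"),
                       draft5, syn)
  expect_identical(d5$anomalies[[1L]]$payload$variant, "distance")

  # a fully unplaced chain is an empty diagnosis with a note
  d6 <- diagnose_chain(fake_chain("gU", list(fake_unplaced(1L),
                                             fake_unplaced(2L))),
                       draft, syn)
  expect_length(d6$anomalies, 0L)
  expect_match(d6$note, "no placed")
})

test_that("injected contig-level defects are recovered on every carrier gene", {
  for (cls in c("CONTIG_MISASSIGNMENT", "UNLOCALIZED_SPLIT",
                "ORIENTATION_FLIP")) {
    b <- cached_run(paste0("ctg_", cls),
                    run_pipeline(small_config(seed = 77L, n_genes = 14L),
                                 defect_specs = list(defect_spec(cls, 1L))))
    ft <- findings_table(b$findings)
    expect_gte(nrow(b$defects), 1L)
    want <- c(CONTIG_MISASSIGNMENT = "SPLIT_CHROMOSOME",
              UNLOCALIZED_SPLIT = "SPLIT_UNLOCALIZED",
              ORIENTATION_FLIP = "ORIENTATION_FLIP")[[cls]]
    for (g in b$defects$gene_id) {
      expect_true(any(ft$gene_id == g & ft$kind == want),
                  info = paste(cls, g))
      expect_identical(b$verdicts$category[b$verdicts$gene_id == g],
                       "wrong")
    }
    # no calls of that kind on genes without a defect record
    callers <- unique(ft$gene_id[ft$kind == want])
    expect_true(all(callers %in% b$defects$gene_id))
  }
})

test_that("unintegrated single-contig scaffolds are flagged as such", {
  b <- cached_run("ctg_UNLOCALIZED_SPLIT",
                  run_pipeline(small_config(seed = 77L, n_genes = 14L),
                               defect_specs = list(
                                 defect_spec("UNLOCALIZED_SPLIT", 1L))))
  hit <- Filter(function(f) f$kind == "SPLIT_UNLOCALIZED" &&
                  isTRUE(f$payload$unintegrated_contig), b$findings)
  expect_gte(length(hit), 1L)

  # a multi-contig scaffold is a plain split, not an unintegrated contig
  pl <- data.frame(contig_id = c("c1", "c2"), target = "scafM",
                   start = c(0L, 1100L), end = c(1000L, 2000L),
                   orientation = "+", stringsAsFactors = FALSE)
  draft <- assembly(
    c(chr1 = strrep("A", 50000L), scafM = strrep("A", 2000L)),
    c(chr1 = "chromosome", scafM = "unlocalized_scaffold",
      c1 = "contig", c2 = "contig"), pl)
  ch <- fake_chain("gM", list(
    fake_placed(1L, "chr1", 1000L, 1100L),
    fake_placed(2L, "scafM", 100L, 200L)), seq_name = "chr1")
  expect_length(check_unintegrated(ch, draft, id_synteny("chr1")), 0L)
})

test_that("chimeric contigs are localized and interleaving is ambiguous", {
  b <- cached_run("chim",
                  run_pipeline(small_config(seed = 88L, n_genes = 14L),
                               defect_specs = list(
                                 defect_spec("CHIMERIC_FUSION", 1L))))
  recs <- b$defects[b$defects$class == "CHIMERIC_FUSION", ]
  expect_gte(nrow(recs), 2L)   # both sides' genes are logged
  pl <- jsonlite::fromJSON(recs$payload[1L])
  d <- b$contig_diagnoses[[pl$contig]]
  expect_identical(d$verdict, "chimeric")
  expect_lte(d$breakpoint_interval[1L], pl$fusion_point)
  expect_gte(d$breakpoint_interval[2L], pl$fusion_point)
  ft <- findings_table(b$findings)
  for (g in recs$gene_id) {
    expect_true(any(ft$gene_id == g & ft$kind == "CHIMERIC_CONTIG"))
  }
  # all other contigs stay consistent
  other <- Filter(function(x) x$contig_id != pl$contig &&
                    !x$evidence_absent, b$contig_diagnoses)
  expect_true(all(vapply(other, `[[`, "", "verdict") == "consistent"))

  # interleaved conflicting placements do not make a chimera call
  plc <- data.frame(contig_id = "c1", target = "chr1", start = 0L,
                    end = 10000L, orientation = "+",
                    stringsAsFactors = FALSE)
  draft <- assembly(c(chr1 = strrep("A", 10000L)),
                    c(chr1 = "chromosome", c1 = "contig"), plc)
  chA <- fake_chain("gA", list(fake_placed(1L, "chr1", 1000L, 1100L),
                               fake_placed(2L, "chr1", 5000L, 5100L)),
                    seq_name = "chr1")
  chB <- fake_chain("gB", list(fake_placed(1L, "chr1", 3000L, 3100L),
                               fake_placed(2L, "chr1", 7000L, 7100L)),
                    seq_name = "chr2")
  r <- diagnose_contigs(list(gA = chA, gB = chB), draft,
                        synteny_map(c("chr1", "chr2"), c("chr1", "chr2")))
  expect_identical(r$diagnoses[["c1"]]$verdict, "consistent")
  kinds <- vapply(r$findings, `[[`, "", "kind")
  expect_true(all(kinds == "AMBIGUOUS_PLACEMENT"))
  expect_setequal(unique(vapply(r$findings, `[[`, "", "gene_id")),
                  c("gA", "gB"))
})

test_that("anomaly calls are invariant under global reverse complement", {
  b <- cached_run("ctg_ORIENTATION_FLIP",
                  run_pipeline(small_config(seed = 77L, n_genes = 14L),
                               defect_specs = list(
                                 defect_spec("ORIENTATION_FLIP", 1L))))
  rc_draft <- assembly(vapply(b$draft$sequences, revcomp, character(1L)),
                       b$draft$role)
  chains2 <- map_transcripts(b$truth$models, b$truth$assembly, rc_draft)
  for (g in names(chains2)) {
    k1 <- sort(vapply(diagnose_chain(b$chains[[g]], b$draft,
                                     b$synteny)$anomalies, `[[`, "",
                      "kind"))
    k2 <- sort(vapply(diagnose_chain(chains2[[g]], rc_draft,
                                     b$synteny)$anomalies, `[[`, "",
                      "kind"))
    expect_identical(k2, k1, label = paste("gene", g))
  }
})
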