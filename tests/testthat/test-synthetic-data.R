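test_that("generated genes are well-formed protein-coding models", {
  truth <- cached_run("truth50", generate_truth(sim_config(seed = 42L)))
  expect_length(truth$models, 50L)
  for (m in truth$models) {
    cds <- cds_sequence(truth$assembly, m)
    expect_identical(substr(cds, 1L, 3L), "ATG")
    expect_true(substr(cds, nchar(cds) - 2L, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
    tr <- translate_cds(cds)
    expect_true(is.na(tr$internal_stop))
  }
})

test_that("every intron carries GT..AG splice dinucleotides", {
  truth <- cached_run("truth50", generate_truth(sim_config(seed = 42L)))
  n_introns <- 0L
  for (m in truth$models) {
    n <- nrow(m$exons)
    if (n < 2L) next
    chrom <- truth$assembly$sequences[[m$seq_name]]
    for (i in seq_len(n - 1L)) {
      # intron between exon i and i+1, in transcription orientation
      if (m$strand == "+") {
        intron <- substr(chrom, m$exons[i, 2L] + 1L, m$exons[i + 1L, 1L])
      } else {
        intron <- revcomp(substr(chrom, m$exons[i + 1L, 2L] + 1L,
                                 m$exons[i, 1L]))
      }
      expect_identical(substr(intron, 1L, 2L), "GT")
      expect_identical(substr(intron, nchar(intron) - 1L, nchar(intron)),
                       "AG")
      n_introns <- n_introns + 1L
    }
  }
  expect_gt(n_introns, 100L)
})

test_that("truth generation is byte-deterministic in seed", {
  a <- generate_truth(small_config(seed = 9L))
  b <- generate_truth(small_config(seed = 9L))
  expect_identical(a$assembly$sequences, b$assembly$sequences)
  expect_identical(a$models, b$models)
  c2 <- generate_truth(small_config(seed = 10L))
  expect_false(identical(a$assembly$sequences, c2$assembly$sequences))
})

test_that("a defect-free draft reassembles the truth exactly", {
  truth <- generate_truth(small_config())
  dd <- derive_draft(truth$assembly, truth$models, list(), seed = 5L)
  for (ch in names(truth$assembly$sequences)) {
    expect_identical(gsub("N", "", dd$draft$sequences[[ch]], fixed = TRUE),
                     truth$assembly$sequences[[ch]])
  }
  expect_equal(nrow(dd$defects), 0L)
  expect_length(dd$draft_models, length(truth$models))
})

test_that("the defect log is reproducible and one row per affected gene", {
  truth <- cached_run("truth50", generate_truth(sim_config(seed = 42L)))
  d1 <- derive_draft(truth$assembly, truth$models, default_defect_specs(),
                     seed = 7L)
  d2 <- derive_draft(truth$assembly, truth$models, default_defect_specs(),
                     seed = 7L)
  expect_identical(d1$defects, d2$defects)
  expect_identical(d1$draft$sequences, d2$draft$sequences)
  expect_false(anyDuplicated(d1$defects$gene_id) > 0L)
  # sequence/annotation-level classes: exactly as many records as specs ask
  n_seq <- sum(d1$defects$class %in%
                 c("STOP_SUBSTITUTION", "FRAMESHIFT_INDEL", "EXON_GAP",
                   "PARTIAL_EXON_GAP", "ANNOTATION_DROP",
                   "MODEL_TRUNCATION"))
  expect_equal(n_seq, 4L + 4L + 4L + 3L + 3L + 3L)
})

test_that("defect log round-trips through TSV, including empty", {
  truth <- generate_truth(small_config())
  dd <- derive_draft(truth$assembly, truth$models,
                     list(defect_spec("STOP_SUBSTITUTION", 2L),
                          defect_spec("ANNOTATION_DROP", 1L)),
                     seed = 3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_defect_log(dd$defects, f)
  back <- read_defect_log(f)
  expect_equal(back, dd$defects, ignore_attr = TRUE)

  write_defect_log(dd$defects[0, ], f)
  empty <- read_defect_log(f)
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty), names(dd$defects))
})

test_that("non-N sequence is conserved up to logged indels and fusions", {
  truth <- cached_run("truth50", generate_truth(sim_config(seed = 42L)))
  dd <- derive_draft(truth$assembly, truth$models, default_defect_specs(),
                     seed = 13L)
  non_n <- function(seqs) sum(nchar(seqs)) -
    sum(vapply(seqs, function(s)
      sum(utf8ToInt(s) == utf8ToInt("N")), numeric(1L)))
  delta <- 0L
  seen_fusions <- character(0)
  for (i in seq_len(nrow(dd$defects))) {
    pl <- jsonlite::fromJSON(dd$defects$payload[i])
    cls <- dd$defects$class[i]
    if (cls == "FRAMESHIFT_INDEL") {
      delta <- delta + ifelse(pl$kind == "ins", pl$k, -pl$k)
    } else if (cls == "EXON_GAP") {
      delta <- delta - (dd$defects$end[i] - dd$defects$start[i])
    } else if (cls == "PARTIAL_EXON_GAP") {
      delta <- delta - pl$len
    } else if (cls == "CHIMERIC_FUSION" && !pl$contig %in% seen_fusions) {
      seen_fusions <- c(seen_fusions, pl$contig)
      delta <- delta - pl$lost_bases
    }
  }
  expect_equal(non_n(dd$draft$sequences),
               non_n(truth$assembly$sequences) + delta)
})

test_that("a lone point defect changes only its logged locus", {
  truth <- generate_truth(small_config(seed = 21L))
  for (cls in c("STOP_SUBSTITUTION", "PARTIAL_EXON_GAP")) {
    clean <- derive_draft(truth$assembly, truth$models, list(), seed = 8L)
    dd <- derive_draft(truth$assembly, truth$models,
                       list(defect_spec(cls, 1L)), seed = 8L)
    rec <- dd$defects[1L, ]
    for (nm in names(dd$draft$sequences)) {
      a <- utf8ToInt(clean$draft$sequences[[nm]])
      b <- utf8ToInt(dd$draft$sequences[[nm]])
      expect_equal(length(a), length(b))
      diffs <- which(a != b)
      if (nm == rec$seq) {
        expect_true(length(diffs) >= 1L)
        expect_true(all(diffs - 1L >= rec$start & diffs - 1L < rec$end))
      } else {
        expect_length(diffs, 0L)
      }
    }
  }
})

test_that("frameshift indels corrupt the translation downstream", {
  truth <- generate_truth(small_config(seed = 33L))
  dd <- derive_draft(truth$assembly, truth$models,
                     list(defect_spec("FRAMESHIFT_INDEL", 2L)), seed = 2L)
  models <- setNames(truth$models,
                     vapply(truth$models, `[[`, "", "gene_id"))
  for (i in seq_len(nrow(dd$defects))) {
    g <- dd$defects$gene_id[i]
    pl <- jsonlite::fromJSON(dd$defects$payload[i])
    expect_true(pl$k %% 3L != 0L)
    # draft model translation diverges from the truth protein downstream
    dm <- Filter(function(m) m$gene_id == g, dd$draft_models)[[1L]]
    truth_prot <- translate_cds(cds_sequence(truth$assembly, models[[g]]))
    draft_cds <- cds_sequence(dd$draft, dm)
    draft_prot <- translate_cds(substr(draft_cds, 1L,
                                       nchar(draft_cds) -
                                         nchar(draft_cds) %% 3L))
    expect_false(identical(truth_prot$protein, draft_prot$protein))
    # identical up to the codon containing the indel
    agree_to <- pl$cds_offset %/% 3L
    expect_identical(substr(draft_prot$protein, 1L, agree_to),
                     substr(truth_prot$protein, 1L, agree_to))
  }
})

test_that("defect specs validate and infeasible classes error", {
  expect_error(defect_spec("NO_SUCH_CLASS"), "unknown")
  truth1 <- generate_truth(sim_config(n_chromosomes = 1L, n_genes = 6L,
                                      seed = 2L))
  expect_error(derive_draft(truth1$assembly, truth1$models,
                            list(defect_spec("CONTIG_MISASSIGNMENT", 1L)),
                            seed = 1L),
               "two chromosomes")
})
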