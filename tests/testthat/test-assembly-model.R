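test_that("FASTA round-trips and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(">a\nACGT", f)
  expect_identical(read_fasta(f), c(a = "ACGT"))

  seqs <- c(chr1 = strrep("ACGTN", 30L), chr2 = "TTTTACGT",
            scaf = "GGGCCCAAA")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)

  writeLines(c(">a", "ACGT", ">a", "TTTT"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(c(">ok", "ACGT", ">amb", "ACRT"), f)
  expect_error(read_fasta(f), "amb")
})

test_that("GFF3 I/O converts coordinates and round-trips models", {
  # single-exon gene at GFF3 1..9 becomes internal (0, 9)
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t1\t9\t.\t+\t.\tID=g1",
               "chr1\t.\tmRNA\t1\t9\t.\t+\t.\tID=g1.t1;Parent=g1",
               "chr1\t.\texon\t1\t9\t.\t+\t.\tID=e1;Parent=g1.t1",
               "chr1\t.\tCDS\t1\t9\t.\t+\t.\tID=c1;Parent=g1.t1"), f)
  models <- read_gff3(f)
  expect_length(models, 1L)
  expect_equal(unname(models[[1L]]$exons[1L, ]), c(0L, 9L))
  expect_equal(models[[1L]]$cds_span, c(0L, 9L))

  # two-gene fixture, one on each strand, with UTRs
  m1 <- transcript_model("gA", "gA.t1", "chr1", "+",
                         cbind(c(10L, 200L), c(100L, 320L)),
                         c(15L, 195L))
  m2 <- transcript_model("gB", "gB.t1", "chr2", "-",
                         cbind(c(500L, 100L), c(640L, 230L)),
                         c(0L, 240L))
  write_gff3(list(m1, m2), f)
  back <- read_gff3(f)
  back <- back[order(vapply(back, `[[`, "", "gene_id"))]
  for (i in 1:2) {
    orig <- list(m1, m2)[[i]]
    expect_equal(back[[i]]$exons, orig$exons)
    expect_equal(back[[i]]$cds_span, orig$cds_span)
    expect_identical(back[[i]]$strand, orig$strand)
    expect_identical(back[[i]]$seq_name, orig$seq_name)
  }

  writeLines(c("##gff-version 3",
               "chr1\t.\tmRNA\t1\t9\t.\t+\t.\tID=orphan.t1",
               "chr1\t.\texon\t1\t9\t.\t+\t.\tID=e1;Parent=orphan.t1",
               "chr1\t.\tCDS\t1\t9\t.\t+\t.\tID=c1;Parent=orphan.t1"), f)
  expect_error(read_gff3(f), "orphan")

  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t1\t50\t.\t+\t.\tID=g1",
               "chr1\t.\tmRNA\t1\t50\t.\t+\t.\tID=g1.t1;Parent=g1",
               "chr1\t.\texon\t1\t80\t.\t+\t.\tID=e1;Parent=g1.t1",
               "chr1\t.\tCDS\t1\t50\t.\t+\t.\tID=c1;Parent=g1.t1"), f)
  expect_error(read_gff3(f), "outside")
})

test_that("placement table I/O converts 1-based inclusive to internal", {
  p <- data.frame(contig_id = c("c1", "c2"), target = "chr1",
                  start = c(0L, 150L), end = c(100L, 400L),
                  orientation = c("+", "-"), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_placements(p, f)
  raw <- read.delim(f)
  expect_equal(raw$start, c(1L, 151L))   # first base is 1 on disk
  expect_equal(raw$end, c(100L, 400L))   # last base inclusive
  expect_equal(read_placements(f), p)
})

test_that("spliced_sequence splices and reverse complements", {
  asm <- assembly(c(s = "AAATTTGGG"))
  mplus <- transcript_model("g", "t", "s", "+",
                            cbind(c(0L, 6L), c(3L, 9L)), c(0L, 6L))
  expect_identical(spliced_sequence(asm, mplus), "AAAGGG")

  mminus <- transcript_model("g", "t", "s", "-",
                             cbind(c(6L, 0L), c(9L, 3L)), c(0L, 6L))
  expect_identical(spliced_sequence(asm, mminus), "CCCTTT")

  # a minus-strand gene equals the plus-strand splice on the
  # reverse-complemented chromosome
  set.seed(11)
  chrom <- random_seq(400L)
  ex_minus <- cbind(c(300L, 120L, 20L), c(360L, 200L, 90L))
  m <- transcript_model("g", "t", "s", "-", ex_minus, c(0L, 210L))
  asm2 <- assembly(c(s = chrom))
  rc <- revcomp(chrom)
  n <- nchar(chrom)
  ex_plus <- cbind(n - ex_minus[, 2L], n - ex_minus[, 1L])
  m2 <- transcript_model("g", "t", "s", "+", ex_plus, c(0L, 210L))
  asm3 <- assembly(c(s = rc))
  expect_identical(spliced_sequence(asm2, m), spliced_sequence(asm3, m2))

  bad <- transcript_model("g", "t", "s", "+",
                          cbind(0L, 20L), c(0L, 20L))
  expect_error(spliced_sequence(assembly(c(s = "ACGTACGT")), bad),
               "beyond")
})

test_that("translate_cds follows the standard code and flags stops", {
  r <- translate_cds("ATGAAATAG")
  expect_identical(r$protein, "MK")
  expect_true(is.na(r$internal_stop))

  r2 <- translate_cds("ATGTAAAAATAG")
  expect_identical(r2$protein, "M")
  expect_identical(r2$internal_stop, 1L)

  expect_warning(r3 <- translate_cds("ATGAAATAGCC"), "ignored")
  expect_identical(r3$protein, "MK")

  # random CDS agrees with an independent translation (Biostrings)
  set.seed(5)
  for (i in 1:5) {
    s <- random_seq(300L)
    mine <- translate_cds(s)
    oracle <- as.character(Biostrings::translate(
      Biostrings::DNAString(s), if.fuzzy.codon = "X"))
    stop_at <- regexpr("*", oracle, fixed = TRUE)
    expect_identical(mine$protein,
                     if (stop_at > 0) substr(oracle, 1L, stop_at - 1L)
                     else oracle)
    if (stop_at > 0 && stop_at < nchar(oracle)) {
      expect_identical(mine$internal_stop, as.integer(stop_at) - 1L)
    }
  }
})

test_that("revcomp is an involution and matches Biostrings", {
  set.seed(3)
  for (i in 1:10) {
    s <- random_seq(sample(200L, 1L), c("A", "C", "G", "T", "N"))
    expect_identical(revcomp(revcomp(s)), s)
    expect_identical(revcomp(s), as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }
})

test_that("assembly invariants are enforced", {
  expect_error(assembly(c(a = "ACGT", a = "TTTT")), "duplicate")
  expect_error(assembly(c(a = "ACRT")), "outside")
  pl <- data.frame(contig_id = "c1", target = "nope", start = 0L,
                   end = 4L, orientation = "+")
  expect_error(assembly(c(a = "ACGT"), placements = pl), "not in assembly")
  pl2 <- data.frame(contig_id = c("c1", "c2"), target = "a",
                    start = c(0L, 2L), end = c(4L, 6L),
                    orientation = "+")
  expect_error(assembly(c(a = "ACGTACGT"),
                        c(a = "chromosome", c1 = "contig", c2 = "contig"),
                        pl2), "overlap")
})

test_that("contig slicing honours orientation and gaps are located", {
  pl <- data.frame(contig_id = c("c1", "c2"), target = "chr",
                   start = c(0L, 8L), end = c(4L, 12L),
                   orientation = c("+", "-"), stringsAsFactors = FALSE)
  asm <- assembly(c(chr = "ACGTNNNNTTAA"),
                  c(chr = "chromosome", c1 = "contig", c2 = "contig"), pl)
  expect_identical(contig_sequence(asm, "c1"), "ACGT")
  expect_identical(contig_sequence(asm, "c2"), revcomp("TTAA"))

  loc <- target_to_contig(asm$placements, "chr", 9L, 11L)
  expect_identical(loc$contig_id, "c2")
  expect_equal(c(loc$start, loc$end), c(1L, 3L))   # flipped frame

  g <- find_gaps(asm, min_gap_len = 4L)
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$start, g$end), c(4L, 8L))
  expect_equal(nrow(find_gaps(asm, min_gap_len = 5L)), 0L)
})
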