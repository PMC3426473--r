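#' Simulation configuration
#'
#' Parameters of the synthetic truth genome. Defaults describe a compact
#' multi-exon vertebrate-like gene complement: 50 protein-coding genes of
#' 4-8 exons spread over 2 chromosomes, with introns long enough that a
#' gene typically spans several of the 5-15 kb contigs the draft is tiled
#' into (see [tiling_config()]).
#'
#' @param n_chromosomes number of chromosomes.
#' @param n_genes total genes, distributed evenly over chromosomes.
#' @param exons_per_gene integer range `c(min, max)`.
#' @param exon_length range in bp (minimum 30: shorter exons carry too
#'   little alignment signal to be placed).
#' @param intron_length range in bp.
#' @param intergenic_length range in bp.
#' @param gc_fraction GC content of generated sequence, in (0, 1).
#' @param utr5_length,utr3_length ranges in bp for untranslated termini
#'   of the first/last exon.
#' @param seed integer seed; the whole truth genome is a deterministic
#'   function of the configuration.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L, n_genes = 50L,
                       exons_per_gene = c(4L, 8L),
                       exon_length = c(90L, 260L),
                       intron_length = c(1000L, 4000L),
                       intergenic_length = c(500L, 3000L),
                       gc_fraction = 0.45,
                       utr5_length = c(0L, 45L),
                       utr3_length = c(0L, 90L),
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              intergenic_length = as.integer(intergenic_length),
              gc_fraction = gc_fraction,
              utr5_length = as.integer(utr5_length),
              utr3_length = as.integer(utr3_length),
              seed = as.integer(seed))
  for (f in c("exons_per_gene", "exon_length", "intron_length",
              "intergenic_length", "utr5_length", "utr3_length")) {
    r <- cfg[[f]]
    if (length(r) != 2L || any(r < 0L) || r[1L] > r[2L]) {
      stop("invalid range for ", f)
    }
  }
  if (cfg$exon_length[1L] < 30L) stop("exon_length minimum must be >= 30")
  if (cfg$exons_per_gene[1L] < 1L) stop("need at least one exon per gene")
  if (cfg$intron_length[1L] < 8L) stop("introns must be >= 8 bp")
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stop("gc_fraction must be in (0, 1)")
  }
  if (cfg$n_chromosomes < 1L || cfg$n_genes < 1L) {
    stop("need at least one chromosome and one gene")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Evaluate expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic 31-bit sub-seed from a root seed and a string key, so a
# defect's randomness depends on its gene and not on spec ordering.
sub_seed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (v in utf8ToInt(key)) {
    h <- (h * 31 + v) %% 2147483647   # doubles: exact below 2^53
  }
  as.integer(h)
}

rand_int <- function(range) {
  if (range[1L] == range[2L]) return(range[1L])
  sample.int(range[2L] - range[1L] + 1L, 1L) + range[1L] - 1L
}

random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# n sense codons (no stops), per-base GC-biased.
random_sense_codons <- function(n, gc) {
  stops <- c("TAA", "TAG", "TGA")
  out <- character(n)
  i <- 1L
  while (i <= n) {
    cod <- random_dna(3L, gc)
    if (!cod %in% stops) {
      out[i] <- cod
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

random_intron <- function(n, gc) {
  # canonical GT..AG splice dinucleotides
  paste0("GT", random_dna(n - 4L, gc), "AG")
}

#' Generate a synthetic truth genome and annotation
#'
#' Builds chromosomes gene by gene. Every gene has an ATG-initiated CDS
#' ending in a stop codon, no internal stop codons, and GT..AG splice
#' dinucleotides on every intron. Roughly half the genes are placed on
#' the reverse strand. The result is byte-deterministic for a fixed
#' configuration.
#'
#' @param config a [sim_config()].
#' @return list with `assembly` (chromosomes only, no placements),
#'   `models` (list of [transcript_model()]) and `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    gc <- config$gc_fraction
    per_chrom <- diff(c(0L, round(seq_len(config$n_chromosomes) *
                                    config$n_genes / config$n_chromosomes)))
    seqs <- character(0)
    models <- list()
    gi <- 0L
    for (ci in seq_len(config$n_chromosomes)) {
      chrom_name <- paste0("chr", ci)
      parts <- character(0)
      pos <- 0L
      add <- function(s) {
        parts[[length(parts) + 1L]] <<- s
        pos <<- pos + nchar(s)
      }
      add(random_dna(rand_int(config$intergenic_length), gc))
      for (g in seq_len(per_chrom[ci])) {
        gi <- gi + 1L
        gene_id <- sprintf("g%03d", gi)
        n_exon <- rand_int(config$exons_per_gene)
        ex_len <- vapply(seq_len(n_exon), function(i)
          rand_int(config$exon_length), integer(1L))
        in_len <- if (n_exon > 1L) {
          vapply(seq_len(n_exon - 1L), function(i)
            rand_int(config$intron_length), integer(1L))
        } else integer(0)
        u5 <- min(rand_int(config$utr5_length), ex_len[1L] - 10L)
        u3 <- min(rand_int(config$utr3_length), ex_len[n_exon] - 10L)
        u5 <- max(u5, 0L); u3 <- max(u3, 0L)
        splen <- sum(ex_len)
        cds_len <- splen - u5 - u3
        u3 <- u3 + cds_len %% 3L            # keep CDS a codon multiple
        cds_len <- cds_len - cds_len %% 3L
        if (cds_len < 30L) stop("gene ", gene_id,
                                " infeasible: CDS under 10 codons")
        cds <- paste0("ATG", random_sense_codons(cds_len / 3L - 2L, gc),
                      sample(c("TAA", "TAG", "TGA"), 1L))
        spliced <- paste0(random_dna(u5, gc), cds, random_dna(u3, gc))
        strand <- sample(c("+", "-"), 1L)
        # exon sequences in transcription order
        ends <- cumsum(ex_len)
        ex_seq <- substring(spliced, c(1L, ends[-n_exon] + 1L), ends)
        introns <- vapply(in_len, function(n) random_intron(n, gc),
                          character(1L))
        gene_seq_tx <- paste0(  # gene body in transcription orientation
          paste0(ex_seq, c(introns, "")), collapse = "")
        gene_len <- nchar(gene_seq_tx)
        gene_start <- pos
        if (strand == "+") {
          add(gene_seq_tx)
          ex_start_tx <- cumsum(c(0L, (ex_len + c(in_len, 0L))[-n_exon]))
          exons <- cbind(gene_start + ex_start_tx,
                         gene_start + ex_start_tx + ex_len)
        } else {
          add(revcomp(gene_seq_tx))
          ex_start_tx <- cumsum(c(0L, (ex_len + c(in_len, 0L))[-n_exon]))
          exons <- cbind(gene_start + gene_len - (ex_start_tx + ex_len),
                         gene_start + gene_len - ex_start_tx)
        }
        models[[gene_id]] <- transcript_model(
          gene_id, paste0(gene_id, ".t1"), chrom_name, strand,
          exons, c(u5, u5 + cds_len))
        add(random_dna(rand_int(config$intergenic_length), gc))
      }
      seqs[[chrom_name]] <- paste(parts, collapse = "")
    }
    asm <- assembly(seqs)
    list(assembly = asm, models = unname(models), config = config)
  })
}
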