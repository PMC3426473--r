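#' Read a FASTA file of draft or reference sequences
#'
#' Plain or gzip-compressed FASTA. Records must have unique names and may
#' contain only A, C, G, T and N: the audit operates on unambiguous draft
#' sequence, so any other IUPAC code is rejected, naming the offending
#' record.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence name in ", path, ": ",
         nm[duplicated(nm)][1L])
  }
  seqs <- stats::setNames(as.character(set), nm)
  for (i in seq_along(seqs)) {
    if (grepl("[^ACGTN]", seqs[[i]])) {
      stop("record '", nm[i], "' in ", path,
           " contains IUPAC codes other than A/C/G/T/N")
    }
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector (an [assembly()] is also
#'   accepted; its sequences are written).
#' @param path output file; a `.gz` suffix writes gzip-compressed output.
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, "assembly")) sequences <- sequences$sequences
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' Expects the conventional gene/mRNA/exon/CDS feature hierarchy. GFF3
#' 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. An mRNA without a gene parent, or an exon/CDS
#' outside its mRNA span, is rejected naming the feature.
#'
#' @param path GFF3 file (plain or gzip).
#' @return list of [transcript_model()] objects.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- vapply(gr$Parent, function(p) {
    if (length(p)) as.character(p[1L]) else NA_character_
  }, character(1L))
  gene_ids <- id[type == "gene"]
  models <- list()
  for (i in which(type == "mRNA")) {
    tid <- id[i]
    gid <- parent[i]
    if (is.na(gid) || !gid %in% gene_ids) {
      stop("mRNA '", tid, "' has no gene parent in ", path)
    }
    strand <- as.character(BiocGenerics::strand(gr)[i])
    m_start <- BiocGenerics::start(gr)[i]
    m_end <- BiocGenerics::end(gr)[i]
    kid <- which(parent == tid)
    ex <- kid[type[kid] == "exon"]
    cd <- kid[type[kid] == "CDS"]
    if (!length(ex)) stop("mRNA '", tid, "' has no exons in ", path)
    ex_start <- BiocGenerics::start(gr)[ex]
    ex_end <- BiocGenerics::end(gr)[ex]
    if (any(ex_start < m_start | ex_end > m_end)) {
      stop("exon outside mRNA span for '", tid, "' in ", path)
    }
    ord <- order(ex_start)
    if (strand == "-") ord <- rev(ord)
    exons <- cbind(start = ex_start[ord] - 1L, end = ex_end[ord])
    # CDS rows -> spliced offsets
    if (!length(cd)) stop("mRNA '", tid, "' has no CDS in ", path)
    cd_start <- min(BiocGenerics::start(gr)[cd]) - 1L
    cd_end <- max(BiocGenerics::end(gr)[cd])
    if (cd_start < min(exons[, 1L]) || cd_end > max(exons[, 2L])) {
      stop("CDS outside mRNA span for '", tid, "' in ", path)
    }
    cds_span <- genomic_to_spliced_span(exons, strand, cd_start, cd_end)
    models[[tid]] <- transcript_model(gid, tid,
                                      as.character(GenomicRanges::seqnames(gr))[i],
                                      strand, exons, cds_span)
  }
  unname(models)
}

# Map a genomic interval [g0, g1) covering the CDS extremes onto 0-based
# half-open spliced-transcript offsets.
genomic_to_spliced_span <- function(exons, strand, g0, g1) {
  lens <- exons[, 2L] - exons[, 1L]
  offs <- cumsum(c(0L, lens[-length(lens)]))
  pos_of <- function(g) {  # spliced offset of genomic position g (0-based)
    for (i in seq_len(nrow(exons))) {
      if (g >= exons[i, 1L] && g < exons[i, 2L]) {
        return(if (strand == "+") offs[i] + (g - exons[i, 1L])
               else offs[i] + (exons[i, 2L] - 1L - g))
      }
    }
    stop("CDS boundary not inside any exon")
  }
  if (strand == "+") {
    c(pos_of(g0), pos_of(g1 - 1L) + 1L)
  } else {
    c(pos_of(g1 - 1L), pos_of(g0) + 1L)
  }
}

# Inverse: spliced offsets -> genomic CDS blocks (list of c(start,end)).
spliced_to_genomic_blocks <- function(exons, strand, sp0, sp1) {
  lens <- exons[, 2L] - exons[, 1L]
  offs <- cumsum(c(0L, lens[-length(lens)]))
  blocks <- list()
  for (i in seq_len(nrow(exons))) {
    lo <- max(sp0 - offs[i], 0L)
    hi <- min(sp1 - offs[i], lens[i])
    if (lo >= hi) next
    blocks[[length(blocks) + 1L]] <-
      if (strand == "+") c(exons[i, 1L] + lo, exons[i, 1L] + hi)
      else c(exons[i, 2L] - hi, exons[i, 2L] - lo)
  }
  blocks
}

#' Write transcript models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features with `ID`/`Parent` attributes,
#' converting internal 0-based half-open coordinates to GFF3 1-based
#' inclusive. `read_gff3(write_gff3(models))` reproduces the models.
#'
#' @param models list of [transcript_model()] objects.
#' @param path output file.
#' @export
write_gff3 <- function(models, path) {
  rows <- list()
  add <- function(seq, type, start0, end0, strand, id, parent,
                  phase = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seq = seq, type = type, start = start0 + 1L, end = end0,
      strand = strand, id = id, parent = parent, phase = phase,
      stringsAsFactors = FALSE)
  }
  for (m in models) {
    g0 <- min(m$exons[, 1L]); g1 <- max(m$exons[, 2L])
    add(m$seq_name, "gene", g0, g1, m$strand, m$gene_id, NA_character_)
    add(m$seq_name, "mRNA", g0, g1, m$strand, m$transcript_id, m$gene_id)
    for (i in seq_len(nrow(m$exons))) {
      add(m$seq_name, "exon", m$exons[i, 1L], m$exons[i, 2L], m$strand,
          paste0(m$transcript_id, ":exon", i), m$transcript_id)
    }
    cds <- spliced_to_genomic_blocks(m$exons, m$strand,
                                     m$cds_span[1L], m$cds_span[2L])
    done <- 0L   # coding bases upstream of this block, transcription order
    for (i in seq_along(cds)) {
      add(m$seq_name, "CDS", cds[[i]][1L], cds[[i]][2L], m$strand,
          paste0(m$transcript_id, ":cds", i), m$transcript_id,
          phase = (3L - done %% 3L) %% 3L)
      done <- done + cds[[i]][2L] - cds[[i]][1L]
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seq,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand)
  gr$type <- tab$type
  gr$phase <- tab$phase
  gr$ID <- tab$id
  gr$Parent <- S4Vectors::unname(IRanges::CharacterList(
    lapply(tab$parent, function(p) if (is.na(p)) character() else p)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write the contig placement table
#'
#' An AGP-like TSV with columns `contig_id`, `target`, `start`, `end`,
#' `orientation`; on disk the coordinates are 1-based inclusive, in
#' memory 0-based half-open.
#'
#' @param path TSV file (plain or gzip).
#' @return data.frame placement table (0-based half-open).
#' @export
read_placements <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$start <- as.integer(tab$start) - 1L
  tab$end <- as.integer(tab$end)
  tab
}

#' @rdname read_placements
#' @param placements in-memory placement table.
#' @export
write_placements <- function(placements, path) {
  out <- placements
  out$start <- out$start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a chromosome-correspondence (synteny) table
#'
#' Two-column TSV: `reference`, `draft`.
#'
#' @param path TSV file.
#' @return named character vector as from [synteny_map()].
#' @export
read_synteny <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  synteny_map(tab$reference, tab$draft)
}

#' @rdname read_synteny
#' @param map named character vector reference -> draft.
#' @export
write_synteny <- function(map, path) {
  utils::write.table(
    data.frame(reference = names(map), draft = unname(map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the ground-truth defect log
#'
#' TSV with one row per applied defect: `gene_id`, `class`, `seq`,
#' `start`, `end` (0-based half-open draft coordinates),
#' `expected_category`, `expected_findings` (comma-separated finding
#' kinds) and `payload` (JSON). Round-trips losslessly; an empty record
#' list yields a header-only file.
#'
#' @param records defect-record data.frame (see [derive_draft()]).
#' @param path TSV file.
#' @export
write_defect_log <- function(records, path) {
  cols <- c("gene_id", "class", "seq", "start", "end",
            "expected_category", "expected_findings", "payload")
  if (is.null(records) || !nrow(records)) {
    records <- data.frame(gene_id = character(), class = character(),
                          seq = character(), start = integer(),
                          end = integer(), expected_category = character(),
                          expected_findings = character(),
                          payload = character(), stringsAsFactors = FALSE)
  }
  utils::write.table(records[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_defect_log
#' @return `read_defect_log` returns the defect-record data.frame.
#' @export
read_defect_log <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = c(gene_id = "character",
                                          class = "character",
                                          seq = "character",
                                          start = "integer",
                                          end = "integer",
                                          expected_category = "character",
                                          expected_findings = "character",
                                          payload = "character"))
  tab
}

#' Read / write sequence roles
#'
#' Two-column TSV (`name`, `role`) recording which draft sequences are
#' chromosomes and which are unlocalized scaffolds (and which names are
#' contigs), so an [assembly()] can be reconstructed from files.
#'
#' @param role named character vector as held by an [assembly()].
#' @param path TSV file.
#' @export
write_roles <- function(role, path) {
  utils::write.table(data.frame(name = names(role), role = unname(role)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roles
#' @return `read_roles` returns the named character vector.
#' @export
read_roles <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$role, tab$name)
}

#' Reconstruct a draft assembly from its on-disk artifacts
#'
#' Expects `draft.fa`, `roles.tsv` and `placements.tsv` in `dir`, as
#' written by [run_pipeline()] or the analysis scripts.
#'
#' @param dir directory holding the three files.
#' @return an [assembly()].
#' @export
assembly_from_files <- function(dir) {
  assembly(read_fasta(file.path(dir, "draft.fa")),
           read_roles(file.path(dir, "roles.tsv")),
           read_placements(file.path(dir, "placements.tsv")))
}
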