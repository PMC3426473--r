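#' Assembly object
#'
#' An assembly is the audited object: a set of named nucleotide sequences
#' (alphabet A, C, G, T, N), a role for each sequence (`"chromosome"` or
#' `"unlocalized_scaffold"`), and a contig placement table describing how
#' contigs tile those sequences. Contig sequences are not stored twice:
#' they are recovered by slicing the target sequence at the placement
#' (see [contig_sequence()]).
#'
#' All coordinates held in an assembly are 0-based half-open. The on-disk
#' placement table uses 1-based inclusive coordinates, as AGP does;
#' [read_placements()] and [write_placements()] convert.
#'
#' @param sequences named character vector of nucleotide sequences.
#' @param role named character vector; one entry per sequence plus,
#'   optionally, one `"contig"` entry per placed contig. Values must be
#'   `"chromosome"`, `"unlocalized_scaffold"` or `"contig"`.
#' @param placements data.frame with columns `contig_id`, `target`,
#'   `start`, `end` (0-based half-open in target coordinates) and
#'   `orientation` (`"+"` or `"-"`). May be empty.
#' @return an object of class `assembly`.
#' @export
assembly <- function(sequences, role = NULL,
                     placements = empty_placements()) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("all assembly sequences must be named")
  }
  if (anyDuplicated(names(sequences))) {
    dup <- names(sequences)[duplicated(names(sequences))][1L]
    stop("duplicate sequence name: ", dup)
  }
  if (is.null(role)) {
    role <- stats::setNames(rep("chromosome", length(sequences)),
                            names(sequences))
  }
  bad_role <- setdiff(role, c("chromosome", "unlocalized_scaffold", "contig"))
  if (length(bad_role)) stop("unknown sequence role: ", bad_role[1L])
  missing_role <- setdiff(names(sequences), names(role))
  if (length(missing_role)) {
    stop("sequence without role: ", missing_role[1L])
  }
  check_nucleotides(sequences)
  placements <- validate_placements(placements, sequences)
  structure(list(sequences = sequences, role = role,
                 placements = placements),
            class = "assembly")
}

empty_placements <- function() {
  data.frame(contig_id = character(), target = character(),
             start = integer(), end = integer(),
             orientation = character(), stringsAsFactors = FALSE)
}

validate_placements <- function(placements, sequences) {
  req <- c("contig_id", "target", "start", "end", "orientation")
  if (!all(req %in% names(placements))) {
    stop("placement table must have columns ", paste(req, collapse = ", "))
  }
  placements <- placements[req]
  if (!nrow(placements)) return(placements)
  if (anyDuplicated(placements$contig_id)) {
    stop("duplicate contig_id in placements: ",
         placements$contig_id[duplicated(placements$contig_id)][1L])
  }
  unknown <- setdiff(placements$target, names(sequences))
  if (length(unknown)) stop("placement target not in assembly: ", unknown[1L])
  if (any(placements$start >= placements$end)) {
    stop("placement with start >= end: ",
         placements$contig_id[placements$start >= placements$end][1L])
  }
  if (!all(placements$orientation %in% c("+", "-"))) {
    stop("placement orientation must be '+' or '-'")
  }
  too_long <- placements$end > nchar(sequences)[placements$target]
  if (any(too_long)) {
    stop("placement extends beyond target: ",
         placements$contig_id[too_long][1L])
  }
  # placements on one target must not overlap
  for (tg in unique(placements$target)) {
    p <- placements[placements$target == tg, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) > 1L && any(p$start[-1L] < p$end[-nrow(p)])) {
      stop("overlapping placements on target ", tg)
    }
  }
  placements[order(placements$target, placements$start), , drop = FALSE]
}

check_nucleotides <- function(sequences) {
  for (nm in names(sequences)) {
    if (grepl("[^ACGTN]", sequences[[nm]])) {
      stop("sequence '", nm, "' contains characters outside A/C/G/T/N")
    }
  }
  invisible(TRUE)
}

#' @export
print.assembly <- function(x, ...) {
  cat("assembly:", length(x$sequences), "sequence(s),",
      sum(x$role == "chromosome"), "chromosome(s),",
      sum(x$role == "unlocalized_scaffold"), "unlocalized scaffold(s),",
      nrow(x$placements), "contig placement(s)\n")
  invisible(x)
}

#' Names of assembly sequences carrying a given role
#'
#' @param asm an [assembly()].
#' @param roles character vector of roles to keep.
#' @return character vector of sequence names.
#' @export
assembly_targets <- function(asm, roles = c("chromosome",
                                            "unlocalized_scaffold")) {
  nm <- names(asm$sequences)
  nm[asm$role[nm] %in% roles]
}

#' Recover a placed contig's sequence from its target
#'
#' Slices the target sequence at the placement span; a `-` orientation
#' placement returns the reverse complement, i.e. the contig as it was
#' before being flipped into the target.
#'
#' @param asm an [assembly()].
#' @param contig_id placement row to extract.
#' @return nucleotide string.
#' @export
contig_sequence <- function(asm, contig_id) {
  p <- asm$placements[asm$placements$contig_id == contig_id, , drop = FALSE]
  if (!nrow(p)) stop("no placement for contig ", contig_id)
  s <- substr(asm$sequences[[p$target]], p$start + 1L, p$end)
  if (p$orientation == "-") s <- revcomp(s) else s
}

#' Map a target-coordinate interval to contig-local coordinates
#'
#' Finds the placement containing the interval and converts it into the
#' contig's own coordinate system (orientation-aware). Returns `NULL`
#' when no single placement contains the interval.
#'
#' @param placements placement table (0-based half-open).
#' @param target target sequence name.
#' @param start,end 0-based half-open interval on the target.
#' @return list with `contig_id`, `start`, `end` (contig-local, 0-based
#'   half-open) and `orientation`, or `NULL`.
#' @export
target_to_contig <- function(placements, target, start, end) {
  p <- placements[placements$target == target &
                    placements$start <= start &
                    placements$end >= end, , drop = FALSE]
  if (!nrow(p)) return(NULL)
  p <- p[1L, ]
  if (p$orientation == "+") {
    list(contig_id = p$contig_id, start = start - p$start,
         end = end - p$start, orientation = "+")
  } else {
    list(contig_id = p$contig_id, start = p$end - end,
         end = p$end - start, orientation = "-")
  }
}

#' Transcript model
#'
#' A gene's exon structure and CDS span. Exons are stored in
#' transcription order as 0-based half-open genomic intervals: ascending
#' genomic coordinates on the `+` strand, descending on `-`. The CDS is a
#' 0-based half-open interval in spliced-transcript coordinates.
#'
#' @param gene_id,transcript_id identifiers.
#' @param seq_name sequence the model lives on.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column integer matrix (start, end), one row per exon,
#'   transcription order.
#' @param cds_span length-2 integer vector, 0-based half-open offsets in
#'   spliced coordinates.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, seq_name, strand,
                             exons, cds_span) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (any(exons[, 1L] >= exons[, 2L])) {
    stop("exon with start >= end in ", transcript_id)
  }
  if (nrow(exons) > 1L) {
    ord <- exons[order(exons[, 1L]), , drop = FALSE]
    if (any(ord[-1L, 1L] < ord[-nrow(ord), 2L])) {
      stop("overlapping exons in ", transcript_id)
    }
    d <- diff(exons[, 1L])
    ok <- if (strand == "+") all(d > 0L) else all(d < 0L)
    if (!ok) {
      stop("exons of ", transcript_id,
           " are not in transcription order for strand ", strand)
    }
  }
  cds_span <- as.integer(cds_span)
  splen <- sum(exons[, 2L] - exons[, 1L])
  if (cds_span[1L] < 0L || cds_span[2L] > splen ||
      cds_span[2L] - cds_span[1L] < 3L) {
    stop("CDS span of ", transcript_id,
         " invalid (need >= 3 nt inside the spliced transcript)")
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 seq_name = seq_name, strand = strand, exons = exons,
                 cds_span = cds_span),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s) on %s(%s): %d exon(s), CDS [%d,%d)\n",
              x$transcript_id, x$gene_id, x$seq_name, x$strand,
              nrow(x$exons), x$cds_span[1L], x$cds_span[2L]))
  invisible(x)
}

#' Exon lengths of a model, in transcription order
#' @param model a [transcript_model()].
#' @return integer vector.
#' @export
exon_lengths <- function(model) {
  as.integer(model$exons[, 2L] - model$exons[, 1L])
}

#' Per-exon CDS intervals in exon-local coordinates
#'
#' For each exon (transcription order) the sub-interval that is coding,
#' 0-based half-open in the exon's own 5'-to-3' coordinates, or `NULL`
#' for wholly untranslated exons.
#'
#' @param model a [transcript_model()].
#' @return list, one entry per exon: `c(start, end)` or `NULL`.
#' @export
exon_cds_intervals <- function(model) {
  lens <- exon_lengths(model)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    lo <- max(model$cds_span[1L] - offs[i], 0L)
    hi <- min(model$cds_span[2L] - offs[i], lens[i])
    if (lo < hi) out[[i]] <- c(lo, hi)
  }
  out
}

#' Synteny map between reference and draft chromosomes
#'
#' Chromosome-level gene content is strongly conserved between close
#' vertebrate relatives, so each reference chromosome predicts the draft
#' chromosome that should host its genes. The map is total over the
#' reference chromosomes in use; the identity map is allowed (and is what
#' the simulator produces, where the reference annotation is the truth
#' genome itself).
#'
#' @param reference,draft equal-length character vectors.
#' @return named character vector: reference chromosome -> draft chromosome.
#' @export
synteny_map <- function(reference, draft) {
  if (length(reference) != length(draft)) {
    stop("reference and draft chromosome vectors differ in length")
  }
  if (anyDuplicated(reference)) stop("duplicate reference chromosome")
  stats::setNames(as.character(draft), as.character(reference))
}

#' Annotate assembly gaps (runs of N)
#'
#' Draft assemblies encode within-scaffold gaps as runs of N. Returns all
#' maximal N-runs of at least `min_gap_len` bases across the chromosome
#' and unlocalized-scaffold sequences.
#'
#' @param asm an [assembly()].
#' @param min_gap_len minimum run length to report (default 10; shorter
#'   runs are treated as isolated ambiguous bases, not gaps).
#' @return data.frame with columns `seq`, `start`, `end` (0-based
#'   half-open).
#' @export
find_gaps <- function(asm, min_gap_len = 10L) {
  out <- list()
  for (nm in assembly_targets(asm)) {
    m <- gregexpr("N+", asm$sequences[[nm]])[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    keep <- len >= min_gap_len
    if (!any(keep)) next
    out[[nm]] <- data.frame(seq = nm, start = as.integer(m[keep] - 1L),
                            end = as.integer(m[keep] - 1L + len[keep]),
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(seq = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
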