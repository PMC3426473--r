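#' Reverse complement of a nucleotide string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

#' Standard genetic code as a codon table
#'
#' The code is data, not logic: [translate_cds()] takes the table as an
#' argument so an alternative code could be supplied, although only the
#' standard code is exercised here.
#'
#' @return named character vector codon -> amino acid (`*` for stop).
#' @export
genetic_code_table <- function() {
  Biostrings::GENETIC_CODE
}

#' Translate a CDS, reporting the first internal stop
#'
#' Translates codon by codon under the supplied code. Codons containing
#' N (or any non-A/C/G/T base) translate to `X`. A trailing partial codon
#' is ignored with a warning. The returned protein is the prefix up to
#' (and excluding) the first stop codon; a stop in the final codon is the
#' normal terminator and is not reported as internal.
#'
#' @param cds nucleotide string, length >= 3.
#' @param code codon table, by default [genetic_code_table()].
#' @return list with `protein` (string), `internal_stop` (0-based codon
#'   index of the first internal stop, or `NA_integer_`) and `n_codons`.
#' @export
translate_cds <- function(cds, code = genetic_code_table()) {
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon")
  if (n %% 3L != 0L) {
    warning("CDS length not a multiple of 3; trailing ", n %% 3L,
            " base(s) ignored")
    n <- n - n %% 3L
  }
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  stops <- which(aa == "*")
  n_codons <- length(aa)
  internal <- NA_integer_
  if (length(stops)) {
    first <- stops[1L]
    if (first < n_codons) internal <- first - 1L
    aa <- aa[seq_len(first - 1L)]
  }
  list(protein = paste(aa, collapse = ""), internal_stop = internal,
       n_codons = n_codons)
}

#' Spliced transcript sequence from an assembly
#'
#' Concatenates the model's exons in transcription order; on the `-`
#' strand each exon substring is reverse complemented, so the result
#' always reads 5' to 3' in mRNA orientation.
#'
#' @param asm an [assembly()] (or a named character vector of sequences).
#' @param model a [transcript_model()].
#' @return nucleotide string.
#' @export
spliced_sequence <- function(asm, model) {
  seqs <- if (inherits(asm, "assembly")) asm$sequences else asm
  if (!model$seq_name %in% names(seqs)) {
    stop("model sequence ", model$seq_name, " not in assembly")
  }
  chrom <- seqs[[model$seq_name]]
  if (any(model$exons[, 2L] > nchar(chrom))) {
    stop("exon of ", model$transcript_id, " beyond end of ", model$seq_name)
  }
  parts <- substring(chrom, model$exons[, 1L] + 1L, model$exons[, 2L])
  if (model$strand == "-") parts <- vapply(parts, revcomp, character(1L))
  paste(parts, collapse = "")
}

#' CDS sequence of a model on an assembly
#'
#' @inheritParams spliced_sequence
#' @return nucleotide string (the coding part of the spliced transcript).
#' @export
cds_sequence <- function(asm, model) {
  sp <- spliced_sequence(asm, model)
  substr(sp, model$cds_span[1L] + 1L, model$cds_span[2L])
}
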