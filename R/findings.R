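# A finding is one detected anomaly attributed to a gene: the detectors
# produce lists of these, the classifier consumes the set of kinds per
# gene, and findings_table() flattens them for TSV/JSON output.

FINDING_KINDS <- c("FRAMESHIFT", "PREMATURE_STOP", "MISSING_EXON",
                   "MISSING_SUBSEQUENCE", "SPURIOUS_EXON",
                   "MODEL_TRUNCATION", "SPLIT_CHROMOSOME",
                   "SPLIT_UNLOCALIZED", "ORIENTATION_FLIP",
                   "ORDER_ANOMALY", "CHIMERIC_CONTIG",
                   "AMBIGUOUS_PLACEMENT")

#' Construct a finding
#'
#' @param gene_id gene the anomaly is attributed to.
#' @param kind one of the finding kinds (see Details).
#' @param target,start,end locus on the draft (0-based half-open), when
#'   localizable.
#' @param payload structured kind-specific evidence (named list).
#' @param evidence one-line human-readable description.
#'
#' @details Kinds: `FRAMESHIFT`, `PREMATURE_STOP`, `MISSING_EXON`,
#' `MISSING_SUBSEQUENCE`, `SPURIOUS_EXON`, `MODEL_TRUNCATION`,
#' `SPLIT_CHROMOSOME`, `SPLIT_UNLOCALIZED`, `ORIENTATION_FLIP`,
#' `ORDER_ANOMALY`, `CHIMERIC_CONTIG`, `AMBIGUOUS_PLACEMENT`.
#' @return list of class `finding`.
#' @export
finding <- function(gene_id, kind, target = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    payload = list(), evidence = "") {
  if (!kind %in% FINDING_KINDS) stop("unknown finding kind: ", kind)
  structure(list(gene_id = gene_id, kind = kind, target = target,
                 start = start, end = end, payload = payload,
                 evidence = evidence),
            class = "finding")
}

#' @export
print.finding <- function(x, ...) {
  cat(sprintf("[%s] %s %s:%s-%s %s\n", x$kind, x$gene_id,
              x$target, x$start, x$end, x$evidence))
  invisible(x)
}

#' Flatten findings to a table
#'
#' @param findings list of [finding()] objects.
#' @return data.frame with `gene_id`, `kind`, `target`, `start`, `end`,
#'   `payload` (JSON) and `evidence`; zero rows for an empty list.
#' @export
findings_table <- function(findings) {
  if (!length(findings)) {
    return(data.frame(gene_id = character(), kind = character(),
                      target = character(), start = integer(),
                      end = integer(), payload = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(lapply(findings, function(f) {
    data.frame(gene_id = f$gene_id, kind = f$kind, target = f$target,
               start = f$start, end = f$end,
               payload = as.character(
                 jsonlite::toJSON(f$payload, auto_unbox = TRUE)),
               evidence = f$evidence, stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
}

finding_kinds_for_gene <- function(findings, gene_id) {
  unique(vapply(Filter(function(f) f$gene_id == gene_id, findings),
                `[[`, "", "kind"))
}
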