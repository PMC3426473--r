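# Six-way survey classification of gene models, the per-category summary,
# and the recovery scorecard joining calls to the simulator's ground
# truth.

CATEGORIES <- c("complete_correct", "wrong", "incomplete",
                "no_protein_derived", "none_annotated", "unclear")

WRONG_KINDS <- c("SPURIOUS_EXON", "SPLIT_CHROMOSOME", "SPLIT_UNLOCALIZED",
                 "CHIMERIC_CONTIG", "ORIENTATION_FLIP", "ORDER_ANOMALY",
                 "FRAMESHIFT")
INCOMPLETE_KINDS <- c("MISSING_EXON", "MISSING_SUBSEQUENCE",
                      "MODEL_TRUNCATION")

#' Classify one gene into a survey category
#'
#' Precedence, most severe first:
#' \enumerate{
#'   \item `none_annotated` — the draft annotation lacks the gene.
#'   \item `no_protein_derived` — a model exists but no CDS translates to
#'     completion (premature stop, or a frameshift destroying the ORF):
#'     the loci an automated pipeline tends to mislabel as pseudogenes.
#'   \item `wrong` — spurious sequence corrupts the model: spurious exon,
#'     split gene, chimeric contig, orientation flip, order anomaly, or a
#'     frameshift with a still-translating downstream ORF.
#'   \item `incomplete` — only truncating evidence (missing exon, missing
#'     sub-exon sequence, truncated model).
#'   \item `unclear` — only ambiguous-placement evidence.
#'   \item `complete_correct` — otherwise.
#' }
#'
#' @param finding_kinds character vector of finding kinds for the gene
#'   (deduplicated or not).
#' @param model_present does the draft annotation contain the gene?
#' @param protein_derivable does some draft CDS translate to completion?
#'   Must be `FALSE` when `model_present` is `FALSE`.
#' @return category string (one of the six).
#' @export
classify_gene <- function(finding_kinds, model_present, protein_derivable) {
  if (!model_present && protein_derivable) {
    stop("protein cannot be derivable without a draft model")
  }
  if (!model_present) return("none_annotated")
  if (!protein_derivable) return("no_protein_derived")
  if (any(finding_kinds %in% WRONG_KINDS)) return("wrong")
  if (any(finding_kinds %in% INCOMPLETE_KINDS)) return("incomplete")
  if (any(finding_kinds == "AMBIGUOUS_PLACEMENT")) return("unclear")
  "complete_correct"
}

#' Summarize verdicts into the survey table
#'
#' Counts and integer percentages (rounded half-up) per category.
#' Percentages are reported per category from raw counts and are not
#' forced to sum to 100.
#'
#' @param verdicts data.frame with a `category` column (one row per
#'   gene), or a character vector of categories.
#' @return list with `counts`, `percentages` (named integer vectors over
#'   the six categories) and `total`.
#' @export
summarize_verdicts <- function(verdicts) {
  cats <- if (is.data.frame(verdicts)) verdicts$category else verdicts
  if (!length(cats)) stop("no verdicts to summarize")
  bad <- setdiff(unique(cats), CATEGORIES)
  if (length(bad)) stop("unknown category: ", bad[1L])
  counts <- vapply(CATEGORIES, function(k) sum(cats == k), integer(1L))
  pct <- as.integer(floor(100 * counts / length(cats) + 0.5))
  names(pct) <- CATEGORIES
  list(counts = counts, percentages = pct, total = length(cats))
}

# Finding kinds a defect class is expected to trigger are recorded per
# record by the simulator (expected_findings); this parses them.
expected_kind_sets <- function(defect_log) {
  strsplit(defect_log$expected_findings, ",", fixed = TRUE)
}

#' Score detector recovery against the ground-truth defect log
#'
#' Joins findings and verdicts to the simulator's defect records:
#' \describe{
#'   \item{sensitivity}{per finding kind, the fraction of defect records
#'     expecting that kind whose gene received at least one finding of
#'     it.}
#'   \item{precision}{per finding kind, the fraction of (gene, kind)
#'     calls backed by a defect record expecting that kind on that gene.}
#'   \item{confusion}{truth category (from the log; genes without a
#'     record are `complete_correct`) against the assigned category, and
#'     the diagonal fraction.}
#' }
#'
#' @param verdicts data.frame with `gene_id` and `category`.
#' @param findings list of [finding()] objects or a [findings_table()]
#'   data.frame.
#' @param defect_log defect-record data.frame from [derive_draft()].
#' @return list with `sensitivity` and `precision` data.frames,
#'   `confusion` matrix and `diagonal_accuracy`.
#' @export
score_recovery <- function(verdicts, findings, defect_log) {
  ft <- if (is.data.frame(findings)) findings else findings_table(findings)
  calls <- unique(ft[c("gene_id", "kind")])
  exp_sets <- expected_kind_sets(defect_log)

  sens <- list()
  for (k in FINDING_KINDS) {
    idx <- which(vapply(exp_sets, function(s) k %in% s, logical(1L)))
    if (!length(idx)) next
    hit <- vapply(idx, function(i) {
      any(calls$gene_id == defect_log$gene_id[i] & calls$kind == k)
    }, logical(1L))
    sens[[k]] <- data.frame(kind = k, n_expected = length(idx),
                            n_detected = sum(hit),
                            sensitivity = mean(hit),
                            stringsAsFactors = FALSE)
  }
  sensitivity <- do.call(rbind, c(sens, list(make.row.names = FALSE)))

  prec <- list()
  for (k in unique(calls$kind)) {
    ck <- calls[calls$kind == k, , drop = FALSE]
    backed <- vapply(ck$gene_id, function(g) {
      i <- which(defect_log$gene_id == g)
      length(i) > 0L && any(vapply(exp_sets[i], function(s) k %in% s,
                                   logical(1L)))
    }, logical(1L))
    prec[[k]] <- data.frame(kind = k, n_calls = nrow(ck),
                            n_backed = sum(backed),
                            precision = mean(backed),
                            stringsAsFactors = FALSE)
  }
  precision <- if (length(prec)) {
    do.call(rbind, c(prec, list(make.row.names = FALSE)))
  } else {
    data.frame(kind = character(), n_calls = integer(),
               n_backed = integer(), precision = numeric(),
               stringsAsFactors = FALSE)
  }

  truth_cat <- stats::setNames(rep("complete_correct", nrow(verdicts)),
                               verdicts$gene_id)
  truth_cat[defect_log$gene_id] <- defect_log$expected_category
  confusion <- table(truth = truth_cat[verdicts$gene_id],
                     assigned = verdicts$category)
  diag_acc <- mean(truth_cat[verdicts$gene_id] == verdicts$category)

  list(sensitivity = sensitivity, precision = precision,
       confusion = confusion, diagonal_accuracy = diag_acc)
}
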