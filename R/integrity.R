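# Sequencing-error consequences visible inside placed genes: frameshifts,
# premature stops, missing exons or sub-exon sequence, and spurious model
# exons. All detectors take exon chains from map_transcripts() and return
# lists of finding() objects; they never throw on degraded input.

#' Detect coding-frame disruption in an exon chain
#'
#' Sums signed indel lengths (+insertion, -deletion) over the CDS portion
#' of each placed exon in transcription order. A frameshift is reported
#' as soon as the cumulative net length is not a multiple of 3 at any
#' point — including between two indels that cancel by the end of the
#' exon, since the protein is corrupted over the interior span.
#'
#' @param chain an `exon_chain`.
#' @param params an [align_params()] (unused by the arithmetic; kept for
#'   interface symmetry).
#' @return list of findings (zero or one `FRAMESHIFT`).
#' @export
detect_frameshift <- function(chain, params = align_params()) {
  cds_iv <- exon_cds_intervals(chain$model)
  cum <- 0L
  offender <- NULL
  shifted <- FALSE
  all_ind <- list()
  for (i in seq_along(chain$exons)) {
    e <- chain$exons[[i]]
    iv <- cds_iv[[i]]
    if (is.null(iv)) next
    if (e$status != "placed") {
      cum <- 0L          # frame continuity unknown across a missing exon
      next
    }
    ind <- e$indels
    ind <- ind[ind$qpos >= iv[1L] & ind$qpos < iv[2L], , drop = FALSE]
    if (nrow(ind)) {
      ind <- ind[order(ind$qpos), , drop = FALSE]
      for (j in seq_len(nrow(ind))) {
        cum <- cum + ifelse(ind$kind[j] == "ins", 1L, -1L) * ind$length[j]
        all_ind[[length(all_ind) + 1L]] <-
          cbind(exon = i, ind[j, ], net_after = cum)
        if (cum %% 3L != 0L && is.null(offender)) {
          offender <- list(exon = i, qpos = ind$qpos[j],
                           tpos = ind$tpos[j], kind = ind$kind[j],
                           length = ind$length[j])
          shifted <- TRUE
        }
      }
    }
  }
  if (!shifted) return(list())
  e <- chain$exons[[offender$exon]]
  list(finding(chain$gene_id, "FRAMESHIFT",
               target = e$target, start = offender$tpos,
               end = offender$tpos + offender$length,
               payload = list(first_indel = offender,
                              net = cum, restored = cum %% 3L == 0L,
                              indels = do.call(rbind, all_ind)),
               evidence = sprintf(
                 "net indel %+d (mod 3 = %d) first at exon %d offset %d",
                 cum, ((cum %% 3L) + 3L) %% 3L, offender$exon,
                 offender$qpos)))
}

# Rebuild the draft CDS from the aligned exon placements, in mRNA
# orientation. Returns NULL when any CDS exon is unplaced or placements
# disagree on target/strand (a split gene: deferred to the misassembly
# detector).
reconstruct_draft_cds <- function(chain) {
  cds_iv <- exon_cds_intervals(chain$model)
  parts <- character(0)
  tgt <- character(0); std <- character(0)
  for (i in seq_along(chain$exons)) {
    iv <- cds_iv[[i]]
    if (is.null(iv)) next
    e <- chain$exons[[i]]
    if (e$status != "placed") return(NULL)
    tgt <- c(tgt, e$target); std <- c(std, e$strand)
    qc <- strsplit(e$aligned_query, "")[[1L]]
    tc <- strsplit(e$aligned_target, "")[[1L]]
    qgap <- qc == "-"
    q_after <- e$qstart + cumsum(!qgap)   # query index after this column
    q_of <- q_after - !qgap               # 0-based index of query char
    emit <- (!qgap & q_of >= iv[1L] & q_of < iv[2L]) |
      (qgap & q_after > iv[1L] & q_after < iv[2L])
    parts <- c(parts, paste(tc[emit & tc != "-"], collapse = ""))
  }
  if (length(unique(tgt)) != 1L || length(unique(std)) != 1L) return(NULL)
  paste(parts, collapse = "")
}

#' Detect a premature stop codon in the reconstructed draft CDS
#'
#' Rebuilds the gene's CDS from the draft placements, translates it, and
#' reports a `PREMATURE_STOP` when the first internal stop falls before
#' the final codon — provided the ortholog CDS itself translates cleanly
#' through that codon, so the stop is a draft artifact and not shared
#' biology. When draft and ortholog CDS have equal length and the stop
#' codon differs by a single base, the causative substitution is named in
#' the payload.
#'
#' @param chain an `exon_chain`.
#' @param draft draft [assembly()] (for locus annotation only).
#' @param ortholog_cds the ortholog CDS nucleotide string.
#' @return list of findings (zero or one `PREMATURE_STOP`).
#' @export
detect_premature_stop <- function(chain, draft, ortholog_cds) {
  dcds <- reconstruct_draft_cds(chain)
  if (is.null(dcds) || nchar(dcds) < 6L) return(list())
  dcds_t <- substr(dcds, 1L, nchar(dcds) - nchar(dcds) %% 3L)
  tr <- translate_cds(dcds_t)
  if (is.na(tr$internal_stop)) return(list())
  ci <- tr$internal_stop
  otr <- translate_cds(substr(ortholog_cds, 1L,
                              nchar(ortholog_cds) - nchar(ortholog_cds) %% 3L))
  if (!is.na(otr$internal_stop) && otr$internal_stop <= ci) return(list())
  payload <- list(codon_index = ci, n_codons = tr$n_codons)
  if (nchar(dcds) == nchar(ortholog_cds)) {
    dcod <- substr(dcds, ci * 3L + 1L, ci * 3L + 3L)
    ocod <- substr(ortholog_cds, ci * 3L + 1L, ci * 3L + 3L)
    d <- which(strsplit(dcod, "")[[1L]] != strsplit(ocod, "")[[1L]])
    if (length(d) == 1L) {
      payload$substitution <- list(pos_in_codon = d - 1L,
                                   ref = substr(ocod, d, d),
                                   alt = substr(dcod, d, d))
    }
  }
  placed <- Filter(function(e) e$status == "placed", chain$exons)
  tg <- placed[[1L]]$target
  list(finding(chain$gene_id, "PREMATURE_STOP", target = tg,
               start = min(vapply(placed, `[[`, 1L, "target_start")),
               end = max(vapply(placed, `[[`, 1L, "target_end")),
               payload = payload,
               evidence = sprintf("internal stop at codon %d of %d",
                                  ci, tr$n_codons)))
}

#' Detect missing exons, noting assembly-gap bracketing
#'
#' Every unplaced ortholog exon (other than sub-signal short exons) is a
#' `MISSING_EXON`. When the flanking placed exons land on one target and
#' an N-run gap lies between them, the absence is `gap_explained`: the
#' sequence most likely falls in the unsequenced gap rather than being
#' deleted.
#'
#' @param chain an `exon_chain`.
#' @param gaps gap table from [find_gaps()].
#' @return list of `MISSING_EXON` findings.
#' @export
detect_missing_exon <- function(chain, gaps) {
  out <- list()
  status <- vapply(chain$exons, `[[`, "", "status")
  for (i in seq_along(chain$exons)) {
    e <- chain$exons[[i]]
    if (e$status != "unplaced" || identical(e$reason, "short")) next
    prev <- rev(which(status[seq_len(i - 1L)] == "placed"))
    nxt <- which(status == "placed" & seq_along(status) > i)
    gap_explained <- FALSE
    locus <- list(target = NA_character_, start = NA_integer_,
                  end = NA_integer_)
    if (length(prev) && length(nxt)) {
      a <- chain$exons[[prev[1L]]]
      b <- chain$exons[[nxt[1L]]]
      if (a$target == b$target) {
        lo <- min(a$target_start, b$target_start)
        hi <- max(a$target_end, b$target_end)
        g <- gaps[gaps$seq == a$target & gaps$start >= lo &
                    gaps$end <= hi, , drop = FALSE]
        gap_explained <- nrow(g) > 0L
        locus <- list(target = a$target, start = min(a$target_end,
                                                     b$target_end),
                      end = max(a$target_start, b$target_start))
      }
    }
    out[[length(out) + 1L]] <- finding(
      chain$gene_id, "MISSING_EXON", target = locus$target,
      start = locus$start, end = locus$end,
      payload = list(exon = i, gap_explained = gap_explained),
      evidence = sprintf("exon %d unplaced%s", i,
                         if (gap_explained) " (N-gap between flanks)" else ""))
  }
  out
}

#' Detect missing sub-exon sequence in placed exons
#'
#' A placed exon supports its ortholog exon only where alignment columns
#' pair it with actual sequence: query positions that are unaligned,
#' deleted, or aligned opposite N carry no support. A contiguous
#' unsupported block of at least `min_block` bases is reported with its
#' span in ortholog-exon coordinates (block boundaries are alignment-
#' dependent to within about 5 bp).
#'
#' @param chain an `exon_chain`.
#' @param min_block minimum unsupported block length (default 15 bp).
#' @return list of `MISSING_SUBSEQUENCE` findings.
#' @export
detect_missing_subsequence <- function(chain, min_block = 15L) {
  out <- list()
  for (i in seq_along(chain$exons)) {
    e <- chain$exons[[i]]
    if (e$status != "placed") next
    covered <- logical(e$exon_len)
    qc <- strsplit(e$aligned_query, "")[[1L]]
    tc <- strsplit(e$aligned_target, "")[[1L]]
    qgap <- qc == "-"
    q_of <- e$qstart + cumsum(!qgap) - !qgap
    sup <- !qgap & tc != "-" & tc != "N"
    covered[q_of[sup] + 1L] <- TRUE
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in which(!runs$values & runs$lengths >= min_block)) {
      out[[length(out) + 1L]] <- finding(
        chain$gene_id, "MISSING_SUBSEQUENCE", target = e$target,
        start = e$target_start, end = e$target_end,
        payload = list(exon = i, block_start = starts[j] - 1L,
                       block_end = ends[j], length = runs$lengths[j]),
        evidence = sprintf("exon %d lacks support for %d bp at [%d,%d)",
                           i, runs$lengths[j], starts[j] - 1L, ends[j]))
    }
  }
  out
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2))
  if (!ov) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Audit the draft's own gene models against ortholog-supported placements
#'
#' A draft-model exon overlapping no ortholog-supported placement
#' (reciprocal overlap below `floor`) while a neighboring model exon is
#' supported is a `SPURIOUS_EXON` — the footprint of an annotation
#' pipeline inventing an exon from intronic sequence. Partial overlaps
#' between `floor` and `support` are routed to `AMBIGUOUS_PLACEMENT`
#' rather than called spurious. Conversely, supported placements at the
#' chain termini with no model exon (same target and strand) are a
#' `MODEL_TRUNCATION`.
#'
#' @param draft_models list of draft [transcript_model()] objects.
#' @param chains exon chains from [map_transcripts()].
#' @param floor reciprocal overlap below which a model exon is
#'   unsupported (default 0.1).
#' @param support reciprocal overlap above which it is supported
#'   (default 0.8).
#' @return list of findings.
#' @export
detect_spurious_exon <- function(draft_models, chains, floor = 0.1,
                                 support = 0.8) {
  out <- list()
  for (dm in draft_models) {
    ch <- chains[[dm$gene_id]]
    if (is.null(ch)) next
    placed <- Filter(function(e) e$status == "placed", ch$exons)
    same_tg <- Filter(function(e) e$target == dm$seq_name, placed)
    n_ex <- nrow(dm$exons)
    r <- vapply(seq_len(n_ex), function(j) {
      if (!length(same_tg)) return(0)
      max(vapply(same_tg, function(e) {
        reciprocal_overlap(dm$exons[j, 1L], dm$exons[j, 2L],
                           e$target_start, e$target_end)
      }, numeric(1L)))
    }, numeric(1L))
    supported <- r >= support
    for (j in seq_len(n_ex)) {
      if (r[j] < floor) {
        nb <- c(j - 1L, j + 1L)
        nb <- nb[nb >= 1L & nb <= n_ex]
        if (any(supported[nb])) {
          out[[length(out) + 1L]] <- finding(
            dm$gene_id, "SPURIOUS_EXON", target = dm$seq_name,
            start = dm$exons[j, 1L], end = dm$exons[j, 2L],
            payload = list(model_exon = j, best_overlap = r[j]),
            evidence = sprintf(
              "model exon %d has no ortholog support (best overlap %.2f)",
              j, r[j]))
        }
      } else if (r[j] < support) {
        out[[length(out) + 1L]] <- finding(
          dm$gene_id, "AMBIGUOUS_PLACEMENT", target = dm$seq_name,
          start = dm$exons[j, 1L], end = dm$exons[j, 2L],
          payload = list(model_exon = j, best_overlap = r[j]),
          evidence = sprintf(
            "model exon %d partially supported (overlap %.2f)", j, r[j]))
      }
    }
    # terminal supported placements absent from the model
    strand_tg <- Filter(function(e) e$strand == dm$strand, same_tg)
    if (length(strand_tg)) {
      idx <- vapply(strand_tg, `[[`, 1L, "exon")
      sup_by_model <- vapply(strand_tg, function(e) {
        any(vapply(seq_len(n_ex), function(j) {
          reciprocal_overlap(dm$exons[j, 1L], dm$exons[j, 2L],
                             e$target_start, e$target_end) >= floor
        }, logical(1L)))
      }, logical(1L))
      ord <- order(idx)
      sup_by_model <- sup_by_model[ord]
      n <- length(sup_by_model)
      lead <- cumsum(sup_by_model) == 0L
      trail <- rev(cumsum(rev(sup_by_model)) == 0L)
      n_term <- sum(lead) + sum(trail & !lead)
      if (n_term > 0L && any(sup_by_model)) {
        out[[length(out) + 1L]] <- finding(
          dm$gene_id, "MODEL_TRUNCATION", target = dm$seq_name,
          start = min(dm$exons[, 1L]), end = max(dm$exons[, 2L]),
          payload = list(n_missing_terminal = n_term,
                         missing_5prime = sum(lead),
                         missing_3prime = sum(trail & !lead)),
          evidence = sprintf(
            "%d terminal ortholog-supported exon(s) absent from model",
            n_term))
      }
    }
  }
  out
}
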