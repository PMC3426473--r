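# Assembly-level anomalies read off exon chains and the contig placement
# table: genes split across chromosomes or onto unlocalized scaffolds,
# exon-order violations, orientation flips, unintegrated contigs and
# chimeric contigs. Exon order is strongly conserved among vertebrates,
# so a chain whose placed exons violate transcription order, strand
# consistency or the synteny-expected chromosome is evidence against the
# assembly rather than the gene.

placed_exon_rows <- function(chain) {
  rows <- Filter(Negate(is.null), lapply(chain$exons, function(e) {
    if (e$status != "placed") return(NULL)
    data.frame(exon = e$exon, target = e$target, start = e$target_start,
               end = e$target_end, strand = e$strand,
               stringsAsFactors = FALSE)
  }))
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Diagnose one exon chain for misassembly anomalies
#'
#' Works from the placed exons only (ambiguous placements are excluded
#' from anomaly evidence). The primary target is the sequence hosting the
#' plurality of placed exons, ties broken by the synteny expectation and
#' then lexicographically. Anomalies:
#' \describe{
#'   \item{SPLIT_CHROMOSOME}{placed exons span two or more chromosome-role
#'     sequences; the misplaced block is the side off the synteny-expected
#'     chromosome.}
#'   \item{SPLIT_UNLOCALIZED}{placed exons on an unlocalized scaffold
#'     while others sit on a chromosome.}
#'   \item{ORIENTATION_FLIP}{an exon's strand differs from the chain's
#'     majority strand.}
#'   \item{ORDER_ANOMALY}{same-target, same-strand exons out of monotonic
#'     target order by more than one exon span (tandem near-duplicates
#'     tolerated), or adjacent placed exons more than `max_intron` apart.}
#' }
#'
#' @param chain an `exon_chain`.
#' @param draft draft [assembly()] (for sequence roles).
#' @param synteny named character vector from [synteny_map()].
#' @param max_intron adjacency distance bound on one target (default 1 Mb).
#' @return a `chain_diagnosis`: `transcript_id`, `gene_id`, `anomalies`
#'   (list of findings), `primary_target`, `synteny_expected_target`,
#'   `note`.
#' @export
diagnose_chain <- function(chain, draft, synteny, max_intron = 1e6) {
  expected <- unname(synteny[chain$model$seq_name])
  diag <- structure(
    list(transcript_id = chain$transcript_id, gene_id = chain$gene_id,
         anomalies = list(), primary_target = NA_character_,
         synteny_expected_target = expected, note = ""),
    class = "chain_diagnosis")
  p <- placed_exon_rows(chain)
  if (is.null(p) || !nrow(p)) {
    diag$note <- "no placed exons"
    return(diag)
  }
  tab <- sort(table(p$target), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  diag$primary_target <- if (!is.na(expected) && expected %in% top) {
    expected
  } else sort(top)[1L]
  roles <- draft$role[p$target]
  add <- function(f) diag$anomalies[[length(diag$anomalies) + 1L]] <<- f

  chrom_targets <- unique(p$target[roles == "chromosome"])
  # an unlocalized scaffold carries its gene's synteny-expected chromosome
  # as an implicit assignment: exons on a wrong chromosome plus exons on
  # scaffolds of the expected chromosome are still a split between
  # chromosomes, even with a single chromosome-role sequence in use
  effective <- chrom_targets
  if (any(roles == "unlocalized_scaffold") && !is.na(expected)) {
    effective <- union(effective, expected)
  }
  misplaced <- if (!is.na(expected)) {
    p$exon[p$target %in% setdiff(chrom_targets, expected)]
  } else p$exon[p$target != diag$primary_target]
  if (length(effective) >= 2L) {
    add(finding(chain$gene_id, "SPLIT_CHROMOSOME",
                target = diag$primary_target,
                payload = list(targets = chrom_targets,
                               expected = expected,
                               misplaced_exons = misplaced),
                evidence = sprintf("placed exons span chromosomes %s (expected %s)",
                                   paste(chrom_targets, collapse = ","),
                                   expected)))
  }
  unloc <- unique(p$target[roles == "unlocalized_scaffold"])
  if (length(unloc) && length(chrom_targets)) {
    add(finding(chain$gene_id, "SPLIT_UNLOCALIZED",
                target = diag$primary_target,
                payload = list(scaffolds = unloc,
                               exons = p$exon[p$target %in% unloc]),
                evidence = sprintf("exon(s) %s on unlocalized scaffold %s",
                                   paste(p$exon[p$target %in% unloc],
                                         collapse = ","),
                                   paste(unloc, collapse = ","))))
  }
  strand_tab <- sort(table(p$strand), decreasing = TRUE)
  majority_strand <- names(strand_tab)[1L]
  minority <- p$exon[p$strand != majority_strand]
  if (length(minority)) {
    add(finding(chain$gene_id, "ORIENTATION_FLIP",
                target = diag$primary_target,
                payload = list(exons = minority,
                               majority_strand = majority_strand),
                evidence = sprintf("exon(s) %s on %s strand, chain majority %s",
                                   paste(minority, collapse = ","),
                                   setdiff(c("+", "-"), majority_strand),
                                   majority_strand)))
  }
  # order within each (target, strand) group, transcription order
  for (tg in unique(p$target)) {
    for (sd in unique(p$strand[p$target == tg])) {
      g <- p[p$target == tg & p$strand == sd, , drop = FALSE]
      g <- g[order(g$exon), , drop = FALSE]
      if (nrow(g) < 2L) next
      step <- diff(g$start)
      if (sd == "-") step <- -step
      span <- pmax(g$end - g$start, 1L)[-1L]
      bad <- which(step < -span)
      if (length(bad)) {
        add(finding(chain$gene_id, "ORDER_ANOMALY", target = tg,
                    payload = list(variant = "inversion",
                                   exons = c(g$exon[bad[1L]],
                                             g$exon[bad[1L] + 1L])),
                    evidence = sprintf(
                      "exons %d and %d out of order on %s(%s)",
                      g$exon[bad[1L]], g$exon[bad[1L] + 1L], tg, sd)))
      }
      far <- which(abs(diff(g$start)) > max_intron)
      if (length(far)) {
        add(finding(chain$gene_id, "ORDER_ANOMALY", target = tg,
                    payload = list(variant = "distance",
                                   exons = c(g$exon[far[1L]],
                                             g$exon[far[1L] + 1L]),
                                   distance = abs(diff(g$start))[far[1L]]),
                    evidence = sprintf(
                      "adjacent exons %d and %d are %d bp apart on %s",
                      g$exon[far[1L]], g$exon[far[1L] + 1L],
                      abs(diff(g$start))[far[1L]], tg)))
      }
    }
  }
  diag
}

#' Flag misplaced blocks on unintegrated single-contig scaffolds
#'
#' A gene block sitting on an unlocalized scaffold that consists of a
#' single contig whose synteny-expected chromosome equals the chain's
#' primary target is the signature of a contig that belongs on that
#' chromosome but was never integrated into its file. Returns
#' `SPLIT_UNLOCALIZED` findings with `payload$unintegrated_contig = TRUE`,
#' meant to refine the plain split finding from [diagnose_chain()].
#'
#' @param chain an `exon_chain`.
#' @param draft draft [assembly()] (roles and placements).
#' @param synteny named character vector from [synteny_map()].
#' @return list of findings.
#' @export
check_unintegrated <- function(chain, draft, synteny) {
  p <- placed_exon_rows(chain)
  if (is.null(p) || !nrow(p)) return(list())
  roles <- draft$role[p$target]
  chrom_tab <- sort(table(p$target[roles == "chromosome"]),
                    decreasing = TRUE)
  if (!length(chrom_tab)) return(list())
  primary <- names(chrom_tab)[1L]
  expected <- unname(synteny[chain$model$seq_name])
  out <- list()
  for (scaf in unique(p$target[roles == "unlocalized_scaffold"])) {
    plc <- draft$placements[draft$placements$target == scaf, , drop = FALSE]
    if (nrow(plc) != 1L) next
    if (!is.na(expected) && expected == primary) {
      out[[length(out) + 1L]] <- finding(
        chain$gene_id, "SPLIT_UNLOCALIZED", target = primary,
        payload = list(scaffolds = scaf,
                       exons = p$exon[p$target == scaf],
                       unintegrated_contig = TRUE,
                       contig = plc$contig_id),
        evidence = sprintf(
          "single-contig scaffold %s (contig %s) belongs on %s",
          scaf, plc$contig_id, primary))
    }
  }
  out
}

#' Diagnose contigs for chimerism from exon placements
#'
#' Resolves every placed exon to its contig through the placement table
#' and groups the placements on each contig by the chromosome their
#' gene's chain expects under synteny. A contig whose groups occupy
#' disjoint contig intervals is chimeric; the breakpoint interval is the
#' gap between the innermost conflicting placements, which must contain
#' the true fusion point. Conflicting groups that interleave (no clean
#' two-sided partition) are not called chimeric: the genes involved are
#' flagged `AMBIGUOUS_PLACEMENT` instead. Contigs without exon evidence
#' are reported consistent with `evidence_absent = TRUE`.
#'
#' @param chains list of `exon_chain` objects.
#' @param draft draft [assembly()].
#' @param synteny named character vector from [synteny_map()].
#' @return list with `diagnoses` (per-contig records: `contig_id`,
#'   `verdict`, `breakpoint_interval`, `groups`, `evidence_absent`) and
#'   `findings` (CHIMERIC_CONTIG / AMBIGUOUS_PLACEMENT findings).
#' @export
diagnose_contigs <- function(chains, draft, synteny) {
  rows <- list()
  for (ch in chains) {
    expected <- unname(synteny[ch$model$seq_name])
    p <- placed_exon_rows(ch)
    if (is.null(p) || !nrow(p)) next
    for (i in seq_len(nrow(p))) {
      loc <- target_to_contig(draft$placements, p$target[i],
                              p$start[i], p$end[i])
      if (is.null(loc)) next
      rows[[length(rows) + 1L]] <- data.frame(
        contig = loc$contig_id, lstart = loc$start, lend = loc$end,
        gene = ch$gene_id, exon = p$exon[i], expected = expected,
        stringsAsFactors = FALSE)
    }
  }
  evidence <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(contig = character(), lstart = integer(), lend = integer(),
               gene = character(), exon = integer(), expected = character(),
               stringsAsFactors = FALSE)
  }
  diagnoses <- list()
  findings <- list()
  for (cid in draft$placements$contig_id) {
    ev <- evidence[evidence$contig == cid, , drop = FALSE]
    d <- list(contig_id = cid, verdict = "consistent",
              breakpoint_interval = NULL, groups = NULL,
              evidence_absent = !nrow(ev))
    if (nrow(ev) && length(unique(ev$expected)) >= 2L) {
      hulls <- do.call(rbind, lapply(split(ev, ev$expected), function(g) {
        data.frame(expected = g$expected[1L], lo = min(g$lstart),
                   hi = max(g$lend), stringsAsFactors = FALSE)
      }))
      hulls <- hulls[order(hulls$lo), , drop = FALSE]
      disjoint <- all(hulls$lo[-1L] >= hulls$hi[-nrow(hulls)])
      if (disjoint) {
        d$verdict <- "chimeric"
        d$breakpoint_interval <- c(hulls$hi[1L], hulls$lo[2L])
        d$groups <- hulls
        for (g in unique(ev$gene)) {
          findings[[length(findings) + 1L]] <- finding(
            g, "CHIMERIC_CONTIG",
            target = cid, start = d$breakpoint_interval[1L],
            end = d$breakpoint_interval[2L],
            payload = list(contig = cid,
                           breakpoint_interval = d$breakpoint_interval,
                           sides = hulls$expected),
            evidence = sprintf(
              "contig %s mixes material expected on %s (breakpoint in [%d,%d))",
              cid, paste(hulls$expected, collapse = " and "),
              d$breakpoint_interval[1L], d$breakpoint_interval[2L]))
        }
      } else {
        for (g in unique(ev$gene)) {
          findings[[length(findings) + 1L]] <- finding(
            g, "AMBIGUOUS_PLACEMENT", target = cid,
            payload = list(contig = cid, interleaved = TRUE),
            evidence = sprintf(
              "contig %s carries interleaved conflicting placements", cid))
        }
      }
    }
    diagnoses[[cid]] <- d
  }
  list(diagnoses = diagnoses, findings = findings)
}
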