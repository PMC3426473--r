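# Internal machinery for derive_draft(): per-gene defect application,
# decoy exon placement, draft model construction and defect-record
# assembly. Coordinates: "local" = contig-local 0-based; "genomic" =
# truth-chromosome 0-based half-open; "target" = final draft sequence.

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

# Spliced offset of the first base of each exon (transcription order).
exon_offsets <- function(model) {
  lens <- exon_lengths(model)
  cumsum(c(0L, lens[-length(lens)]))
}

# Genomic position of a transcription-local exon offset.
exon_local_to_genomic <- function(model, exon, q) {
  if (model$strand == "+") model$exons[exon, 1L] + q
  else model$exons[exon, 2L] - 1L - q
}

gene_eligible <- function(model, class, params, truth) {
  n_ex <- nrow(model$exons)
  cds_len <- model$cds_span[2L] - model$cds_span[1L]
  switch(class,
    STOP_SUBSTITUTION = cds_len >= 150L,
    FRAMESHIFT_INDEL = {
      iv <- exon_cds_intervals(model)
      any(vapply(iv, function(x) !is.null(x) && x[2L] - x[1L] >= 80L,
                 logical(1L)))
    },
    EXON_GAP = {
      if (n_ex < 3L) return(FALSE)
      lens <- exon_lengths(model)
      # an internal exon whose flanking introns leave room for a decoy
      intr <- abs(model$exons[-1L, 1L] - model$exons[-n_ex, 2L])
      any(vapply(2:(n_ex - 1L), function(e) {
        min(intr[e - 1L], intr[e]) >= ceiling(lens[e] * 1.3) + 80L
      }, logical(1L)))
    },
    PARTIAL_EXON_GAP = any(exon_lengths(model) >= 140L),
    ANNOTATION_DROP = TRUE,
    MODEL_TRUNCATION = n_ex >= 3L,
    FALSE)
}

# Apply one sequence/annotation-level defect to a gene. Returns a list
# with the class, an optional contig edit, bookkeeping for the draft
# model, and the category/finding kinds the defect implies.
apply_gene_defect <- function(class, model, truth, exon_idx, ctg_src,
                              params) {
  out <- list(class = class, edit = NULL)
  to_edit <- function(exon, gpos, ref_len, alt) {
    row <- exon_idx[exon_idx$exon == exon, ]
    src <- ctg_src[[row$contig]]
    list(contig = row$contig, pos = gpos - src$start,
         ref_len = as.integer(ref_len), alt = alt)
  }
  if (class == "STOP_SUBSTITUTION") {
    cds <- cds_sequence(truth, model)
    sub <- stop_substitution_for(cds)
    if (is.null(sub)) stop("no single-base stop available in ",
                           model$gene_id)
    t <- model$cds_span[1L] + sub$codon_index * 3L + sub$offset
    offs <- exon_offsets(model)
    exon <- max(which(offs <= t))
    q <- t - offs[exon]
    gpos <- exon_local_to_genomic(model, exon, q)
    alt_g <- if (model$strand == "+") sub$alt else complement_base(sub$alt)
    out$edit <- to_edit(exon, gpos, 1L, alt_g)
    out$payload <- list(codon_index = sub$codon_index, ref = sub$ref,
                        alt = sub$alt)
    out$expected_category <- "no_protein_derived"
    out$expected_findings <- "PREMATURE_STOP"
  } else if (class == "FRAMESHIFT_INDEL") {
    iv <- exon_cds_intervals(model)
    ok <- which(vapply(iv, function(x) !is.null(x) && x[2L] - x[1L] >= 80L,
                       logical(1L)))
    exon <- ok[sample.int(length(ok), 1L)]
    k <- sample.int(min(2L, params$indel_max %||% 2L), 1L)
    kind <- sample(c("ins", "del"), 1L)
    lo <- iv[[exon]][1L] + 25L
    hi <- iv[[exon]][2L] - 25L - k
    q <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    offs <- exon_offsets(model)
    tc <- offs[exon] + q - model$cds_span[1L]   # CDS-local offset
    cds <- cds_sequence(truth, model)
    if (kind == "ins") {
      alt <- random_dna(k, 0.5)
      cds2 <- paste0(substr(cds, 1L, tc), alt,
                     substr(cds, tc + 1L, nchar(cds)))
      if (model$strand == "+") {
        out$edit <- to_edit(exon, exon_local_to_genomic(model, exon, q),
                            0L, alt)
      } else {
        # insertion before transcription-local q = genomic insertion at
        # the position just above the base mapped from q
        gpos <- exon_local_to_genomic(model, exon, q) + 1L
        out$edit <- to_edit(exon, gpos, 0L, revcomp(alt))
      }
    } else {
      cds2 <- paste0(substr(cds, 1L, tc),
                     substr(cds, tc + k + 1L, nchar(cds)))
      g <- if (model$strand == "+") {
        exon_local_to_genomic(model, exon, q)
      } else {
        exon_local_to_genomic(model, exon, q + k - 1L)
      }
      out$edit <- to_edit(exon, g, k, "")
    }
    tr <- translate_cds(substr(cds2, 1L,
                               nchar(cds2) - nchar(cds2) %% 3L))
    had_stop <- !is.na(tr$internal_stop)
    out$payload <- list(kind = kind, k = k, exon = exon, cds_offset = tc,
                        downstream_stop = had_stop)
    out$expected_category <- if (had_stop) "no_protein_derived" else "wrong"
    out$expected_findings <- if (had_stop) {
      c("FRAMESHIFT", "PREMATURE_STOP")
    } else "FRAMESHIFT"
  } else if (class == "EXON_GAP") {
    n_ex <- nrow(model$exons)
    lens <- exon_lengths(model)
    intr <- abs(model$exons[-1L, 1L] - model$exons[-n_ex, 2L])
    ok <- which(vapply(2:(n_ex - 1L), function(e) {
      min(intr[e - 1L], intr[e]) >= ceiling(lens[e] * 1.3) + 80L
    }, logical(1L))) + 1L
    exon <- ok[sample.int(length(ok), 1L)]
    mg <- params$gap_margin %||% 10L
    row <- exon_idx[exon_idx$exon == exon, ]
    src <- ctg_src[[row$contig]]
    gs <- max(model$exons[exon, 1L] - mg, src$start)
    ge <- min(model$exons[exon, 2L] + mg, src$end)
    out$edit <- list(contig = row$contig, pos = gs - src$start,
                     ref_len = as.integer(ge - gs),
                     alt = strrep("N", ge - gs))
    out$exon <- exon
    out$lost_len <- lens[exon]
    out$margin <- mg
    out$payload <- list(exon = exon, lost_len = lens[exon], margin = mg)
    out$expected_category <- "wrong"
    out$expected_findings <- c("MISSING_EXON", "SPURIOUS_EXON")
  } else if (class == "PARTIAL_EXON_GAP") {
    plen <- params$partial_gap_len %||% 30L
    lens <- exon_lengths(model)
    ok <- which(lens >= plen + 110L)
    exon <- ok[sample.int(length(ok), 1L)]
    mid <- (lens[exon] - plen) %/% 2L
    q <- max(50L, min(mid + sample.int(21L, 1L) - 11L,
                      lens[exon] - plen - 50L))
    g0 <- if (model$strand == "+") model$exons[exon, 1L] + q
          else model$exons[exon, 2L] - q - plen
    row <- exon_idx[exon_idx$exon == exon, ]
    src <- ctg_src[[row$contig]]
    out$edit <- list(contig = row$contig, pos = g0 - src$start,
                     ref_len = as.integer(plen), alt = strrep("N", plen))
    out$payload <- list(exon = exon, offset = q, len = plen)
    out$expected_category <- "incomplete"
    out$expected_findings <- "MISSING_SUBSEQUENCE"
  } else if (class == "ANNOTATION_DROP") {
    out$payload <- list()
    out$expected_category <- "none_annotated"
    out$expected_findings <- character(0)
  } else if (class == "MODEL_TRUNCATION") {
    n_ex <- nrow(model$exons)
    out$n_drop <- if (n_ex >= 4L) sample.int(2L, 1L) else 1L
    out$payload <- list(n_drop = out$n_drop)
    out$expected_category <- "incomplete"
    out$expected_findings <- "MODEL_TRUNCATION"
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Replace the lifted interval of a gap-lost exon with a decoy interval
# sampled from the gene's own intron, length-matched within 20%, avoiding
# N runs in the final draft sequence. Mirrors an annotation pipeline
# inventing an exon from intronic sequence when the real exon is absent.
add_decoy_exon <- function(lf, d, draft) {
  e <- d$exon
  i_e <- which(lf$exon == e)
  row_e <- lf[i_e, ]
  flank <- lf[lf$exon %in% c(e - 1L, e + 1L), ]
  target_seq <- draft$sequences[[row_e$target]]
  low_bound <- max(flank$end[flank$end <= row_e$start]) + 10L
  high_bound <- min(flank$start[flank$start >= row_e$end]) - 10L
  nz0 <- row_e$start - d$margin - 5L
  nz1 <- row_e$end + d$margin + 5L
  dlen <- max(30L, as.integer(round(d$lost_len *
                                      stats::runif(1L, 0.8, 1.2))))
  spaces <- list(c(low_bound, nz0), c(nz1, high_bound))
  pick <- function(dlen) {
    cand <- list()
    for (sp in spaces) {
      if (sp[2L] - sp[1L] >= dlen) cand[[length(cand) + 1L]] <- sp
    }
    if (!length(cand)) return(NULL)
    for (try in seq_len(50L)) {
      sp <- cand[[sample.int(length(cand), 1L)]]
      s <- sp[1L] + sample.int(sp[2L] - sp[1L] - dlen + 1L, 1L) - 1L
      if (!grepl("N", substr(target_seq, s + 1L, s + dlen), fixed = TRUE)) {
        return(c(s, s + dlen))
      }
    }
    NULL
  }
  dec <- pick(dlen)
  if (is.null(dec)) dec <- pick(30L)
  if (is.null(dec)) stop("no N-free intronic space for decoy exon near ",
                         row_e$target, ":", row_e$start)
  lf$start[i_e] <- dec[1L]
  lf$end[i_e] <- dec[2L]
  attr(lf, "decoy") <- list(target = row_e$target, start = dec[1L],
                            end = dec[2L])
  lf
}

# Assemble a draft transcript_model from retained lifted exons.
make_draft_model <- function(model, lf) {
  if (!nrow(lf)) return(NULL)
  lf <- lf[order(lf$exon), , drop = FALSE]
  splen <- sum(lf$end - lf$start)
  if (splen < 3L) return(NULL)
  c0 <- min(model$cds_span[1L], splen - 3L)
  c1 <- max(c0 + 3L, min(model$cds_span[2L], splen))
  transcript_model(model$gene_id, model$transcript_id,
                   lf$target[1L], lf$strand[1L],
                   cbind(lf$start, lf$end), c(c0, c1))
}

# One defect-record row per (gene, applied defect).
build_defect_records <- function(assignments, gene_defect, models,
                                 exon_index, lifted, fusions, placements,
                                 ctg_edits, genes_in_contig, draft) {
  rows <- list()
  add_row <- function(gene, class, seq, start, end, category, findings,
                      payload) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gene, class = class, seq = seq,
      start = as.integer(start), end = as.integer(end),
      expected_category = category,
      expected_findings = paste(findings, collapse = ","),
      payload = as.character(jsonlite::toJSON(payload, auto_unbox = TRUE)),
      stringsAsFactors = FALSE)
  }
  gene_hull <- function(g) {
    lf <- lifted[[g]]
    key <- paste(lf$target, lf$strand)
    maj <- names(sort(table(key), decreasing = TRUE))[1L]
    lf <- lf[key == maj, , drop = FALSE]
    list(seq = lf$target[1L], start = min(lf$start), end = max(lf$end))
  }
  # expected chain anomalies implied by where a gene's exons actually land
  chain_kinds <- function(g) {
    lf <- lifted[[g]]
    kinds <- character(0)
    chrom_targets <- unique(lf$target[draft$role[lf$target] == "chromosome"])
    unloc <- any(draft$role[lf$target] == "unlocalized_scaffold")
    expected <- models[[g]]$seq_name   # identity synteny
    effective <- chrom_targets
    if (unloc) effective <- union(effective, expected)
    if (length(effective) >= 2L) kinds <- c(kinds, "SPLIT_CHROMOSOME")
    if (unloc && length(chrom_targets) >= 1L) {
      kinds <- c(kinds, "SPLIT_UNLOCALIZED")
    }
    if (length(unique(lf$strand)) > 1L) kinds <- c(kinds, "ORIENTATION_FLIP")
    kinds
  }
  for (a in assignments) {
    if (!is.null(a$gene)) {
      g <- a$gene
      d <- gene_defect[[g]]
      if (!is.null(d$edit)) {
        ed <- d$edit
        pos2 <- lift_local(ed$pos, ctg_edits[[ed$contig]])
        p <- placements[placements$contig_id == ed$contig, ]
        start <- p$start + pos2
        end <- start + max(nchar(ed$alt), 1L)
        payload <- d$payload
        if (!is.null(d$decoy)) payload$decoy <- d$decoy
        add_row(g, a$class, p$target, start, end, d$expected_category,
                d$expected_findings, payload)
      } else {
        h <- gene_hull(g)
        add_row(g, a$class, h$seq, h$start, h$end, d$expected_category,
                d$expected_findings, d$payload)
      }
    } else if (a$class == "CHIMERIC_FUSION") {
      p <- placements[placements$contig_id == a$fid, ]
      bp_target <- if (p$orientation == "+") p$start + a$bpA
                   else p$end - a$bpA
      genes <- union(genes_in_contig[[a$cA]], genes_in_contig[[a$cB]])
      for (g in sort(genes)) {
        kinds <- c("CHIMERIC_CONTIG", chain_kinds(g))
        add_row(g, a$class, p$target, p$start, p$end, "wrong", kinds,
                list(contig = a$fid, source_a = a$cA, source_b = a$cB,
                     fusion_point = a$bpA, fusion_target_pos = bp_target,
                     lost_bases = a$lost))
      }
    } else {
      p <- placements[placements$contig_id == a$contig, ]
      for (g in sort(genes_in_contig[[a$contig]])) {
        kinds <- chain_kinds(g)
        add_row(g, a$class, p$target, p$start, p$end, "wrong", kinds,
                list(contig = a$contig, from = a$from,
                     to = if (is.na(a$to)) p$target else a$to))
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), class = character(),
                      seq = character(), start = integer(),
                      end = integer(), expected_category = character(),
                      expected_findings = character(),
                      payload = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$gene_id), , drop = FALSE]
}
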