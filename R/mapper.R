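#' Alignment and placement parameters
#'
#' BLASTN-like scoring for placing ortholog exons on a draft assembly by
#' local alignment. A gap of length L costs `gap_open + gap_extend * L`.
#' N in the target is scored as a mismatch, never a match, so placements
#' shrink at assembly gaps rather than bridging them; for the same reason
#' `identity` is computed over non-N aligned columns only (N carries no
#' sequence evidence for or against the exon).
#'
#' `min_identity`/`min_coverage` gate the `placed` status: coverage is
#' the aligned fraction of the exon, identity the match fraction of
#' aligned non-N columns. Defaults are chosen so single-base errors still
#' place an exon while unrelated (e.g. decoy intronic) sequence does not.
#' Exons shorter than `min_exon_len` are reported `unplaced` (too little
#' signal). Candidates within `tie_margin` of the best score make a
#' placement `ambiguous`.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch penalty (> 0).
#' @param gap_open,gap_extend affine gap penalties (> 0).
#' @param min_identity minimum identity for a placed exon, in (0, 1].
#' @param min_coverage minimum aligned fraction of the exon, in (0, 1].
#' @param tie_margin score slack within which a runner-up placement makes
#'   the exon ambiguous (0 = exact ties only).
#' @param seed_k exact-seed length for the candidate-window prefilter.
#' @param seed_stride stride between seeds along the exon.
#' @param window_pad bases added around a seeded candidate window.
#' @param min_exon_len exons shorter than this are not placed.
#' @return list of class `align_params`.
#' @export
align_params <- function(match = 2L, mismatch = 3L, gap_open = 5L,
                         gap_extend = 2L, min_identity = 0.85,
                         min_coverage = 0.80, tie_margin = 0,
                         seed_k = 11L, seed_stride = 8L,
                         window_pad = 40L, min_exon_len = 20L) {
  stopifnot(match > 0, mismatch > 0, gap_open > 0, gap_extend > 0,
            min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1, tie_margin >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity,
                 min_coverage = min_coverage, tie_margin = tie_margin,
                 seed_k = as.integer(seed_k),
                 seed_stride = as.integer(seed_stride),
                 window_pad = as.integer(window_pad),
                 min_exon_len = as.integer(min_exon_len)),
            class = "align_params")
}

#' Optimal local alignment of a query against a target
#'
#' Smith-Waterman local alignment with affine gaps under the
#' [align_params()] scoring scheme (a gap of length L costs
#' `gap_open + gap_extend * L`; the empty alignment scores 0).
#'
#' @param query,target nucleotide strings; the query must be non-empty
#'   A/C/G/T, the target may contain N (scored as mismatch).
#' @param params an [align_params()].
#' @return `NULL` when no alignment scores above 0, otherwise a list:
#'   `score`; `qstart`,`qend`,`tstart`,`tend` (0-based half-open aligned
#'   spans); `identity` (matches / non-N aligned columns); `n_match`,
#'   `n_mismatch`; `indels` data.frame (`qpos`, `tpos`, `length`, `kind`
#'   in ins/del, positions 0-based; `ins` = extra target bases, `del` =
#'   query bases absent from the target); `aligned_query`,
#'   `aligned_target` (gapped strings).
#' @export
local_align <- function(query, target, params = align_params()) {
  if (!nchar(query)) stop("empty query")
  if (grepl("[^ACGT]", query)) stop("query must be A/C/G/T only")
  sw <- sw_align_cpp(query, target, params$match, params$mismatch,
                     params$gap_open, params$gap_extend)
  if (sw$score <= 0) return(NULL)
  alignment_summary(sw$aligned_query, sw$aligned_target,
                    qstart = sw$qstart, tstart = sw$tstart,
                    score = sw$score)
}

# Column-walk a gapped alignment into coordinates, identity and indels.
alignment_summary <- function(qa, ta, qstart, tstart, score) {
  qc <- utf8ToInt(qa)
  tc <- utf8ToInt(ta)
  gap_chr <- utf8ToInt("-")
  n_chr <- utf8ToInt("N")
  qgap <- qc == gap_chr
  tgap <- tc == gap_chr
  qpos <- qstart + cumsum(!qgap)   # 1 past the query index of each column
  tpos <- tstart + cumsum(!tgap)
  both <- !qgap & !tgap
  n_match <- sum(both & qc == tc)
  n_mismatch <- sum(both & qc != tc)
  denom <- sum(both & tc != n_chr)
  identity <- if (denom) sum(both & qc == tc & tc != n_chr) / denom else 0
  runs <- rle(ifelse(qgap, "ins", ifelse(tgap, "del", "m")))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != "m"
  indels <- data.frame(
    qpos = qpos[starts[keep]] - ifelse(runs$values[keep] == "ins", 0L, 1L),
    tpos = tpos[starts[keep]] - ifelse(runs$values[keep] == "del", 0L, 1L),
    length = runs$lengths[keep],
    kind = runs$values[keep],
    stringsAsFactors = FALSE)
  list(score = score,
       qstart = qstart, qend = qstart + sum(!qgap),
       tstart = tstart, tend = tstart + sum(!tgap),
       identity = identity, n_match = n_match, n_mismatch = n_mismatch,
       indels = indels, aligned_query = qa, aligned_target = ta)
}

# ---- seeded candidate windows ---------------------------------------------

seed_offsets <- function(len, k, stride) {
  if (len < k) return(integer(0))
  unique(c(seq.int(0L, len - k, by = stride), len - k))
}

# Exact-seed prefilter: for every exon sequence (both orientations), find
# seed hits in the draft's chromosome/scaffold sequences with a single
# Aho-Corasick pass per target, and cluster implied exon starts into
# candidate windows.
find_candidate_windows <- function(exon_seqs, asm, params) {
  k <- params$seed_k
  seeds <- list()
  for (nm in names(exon_seqs)) {
    s <- exon_seqs[[nm]]
    len <- nchar(s)
    if (len < max(k, params$min_exon_len)) next
    for (strand in c("+", "-")) {
      ss <- if (strand == "+") s else revcomp(s)
      off <- seed_offsets(len, k, params$seed_stride)
      seeds[[length(seeds) + 1L]] <- data.frame(
        exon = nm, strand = strand, offset = off,
        seq = substring(ss, off + 1L, off + k), stringsAsFactors = FALSE)
    }
  }
  if (!length(seeds)) return(NULL)
  seeds <- do.call(rbind, seeds)
  seeds <- seeds[!grepl("N", seeds$seq, fixed = TRUE), , drop = FALSE]
  dict <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$seq))
  hits <- list()
  for (tg in assembly_targets(asm)) {
    mi <- Biostrings::matchPDict(dict, Biostrings::DNAString(asm$sequences[[tg]]))
    cnt <- S4Vectors::elementNROWS(mi)
    if (!sum(cnt)) next
    starts <- BiocGenerics::start(IRanges::stack(mi))
    si <- rep(seq_along(cnt), cnt)
    hits[[length(hits) + 1L]] <- data.frame(
      exon = seeds$exon[si], strand = seeds$strand[si], target = tg,
      implied = starts - 1L - seeds$offset[si], stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(NULL)
  hits <- do.call(rbind, hits)
  n_seeds <- table(paste(seeds$exon, seeds$strand, sep = "\r"))
  # cluster implied starts within 50 bp per (exon, target, strand); when
  # an exon contributes many seeds, a 1-seed cluster is almost surely a
  # random k-mer hit and is dropped before alignment
  out <- list()
  key <- paste(hits$exon, hits$target, hits$strand, sep = "\r")
  for (kk in unique(key)) {
    h <- hits[key == kk, , drop = FALSE]
    avail <- n_seeds[[paste(h$exon[1L], h$strand[1L], sep = "\r")]]
    v <- sort(h$implied)
    grp <- cumsum(c(1L, diff(v) > 50L))
    for (gnum in unique(grp)) {
      vg <- v[grp == gnum]
      if (length(vg) < 2L && avail >= 6L) next
      out[[length(out) + 1L]] <- data.frame(
        exon = h$exon[1L], target = h$target[1L], strand = h$strand[1L],
        implied = as.integer(stats::median(unique(vg))),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Align one exon against one candidate window; returns a placement record
# in forward target coordinates with query coordinates in exon (mRNA)
# orientation.
align_window <- function(exon_seq, asm, target, strand, implied, params) {
  len <- nchar(exon_seq)
  pad <- params$window_pad + len %/% 10L
  tlen <- nchar(asm$sequences[[target]])
  w0 <- max(implied - pad, 0L)
  w1 <- min(implied + len + pad, tlen)
  if (w1 - w0 < params$seed_k) return(NULL)
  win <- substr(asm$sequences[[target]], w0 + 1L, w1)
  if (strand == "-") win <- revcomp(win)
  la <- local_align(exon_seq, win, params)
  if (is.null(la)) return(NULL)
  wlen <- w1 - w0
  if (strand == "+") {
    tstart <- w0 + la$tstart; tend <- w0 + la$tend
  } else {
    tstart <- w0 + wlen - la$tend; tend <- w0 + wlen - la$tstart
  }
  list(target = target, strand = strand,
       target_start = tstart, target_end = tend,
       score = la$score, identity = la$identity,
       coverage = (la$qend - la$qstart) / len,
       qstart = la$qstart, qend = la$qend, exon_len = len,
       n_match = la$n_match, n_mismatch = la$n_mismatch,
       indels = la$indels,
       aligned_query = la$aligned_query,
       aligned_target = la$aligned_target)
}

placement_candidates <- function(exon_seq, asm, params, windows) {
  cands <- list()
  if (!is.null(windows) && nrow(windows)) {
    for (i in seq_len(nrow(windows))) {
      pl <- align_window(exon_seq, asm, windows$target[i],
                         windows$strand[i], windows$implied[i], params)
      if (!is.null(pl)) cands[[length(cands) + 1L]] <- pl
    }
  }
  if (!length(cands)) return(list())
  # drop duplicate hits of the same locus found through overlapping windows
  keep <- rep(TRUE, length(cands))
  for (i in seq_along(cands)) {
    if (!keep[i]) next
    for (j in seq_along(cands)) {
      if (i == j || !keep[j]) next
      a <- cands[[i]]; b <- cands[[j]]
      if (a$target == b$target && a$strand == b$strand &&
          a$target_start < b$target_end && b$target_start < a$target_end) {
        if (b$score < a$score ||
            (b$score == a$score && j > i)) keep[j] <- FALSE
      }
    }
  }
  cands <- cands[keep]
  cands[order(-vapply(cands, `[[`, numeric(1L), "score"))]
}

#' Place one exon sequence on a draft assembly
#'
#' Seeds candidate windows with exact k-mers on both strands, aligns the
#' exon against each window, and reports candidates sorted by score with
#' a placement status: `placed` when the best candidate passes the
#' identity and coverage thresholds, `ambiguous` when a runner-up ties it
#' within `tie_margin`, `unplaced` otherwise (including exons shorter
#' than `min_exon_len`).
#'
#' @param exon_seq exon nucleotide string in mRNA orientation.
#' @param asm draft [assembly()].
#' @param params an [align_params()].
#' @return list with `status` and `candidates` (list of placement
#'   records).
#' @export
place_exon <- function(exon_seq, asm, params = align_params()) {
  if (nchar(exon_seq) < params$min_exon_len) {
    return(list(status = "unplaced", reason = "short", candidates = list()))
  }
  win <- find_candidate_windows(list(x = exon_seq), asm, params)
  cands <- placement_candidates(exon_seq, asm, params, win)
  status_candidates(cands, params)
}

status_candidates <- function(cands, params) {
  passing <- Filter(function(p) {
    p$identity >= params$min_identity && p$coverage >= params$min_coverage
  }, cands)
  if (!length(passing)) {
    return(list(status = "unplaced", candidates = cands))
  }
  best <- passing[[1L]]
  tied <- sum(vapply(passing, function(p)
    p$score >= best$score - params$tie_margin, logical(1L)))
  status <- if (tied >= 2L) "ambiguous" else "placed"
  list(status = status, best = best, candidates = passing)
}

#' Map ortholog transcripts onto a draft assembly as exon chains
#'
#' For each transcript model on the ortholog (reference) genome, extracts
#' every exon sequence in mRNA orientation, places it on the draft with
#' [place_exon()] semantics (all exons share one seeded prefilter pass),
#' and assembles the placements into an exon chain that preserves
#' transcription order — never re-sorted by target coordinate, since
#' order violations are the misassembly signal.
#'
#' @param models list of [transcript_model()] on the ortholog genome.
#' @param ortholog ortholog [assembly()] (or named sequence vector).
#' @param draft draft [assembly()].
#' @param params an [align_params()].
#' @return list of `exon_chain` objects: `transcript_id`, `gene_id`,
#'   `model`, and `exons` — one entry per ortholog exon with `status`
#'   (`placed`/`ambiguous`/`unplaced`) and, when available, the best
#'   placement.
#' @export
map_transcripts <- function(models, ortholog, draft,
                            params = align_params()) {
  seqs <- if (inherits(ortholog, "assembly")) ortholog$sequences else ortholog
  exon_seqs <- list()
  for (m in models) {
    chrom <- seqs[[m$seq_name]]
    for (i in seq_len(nrow(m$exons))) {
      s <- substr(chrom, m$exons[i, 1L] + 1L, m$exons[i, 2L])
      if (m$strand == "-") s <- revcomp(s)
      exon_seqs[[paste0(m$gene_id, "\r", i)]] <- s
    }
  }
  windows <- find_candidate_windows(exon_seqs, draft, params)
  chains <- list()
  for (m in models) {
    exons <- vector("list", nrow(m$exons))
    for (i in seq_len(nrow(m$exons))) {
      key <- paste0(m$gene_id, "\r", i)
      es <- exon_seqs[[key]]
      if (nchar(es) < params$min_exon_len) {
        exons[[i]] <- list(exon = i, status = "unplaced", reason = "short")
        next
      }
      win <- if (is.null(windows)) NULL else
        windows[windows$exon == key, , drop = FALSE]
      st <- status_candidates(
        placement_candidates(es, draft, params, win), params)
      ex <- list(exon = i, status = st$status)
      if (!is.null(st$best)) ex <- c(ex, st$best)
      ex$n_candidates <- length(st$candidates)
      exons[[i]] <- ex
    }
    chains[[m$gene_id]] <- structure(
      list(transcript_id = m$transcript_id, gene_id = m$gene_id,
           model = m, exons = exons),
      class = "exon_chain")
  }
  chains
}

#' @export
print.exon_chain <- function(x, ...) {
  st <- vapply(x$exons, `[[`, "", "status")
  cat(sprintf("exon_chain %s: %d exons (%d placed, %d ambiguous, %d unplaced)\n",
              x$transcript_id, length(st), sum(st == "placed"),
              sum(st == "ambiguous"), sum(st == "unplaced")))
  invisible(x)
}

#' Map one transcript onto a draft assembly
#'
#' Convenience wrapper around [map_transcripts()] for a single model.
#'
#' @inheritParams map_transcripts
#' @param model a [transcript_model()].
#' @return an `exon_chain`.
#' @export
map_transcript <- function(model, ortholog, draft,
                           params = align_params()) {
  map_transcripts(list(model), ortholog, draft, params)[[1L]]
}

#' Flatten exon chains to a placement table
#'
#' BED-like view of the placed exons (one row per ortholog exon,
#' unplaced exons included with NA coordinates).
#'
#' @param chains list of `exon_chain` objects.
#' @return data.frame with columns `gene_id`, `exon`, `status`, `target`,
#'   `start`, `end`, `strand`, `score`, `identity`, `coverage`.
#' @export
chains_to_table <- function(chains) {
  rows <- lapply(chains, function(ch) {
    do.call(rbind, lapply(ch$exons, function(e) {
      data.frame(gene_id = ch$gene_id, exon = e$exon, status = e$status,
                 target = e$target %||% NA_character_,
                 start = e$target_start %||% NA_integer_,
                 end = e$target_end %||% NA_integer_,
                 strand = e$strand %||% NA_character_,
                 score = e$score %||% NA_real_,
                 identity = e$identity %||% NA_real_,
                 coverage = e$coverage %||% NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
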