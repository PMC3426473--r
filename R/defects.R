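#' Draft tiling configuration
#'
#' The draft is produced by cutting each truth chromosome into contigs and
#' reassembling them with fixed-length N gaps, emulating the
#' within-scaffold gaps of a Sanger-era draft. Cut points are snapped out
#' of exons so a single exon never straddles a contig boundary; with the
#' default 5-15 kb contigs and the default gene geometry most genes span
#' several contigs, which is what makes contig-level defects visible in
#' exon chains.
#'
#' @param contig_length range `c(min, max)` in bp.
#' @param gap_length N-run length between adjacent contigs.
#' @return list of class `tiling_config`.
#' @export
tiling_config <- function(contig_length = c(5000L, 15000L),
                          gap_length = 100L) {
  stopifnot(length(contig_length) == 2L, contig_length[1L] > 0L,
            contig_length[1L] <= contig_length[2L], gap_length >= 10L)
  structure(list(contig_length = as.integer(contig_length),
                 gap_length = as.integer(gap_length)),
            class = "tiling_config")
}

#' Defect specification
#'
#' One injected defect class and how many genes (or which genes) it is
#' applied to. Classes:
#' \describe{
#'   \item{STOP_SUBSTITUTION}{one base substituted to create an in-frame
#'     stop codon.}
#'   \item{FRAMESHIFT_INDEL}{a 1-2 bp insertion or deletion inside a CDS
#'     exon.}
#'   \item{EXON_GAP}{a whole internal exon (plus a small margin) replaced
#'     by an N run; the draft gene model replaces the lost exon with a
#'     decoy exon sampled from the gene's own intron.}
#'   \item{PARTIAL_EXON_GAP}{a 30 bp sub-span of a large exon replaced by
#'     an N run.}
#'   \item{CONTIG_MISASSIGNMENT}{a contig carrying a strict subset of a
#'     gene's exons moved to a different chromosome.}
#'   \item{UNLOCALIZED_SPLIT}{such a contig moved onto a new single-contig
#'     unlocalized scaffold.}
#'   \item{ORIENTATION_FLIP}{a placed contig reverse complemented in situ.}
#'   \item{CHIMERIC_FUSION}{a prefix of a contig from one chromosome fused
#'     to the suffix of a contig from another, the product placed at the
#'     first contig's slot.}
#'   \item{ANNOTATION_DROP}{the gene removed from the draft annotation
#'     only.}
#'   \item{MODEL_TRUNCATION}{the draft gene model emitted without its
#'     terminal exon(s).}
#' }
#'
#' @param class one of the class names above.
#' @param n number of applications (contig-level classes count moved
#'   contigs/fusions; every gene with exons on a moved contig is logged).
#' @param genes optional explicit gene ids instead of random choice.
#' @param params optional class parameters (e.g. `gap_margin`,
#'   `indel_max`, `partial_gap_len`).
#' @return list of class `defect_spec`.
#' @export
defect_spec <- function(class, n = 1L, genes = NULL, params = list()) {
  classes <- c("STOP_SUBSTITUTION", "FRAMESHIFT_INDEL", "EXON_GAP",
               "PARTIAL_EXON_GAP", "CONTIG_MISASSIGNMENT",
               "UNLOCALIZED_SPLIT", "ORIENTATION_FLIP", "CHIMERIC_FUSION",
               "ANNOTATION_DROP", "MODEL_TRUNCATION")
  if (!class %in% classes) stop("unknown defect class: ", class)
  structure(list(class = class, n = as.integer(n), genes = genes,
                 params = params), class = "defect_spec")
}

#' Default defect mix
#'
#' The standard survey conditions: every defect class represented, one
#' defect per affected gene, roughly 30 of the default 50 genes hit
#' (contig-level defects also log the bystander genes whose exons ride
#' the moved contig).
#'
#' @return list of [defect_spec()] objects.
#' @export
default_defect_specs <- function() {
  list(defect_spec("CHIMERIC_FUSION", 1L),
       defect_spec("CONTIG_MISASSIGNMENT", 2L),
       defect_spec("UNLOCALIZED_SPLIT", 2L),
       defect_spec("ORIENTATION_FLIP", 2L),
       defect_spec("STOP_SUBSTITUTION", 4L),
       defect_spec("FRAMESHIFT_INDEL", 4L),
       defect_spec("EXON_GAP", 4L),
       defect_spec("PARTIAL_EXON_GAP", 3L),
       defect_spec("ANNOTATION_DROP", 3L),
       defect_spec("MODEL_TRUNCATION", 3L))
}

# ---- internal helpers -----------------------------------------------------

# Cut one chromosome into contigs, snapping cut points out of exons.
tile_chromosome <- function(chrom_len, exon_intervals, tiling) {
  cuts <- integer(0)
  pos <- 0L
  repeat {
    nxt <- pos + rand_int(tiling$contig_length)
    if (nxt >= chrom_len) break
    if (nrow(exon_intervals)) {
      hit <- which(exon_intervals$start - 5L < nxt &
                     exon_intervals$end + 5L > nxt)
      if (length(hit)) nxt <- max(exon_intervals$end[hit]) + 5L
    }
    if (nxt >= chrom_len) break
    cuts <- c(cuts, nxt)
    pos <- nxt
  }
  cbind(start = c(0L, cuts), end = c(cuts, chrom_len))
}

apply_edits <- function(seq, edits) {
  if (is.null(edits) || !nrow(edits)) return(seq)
  edits <- edits[order(-edits$pos), , drop = FALSE]
  for (i in seq_len(nrow(edits))) {
    seq <- paste0(substr(seq, 1L, edits$pos[i]),
                  edits$alt[i],
                  substr(seq, edits$pos[i] + edits$ref_len[i] + 1L,
                         nchar(seq)))
  }
  seq
}

lift_local <- function(pos, edits) {
  if (is.null(edits) || !nrow(edits)) return(pos)
  delta <- nchar(edits$alt) - edits$ref_len
  vapply(pos, function(p) p + sum(delta[edits$pos < p]), integer(1L))
}

# Single-base substitutions turning an interior codon into a stop.
stop_substitution_for <- function(cds) {
  stops <- c("TAA", "TAG", "TGA")
  n_cod <- nchar(cds) %/% 3L
  cand <- seq.int(4L, n_cod - 4L)   # 0-based codon indices 3 .. n-5
  cand <- sample(cand)
  for (ci in cand) {
    idx <- ci - 1L
    codon <- substr(cds, idx * 3L + 1L, idx * 3L + 3L)
    for (s in sample(stops)) {
      d <- which(strsplit(codon, "")[[1L]] != strsplit(s, "")[[1L]])
      if (length(d) == 1L) {
        return(list(codon_index = idx, offset = d - 1L,
                    alt = substr(s, d, d),
                    ref = substr(codon, d, d)))
      }
    }
  }
  NULL
}

#' Derive a corrupted draft assembly from a truth genome
#'
#' Tiles the truth chromosomes into contigs joined by N gaps, injects the
#' requested defects, reassembles chromosome and scaffold sequences from
#' the (possibly rearranged) contig layout, lifts the truth annotation
#' into draft coordinates to produce the draft's own gene models, and logs
#' every applied defect with its draft-coordinate locus, the finding kinds
#' it should trigger, and the survey category it implies.
#'
#' Genes receive at most one defect class. Contig-level defects are
#' assigned first and claim every gene with an exon on the moved contig;
#' sequence- and annotation-level defects are then drawn from the
#' remaining untouched genes. Per-gene randomness is driven by a substream
#' keyed on the gene id, so the same seed reproduces the same draft
#' regardless of spec ordering.
#'
#' @param truth truth [assembly()] from [generate_truth()].
#' @param models truth transcript models.
#' @param defect_specs list of [defect_spec()]; `list()` derives a clean
#'   draft (tiling only).
#' @param tiling a [tiling_config()].
#' @param seed integer seed for tiling and defect placement.
#' @return list with `draft` (an [assembly()] with placements),
#'   `draft_models` (the draft's own annotation), `defects` (defect-record
#'   data.frame as written by [write_defect_log()]) and `synteny`
#'   (identity map over the truth chromosomes).
#' @export
derive_draft <- function(truth, models, defect_specs = list(),
                         tiling = tiling_config(), seed = 1L) {
  stopifnot(inherits(truth, "assembly"))
  with_seed(seed, {
    chroms <- assembly_targets(truth, "chromosome")
    models <- stats::setNames(models,
                              vapply(models, `[[`, "", "gene_id"))

    ## ---- tiling ----
    ctg_src <- list(); ctg_seq <- list(); ctg_edits <- list()
    layout <- list()
    for (ch in chroms) {
      ex <- do.call(rbind, lapply(models, function(m) {
        if (m$seq_name != ch) return(NULL)
        data.frame(start = m$exons[, 1L], end = m$exons[, 2L])
      }))
      if (is.null(ex)) ex <- data.frame(start = integer(), end = integer())
      tiles <- tile_chromosome(nchar(truth$sequences[[ch]]), ex, tiling)
      ids <- sprintf("ctg_%s_%03d", ch, seq_len(nrow(tiles)))
      for (i in seq_len(nrow(tiles))) {
        ctg_src[[ids[i]]] <- list(chrom = ch, start = tiles[i, 1L],
                                  end = tiles[i, 2L])
        ctg_seq[[ids[i]]] <- substr(truth$sequences[[ch]],
                                    tiles[i, 1L] + 1L, tiles[i, 2L])
      }
      layout[[ch]] <- data.frame(contig_id = ids, orientation = "+",
                                 stringsAsFactors = FALSE)
    }
    roles <- stats::setNames(rep("chromosome", length(chroms)), chroms)

    ## ---- exon -> contig index ----
    contig_of <- function(ch, g0, g1) {
      for (id in layout[[ch]]$contig_id) {
        s <- ctg_src[[id]]
        if (s$start <= g0 && s$end >= g1) return(id)
      }
      stop("exon not contained in a single contig")
    }
    exon_index <- list()   # gene -> data.frame(exon, contig, lstart, lend)
    genes_in_contig <- list()
    for (g in names(models)) {
      m <- models[[g]]
      rows <- lapply(seq_len(nrow(m$exons)), function(i) {
        cid <- contig_of(m$seq_name, m$exons[i, 1L], m$exons[i, 2L])
        data.frame(exon = i, contig = cid,
                   lstart = m$exons[i, 1L] - ctg_src[[cid]]$start,
                   lend = m$exons[i, 2L] - ctg_src[[cid]]$start,
                   stringsAsFactors = FALSE)
      })
      exon_index[[g]] <- do.call(rbind, rows)
      for (cid in unique(exon_index[[g]]$contig)) {
        genes_in_contig[[cid]] <- c(genes_in_contig[[cid]], g)
      }
    }

    ## ---- defect assignment ----
    affected <- character(0)
    used_contigs <- character(0)
    assignments <- list()   # per applied defect: class, genes, contig(s), params
    fusions <- list()       # fused contig bookkeeping

    contig_eligible <- function(cid) {
      if (cid %in% used_contigs) return(FALSE)
      gs <- genes_in_contig[[cid]]
      if (is.null(gs)) return(FALSE)
      for (g in gs) {
        if (g %in% affected) return(FALSE)
        idx <- exon_index[[g]]
        n_in <- sum(idx$contig == cid)
        if (n_in >= nrow(idx)) return(FALSE)   # must be a strict subset
      }
      TRUE
    }
    has_middle_exon <- function(cid) {
      any(vapply(genes_in_contig[[cid]], function(g) {
        idx <- exon_index[[g]]
        any(idx$contig == cid & idx$exon > 1L & idx$exon < max(idx$exon))
      }, logical(1L)))
    }
    pick_contig <- function(pool) {
      ok <- pool[vapply(pool, contig_eligible, logical(1L))]
      if (!length(ok)) return(NULL)
      mid <- ok[vapply(ok, has_middle_exon, logical(1L))]
      cand <- if (length(mid)) mid else ok
      # prefer contigs whose lowest hosted exon index is smallest (tie-break)
      cand[sample(length(cand), 1L)]
    }
    claim <- function(cid) {
      used_contigs <<- c(used_contigs, cid)
      affected <<- union(affected, genes_in_contig[[cid]])
    }

    specs <- defect_specs
    ord <- order(!vapply(specs, function(s) s$class %in%
                           c("CHIMERIC_FUSION", "CONTIG_MISASSIGNMENT",
                             "UNLOCALIZED_SPLIT", "ORIENTATION_FLIP"),
                         logical(1L)))
    for (spec in specs[ord]) {
      for (rep_i in seq_len(spec$n)) {
        cls <- spec$class
        if (cls == "CHIMERIC_FUSION") {
          if (length(chroms) < 2L) {
            stop("CHIMERIC_FUSION needs at least two chromosomes")
          }
          pair <- NULL
          for (try in seq_len(200L)) {
            two <- sample(chroms, 2L)
            poolA <- layout[[two[1L]]]$contig_id
            poolA <- poolA[vapply(poolA, contig_eligible, logical(1L))]
            poolA <- poolA[vapply(poolA, function(cid) {
              mx <- max(unlist(lapply(genes_in_contig[[cid]], function(g) {
                idx <- exon_index[[g]]; idx$lend[idx$contig == cid]
              })))
              mx <= nchar(ctg_seq[[cid]]) - 40L
            }, logical(1L))]
            poolB <- layout[[two[2L]]]$contig_id
            poolB <- poolB[vapply(poolB, contig_eligible, logical(1L))]
            poolB <- poolB[vapply(poolB, function(cid) {
              mn <- min(unlist(lapply(genes_in_contig[[cid]], function(g) {
                idx <- exon_index[[g]]; idx$lstart[idx$contig == cid]
              })))
              mn >= 40L
            }, logical(1L))]
            if (length(poolA) && length(poolB)) {
              pair <- list(chrA = two[1L], chrB = two[2L],
                           cA = poolA[sample(length(poolA), 1L)],
                           cB = poolB[sample(length(poolB), 1L)])
              break
            }
          }
          if (is.null(pair)) stop("no eligible contig pair for CHIMERIC_FUSION")
          claim(pair$cA); claim(pair$cB)
          assignments[[length(assignments) + 1L]] <-
            c(list(class = cls), pair)
        } else if (cls %in% c("CONTIG_MISASSIGNMENT", "UNLOCALIZED_SPLIT",
                              "ORIENTATION_FLIP")) {
          if (cls == "CONTIG_MISASSIGNMENT" && length(chroms) < 2L) {
            stop("CONTIG_MISASSIGNMENT needs at least two chromosomes")
          }
          pool <- unlist(lapply(chroms, function(ch) layout[[ch]]$contig_id))
          cid <- pick_contig(pool)
          if (is.null(cid)) stop("no eligible contig for ", cls)
          claim(cid)
          src_ch <- ctg_src[[cid]]$chrom
          dest <- if (cls == "CONTIG_MISASSIGNMENT") {
            sample(setdiff(chroms, src_ch), 1L)
          } else NA_character_
          assignments[[length(assignments) + 1L]] <-
            list(class = cls, contig = cid, from = src_ch, to = dest)
        } else {
          pool <- if (!is.null(spec$genes)) {
            setdiff(spec$genes, affected)
          } else setdiff(names(models), affected)
          elig <- pool[vapply(pool, function(g) {
            gene_eligible(models[[g]], cls, spec$params, truth)
          }, logical(1L))]
          if (!length(elig)) stop("no eligible gene for ", cls)
          g <- elig[sample(length(elig), 1L)]
          affected <- c(affected, g)
          assignments[[length(assignments) + 1L]] <-
            list(class = cls, gene = g, params = spec$params)
        }
      }
    }

    ## ---- apply sequence-level defects (contig edits) ----
    gene_defect <- list()   # gene -> list(class, payload, ...)
    for (a in assignments) {
      if (!a$class %in% c("STOP_SUBSTITUTION", "FRAMESHIFT_INDEL",
                          "EXON_GAP", "PARTIAL_EXON_GAP",
                          "ANNOTATION_DROP", "MODEL_TRUNCATION")) next
      g <- a$gene
      m <- models[[g]]
      res <- with_seed(sub_seed(seed, g), {
        apply_gene_defect(a$class, m, truth, exon_index[[g]], ctg_src,
                          a$params)
      })
      if (!is.null(res$edit)) {
        cid <- res$edit$contig
        ctg_edits[[cid]] <- rbind(ctg_edits[[cid]],
                                  data.frame(pos = res$edit$pos,
                                             ref_len = res$edit$ref_len,
                                             alt = res$edit$alt,
                                             stringsAsFactors = FALSE))
        ctg_seq[[cid]] <- NA  # rebuilt below from edits
      }
      gene_defect[[g]] <- res
    }
    # re-slice edited contig sequences
    for (cid in names(ctg_edits)) {
      s <- ctg_src[[cid]]
      raw <- substr(truth$sequences[[s$chrom]], s$start + 1L, s$end)
      ctg_seq[[cid]] <- apply_edits(raw, ctg_edits[[cid]])
    }

    ## ---- apply contig-level rearrangements ----
    remove_from_layout <- function(ch, cid) {
      layout[[ch]] <<- layout[[ch]][layout[[ch]]$contig_id != cid, ,
                                    drop = FALSE]
    }
    for (ai in seq_along(assignments)) {
      a <- assignments[[ai]]
      if (a$class == "CONTIG_MISASSIGNMENT") {
        remove_from_layout(a$from, a$contig)
        layout[[a$to]] <- rbind(layout[[a$to]],
                                data.frame(contig_id = a$contig,
                                           orientation = "+",
                                           stringsAsFactors = FALSE))
      } else if (a$class == "UNLOCALIZED_SPLIT") {
        remove_from_layout(a$from, a$contig)
        scaf <- paste0("scaffold_", a$contig)
        layout[[scaf]] <- data.frame(contig_id = a$contig,
                                     orientation = "+",
                                     stringsAsFactors = FALSE)
        roles[scaf] <- "unlocalized_scaffold"
      } else if (a$class == "ORIENTATION_FLIP") {
        i <- which(layout[[a$from]]$contig_id == a$contig)
        layout[[a$from]]$orientation[i] <- "-"
      } else if (a$class == "CHIMERIC_FUSION") {
        lenA <- nchar(ctg_seq[[a$cA]])
        lenB <- nchar(ctg_seq[[a$cB]])
        maxA <- max(unlist(lapply(genes_in_contig[[a$cA]], function(g) {
          idx <- exon_index[[g]]; idx$lend[idx$contig == a$cA]
        })))
        minB <- min(unlist(lapply(genes_in_contig[[a$cB]], function(g) {
          idx <- exon_index[[g]]; idx$lstart[idx$contig == a$cB]
        })))
        bpA <- maxA + 20L + sample.int(max(lenA - 20L - maxA, 1L), 1L) - 1L
        bpA <- min(bpA, lenA)
        bpB <- sample.int(max(minB - 20L, 1L), 1L)
        fid <- paste0("chim_", a$cA, "_", a$cB)
        ctg_seq[[fid]] <- paste0(substr(ctg_seq[[a$cA]], 1L, bpA),
                                 substr(ctg_seq[[a$cB]], bpB + 1L, lenB))
        ctg_src[[fid]] <- list(chrom = a$chrA, start = NA_integer_,
                               end = NA_integer_)
        i <- which(layout[[a$chrA]]$contig_id == a$cA)
        layout[[a$chrA]]$contig_id[i] <- fid
        remove_from_layout(a$chrB, a$cB)
        fusions[[a$cA]] <- list(fused = fid, offset = 0L,
                                lo = 0L, hi = bpA)
        fusions[[a$cB]] <- list(fused = fid, offset = bpA - bpB,
                                lo = bpB, hi = lenB)
        a$bpA <- bpA; a$bpB <- bpB; a$fid <- fid
        a$lost <- (lenA - bpA) + bpB
      }
      assignments[[ai]] <- a
    }

    ## ---- assemble final sequences and placements ----
    gap <- strrep("N", tiling$gap_length)
    seqs <- character(0)
    plc <- list()
    for (tg in names(layout)) {
      lay <- layout[[tg]]
      pieces <- character(nrow(lay))
      pos <- 0L
      for (i in seq_len(nrow(lay))) {
        s <- ctg_seq[[lay$contig_id[i]]]
        pieces[i] <- if (lay$orientation[i] == "-") revcomp(s) else s
        plc[[length(plc) + 1L]] <- data.frame(
          contig_id = lay$contig_id[i], target = tg, start = pos,
          end = pos + nchar(s), orientation = lay$orientation[i],
          stringsAsFactors = FALSE)
        pos <- pos + nchar(s) + tiling$gap_length
      }
      seqs[[tg]] <- paste(pieces, collapse = gap)
    }
    placements <- do.call(rbind, c(plc, list(make.row.names = FALSE)))
    for (cid in placements$contig_id) roles[cid] <- "contig"
    draft <- assembly(seqs, roles, placements)

    ## ---- lift truth exons into draft coordinates ----
    lift_exon <- function(g, i) {
      row <- exon_index[[g]][exon_index[[g]]$exon == i, ]
      cid <- row$contig; ls <- row$lstart; le <- row$lend
      if (!is.null(fusions[[cid]])) {
        fu <- fusions[[cid]]
        ls <- ls + fu$offset; le <- le + fu$offset
        cid <- fu$fused
      }
      ed <- ctg_edits[[cid]]
      ls2 <- lift_local(ls, ed); le2 <- lift_local(le, ed)
      p <- placements[placements$contig_id == cid, ]
      if (p$orientation == "+") {
        list(target = p$target, start = p$start + ls2,
             end = p$start + le2, flipped = FALSE)
      } else {
        list(target = p$target, start = p$end - le2,
             end = p$end - ls2, flipped = TRUE)
      }
    }
    lifted <- list()
    for (g in names(models)) {
      m <- models[[g]]
      rows <- lapply(seq_len(nrow(m$exons)), function(i) {
        lf <- lift_exon(g, i)
        strand <- if (lf$flipped) flip_strand(m$strand) else m$strand
        data.frame(exon = i, target = lf$target, start = lf$start,
                   end = lf$end, strand = strand, stringsAsFactors = FALSE)
      })
      lifted[[g]] <- do.call(rbind, rows)
    }

    ## ---- draft gene models ----
    draft_models <- list()
    for (g in names(models)) {
      d <- gene_defect[[g]]
      if (!is.null(d) && d$class == "ANNOTATION_DROP") next
      lf <- lifted[[g]]
      m <- models[[g]]
      if (!is.null(d) && d$class == "MODEL_TRUNCATION") {
        lf <- lf[lf$exon <= nrow(m$exons) - d$n_drop, , drop = FALSE]
      }
      key <- paste(lf$target, lf$strand)
      maj <- names(sort(table(key), decreasing = TRUE))[1L]
      lf <- lf[key == maj, , drop = FALSE]
      if (!is.null(d) && d$class == "EXON_GAP") {
        lf <- add_decoy_exon(lf, d, draft)
        gene_defect[[g]]$decoy <- attr(lf, "decoy")
      }
      dm <- make_draft_model(m, lf)
      if (!is.null(dm)) draft_models[[g]] <- dm
    }

    ## ---- defect records ----
    records <- build_defect_records(assignments, gene_defect, models,
                                    exon_index, lifted, fusions, placements,
                                    ctg_edits, genes_in_contig, draft)
    synteny <- synteny_map(chroms, chroms)
    list(draft = draft, draft_models = unname(draft_models),
         defects = records, synteny = synteny)
  })
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")
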