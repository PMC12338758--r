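# Native transcript classification against a reference annotation.
#
# Each evidence transcript gets exactly one class code from a fixed decision
# ladder (first match wins):
#   EXACT              identical intron chain (multi-exon; terminal exon ends
#                      are ignored) or, for single-exon transcripts,
#                      reciprocal exonic overlap >= `single_exon_frac` with a
#                      single-exon reference transcript
#   SPANS_MULTIPLE     same-strand exonic overlap with >= 2 reference genes
#   NOVEL_ISOFORM      multi-exon, shares >= 1 intron (both ends) with
#                      exactly one reference gene, chain not identical
#   CONTAINED          intron chain a contiguous sub-chain of a reference
#                      transcript, or a single-exon transcript lying inside
#                      a reference exon
#   EXONIC_OVERLAP_ONLY same-strand exonic overlap with one gene, no shared
#                      intron
#   OPPOSITE_STRAND    exonic overlap only with genes on the other strand
#   INTERGENIC         no exonic overlap with any reference gene
#
# "Touching" a gene means same-strand exon-to-exon base overlap (never mere
# genomic-span overlap), so genes nested inside long introns are not joined
# spuriously. Strand "." (permitted on single-exon transcripts only) is
# treated as compatible with both strands.

CLASS_CODES <- c("EXACT", "NOVEL_ISOFORM", "CONTAINED", "SPANS_MULTIPLE",
                 "INTERGENIC", "OPPOSITE_STRAND", "EXONIC_OVERLAP_ONLY")

.introns_of <- function(starts, ends) {
  n <- length(starts)
  if (n < 2L) return(data.table(istart = integer(0), iend = integer(0)))
  data.table(istart = ends[-n] + 1L, iend = starts[-1L] - 1L)
}

.chain_str <- function(istart, iend) {
  paste0(";", paste(paste0(istart, "-", iend), collapse = ";"), ";")
}

# Precomputed reference lookup structures.
.ref_index <- function(reference) {
  ex <- reference$exons
  nex <- ex[, .(n = .N), by = transcript_id]
  multi_ids <- nex[n > 1L, transcript_id]
  if (length(multi_ids)) {
    mx <- ex[transcript_id %in% multi_ids][order(transcript_id, start)]
    introns <- mx[, .(istart = end[-.N] + 1L, iend = start[-1L] - 1L,
                      seqid = seqid[1L], strand = strand[1L],
                      gene_id = gene_id[1L]), by = transcript_id]
    chains <- introns[, .(chain = .chain_str(istart, iend),
                          seqid = seqid[1L], strand = strand[1L],
                          gene_id = gene_id[1L]), by = transcript_id]
    chains[, ckey := paste(seqid, strand, chain, sep = "|")]
    gene_introns <- unique(introns[, .(ikey = paste(seqid, strand, istart,
                                                    iend, sep = "|"),
                                       gene_id)])
  } else {
    chains <- data.table(transcript_id = character(0), chain = character(0),
                         seqid = character(0), strand = character(0),
                         gene_id = character(0), ckey = character(0))
    gene_introns <- data.table(ikey = character(0), gene_id = character(0))
  }
  single <- ex[!transcript_id %in% multi_ids,
               .(transcript_id, gene_id, seqid, strand, start, end)]
  fx <- ex[, .(seqid, start, end, r_strand = strand, r_gene = gene_id,
               r_tx = transcript_id)]
  setkey(fx, seqid, start, end)
  gene_rank <- reference$genes[, .(gene_id, rank = seq_len(.N))]
  list(fx = fx, chains = chains, gene_introns = gene_introns,
       single = single, single_ids = single$transcript_id,
       gene_rank = stats::setNames(gene_rank$rank, gene_rank$gene_id))
}

.order_genes <- function(gids, idx) {
  if (length(gids) == 0L) return(character(0))
  gids[order(idx$gene_rank[gids], gids)]
}

#' Classify all evidence transcripts against a reference annotation
#'
#' @param evidence,reference `AnnotationSet` objects.
#' @param single_exon_frac reciprocal-overlap fraction two single-exon
#'   transcripts must share to count as the same transcript (default 0.8).
#' @return a data.table with one row per evidence transcript, in canonical
#'   evidence order (seqid, start, transcript_id): columns `transcript_id`,
#'   `code`, `ref_gene_ids` (list column, genes ordered by genomic position),
#'   `matched_ref_transcript_id` (`NA` unless `code == "EXACT"`).
#' @export
classify_all <- function(evidence, reference, single_exon_frac = 0.8) {
  stopifnot(inherits(evidence, "AnnotationSet"),
            inherits(reference, "AnnotationSet"))
  ev_ids <- evidence$transcripts$transcript_id
  if (length(ev_ids) == 0L)
    return(data.table(transcript_id = character(0), code = character(0),
                      ref_gene_ids = list(),
                      matched_ref_transcript_id = character(0)))
  idx <- .ref_index(reference)

  # one overlap join for all evidence exons
  evex <- evidence$exons[, .(seqid, start, end, strand,
                             ev_tx = transcript_id)]
  ov <- if (nrow(idx$fx)) {
    foverlaps(evex, idx$fx, by.x = c("seqid", "start", "end"), nomatch = NULL)
  } else {
    data.table(seqid = character(0), start = integer(0), end = integer(0),
               r_strand = character(0), r_gene = character(0),
               r_tx = character(0), i.start = integer(0), i.end = integer(0),
               strand = character(0), ev_tx = character(0))
  }
  if (nrow(ov)) {
    ov[, same := strand == "." | strand == r_strand]
    ov[, ovw := pmin(end, i.end) - pmax(start, i.start) + 1L]
  }
  ov_by_tx <- if (nrow(ov)) split(ov, by = "ev_tx") else list()

  exl <- split(evidence$exons, by = "transcript_id")
  single_len <- stats::setNames(
    idx$single$end - idx$single$start + 1L, idx$single$transcript_id)

  res <- vector("list", length(ev_ids))
  for (i in seq_along(ev_ids)) {
    tid <- ev_ids[i]
    tex <- exl[[tid]][order(start)]
    n_ex <- nrow(tex)
    tlen <- sum(tex$end - tex$start + 1L)
    o <- ov_by_tx[[tid]]
    same_genes <- if (is.null(o)) character(0) else
      .order_genes(unique(o[same == TRUE, r_gene]), idx)
    opp_genes <- if (is.null(o)) character(0) else
      .order_genes(unique(o[same == FALSE, r_gene]), idx)

    code <- NULL
    matched <- NA_character_
    gids <- same_genes

    if (n_ex > 1L) {
      intr <- .introns_of(tex$start, tex$end)
      this_key <- paste(tex$seqid[1L], tex$strand[1L],
                        .chain_str(intr$istart, intr$iend), sep = "|")
      hit <- idx$chains[which(idx$chains$ckey == this_key)]
      if (nrow(hit)) {
        hit <- hit[order(transcript_id)]
        code <- "EXACT"
        matched <- hit$transcript_id[1L]
        gids <- hit$gene_id[1L]
      }
    } else {
      # single-exon: reciprocal overlap with a single-exon reference transcript
      if (!is.null(o)) {
        cand <- o[same == TRUE & r_tx %in% idx$single_ids]
        if (nrow(cand)) {
          rlen <- single_len[cand$r_tx]
          ok <- cand$ovw / tlen >= single_exon_frac &
            cand$ovw / rlen >= single_exon_frac
          if (any(ok)) {
            ctx <- sort(cand$r_tx[ok])[1L]
            code <- "EXACT"
            matched <- ctx
            gids <- idx$single[transcript_id == ctx, gene_id]
          }
        }
      }
    }

    if (is.null(code) && length(same_genes) >= 2L) {
      code <- "SPANS_MULTIPLE"
      gids <- same_genes
    }

    if (is.null(code) && n_ex > 1L) {
      intr <- .introns_of(tex$start, tex$end)
      ikeys <- paste(tex$seqid[1L], tex$strand[1L], intr$istart, intr$iend,
                     sep = "|")
      share <- unique(idx$gene_introns[ikey %in% ikeys, gene_id])
      if (length(share) == 1L) {
        code <- "NOVEL_ISOFORM"
        gids <- .order_genes(unique(c(same_genes, share)), idx)
      } else if (length(share) == 0L) {
        # contained multi-exon: contiguous sub-chain of a reference chain
        cstr <- .chain_str(intr$istart, intr$iend)
        cc <- idx$chains[seqid == tex$seqid[1L] & strand == tex$strand[1L]]
        if (nrow(cc) && any(grepl(substr(cstr, 2L, nchar(cstr) - 1L),
                                  cc$chain, fixed = TRUE))) {
          code <- "CONTAINED"
          gids <- same_genes
        }
      }
    }

    if (is.null(code) && n_ex == 1L && !is.null(o)) {
      # contained single-exon: fully inside a same-strand reference exon
      if (nrow(o[same == TRUE & start <= i.start & i.end <= end])) {
        code <- "CONTAINED"
        gids <- same_genes
      }
    }

    if (is.null(code)) {
      if (length(same_genes) == 1L) {
        code <- "EXONIC_OVERLAP_ONLY"
        gids <- same_genes
      } else if (length(opp_genes) >= 1L) {
        code <- "OPPOSITE_STRAND"
        gids <- opp_genes
      } else {
        code <- "INTERGENIC"
        gids <- character(0)
      }
    }

    res[[i]] <- list(transcript_id = tid, code = code,
                     ref_gene_ids = list(gids),
                     matched_ref_transcript_id = matched)
  }
  out <- rbindlist(res)
  out
}

#' Classify a single transcript
#'
#' Convenience wrapper around [classify_all()] for one transcript model.
#'
#' @param t a one-transcript `AnnotationSet`, or a list with elements
#'   `transcript_id`, `gene_id`, `seqid`, `strand` and `exons` (a data.frame
#'   with `start`, `end`).
#' @inheritParams classify_all
#' @return a one-row data.table as in [classify_all()].
#' @export
classify_transcript <- function(t, reference, single_exon_frac = 0.8) {
  if (!inherits(t, "AnnotationSet")) {
    stopifnot(is.list(t), !is.null(t$exons))
    t <- annotation_set(
      data.frame(seqid = t$seqid, start = t$exons$start, end = t$exons$end,
                 strand = t$strand, gene_id = t$gene_id %||% "g_query",
                 transcript_id = t$transcript_id),
      provenance = "evidence")
  }
  stopifnot(nrow(t$transcripts) == 1L)
  classify_all(t, reference, single_exon_frac = single_exon_frac)
}
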