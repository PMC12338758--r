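#' @importFrom data.table data.table setkey setkeyv as.data.table copy setorder
#'   setorderv rbindlist setnames foverlaps := .N .SD fifelse
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "transcript_id", "gene_id", "seqid", "start", "end", "strand",
  "attributes", "type", "line", "attrs", "len", "n_tx", "code",
  "ref_gene_ids", "matched_ref_transcript_id", "busco_id", "status",
  "sequence_id", "score", "length_nt", "category", "padj", "log2fc",
  "base_mean", "pvalue", "neglog10_padj", "direction", "i.start", "i.end",
  "r_gene", "r_tx", "r_strand", "n_exons", "k", "count", "ev_tx", "width",
  "same", "ovw", "ckey", "ikey", "gene", "o_tx", "o_strand", "lineno",
  "h_start", "h_end", "n", "N", "n_seqid", "n_strand", "n_gene", "disjoint",
  "n_genes_complete", "any_frag", "istart", "iend", "chain"
))

#' Construct an annotation set from a flat exon table
#'
#' The central container of the package: a validated set of gene models,
#' each a group of transcript models, each an ordered chain of exons.
#' Coordinates are GTF-style, 1-based and inclusive at both ends.
#'
#' @param exons a data.frame with columns `seqid`, `start`, `end`, `strand`
#'   (`"+"`, `"-"`, or `"."` for unstranded single-exon transcripts),
#'   `gene_id`, `transcript_id`; one row per exon.
#' @param provenance one of `"reference"`, `"evidence"`, `"updated"`.
#' @param gene_attrs optional named list: `gene_id` -> named character vector
#'   of GTF attributes (excluding `gene_id` itself).
#' @param tx_attrs optional named list: `transcript_id` -> named character
#'   vector of GTF attributes (excluding `gene_id`/`transcript_id`).
#' @return an object of class `AnnotationSet` with components `genes`,
#'   `transcripts`, `exons` (data.tables) and `provenance`.
#' @export
annotation_set <- function(exons, provenance = c("reference", "evidence", "updated"),
                           gene_attrs = NULL, tx_attrs = NULL) {
  provenance <- match.arg(provenance)
  ex <- as.data.table(exons)
  required <- c("seqid", "start", "end", "strand", "gene_id", "transcript_id")
  missing_cols <- setdiff(required, names(ex))
  if (length(missing_cols))
    stop("exon table lacks column(s): ", paste(missing_cols, collapse = ", "))
  ex <- ex[, .(seqid = as.character(seqid), start = as.integer(start),
               end = as.integer(end), strand = as.character(strand),
               gene_id = as.character(gene_id),
               transcript_id = as.character(transcript_id))]

  if (nrow(ex) == 0L) {
    return(.new_annotation_set(
      genes = data.table(gene_id = character(), seqid = character(),
                         strand = character(), start = integer(),
                         end = integer(), attributes = list()),
      transcripts = data.table(transcript_id = character(), gene_id = character(),
                               seqid = character(), strand = character(),
                               start = integer(), end = integer(),
                               attributes = list()),
      exons = ex, provenance = provenance))
  }

  if (anyNA(ex$start) || anyNA(ex$end))
    stop("non-integer exon coordinates")
  if (any(ex$start < 1L))
    stop("exon start < 1 (coordinates are 1-based)")
  bad <- which(ex$end < ex$start)
  if (length(bad))
    stop("exon with end < start for transcript ", ex$transcript_id[bad[1L]])
  if (!all(ex$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")

  # per-transcript consistency
  setorder(ex, seqid, gene_id, transcript_id, start)
  tx <- ex[, .(gene_id = gene_id[1L], seqid = seqid[1L], strand = strand[1L],
               start = min(start), end = max(end), n_exons = .N,
               n_seqid = data.table::uniqueN(seqid),
               n_strand = data.table::uniqueN(strand),
               n_gene = data.table::uniqueN(gene_id),
               disjoint = .N == 1L || all(start[-1L] > end[-.N])),
           by = transcript_id]
  if (any(tx$n_seqid > 1L))
    stop("transcript ", tx$transcript_id[which(tx$n_seqid > 1L)[1L]],
         " has exons on multiple sequences")
  if (any(tx$n_strand > 1L))
    stop("transcript ", tx$transcript_id[which(tx$n_strand > 1L)[1L]],
         " has exons on multiple strands")
  if (any(tx$n_gene > 1L))
    stop("duplicate transcript_id under different gene_ids: ",
         tx$transcript_id[which(tx$n_gene > 1L)[1L]])
  if (!all(tx$disjoint))
    stop("transcript ", tx$transcript_id[which(!tx$disjoint)[1L]],
         " has overlapping or unsorted exons")
  if (any(tx$n_exons > 1L & tx$strand == "."))
    stop("multi-exon transcript ",
         tx$transcript_id[which(tx$n_exons > 1L & tx$strand == ".")[1L]],
         " must be stranded ('+' or '-')")

  gn <- tx[, .(seqid = seqid[1L], strand = strand[1L],
               start = min(start), end = max(end),
               n_seqid = data.table::uniqueN(seqid),
               n_strand = data.table::uniqueN(strand)),
           by = gene_id]
  if (any(gn$n_seqid > 1L))
    stop("gene ", gn$gene_id[which(gn$n_seqid > 1L)[1L]],
         " has transcripts on multiple sequences")
  if (any(gn$n_strand > 1L))
    stop("gene ", gn$gene_id[which(gn$n_strand > 1L)[1L]],
         " has transcripts on multiple strands")

  empty_attr <- stats::setNames(character(0), character(0))
  gattr <- lapply(gn$gene_id, function(g) {
    a <- gene_attrs[[g]]
    if (is.null(a)) empty_attr else a
  })
  tattr <- lapply(tx$transcript_id, function(t) {
    a <- tx_attrs[[t]]
    if (is.null(a)) empty_attr else a
  })

  genes <- gn[, .(gene_id, seqid, strand, start, end)]
  data.table::set(genes, j = "attributes", value = list(gattr))
  transcripts <- tx[, .(transcript_id, gene_id, seqid, strand, start, end)]
  data.table::set(transcripts, j = "attributes", value = list(tattr))

  .new_annotation_set(genes, transcripts,
                      ex[, .(seqid, start, end, strand, gene_id, transcript_id)],
                      provenance)
}

.new_annotation_set <- function(genes, transcripts, exons, provenance) {
  setorder(genes, seqid, start, gene_id)
  setorder(transcripts, seqid, start, transcript_id)
  setorder(exons, seqid, gene_id, transcript_id, start)
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 provenance = provenance),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet (%s): %d genes, %d transcripts, %d exons on %d sequence(s)\n",
              x$provenance, nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              data.table::uniqueN(x$exons$seqid)))
  invisible(x)
}

#' Test two annotation sets for equality
#'
#' Field-level equality on genes, transcripts and exons (coordinates,
#' strands, identifiers and attribute maps); provenance is ignored.
#' Canonical ordering makes the comparison independent of construction order.
#'
#' @param a,b `AnnotationSet` objects.
#' @return `TRUE` or `FALSE`.
#' @export
anno_equal <- function(a, b) {
  stopifnot(inherits(a, "AnnotationSet"), inherits(b, "AnnotationSet"))
  cmp_tbl <- function(x, y) {
    if (nrow(x) != nrow(y)) return(FALSE)
    plain <- setdiff(names(x), "attributes")
    if (!identical(as.list(x[, plain, with = FALSE]),
                   as.list(y[, plain, with = FALSE]))) return(FALSE)
    if ("attributes" %in% names(x)) {
      for (i in seq_len(nrow(x)))
        if (!identical(x$attributes[[i]], y$attributes[[i]])) return(FALSE)
    }
    TRUE
  }
  cmp_tbl(a$genes, b$genes) && cmp_tbl(a$transcripts, b$transcripts) &&
    cmp_tbl(a$exons, b$exons)
}

# transcript lengths (sum of exon widths) as a data.table
.tx_lengths <- function(anno) {
  anno$exons[, .(len = sum(end - start + 1L)), by = transcript_id]
}

#' Map transcript IDs to gene IDs
#'
#' @param anno an `AnnotationSet`.
#' @return named character vector, names = transcript IDs, values = gene IDs.
#' @export
tx_to_gene_map <- function(anno) {
  stopifnot(inherits(anno, "AnnotationSet"))
  stats::setNames(anno$transcripts$gene_id, anno$transcripts$transcript_id)
}
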