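# Gene-level reconciliation of transcript-mode BUSCO results. Transcript-mode
# BUSCO flags a gene's isoforms as "Duplicated" hits; collapsing hits through
# a transcript->gene map restores the single-copy interpretation.

BUSCO_STATUSES <- c("Complete", "Duplicated", "Fragmented", "Missing")

#' Parse a BUSCO full_table TSV
#'
#' Accepts the transcriptome-mode `full_table.tsv` dialect: tab-separated
#' columns Busco id, Status, Sequence, Score, Length; `#` comment lines are
#' skipped; Missing rows have no sequence. Multiple rows per BUSCO id are
#' allowed (Duplicated).
#'
#' @param x path to a full_table file, or a character vector of its lines.
#' @return data.table with columns `busco_id`, `status`, `sequence_id`,
#'   `score`, `length_nt` (the latter three `NA` for Missing rows).
#' @export
parse_busco_table <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.table(busco_id = character(0), status = character(0),
                      sequence_id = character(0), score = numeric(0),
                      length_nt = integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(f, i) if (length(f) >= i && nzchar(f[i])) f[i] else NA_character_
  out <- data.table(
    busco_id = vapply(fields, get, "", 1L),
    status = vapply(fields, get, "", 2L),
    sequence_id = vapply(fields, get, "", 3L),
    score = suppressWarnings(as.numeric(vapply(fields, get, "", 4L))),
    length_nt = suppressWarnings(as.integer(vapply(fields, get, "", 5L))))
  bad <- which(!out$status %in% BUSCO_STATUSES)
  if (length(bad))
    stop("unknown BUSCO status '", out$status[bad[1L]], "' for id ",
         out$busco_id[bad[1L]])
  incons <- out[(status == "Missing") != is.na(sequence_id)]
  if (nrow(incons))
    stop("BUSCO id ", incons$busco_id[1L],
         ": Missing rows must lack a sequence and non-Missing rows must have one")
  out
}

#' Percentage of a BUSCO category
#'
#' `100 * count / n_total`, rounded half-up to two decimals, as completeness
#' tables print it.
#'
#' @param count category count (0..n_total).
#' @param n_total size of the BUSCO set (> 0).
#' @return numeric scalar.
#' @export
busco_percent <- function(count, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  stopifnot(count >= 0, count <= n_total)
  round_half_up(100 * count / n_total, 2L)
}

#' Collapse transcript-level BUSCO hits to gene-level completeness
#'
#' For each BUSCO id, its Complete/Duplicated hits are mapped to genes; if
#' they land on one distinct gene the BUSCO is complete-single (isoform-level
#' duplication collapses), on two or more genes complete-duplicated.
#' Complete outranks Fragmented: a BUSCO with any Complete/Duplicated hit is
#' complete regardless of additional Fragmented hits. BUSCOs with only
#' Fragmented hits are fragmented; the rest are missing.
#'
#' @param records data.table from [parse_busco_table()].
#' @param tx_to_gene named character vector mapping transcript IDs to gene
#'   IDs (e.g. [tx_to_gene_map()] of the updated annotation).
#' @return a list of class `busco_gene_summary`: `n_total`, counts
#'   `n_complete_total`, `n_complete_single`, `n_complete_duplicated`,
#'   `n_fragmented`, `n_missing`, matching `pct_*` percentages (2 decimals),
#'   and `categories` (data.table of per-BUSCO gene-level category).
#' @export
reconcile_gene_level <- function(records, tx_to_gene) {
  rec <- as.data.table(records)
  hits <- rec[!is.na(sequence_id)]
  unknown <- setdiff(hits$sequence_id, names(tx_to_gene))
  if (length(unknown))
    stop("BUSCO hit on transcript absent from the annotation: ", unknown[1L])
  hits[, gene := tx_to_gene[sequence_id]]
  per <- rec[, .(any_row = TRUE), by = busco_id]
  cat_of <- hits[, .(
    n_genes_complete = data.table::uniqueN(
      gene[status %in% c("Complete", "Duplicated")]),
    any_frag = any(status == "Fragmented")), by = busco_id]
  per <- merge(per, cat_of, by = "busco_id", all.x = TRUE)
  per[, category := fifelse(
    !is.na(n_genes_complete) & n_genes_complete == 1L, "complete_single",
    fifelse(!is.na(n_genes_complete) & n_genes_complete >= 2L,
            "complete_duplicated",
            fifelse(!is.na(any_frag) & any_frag, "fragmented", "missing")))]
  n_total <- nrow(per)
  if (n_total == 0L) stop("no BUSCO records")
  cnt <- function(x) sum(per$category == x)
  ns <- cnt("complete_single"); nd <- cnt("complete_duplicated")
  nf <- cnt("fragmented"); nm <- cnt("missing")
  structure(list(
    n_total = n_total,
    n_complete_total = ns + nd,
    n_complete_single = ns,
    n_complete_duplicated = nd,
    n_fragmented = nf,
    n_missing = nm,
    pct_complete_total = busco_percent(ns + nd, n_total),
    pct_complete_single = busco_percent(ns, n_total),
    pct_complete_duplicated = busco_percent(nd, n_total),
    pct_fragmented = busco_percent(nf, n_total),
    pct_missing = busco_percent(nm, n_total),
    categories = per[order(busco_id), .(busco_id, category)]
  ), class = "busco_gene_summary")
}

#' @export
print.busco_gene_summary <- function(x, ...) {
  cat(sprintf("Gene-level BUSCO summary (n = %d)\n", x$n_total))
  rows <- rbind(
    c("complete-total", x$n_complete_total, x$pct_complete_total),
    c("complete-single", x$n_complete_single, x$pct_complete_single),
    c("complete-duplicated", x$n_complete_duplicated, x$pct_complete_duplicated),
    c("fragmented", x$n_fragmented, x$pct_fragmented),
    c("missing", x$n_missing, x$pct_missing))
  cat(sprintf("  %-20s %5s  %6s\n", rows[, 1], rows[, 2], rows[, 3]), sep = "")
  invisible(x)
}

#' Gene-level BUSCO summary as a table
#'
#' @param x a `busco_gene_summary`.
#' @return data.table with columns `category`, `count`, `percent`.
#' @export
busco_summary_table <- function(x) {
  stopifnot(inherits(x, "busco_gene_summary"))
  data.table(
    category = c("complete-total", "complete-single", "complete-duplicated",
                 "fragmented", "missing", "total"),
    count = c(x$n_complete_total, x$n_complete_single,
              x$n_complete_duplicated, x$n_fragmented, x$n_missing,
              x$n_total),
    percent = c(x$pct_complete_total, x$pct_complete_single,
                x$pct_complete_duplicated, x$pct_fragmented, x$pct_missing,
                NA_real_))
}
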