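# Threshold-based summaries of differential-expression result tables
# (DESeq2 export dialect). The model fit itself is upstream; this module owns
# the significance thresholds, fold-change binning, multi-timepoint overlap
# algebra, top tables, volcano preparation, and ranked-list export.

#' Read a differential-expression results table
#'
#' Accepts the DESeq2 export dialect: a delimited file with a header carrying
#' (at least) a gene identifier column plus `baseMean`, `log2FoldChange`,
#' `pvalue`, `padj`. The gene column may be named `gene_id`, `gene`, or be
#' the first (possibly unnamed row-name) column.
#'
#' @param path file path (TSV or CSV; separator sniffed by `fread`).
#' @return data.table with columns `gene_id`, `base_mean`, `log2fc`,
#'   `pvalue`, `padj`.
#' @export
read_de_table <- function(path) {
  dt <- data.table::fread(path)
  nm <- names(dt)
  gene_col <- intersect(c("gene_id", "gene", "V1"), nm)[1L]
  if (is.na(gene_col)) gene_col <- nm[1L]
  pick <- function(cands) {
    hit <- nm[tolower(nm) %in% tolower(cands)]
    if (length(hit) == 0L)
      stop("results table lacks a column named one of: ",
           paste(cands, collapse = ", "))
    hit[1L]
  }
  out <- data.table(
    gene_id = as.character(dt[[gene_col]]),
    base_mean = as.numeric(dt[[pick(c("baseMean", "base_mean"))]]),
    log2fc = as.numeric(dt[[pick(c("log2FoldChange", "log2fc"))]]),
    pvalue = as.numeric(dt[[pick("pvalue")]]),
    padj = as.numeric(dt[[pick("padj")]]))
  bad <- out[(!is.na(pvalue) & (pvalue < 0 | pvalue > 1)) |
               (!is.na(padj) & (padj < 0 | padj > 1))]
  if (nrow(bad))
    stop("p-value outside [0, 1] for gene ", bad$gene_id[1L])
  out
}

.as_de <- function(records) {
  dt <- as.data.table(records)
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(dt)))
  dt
}

#' Significant up/down gene sets
#'
#' A gene is upregulated when `padj < padj_max` and `log2fc > lfc_min`,
#' downregulated when `padj < padj_max` and `log2fc < -lfc_min`; both
#' inequalities are strict. Records with missing `padj` are excluded.
#'
#' @param records DE table (see [read_de_table()]).
#' @param padj_max adjusted-p (FDR) cutoff, default 0.1.
#' @param lfc_min absolute log2-fold-change cutoff, default 0.6.
#' @return list with character vectors `up` and `down`.
#' @export
filter_significant <- function(records, padj_max = 0.1, lfc_min = 0.6) {
  dt <- .as_de(records)
  ok <- !is.na(dt$padj) & !is.na(dt$log2fc) & dt$padj < padj_max
  list(up = sort(dt$gene_id[ok & dt$log2fc > lfc_min]),
       down = sort(dt$gene_id[ok & dt$log2fc < -lfc_min]))
}

#' Fold-change bin summary for one timepoint
#'
#' Counts how many significant genes changed 4-fold or more
#' (`|log2fc| >= fold_lfc`, inclusive) and reports the printed-style
#' percentage (integer unless exact at one decimal, e.g. 62.5).
#'
#' @param sig list with `up`/`down` sets from [filter_significant()] over
#'   the same records.
#' @param records the DE table the sets came from.
#' @param day timepoint label carried through to the output.
#' @param fold_lfc log2 fold-change magnitude defining the high-fold bin
#'   (default 2, i.e. 4-fold).
#' @return a list of class `timepoint_summary`: `day`, `up`, `down`,
#'   `up_ge4fold`, `down_ge4fold`, `up_ge4fold_pct`, `down_ge4fold_pct`.
#' @export
fold_bin_summary <- function(sig, records, day = NA, fold_lfc = 2) {
  dt <- .as_de(records)
  stopifnot(length(intersect(sig$up, sig$down)) == 0L)
  lfc <- stats::setNames(dt$log2fc, dt$gene_id)
  up4 <- sum(abs(lfc[sig$up]) >= fold_lfc)
  dn4 <- sum(abs(lfc[sig$down]) >= fold_lfc)
  structure(list(
    day = day, up = sig$up, down = sig$down,
    up_ge4fold = up4, down_ge4fold = dn4,
    up_ge4fold_pct = if (length(sig$up)) fold_percent(up4, length(sig$up)) else 0,
    down_ge4fold_pct = if (length(sig$down)) fold_percent(dn4, length(sig$down)) else 0
  ), class = "timepoint_summary")
}

#' @export
print.timepoint_summary <- function(x, ...) {
  cat(sprintf("Day %s: %d up (%d >= 4-fold, %s%%), %d down (%d >= 4-fold, %s%%)\n",
              x$day, length(x$up), x$up_ge4fold, x$up_ge4fold_pct,
              length(x$down), x$down_ge4fold, x$down_ge4fold_pct))
  invisible(x)
}

.venn3 <- function(a, b, c3) {
  list(
    d1_only = setdiff(a, union(b, c3)),
    d3_only = setdiff(b, union(a, c3)),
    d7_only = setdiff(c3, union(a, b)),
    d1_d3 = setdiff(intersect(a, b), c3),
    d1_d7 = setdiff(intersect(a, c3), b),
    d3_d7 = setdiff(intersect(b, c3), a),
    d1_d3_d7 = intersect(intersect(a, b), c3))
}

#' Three-timepoint overlap (Venn) table
#'
#' Exact set algebra over the up sets and the down sets of three timepoint
#' summaries: the seven disjoint regions of a 3-set Venn partition.
#'
#' @param s1,s3,s7 `timepoint_summary` objects (days 1, 3, 7).
#' @return a data.table with columns `direction` (`up`/`down`), `region`
#'   (`d1_only`, `d3_only`, `d7_only`, `d1_d3`, `d1_d7`, `d3_d7`,
#'   `d1_d3_d7`) and `count`; region members are attached as attribute
#'   `"members"` (a nested list).
#' @export
overlap_sets <- function(s1, s3, s7) {
  up <- .venn3(s1$up, s3$up, s7$up)
  dn <- .venn3(s1$down, s3$down, s7$down)
  out <- rbind(
    data.table(direction = "up", region = names(up),
               count = lengths(up)),
    data.table(direction = "down", region = names(dn),
               count = lengths(dn)))
  attr(out, "members") <- list(up = up, down = dn)
  out
}

#' Top up/down regulated genes after a low-expression filter
#'
#' Among significant genes with `base_mean >= base_mean_min`, the `n`
#' largest log2 fold changes (up list, descending) and the `n` smallest
#' (down list, ascending). Ties break lexicographically by gene id. When an
#' annotation table is supplied, a `description` column is attached;
#' entries whose BLAST E-value exceeds `nss_evalue_max` are labelled
#' `"NSS"` (no significant similarity).
#'
#' @param records DE table.
#' @param sig significant sets from [filter_significant()].
#' @param base_mean_min expression floor (default 70).
#' @param n list length cap (default 10).
#' @param annotation optional data.frame with `gene_id`, `description` and
#'   optionally `evalue`.
#' @param nss_evalue_max E-value above which a hit is labelled NSS
#'   (default 1e-10).
#' @return list of two data.tables, `up` and `down`, with columns
#'   `gene_id`, `base_mean`, `log2fc`, `padj` (+ `description`).
#' @export
top_table <- function(records, sig, base_mean_min = 70, n = 10,
                      annotation = NULL, nss_evalue_max = 1e-10) {
  dt <- .as_de(records)
  stopifnot("base_mean" %in% names(dt))
  keep <- dt[gene_id %in% c(sig$up, sig$down) & !is.na(base_mean) &
               base_mean >= base_mean_min]
  decorate <- function(x) {
    if (is.null(annotation)) return(x)
    an <- as.data.table(annotation)
    desc <- stats::setNames(as.character(an$description), an$gene_id)
    out_desc <- unname(desc[x$gene_id])
    if ("evalue" %in% names(an)) {
      ev <- stats::setNames(as.numeric(an$evalue), an$gene_id)
      nss <- !is.na(ev[x$gene_id]) & ev[x$gene_id] > nss_evalue_max
      out_desc[nss] <- "NSS"
    }
    x$description <- out_desc
    x
  }
  up <- keep[gene_id %in% sig$up][order(-log2fc, gene_id)]
  dn <- keep[gene_id %in% sig$down][order(log2fc, gene_id)]
  list(up = decorate(utils::head(up[, .(gene_id, base_mean, log2fc, padj)], n)),
       down = decorate(utils::head(dn[, .(gene_id, base_mean, log2fc, padj)], n)))
}

#' Volcano-plot preparation table
#'
#' Clamps adjusted p-values below `p_floor` to `p_floor` and assigns each
#' gene one of four plot categories: `significant` (passes both thresholds),
#' `p_only` (padj passes, fold change does not), `fc_only` (fold change
#' passes, padj does not), `ns` (neither). Records with missing `padj` are
#' dropped.
#'
#' @param records DE table.
#' @param padj_max,lfc_min thresholds as in [filter_significant()].
#' @param p_floor smallest representable adjusted p (default 1e-10).
#' @return data.table with `gene_id`, `log2fc`, `neglog10_padj`, `category`.
#' @export
volcano_prep <- function(records, padj_max = 0.1, lfc_min = 0.6,
                         p_floor = 1e-10) {
  dt <- .as_de(records)[!is.na(padj) & !is.na(log2fc)]
  dt[, neglog10_padj := -log10(pmax(padj, p_floor))]
  p_ok <- dt$padj < padj_max
  fc_ok <- abs(dt$log2fc) > lfc_min
  dt[, category := fifelse(p_ok & fc_ok, "significant",
                           fifelse(p_ok, "p_only",
                                   fifelse(fc_ok, "fc_only", "ns")))]
  dt[, .(gene_id, log2fc, neglog10_padj, category)]
}

#' Ranked-list export for enrichment analysis
#'
#' Two-column (gene id, log2 fold change) ranked list restricted to genes
#' with `base_mean >= base_mean_min`, sorted by fold change descending with
#' lexicographic gene-id tie-break — the shape ranked-list enrichment tools
#' ingest.
#'
#' @param records DE table.
#' @param base_mean_min expression floor (default 100).
#' @param file optional path; when given, a headerless TSV is written.
#' @return data.table with `gene_id`, `log2fc` (invisibly when `file`
#'   given).
#' @export
ranked_export <- function(records, base_mean_min = 100, file = NULL) {
  dt <- .as_de(records)
  stopifnot("base_mean" %in% names(dt))
  out <- dt[!is.na(base_mean) & base_mean >= base_mean_min &
              !is.na(log2fc)][order(-log2fc, gene_id),
                              .(gene_id, log2fc)]
  if (!is.null(file)) {
    data.table::fwrite(out, file, sep = "\t", col.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Split direction-tagged enrichment rows into up and down lists
#'
#' Rows tagged `"both"` are duplicated into both outputs; row order is
#' preserved.
#'
#' @param rows data.frame with a `direction` column in
#'   `{"up", "down", "both"}`.
#' @return list of two data.tables, `up` (= up + both rows) and `down`
#'   (= down + both rows).
#' @export
split_enrichment_directions <- function(rows) {
  dt <- as.data.table(rows)
  stopifnot("direction" %in% names(dt))
  bad <- setdiff(unique(dt$direction), c("up", "down", "both"))
  if (length(bad))
    stop("unknown direction label: ", bad[1L])
  list(up = dt[direction %in% c("up", "both")],
       down = dt[direction %in% c("down", "both")])
}
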