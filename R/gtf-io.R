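# GTF reading/writing. Dialect: GTF2.2 attributes (key "value"; ...), 1-based
# inclusive coordinates. Exon lines are authoritative; gene/transcript header
# lines are optional metadata whose extents must agree with the exon-derived
# extents.

.extract_attr <- function(s, key) {
  hit <- regexpr(paste0("(?<=", key, " \")[^\"]*"), s, perl = TRUE)
  out <- rep(NA_character_, length(s))
  out[hit > 0L] <- regmatches(s, hit)
  out
}

.parse_attr_map <- function(s) {
  # named character vector in source order
  mm <- regmatches(s, gregexpr('([A-Za-z][A-Za-z0-9_.-]*)\\s+"([^"]*)"', s))[[1L]]
  if (length(mm) == 0L) return(stats::setNames(character(0), character(0)))
  keys <- sub('^([A-Za-z][A-Za-z0-9_.-]*)\\s+".*$', "\\1", mm)
  vals <- sub('^[A-Za-z][A-Za-z0-9_.-]*\\s+"([^"]*)".*$', "\\1", mm)
  stats::setNames(vals, keys)
}

.strip_ids <- function(a) a[setdiff(names(a), c("gene_id", "transcript_id"))]

#' Parse GTF text into an annotation set
#'
#' @param lines character vector of GTF lines (as from [readLines()]).
#'   Comment lines (`#`) and blank lines are skipped.
#' @param provenance provenance label for the resulting set.
#' @return an [annotation_set()] object.
#' @details Gene models are assembled from `exon` features, whose attribute
#'   column must carry `gene_id` and `transcript_id`. Optional `gene` and
#'   `transcript` features contribute attributes and are checked for extent
#'   agreement with the exon-derived models. Other feature types (CDS, UTR,
#'   ...) are ignored.
#' @export
parse_gtf <- function(lines, provenance = c("reference", "evidence", "updated")) {
  provenance <- match.arg(provenance)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L)
    return(annotation_set(
      data.frame(seqid = character(), start = integer(), end = integer(),
                 strand = character(), gene_id = character(),
                 transcript_id = character()),
      provenance = provenance))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GTF line ", lineno[which(nf != 9L)[1L]],
         ": expected 9 tab-separated columns, found ", nf[which(nf != 9L)[1L]])
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end))
    stop("malformed GTF line ", lineno[which(is.na(start) | is.na(end))[1L]],
         ": non-integer coordinates")
  feat <- data.table(lineno = lineno, seqid = m[, 1L], type = m[, 3L],
                     start = start, end = end, strand = m[, 7L],
                     attrs = m[, 9L])
  bad <- which(feat$end < feat$start)
  if (length(bad))
    stop("GTF line ", feat$lineno[bad[1L]], ": end < start")

  ex <- feat[type == "exon"]
  if (nrow(ex)) {
    ex[, gene_id := .extract_attr(attrs, "gene_id")]
    ex[, transcript_id := .extract_attr(attrs, "transcript_id")]
    if (anyNA(ex$gene_id) || anyNA(ex$transcript_id))
      stop("GTF line ", ex$lineno[which(is.na(ex$gene_id) | is.na(ex$transcript_id))[1L]],
           ": exon feature lacks gene_id or transcript_id attribute")
  } else {
    ex[, `:=`(gene_id = character(0), transcript_id = character(0))]
  }

  # transcript attributes: transcript header line wins, else first exon line
  tx_attrs <- list()
  first_ex <- ex[!duplicated(transcript_id)]
  for (i in seq_len(nrow(first_ex)))
    tx_attrs[[first_ex$transcript_id[i]]] <- .strip_ids(.parse_attr_map(first_ex$attrs[i]))

  txh <- feat[type == "transcript"]
  for (i in seq_len(nrow(txh))) {
    tid <- .extract_attr(txh$attrs[i], "transcript_id")
    if (is.na(tid))
      stop("GTF line ", txh$lineno[i], ": transcript feature lacks transcript_id")
    tx_attrs[[tid]] <- .strip_ids(.parse_attr_map(txh$attrs[i]))
  }

  gene_attrs <- list()
  gh <- feat[type == "gene"]
  for (i in seq_len(nrow(gh))) {
    gid <- .extract_attr(gh$attrs[i], "gene_id")
    if (is.na(gid))
      stop("GTF line ", gh$lineno[i], ": gene feature lacks gene_id")
    gene_attrs[[gid]] <- .strip_ids(.parse_attr_map(gh$attrs[i]))
  }

  anno <- annotation_set(
    ex[, .(seqid, start, end, strand, gene_id, transcript_id)],
    provenance = provenance, gene_attrs = gene_attrs, tx_attrs = tx_attrs)

  # header/extent agreement
  if (nrow(gh)) {
    gh[, gene_id := .extract_attr(attrs, "gene_id")]
    chk <- merge(gh[, .(gene_id, h_start = start, h_end = end)],
                 anno$genes[, .(gene_id, start, end)], by = "gene_id")
    if (nrow(chk) < nrow(gh)) {
      orphan <- setdiff(gh$gene_id, anno$genes$gene_id)
      stop("gene feature '", orphan[1L], "' has no exon features")
    }
    off <- chk[h_start != start | h_end != end]
    if (nrow(off))
      stop("gene feature '", off$gene_id[1L],
           "' extent disagrees with its exons")
  }
  if (nrow(txh)) {
    txh[, transcript_id := .extract_attr(attrs, "transcript_id")]
    chk <- merge(txh[, .(transcript_id, h_start = start, h_end = end)],
                 anno$transcripts[, .(transcript_id, start, end)],
                 by = "transcript_id")
    if (nrow(chk) < nrow(txh)) {
      orphan <- setdiff(txh$transcript_id, anno$transcripts$transcript_id)
      stop("transcript feature '", orphan[1L], "' has no exon features")
    }
    off <- chk[h_start != start | h_end != end]
    if (nrow(off))
      stop("transcript feature '", off$transcript_id[1L],
           "' extent disagrees with its exons")
  }
  anno
}

#' Read a GTF file
#'
#' @param path path to a GTF file.
#' @inheritParams parse_gtf
#' @return an [annotation_set()].
#' @export
read_gtf <- function(path, provenance = c("reference", "evidence", "updated")) {
  parse_gtf(readLines(path), provenance = match.arg(provenance))
}

.fmt_attrs <- function(ids, extra) {
  base <- paste0(names(ids), " \"", unname(ids), "\";", collapse = " ")
  if (length(extra) == 0L) return(base)
  paste(base, paste0(names(extra), " \"", unname(extra), "\";", collapse = " "))
}

#' Write an annotation set as GTF text
#'
#' Emits `gene`, `transcript` and `exon` features in canonical order
#' (sequence, then start coordinate); output is deterministic, so the same
#' set always produces byte-identical text, and `parse_gtf(write_gtf(x))`
#' reconstructs an equal set.
#'
#' @param anno an `AnnotationSet`.
#' @param file optional path; when given, lines are written there.
#' @param source_label value for the GTF source column.
#' @return character vector of GTF lines (invisibly when `file` is given).
#' @export
write_gtf <- function(anno, file = NULL, source_label = "annotweave") {
  stopifnot(inherits(anno, "AnnotationSet"))
  out <- character(0)
  gl <- anno$genes
  tl <- anno$transcripts
  el <- anno$exons
  for (i in seq_len(nrow(gl))) {
    g <- gl[i]
    out <- c(out, paste(g$seqid, source_label, "gene", g$start, g$end, ".",
                        g$strand, ".",
                        .fmt_attrs(c(gene_id = g$gene_id), g$attributes[[1L]]),
                        sep = "\t"))
    gtx <- tl[gene_id == g$gene_id]
    for (j in seq_len(nrow(gtx))) {
      t <- gtx[j]
      ta <- t$attributes[[1L]]
      ids <- c(gene_id = g$gene_id, transcript_id = t$transcript_id)
      out <- c(out, paste(t$seqid, source_label, "transcript", t$start, t$end,
                          ".", t$strand, ".", .fmt_attrs(ids, ta), sep = "\t"))
      tex <- el[transcript_id == t$transcript_id]
      for (kk in seq_len(nrow(tex))) {
        e <- tex[kk]
        out <- c(out, paste(e$seqid, source_label, "exon", e$start, e$end, ".",
                            e$strand, ".", .fmt_attrs(ids, ta), sep = "\t"))
      }
    }
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Assembly summary statistics
#'
#' Counts and transcript-length statistics of an annotation set. Transcript
#' length is exonic length (the sum of exon widths), not genomic span.
#' The transcripts-per-gene mean is reported to one decimal and length means
#' to the nearest nucleotide, rounding half-up.
#'
#' @param anno a non-empty `AnnotationSet`.
#' @return a list of class `assembly_stats` with fields `n_genes`,
#'   `n_transcripts`, `mean_tx_per_gene`, `max_tx_per_gene`,
#'   `mean_tx_length`, `median_tx_length`, `max_tx_length`.
#' @export
summarize_annotation <- function(anno) {
  stopifnot(inherits(anno, "AnnotationSet"))
  if (nrow(anno$genes) == 0L)
    stop("cannot summarize an empty annotation set")
  lens <- .tx_lengths(anno)$len
  txpg <- anno$transcripts[, .N, by = gene_id]$N
  structure(list(
    n_genes = nrow(anno$genes),
    n_transcripts = nrow(anno$transcripts),
    mean_tx_per_gene = round_half_up(nrow(anno$transcripts) / nrow(anno$genes), 1L),
    max_tx_per_gene = max(txpg),
    mean_tx_length = as.integer(round_half_up(mean(lens), 0L)),
    median_tx_length = as.integer(round_half_up(stats::median(lens), 0L)),
    max_tx_length = max(lens)
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("Genes: %s\nTranscripts: %s\nAverage transcripts per gene: %.1f\n",
              format(x$n_genes, big.mark = ","),
              format(x$n_transcripts, big.mark = ","), x$mean_tx_per_gene))
  cat(sprintf("Max transcripts per gene: %d\n", x$max_tx_per_gene))
  cat(sprintf("Average transcript length: %s\nMedian transcript length: %s\nMax transcript length: %s\n",
              format(x$mean_tx_length, big.mark = ","),
              format(x$median_tx_length, big.mark = ","),
              format(x$max_tx_length, big.mark = ",")))
  invisible(x)
}
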