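# Exhaustive pairwise classification oracle: enumerates every
# (evidence transcript, reference transcript) pair with plain base-R loops,
# no interval index, no shared code with the package's classifier.

oracle_introns <- function(df) {
  df <- df[order(df$start), , drop = FALSE]
  n <- nrow(df)
  if (n < 2L) return(NULL)
  cbind(df$end[-n] + 1L, df$start[-1L] - 1L)
}

oracle_classify <- function(evidence, reference, single_exon_frac = 0.8) {
  rex <- as.data.frame(reference$exons)
  ref_by_tx <- split(rex, rex$transcript_id)
  gene_of <- setNames(reference$transcripts$gene_id,
                      reference$transcripts$transcript_id)
  gene_order <- reference$genes$gene_id
  eex <- as.data.frame(evidence$exons)
  ev_by_tx <- split(eex, eex$transcript_id)

  out <- list()
  for (tid in evidence$transcripts$transcript_id) {
    te <- ev_by_tx[[tid]]
    te <- te[order(te$start), , drop = FALSE]
    tlen <- sum(te$end - te$start + 1L)
    ti <- oracle_introns(te)

    same_genes <- character(0); opp_genes <- character(0)
    exact_multi <- character(0); exact_single <- character(0)
    shared_genes <- character(0); contained <- FALSE

    for (rtid in names(ref_by_tx)) {
      re <- ref_by_tx[[rtid]]
      re <- re[order(re$start), , drop = FALSE]
      if (re$seqid[1L] != te$seqid[1L]) next
      ovb <- 0L
      for (i in seq_len(nrow(te)))
        for (j in seq_len(nrow(re)))
          ovb <- ovb + max(0L, min(te$end[i], re$end[j]) -
                             max(te$start[i], re$start[j]) + 1L)
      if (ovb == 0L) next
      g <- unname(gene_of[rtid])
      if (!(te$strand[1L] == "." || te$strand[1L] == re$strand[1L])) {
        opp_genes <- union(opp_genes, g)
        next
      }
      same_genes <- union(same_genes, g)
      ri <- oracle_introns(re)
      if (!is.null(ti) && !is.null(ri)) {
        n_shared <- 0L
        for (i in seq_len(nrow(ti)))
          if (any(ri[, 1L] == ti[i, 1L] & ri[, 2L] == ti[i, 2L]))
            n_shared <- n_shared + 1L
        if (n_shared > 0L) shared_genes <- union(shared_genes, g)
        if (nrow(ti) == nrow(ri) && all(ti == ri))
          exact_multi <- c(exact_multi, rtid)
        if (nrow(ti) < nrow(ri)) {
          for (off in 0:(nrow(ri) - nrow(ti)))
            if (all(ri[(off + 1L):(off + nrow(ti)), , drop = FALSE] == ti))
              contained <- TRUE
        }
      }
      if (is.null(ti)) {
        if (is.null(ri)) {
          rlen <- sum(re$end - re$start + 1L)
          if (ovb / tlen >= single_exon_frac && ovb / rlen >= single_exon_frac)
            exact_single <- c(exact_single, rtid)
        }
        if (any(re$start <= te$start[1L] & te$end[1L] <= re$end))
          contained <- TRUE
      }
    }

    ord <- function(g) g[order(match(g, gene_order), g)]
    if (!is.null(ti) && length(exact_multi)) {
      m <- sort(exact_multi)[1L]
      row <- list(code = "EXACT", genes = unname(gene_of[m]), matched = m)
    } else if (is.null(ti) && length(exact_single)) {
      m <- sort(exact_single)[1L]
      row <- list(code = "EXACT", genes = unname(gene_of[m]), matched = m)
    } else if (length(same_genes) >= 2L) {
      row <- list(code = "SPANS_MULTIPLE", genes = ord(same_genes),
                  matched = NA_character_)
    } else if (!is.null(ti) && length(shared_genes) == 1L) {
      row <- list(code = "NOVEL_ISOFORM",
                  genes = ord(union(same_genes, shared_genes)),
                  matched = NA_character_)
    } else if (contained) {
      row <- list(code = "CONTAINED", genes = ord(same_genes),
                  matched = NA_character_)
    } else if (length(same_genes) == 1L) {
      row <- list(code = "EXONIC_OVERLAP_ONLY", genes = same_genes,
                  matched = NA_character_)
    } else if (length(opp_genes)) {
      row <- list(code = "OPPOSITE_STRAND", genes = ord(opp_genes),
                  matched = NA_character_)
    } else {
      row <- list(code = "INTERGENIC", genes = character(0),
                  matched = NA_character_)
    }
    out[[tid]] <- row
  }
  out
}

expect_matches_oracle <- function(evidence, reference) {
  got <- classify_all(evidence, reference)
  want <- oracle_classify(evidence, reference)
  for (i in seq_len(nrow(got))) {
    tid <- got$transcript_id[i]
    expect_identical(got$code[i], want[[tid]]$code, label = paste("code of", tid))
    expect_identical(got$ref_gene_ids[[i]], want[[tid]]$genes,
                     label = paste("genes of", tid))
    expect_identical(got$matched_ref_transcript_id[i], want[[tid]]$matched,
                     label = paste("match of", tid))
  }
  invisible(got)
}
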