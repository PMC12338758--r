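# Evidence-driven annotation update: turn per-transcript class codes into an
# update plan (isoform additions, union-find gene merges, novel genes), apply
# it to the reference, and account for what was done.

#' Configuration for planning an annotation update
#'
#' @param min_novel_single_exon_len minimum exonic length (nt) for a
#'   single-exon intergenic transcript to seed a novel gene; shorter
#'   fragments are discarded (default 200).
#' @param id_prefix prefix for newly assigned gene identifiers.
#' @param id_offset first counter value for new gene identifiers.
#' @param id_width zero-padded width of the numeric part.
#' @return a list of class `update_config`.
#' @export
update_config <- function(min_novel_single_exon_len = 200L,
                          id_prefix = "GBIG_", id_offset = 0L,
                          id_width = 6L) {
  stopifnot(min_novel_single_exon_len >= 0L, id_offset >= 0L, id_width >= 1L)
  structure(list(min_novel_single_exon_len = as.integer(min_novel_single_exon_len),
                 id_prefix = id_prefix, id_offset = as.integer(id_offset),
                 id_width = as.integer(id_width)),
            class = "update_config")
}

#' Format a new gene identifier from a counter value
#'
#' Identifiers are the prefix plus a zero-padded sequential integer, e.g.
#' counter 14732 gives `"GBIG_014732"` at the default width of 6.
#'
#' @param counter non-negative integer counter value(s).
#' @param prefix identifier prefix.
#' @param width zero-padded digit width; counters needing more digits are an
#'   error (counter exhaustion).
#' @return character vector of identifiers.
#' @export
format_gene_id <- function(counter, prefix = "GBIG_", width = 6L) {
  counter <- as.integer(counter)
  stopifnot(all(counter >= 0L))
  if (any(counter > 10^width - 1L))
    stop("gene id counter exhausted (> ", 10^width - 1L, ")")
  sprintf("%s%0*d", prefix, width, counter)
}

# Sequential id generator that never emits an id already in `reserved`.
.id_generator <- function(reserved, config) {
  counter <- config$id_offset
  function() {
    repeat {
      id <- format_gene_id(counter, config$id_prefix, config$id_width)
      counter <<- counter + 1L
      if (!id %in% reserved) return(id)
    }
  }
}

.action <- function(kind, evidence_transcript_ids, target_gene_ids,
                    new_gene_id = NA_character_) {
  list(kind = kind, evidence_transcript_ids = evidence_transcript_ids,
       target_gene_ids = target_gene_ids, new_gene_id = new_gene_id)
}

# Canonical action order: genomic position of the action's anchor
# (first target gene, or first evidence transcript for novel genes).
.sort_actions <- function(actions, reference, evidence) {
  if (length(actions) == 0L) return(actions)
  gpos <- reference$genes
  tpos <- evidence$transcripts
  keyf <- function(a) {
    if (a$kind == "NEW_GENE") {
      p <- tpos[transcript_id %in% a$evidence_transcript_ids]
    } else {
      p <- gpos[gene_id %in% a$target_gene_ids]
    }
    list(seqid = min(p$seqid), start = min(p$start))
  }
  ks <- lapply(actions, keyf)
  kinds <- vapply(actions, `[[`, "", "kind")
  ord <- order(vapply(ks, `[[`, "", "seqid"),
               vapply(ks, function(k) k$start, 0),
               match(kinds, c("MERGE", "ADD_ISOFORM", "NEW_GENE")))
  actions[ord]
}

#' Plan an annotation update from comparison results
#'
#' Translates class codes into actions:
#' * `NOVEL_ISOFORM` transcripts become `ADD_ISOFORM` actions (one per
#'   target gene, all its new isoforms grouped);
#' * `SPANS_MULTIPLE` transcripts induce edges between the reference genes
#'   they touch; connected components of that graph (union-find) become
#'   `MERGE` actions, so chained evidence joins k genes even when no single
#'   transcript spans all k;
#' * `INTERGENIC` transcripts (after dropping single-exon fragments shorter
#'   than `config$min_novel_single_exon_len`) are clustered by mutual
#'   same-strand exonic overlap; each cluster becomes one `NEW_GENE` action;
#' * `EXACT`, `CONTAINED`, `EXONIC_OVERLAP_ONLY` and `OPPOSITE_STRAND`
#'   transcripts are discarded (counted, not instantiated). Under this
#'   ladder a `CONTAINED` result carries no intron absent from its gene, so
#'   it adds no structure worth a new isoform.
#'
#' New gene identifiers are assigned here, sequentially in genomic order of
#' the actions, skipping any identifier already present in the reference.
#'
#' @param comparisons result of [classify_all()] against `reference`.
#' @param reference the reference `AnnotationSet`.
#' @param evidence the evidence `AnnotationSet` the comparisons were made
#'   from (needed for intergenic clustering and length filters).
#' @param config an [update_config()].
#' @return a list of class `UpdatePlan` with `actions`, `id_counter_start`,
#'   and `discarded` (evidence transcript IDs dropped by the plan).
#' @export
plan_updates <- function(comparisons, reference, evidence,
                         config = update_config()) {
  stopifnot(inherits(reference, "AnnotationSet"),
            inherits(evidence, "AnnotationSet"),
            inherits(config, "update_config"))
  cmp <- as.data.table(comparisons)
  touched <- unique(unlist(cmp$ref_gene_ids))
  unknown <- setdiff(touched, reference$genes$gene_id)
  if (length(unknown))
    stop("comparison references gene(s) absent from the reference: ",
         paste(utils::head(unknown, 3L), collapse = ", "))

  discarded <- cmp[code %in% c("EXACT", "EXONIC_OVERLAP_ONLY",
                               "OPPOSITE_STRAND", "CONTAINED"),
                   transcript_id]

  # isoform additions, grouped by target gene
  iso <- cmp[code == "NOVEL_ISOFORM"]
  iso_actions <- list()
  if (nrow(iso)) {
    iso[, gene := vapply(ref_gene_ids, function(g) g[[1L]], "")]
    by_gene <- split(iso$transcript_id, iso$gene)
    iso_actions <- unname(Map(function(g, tx) .action("ADD_ISOFORM", sort(tx), g),
                              names(by_gene), by_gene))
  }

  # merges: union-find closure over spanned gene sets
  spans <- cmp[code == "SPANS_MULTIPLE"]
  merge_actions <- list()
  if (nrow(spans)) {
    uf <- uf_new()
    for (gs in spans$ref_gene_ids) {
      for (j in seq_along(gs)[-1L]) uf_union(uf, gs[[1L]], gs[[j]])
    }
    comps <- uf_components(uf, unique(unlist(spans$ref_gene_ids)))
    comps <- Filter(function(cmp_g) length(cmp_g) >= 2L, comps)
    # evidence transcripts attach to the component holding their genes
    root_of <- function(g) uf_find(uf, g)
    comp_key <- vapply(comps, function(g) root_of(g[[1L]]), "")
    tx_root <- vapply(spans$ref_gene_ids, function(g) root_of(g[[1L]]), "")
    gstart <- stats::setNames(reference$genes$start, reference$genes$gene_id)
    merge_actions <- lapply(seq_along(comps), function(i) {
      genes <- comps[[i]]
      genes <- genes[order(gstart[genes], genes)]
      .action("MERGE", sort(spans$transcript_id[tx_root == comp_key[i]]),
              genes)
    })
  }

  # novel genes: cluster surviving intergenic transcripts by exonic overlap
  inter <- cmp[code == "INTERGENIC", transcript_id]
  if (length(inter)) {
    lens <- .tx_lengths(evidence)
    nex <- evidence$exons[, .(n = .N), by = transcript_id]
    info <- merge(merge(lens, nex, by = "transcript_id"),
                  evidence$transcripts[, .(transcript_id)],
                  by = "transcript_id")
    short <- info[transcript_id %in% inter & n == 1L &
                    len < config$min_novel_single_exon_len, transcript_id]
    discarded <- c(discarded, short)
    inter <- setdiff(inter, short)
  }
  novel_actions <- list()
  if (length(inter)) {
    iex <- evidence$exons[transcript_id %in% inter,
                          .(seqid, start, end, strand, transcript_id)]
    iy <- copy(iex)
    setnames(iy, c("strand", "transcript_id"), c("o_strand", "o_tx"))
    setkey(iy, seqid, start, end)
    pair <- foverlaps(iex, iy, by.x = c("seqid", "start", "end"),
                      nomatch = NULL)
    pair <- pair[transcript_id != o_tx &
                   (strand == "." | o_strand == "." | strand == o_strand)]
    uf <- uf_new()
    for (t in inter) uf_find(uf, t)
    if (nrow(pair))
      for (i in seq_len(nrow(pair)))
        uf_union(uf, pair$transcript_id[i], pair$o_tx[i])
    clusters <- uf_components(uf, inter)
    novel_actions <- lapply(clusters,
                            function(tx) .action("NEW_GENE", sort(tx),
                                                 character(0)))
  }

  actions <- .sort_actions(c(merge_actions, iso_actions, novel_actions),
                           reference, evidence)
  nextid <- .id_generator(reference$genes$gene_id, config)
  actions <- lapply(actions, function(a) {
    if (a$kind %in% c("MERGE", "NEW_GENE")) a$new_gene_id <- nextid()
    a
  })

  # plan invariants
  mg <- unlist(lapply(actions, function(a)
    if (a$kind == "MERGE") a$target_gene_ids else character(0)))
  if (anyDuplicated(mg))
    stop("internal error: a reference gene appears in two MERGE actions")
  alltx <- unlist(lapply(actions, `[[`, "evidence_transcript_ids"))
  if (anyDuplicated(alltx) || length(intersect(alltx, discarded)))
    stop("internal error: an evidence transcript appears in two actions")

  structure(list(actions = actions, id_counter_start = config$id_offset,
                 discarded = sort(unique(discarded)), config = config),
            class = "UpdatePlan")
}

#' @export
print.UpdatePlan <- function(x, ...) {
  kinds <- vapply(x$actions, `[[`, "", "kind")
  cat(sprintf("UpdatePlan: %d ADD_ISOFORM, %d MERGE, %d NEW_GENE, %d discarded\n",
              sum(kinds == "ADD_ISOFORM"), sum(kinds == "MERGE"),
              sum(kinds == "NEW_GENE"), length(x$discarded)))
  invisible(x)
}

# next free <gene_id>.tN name
.next_iso_name <- function(gene_id, n_existing, used) {
  n <- n_existing + 1L
  repeat {
    nm <- paste0(gene_id, ".t", n)
    if (!nm %in% used) return(nm)
    n <- n + 1L
  }
}

#' Apply an update plan to the reference annotation
#'
#' * `ADD_ISOFORM`: the evidence transcript is inserted into the reference
#'   gene and renamed `<gene_id>.tN` (next free index); the gene's identity
#'   and attributes are untouched.
#' * `MERGE`: one new gene (the plan's `new_gene_id`) absorbs all
#'   transcripts of the merged reference genes, with their transcript IDs
#'   retained verbatim; the joining evidence transcripts come in as new
#'   isoforms. Merged genes' annotation text is concatenated per attribute
#'   key, `";"`-joined in ascending order of subunit gene start.
#' * `NEW_GENE`: a new gene with the clustered transcripts as
#'   `<new_gene_id>.tN`.
#'
#' Reference genes not named by any action pass through unchanged,
#' attributes byte-identical.
#'
#' @param reference,evidence `AnnotationSet` objects the plan was built from.
#' @param plan an `UpdatePlan` from [plan_updates()].
#' @return a list with `annotation` (the updated `AnnotationSet`) and
#'   `report` (an `UpdateReport`; see [merge_distribution_table()]).
#' @export
apply_updates <- function(reference, evidence, plan) {
  stopifnot(inherits(plan, "UpdatePlan"))
  ref_ex <- copy(reference$exons)
  gene_attrs <- stats::setNames(reference$genes$attributes,
                                reference$genes$gene_id)
  tx_attrs <- stats::setNames(reference$transcripts$attributes,
                              reference$transcripts$transcript_id)
  gstart <- stats::setNames(reference$genes$start, reference$genes$gene_id)
  ev_ex <- evidence$exons
  ev_tx_attrs <- stats::setNames(evidence$transcripts$attributes,
                                 evidence$transcripts$transcript_id)
  ev_order <- evidence$transcripts$transcript_id  # canonical genomic order

  used_tx <- c(reference$transcripts$transcript_id,
               character(0))
  out_ex <- list(ref_ex)
  n_added_by_gene <- integer(0)

  new_ids <- vapply(plan$actions, function(a) a$new_gene_id %||% NA_character_,
                    "")
  new_ids <- new_ids[!is.na(new_ids)]
  clash <- intersect(new_ids, reference$genes$gene_id)
  if (length(clash))
    stop("new gene id collides with an existing gene: ", clash[1L])
  if (anyDuplicated(new_ids))
    stop("duplicate new gene id in plan")

  ren_ev <- function(tx_ids, gid, n_existing) {
    # returns data.table of renamed evidence exon rows; updates used_tx and
    # tx_attrs in the enclosing frame
    tx_ids <- tx_ids[order(match(tx_ids, ev_order))]
    rows <- list()
    for (tid in tx_ids) {
      nm <- .next_iso_name(gid, n_existing, used_tx)
      n_existing <- n_existing + 1L
      used_tx <<- c(used_tx, nm)
      tx_attrs[[nm]] <<- ev_tx_attrs[[tid]]
      e <- ev_ex[transcript_id == tid]
      rows[[length(rows) + 1L]] <-
        data.table(seqid = e$seqid, start = e$start, end = e$end,
                   strand = e$strand, gene_id = gid, transcript_id = nm)
    }
    rbindlist(rows)
  }

  merge_sizes <- integer(0)
  iso_per_gene <- integer(0)
  gene_remap <- character(0)  # merged subunit gene_id -> new gene_id

  for (a in plan$actions) {
    if (a$kind == "ADD_ISOFORM") {
      g <- a$target_gene_ids
      n_exist <- nrow(reference$transcripts[gene_id == g])
      out_ex[[length(out_ex) + 1L]] <-
        ren_ev(a$evidence_transcript_ids, g, n_exist)
      iso_per_gene[g] <- length(a$evidence_transcript_ids)
    } else if (a$kind == "MERGE") {
      G <- a$new_gene_id
      subs <- a$target_gene_ids
      merge_sizes <- c(merge_sizes, length(subs))
      gene_remap[subs] <- G
      n_exist <- nrow(reference$transcripts[gene_id %in% subs])
      out_ex[[length(out_ex) + 1L]] <-
        ren_ev(a$evidence_transcript_ids, G, n_exist)
      # concatenate annotation text in ascending subunit start order
      subs_ord <- subs[order(gstart[subs], subs)]
      keys <- unique(unlist(lapply(subs_ord, function(s) names(gene_attrs[[s]]))))
      merged <- vapply(keys, function(k) {
        vals <- unlist(lapply(subs_ord, function(s) gene_attrs[[s]][k]))
        paste(vals[!is.na(vals)], collapse = ";")
      }, "")
      gene_attrs[subs] <- NULL
      gene_attrs[[G]] <- stats::setNames(merged, keys)
    } else { # NEW_GENE
      G <- a$new_gene_id
      out_ex[[length(out_ex) + 1L]] <- ren_ev(a$evidence_transcript_ids, G, 0L)
      gene_attrs[[G]] <- stats::setNames(character(0), character(0))
    }
  }

  all_ex <- rbindlist(out_ex)
  if (length(gene_remap)) {
    hit <- all_ex$gene_id %in% names(gene_remap)
    all_ex[hit, gene_id := gene_remap[gene_id]]
  }
  updated <- annotation_set(all_ex, provenance = "updated",
                            gene_attrs = gene_attrs, tx_attrs = tx_attrs)

  md <- table(merge_sizes)
  merge_distribution <- stats::setNames(as.integer(md),
                                        names(md))
  report <- structure(list(
    n_isoforms_added = sum(iso_per_gene),
    n_genes_gaining_isoforms = length(iso_per_gene),
    max_isoforms_added_to_one_gene =
      if (length(iso_per_gene)) max(iso_per_gene) else 0L,
    merge_distribution = merge_distribution,
    n_novel_genes = sum(vapply(plan$actions, `[[`, "", "kind") == "NEW_GENE"),
    n_discarded = length(plan$discarded)
  ), class = "UpdateReport")

  list(annotation = updated, report = report)
}

#' @export
print.UpdateReport <- function(x, ...) {
  cat(sprintf("UpdateReport: %d isoforms added to %d genes (max %d/gene); %d merges; %d novel genes; %d discarded\n",
              x$n_isoforms_added, x$n_genes_gaining_isoforms,
              x$max_isoforms_added_to_one_gene,
              sum(x$merge_distribution), x$n_novel_genes, x$n_discarded))
  invisible(x)
}

#' Merge-size distribution table
#'
#' Tabulates how many merge instances joined k reference gene neighbors,
#' with a final total row.
#'
#' @param x an `UpdateReport`, or a named vector/list mapping k (as names)
#'   to instance counts.
#' @return a data.table with columns `k` (character; final row `"total"`)
#'   and `count`, sorted ascending by k.
#' @export
merge_distribution_table <- function(x) {
  dist <- if (inherits(x, "UpdateReport")) x$merge_distribution else unlist(x)
  if (length(dist) == 0L)
    return(data.table(k = "total", count = 0L))
  ks <- as.integer(names(dist))
  stopifnot(!anyNA(ks), all(ks >= 2L))
  ord <- order(ks)
  data.table(k = c(as.character(ks[ord]), "total"),
             count = c(as.integer(dist[ord]), sum(as.integer(dist))))
}

#' Write an update report as JSON
#'
#' @param report an `UpdateReport` from [apply_updates()].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_update_report <- function(report, file) {
  stopifnot(inherits(report, "UpdateReport"))
  x <- unclass(report)
  x$merge_distribution <- as.list(x$merge_distribution)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Run the full update pipeline
#'
#' Classify evidence transcripts, plan the update, and apply it.
#'
#' @inheritParams plan_updates
#' @inheritParams classify_all
#' @return a list with `comparisons`, `plan`, `annotation`, `report`.
#' @export
update_annotation <- function(reference, evidence, config = update_config(),
                              single_exon_frac = 0.8) {
  cmp <- classify_all(evidence, reference, single_exon_frac = single_exon_frac)
  plan <- plan_updates(cmp, reference, evidence, config = config)
  res <- apply_updates(reference, evidence, plan)
  list(comparisons = cmp, plan = plan, annotation = res$annotation,
       report = res$report)
}
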