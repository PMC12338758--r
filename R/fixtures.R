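# Deterministic synthetic-data generators. Every generated artifact comes
# with a truth log sufficient to verify the consuming module's output
# exactly, so the whole pipeline is testable without any external download.
#
# What the generator emulates: a draft-genome annotation laid out as
# non-overlapping loci on synthetic scaffolds, plus assembled-transcript
# evidence planted to realize each classification outcome (exact matches
# with ragged transcript ends, novel isoforms sharing an intron, chains of
# gene-joining transcripts, intergenic novel-gene clusters, antisense
# fragments, and sub-threshold single-exon fragments). What it does not
# emulate: read-level noise, soft-clipped alignment artifacts, overlapping
# reference loci, or expression-driven assembly dropout.

.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.sample_int <- function(range, n = 1L) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

#' Specify a synthetic reference/evidence scenario
#'
#' The spec fixes how many reference genes exist and how many evidence
#' transcripts of each classification outcome are planted.
#'
#' @param seed RNG seed; same seed, same output, byte for byte.
#' @param n_ref_genes number of reference genes.
#' @param n_exact evidence transcripts matching a reference transcript
#'   exactly (multi-exon copies get ragged terminal-exon ends).
#' @param n_novel_isoforms evidence transcripts sharing an intron with one
#'   gene but introducing a novel chain (each on its own gene).
#' @param merge_groups integer vector of merge sizes k (each >= 2); group k
#'   consumes k consecutive reference genes. Groups of k > 2 are realized as
#'   k-1 pairwise-spanning transcripts, so merging requires transitive
#'   closure.
#' @param n_novel_genes intergenic transcript clusters (novel genes).
#' @param n_opposite_strand antisense single-exon fragments over a gene.
#' @param n_intergenic_discard intergenic single-exon fragments of 120 nt,
#'   below the default 200 nt novel-gene floor.
#' @param exon_count_range,exon_len_range,intron_len_range inclusive integer
#'   ranges for reference gene structure.
#' @return a list of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 1L, n_ref_genes = 30L, n_exact = 5L,
                          n_novel_isoforms = 5L, merge_groups = c(2L, 3L),
                          n_novel_genes = 3L, n_opposite_strand = 2L,
                          n_intergenic_discard = 2L,
                          exon_count_range = c(2L, 5L),
                          exon_len_range = c(100L, 400L),
                          intron_len_range = c(60L, 500L)) {
  merge_groups <- as.integer(merge_groups)
  counts <- c(n_exact, n_novel_isoforms, n_novel_genes, n_opposite_strand,
              n_intergenic_discard)
  if (any(counts < 0L)) stop("all scenario counts must be >= 0")
  if (length(merge_groups) && any(merge_groups < 2L))
    stop("merge group sizes must be >= 2")
  needed <- sum(merge_groups) + n_novel_isoforms
  pool <- n_ref_genes - needed
  if (pool < 0L)
    stop("infeasible scenario: merge groups and isoform targets need ",
         needed, " genes but n_ref_genes = ", n_ref_genes)
  if (pool < 1L && (n_exact > 0L || n_opposite_strand > 0L))
    stop("infeasible scenario: no reference genes left for exact/antisense evidence")
  if (exon_count_range[1L] < 1L || exon_len_range[1L] < 30L ||
      intron_len_range[1L] < 30L)
    stop("exon count must be >= 1, exon/intron lengths >= 30")
  structure(list(seed = as.integer(seed), n_ref_genes = as.integer(n_ref_genes),
                 n_exact = as.integer(n_exact),
                 n_novel_isoforms = as.integer(n_novel_isoforms),
                 merge_groups = merge_groups,
                 n_novel_genes = as.integer(n_novel_genes),
                 n_opposite_strand = as.integer(n_opposite_strand),
                 n_intergenic_discard = as.integer(n_intergenic_discard),
                 exon_count_range = as.integer(exon_count_range),
                 exon_len_range = as.integer(exon_len_range),
                 intron_len_range = as.integer(intron_len_range)),
            class = "scenario_spec")
}

#' Scenario reproducing the observed merge-size distribution
#'
#' The merge distribution `{2: 1082, 3: 233, 4: 53, 5: 27, 6: 9, 7: 4,
#' 11: 1}` scaled down by `scale` (each size kept with at least one
#' instance, so the k = 11 chain is always present).
#'
#' @param scale integer divisor for the instance counts (default 50; use 1
#'   for the full-size distribution).
#' @param seed RNG seed.
#' @param ... passed to [scenario_spec()].
#' @return a `scenario_spec`.
#' @export
scenario_spec_table2 <- function(scale = 50L, seed = 1L, ...) {
  full <- c(`2` = 1082L, `3` = 233L, `4` = 53L, `5` = 27L, `6` = 9L,
            `7` = 4L, `11` = 1L)
  counts <- pmax(1L, as.integer(round(full / scale)))
  groups <- rep(as.integer(names(full)), counts)
  scenario_spec(seed = seed, merge_groups = groups,
                n_ref_genes = sum(groups) + 10L, n_exact = 3L,
                n_novel_isoforms = 3L, n_novel_genes = 2L,
                n_opposite_strand = 1L, n_intergenic_discard = 1L, ...)
}

# one reference gene body: exon table relative to a start cursor
.gene_body <- function(cursor, n_exons, exon_lens, intron_lens) {
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  pos <- cursor
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    ends[i] <- pos + exon_lens[i] - 1L
    pos <- ends[i] + 1L + if (i < n_exons) intron_lens[i] else 0L
  }
  data.table(start = starts, end = ends)
}

#' Generate a reference/evidence annotation pair with ground truth
#'
#' Reference genes are laid out left to right on `Scaffold1` with
#' inter-gene gaps larger than any intron; novel-gene clusters and
#' sub-threshold fragments live on `Scaffold2`. Evidence transcripts are
#' constructed per planted class (see [scenario_spec()]).
#'
#' @param spec a [scenario_spec()].
#' @return list with `reference` and `evidence` (`AnnotationSet`s) and
#'   `truth`: `codes` (data.table `transcript_id`, `code`, `ref_gene_ids`),
#'   `actions` (planted `UpdateAction` list), and `expected` (planted
#'   report-level counts).
#' @export
make_annotation_pair <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  .with_seed(spec$seed, function() .make_annotation_pair_impl(spec))
}

.make_annotation_pair_impl <- function(spec) {
  n <- spec$n_ref_genes
  gid <- sprintf("GBI_%05d", seq_len(n))
  gap <- 2L * spec$intron_len_range[2L] + 2000L

  # gene roles laid out left to right: merge groups first, then isoform
  # targets, then the general pool
  roles <- rep("pool", n)
  group_of <- rep(NA_integer_, n)
  at <- 1L
  for (gi in seq_along(spec$merge_groups)) {
    k <- spec$merge_groups[gi]
    roles[at:(at + k - 1L)] <- "merge"
    group_of[at:(at + k - 1L)] <- gi
    at <- at + k
  }
  iso_targets <- integer(0)
  if (spec$n_novel_isoforms > 0L) {
    iso_targets <- at:(at + spec$n_novel_isoforms - 1L)
    roles[iso_targets] <- "isoform"
    at <- at + spec$n_novel_isoforms
  }
  pool <- which(roles == "pool")

  strand <- character(n)
  for (gi in seq_along(spec$merge_groups)) {
    s <- sample(c("+", "-"), 1L)
    strand[which(group_of == gi)] <- s
  }
  free <- which(is.na(group_of))
  strand[free] <- sample(c("+", "-"), length(free), replace = TRUE)

  # reference bodies
  cursor <- 1000L
  ref_rows <- list()
  gene_exons <- vector("list", n)
  gene_end <- integer(n)
  for (i in seq_len(n)) {
    n_ex <- .sample_int(spec$exon_count_range)
    if (roles[i] == "isoform") n_ex <- max(2L, n_ex)
    body <- .gene_body(cursor, n_ex,
                       .sample_int(spec$exon_len_range, n_ex),
                       .sample_int(spec$intron_len_range, max(1L, n_ex - 1L)))
    gene_exons[[i]] <- body
    gene_end[i] <- max(body$end)
    ref_rows[[length(ref_rows) + 1L]] <-
      data.table(seqid = "Scaffold1", start = body$start, end = body$end,
                 strand = strand[i], gene_id = gid[i],
                 transcript_id = paste0(gid[i], ".t1"))
    # a truncated second isoform for some pool genes with >= 3 exons
    if (roles[i] == "pool" && nrow(body) >= 3L && i %% 4L == 0L) {
      ref_rows[[length(ref_rows) + 1L]] <-
        data.table(seqid = "Scaffold1", start = body$start[-1L],
                   end = body$end[-1L], strand = strand[i], gene_id = gid[i],
                   transcript_id = paste0(gid[i], ".t2"))
    }
    cursor <- gene_end[i] + gap
  }
  gene_attrs <- stats::setNames(
    lapply(seq_len(n), function(i) c(note = sprintf("synthetic locus %d", i))),
    gid)

  # evidence
  ev_rows <- list()
  truth_codes <- list()
  planted <- list()
  ev_n <- 0L
  add_ev <- function(exon_dt, strand_, seqid = "Scaffold1") {
    ev_n <<- ev_n + 1L
    tid <- sprintf("STRG.%d.1", ev_n)
    ev_rows[[length(ev_rows) + 1L]] <<-
      data.table(seqid = seqid, start = exon_dt$start, end = exon_dt$end,
                 strand = strand_, gene_id = sprintf("STRG.%d", ev_n),
                 transcript_id = tid)
    tid
  }
  log_code <- function(tid, code, genes = character(0)) {
    truth_codes[[length(truth_codes) + 1L]] <<-
      data.table(transcript_id = tid, code = code,
                 ref_gene_ids = list(genes))
  }

  # exact matches (pool genes, cycling)
  for (j in seq_len(spec$n_exact)) {
    i <- pool[(j - 1L) %% length(pool) + 1L]
    body <- copy(gene_exons[[i]])
    if (nrow(body) > 1L) {
      body[1L, start := max(1L, start - 10L)]
      body[.N, end := end + 10L]
    }
    tid <- add_ev(body, strand[i])
    log_code(tid, "EXACT", gid[i])
  }

  # novel isoforms: keep the first intron, bridge the rest with a novel exon
  for (j in seq_along(iso_targets)) {
    i <- iso_targets[j]
    body <- gene_exons[[i]]
    keep <- body[1:2]
    novel <- data.table(start = gene_end[i] + 500L,
                        end = gene_end[i] + 649L)
    tid <- add_ev(rbind(keep, novel), strand[i])
    log_code(tid, "NOVEL_ISOFORM", gid[i])
    planted[[length(planted) + 1L]] <-
      list(kind = "ADD_ISOFORM", evidence_transcript_ids = tid,
           target_gene_ids = gid[i])
  }

  # merge groups: k - 1 pairwise-spanning transcripts (single transcript
  # when k == 2), so k > 2 requires union-find closure
  for (gi in seq_along(spec$merge_groups)) {
    members <- which(group_of == gi)
    tx_ids <- character(0)
    for (j in seq_len(length(members) - 1L)) {
      a <- members[j]; b <- members[j + 1L]
      la <- gene_exons[[a]][.N]  # last exon of upstream gene
      fb <- gene_exons[[b]][1L]  # first exon of downstream gene
      exo <- data.table(start = c(la$start + 5L, fb$start),
                        end = c(la$end, fb$end - 5L))
      tid <- add_ev(exo, strand[members[1L]])
      tx_ids <- c(tx_ids, tid)
      log_code(tid, "SPANS_MULTIPLE", gid[c(a, b)])
    }
    planted[[length(planted) + 1L]] <-
      list(kind = "MERGE", evidence_transcript_ids = tx_ids,
           target_gene_ids = gid[members])
  }

  # novel genes on Scaffold2: clusters of 1-2 mutually overlapping
  # multi-exon transcripts
  cursor2 <- 1000L
  for (c_i in seq_len(spec$n_novel_genes)) {
    n_ex <- .sample_int(c(2L, 3L))
    body <- .gene_body(cursor2, n_ex, .sample_int(spec$exon_len_range, n_ex),
                       .sample_int(spec$intron_len_range, max(1L, n_ex - 1L)))
    s <- sample(c("+", "-"), 1L)
    tx_ids <- add_ev(body, s, seqid = "Scaffold2")
    if (c_i %% 2L == 0L) {
      alt <- copy(body)
      alt[1L, start := start + 20L]
      alt[.N, end := end + 30L]
      tx_ids <- c(tx_ids, add_ev(alt, s, seqid = "Scaffold2"))
    }
    for (tid in tx_ids) log_code(tid, "INTERGENIC")
    planted[[length(planted) + 1L]] <-
      list(kind = "NEW_GENE", evidence_transcript_ids = tx_ids,
           target_gene_ids = character(0))
    cursor2 <- max(body$end) + 30L + gap
  }

  # antisense fragments over pool genes
  for (j in seq_len(spec$n_opposite_strand)) {
    i <- pool[(j + spec$n_exact - 1L) %% length(pool) + 1L]
    e1 <- gene_exons[[i]][1L]
    frag <- data.table(start = e1$start + 10L,
                       end = e1$start + 10L + min(e1$end - e1$start - 20L, 150L))
    tid <- add_ev(frag, if (strand[i] == "+") "-" else "+")
    log_code(tid, "OPPOSITE_STRAND", gid[i])
  }

  # sub-threshold intergenic single-exon fragments on Scaffold2
  for (j in seq_len(spec$n_intergenic_discard)) {
    frag <- data.table(start = cursor2, end = cursor2 + 119L)
    tid <- add_ev(frag, sample(c("+", "-"), 1L), seqid = "Scaffold2")
    log_code(tid, "INTERGENIC")
    cursor2 <- cursor2 + 120L + gap
  }

  reference <- annotation_set(rbindlist(ref_rows), provenance = "reference",
                              gene_attrs = gene_attrs)
  evidence <- if (length(ev_rows)) {
    annotation_set(rbindlist(ev_rows), provenance = "evidence")
  } else {
    annotation_set(data.frame(seqid = character(), start = integer(),
                              end = integer(), strand = character(),
                              gene_id = character(),
                              transcript_id = character()),
                   provenance = "evidence")
  }

  md <- table(spec$merge_groups)
  truth <- list(
    codes = if (length(truth_codes)) rbindlist(truth_codes) else
      data.table(transcript_id = character(0), code = character(0),
                 ref_gene_ids = list()),
    actions = planted,
    expected = list(
      n_isoforms_added = spec$n_novel_isoforms,
      n_genes_gaining_isoforms = spec$n_novel_isoforms,
      max_isoforms_added_to_one_gene =
        if (spec$n_novel_isoforms > 0L) 1L else 0L,
      merge_distribution = stats::setNames(as.integer(md), names(md)),
      n_novel_genes = spec$n_novel_genes,
      n_discarded = spec$n_exact + spec$n_opposite_strand +
        spec$n_intergenic_discard))
  list(reference = reference, evidence = evidence, truth = truth)
}

#' Generate a transcript-mode BUSCO full_table with planted gene-level truth
#'
#' Realizes the requested gene-level categories with transcript-level rows,
#' including isoform-level duplications (Duplicated rows on two isoforms of
#' one gene) that must collapse to complete-single, and occasional extra
#' Fragmented rows on complete BUSCOs to exercise status precedence.
#'
#' @param n_single,n_duplicated,n_fragmented,n_missing planted gene-level
#'   category counts.
#' @param seed RNG seed.
#' @return list with `lines` (full_table text), `records` (parsed),
#'   `tx_to_gene` (named character vector), and `truth` (data.table
#'   `busco_id`, `category`).
#' @export
make_busco_table <- function(n_single = 939L, n_duplicated = 58L,
                             n_fragmented = 9L, n_missing = 7L, seed = 1L) {
  stopifnot(n_single >= 0L, n_duplicated >= 0L, n_fragmented >= 0L,
            n_missing >= 0L)
  .with_seed(seed, function() {
    n_genes <- n_single + 2L * n_duplicated + n_fragmented
    genes <- sprintf("BG_%05d", seq_len(max(n_genes, 1L)))
    t1 <- paste0(genes, ".t1"); t2 <- paste0(genes, ".t2")
    tx_to_gene <- stats::setNames(c(genes, genes), c(t1, t2))
    n_total <- n_single + n_duplicated + n_fragmented + n_missing
    ids <- sprintf("busco_%04dat0", seq_len(n_total))
    sc <- function() sprintf("%.1f", stats::runif(1L, 200, 1500))
    ln <- function() sample(200:2000, 1L)
    lines <- c("# Busco id\tStatus\tSequence\tScore\tLength")
    g_at <- 0L; id_at <- 0L
    take_gene <- function(k) {
      out <- genes[(g_at + 1L):(g_at + k)]
      g_at <<- g_at + k
      out
    }
    for (i in seq_len(n_single)) {
      id_at <- id_at + 1L; g <- take_gene(1L)
      if (i %% 3L == 0L) {
        # isoform-level duplication: must collapse to complete-single
        lines <- c(lines,
                   paste(ids[id_at], "Duplicated", paste0(g, ".t1"), sc(), ln(),
                         sep = "\t"),
                   paste(ids[id_at], "Duplicated", paste0(g, ".t2"), sc(), ln(),
                         sep = "\t"))
      } else {
        lines <- c(lines,
                   paste(ids[id_at], "Complete", paste0(g, ".t1"), sc(), ln(),
                         sep = "\t"))
        if (i %% 7L == 0L)  # complete outranks fragmented
          lines <- c(lines,
                     paste(ids[id_at], "Fragmented", paste0(g, ".t2"), sc(),
                           ln(), sep = "\t"))
      }
    }
    for (i in seq_len(n_duplicated)) {
      id_at <- id_at + 1L; g <- take_gene(2L)
      lines <- c(lines,
                 paste(ids[id_at], "Duplicated", paste0(g[1L], ".t1"), sc(),
                       ln(), sep = "\t"),
                 paste(ids[id_at], "Duplicated", paste0(g[2L], ".t1"), sc(),
                       ln(), sep = "\t"))
    }
    for (i in seq_len(n_fragmented)) {
      id_at <- id_at + 1L; g <- take_gene(1L)
      lines <- c(lines,
                 paste(ids[id_at], "Fragmented", paste0(g, ".t1"), sc(), ln(),
                       sep = "\t"))
    }
    for (i in seq_len(n_missing)) {
      id_at <- id_at + 1L
      lines <- c(lines, paste(ids[id_at], "Missing", sep = "\t"))
    }
    truth <- data.table(
      busco_id = ids,
      category = rep(c("complete_single", "complete_duplicated", "fragmented",
                       "missing"),
                     c(n_single, n_duplicated, n_fragmented, n_missing)))
    list(lines = lines, records = parse_busco_table(lines),
         tx_to_gene = tx_to_gene, truth = truth[order(busco_id)])
  })
}

#' Generate three-timepoint differential-expression tables with truth
#'
#' Plants per-day significant up/down sets, their >= 4-fold subsets, and a
#' cross-day overlap structure; all planted values sit at least 0.01 away
#' from every threshold boundary (boundary semantics are tested separately).
#' Non-significant bulk genes get `padj >= 0.11`, or a significant `padj`
#' with `|log2fc| <= 0.58` so they exercise the volcano `p_only` category.
#' Per-gene `baseMean` values straddle the 70 and 100 expression cutoffs.
#'
#' @param seed RNG seed.
#' @param up,down named per-day significant set sizes (days 1, 3, 7).
#' @param up_ge4,down_ge4 per-day counts with `|log2fc| >= 2`.
#' @param up_overlaps list with `d1_d3`, `d1_d7`, `d3_d7`, `d1_d3_d7`
#'   pairwise-only and triple overlap sizes for the up sets (down sets are
#'   disjoint across days).
#' @param n_null number of non-significant bulk genes shared by all tables.
#' @return list with `tables` (list `day1`, `day3`, `day7` of DE
#'   data.tables) and `truth` (per-day sets/counts and overlap region
#'   counts).
#' @export
make_de_tables <- function(seed = 1L,
                           up = c(d1 = 263L, d3 = 218L, d7 = 24L),
                           down = c(d1 = 173L, d3 = 71L, d7 = 14L),
                           up_ge4 = c(d1 = 75L, d3 = 131L, d7 = 15L),
                           down_ge4 = c(d1 = 14L, d3 = 22L, d7 = 13L),
                           up_overlaps = list(d1_d3 = 13L, d1_d7 = 1L,
                                              d3_d7 = 5L, d1_d3_d7 = 3L),
                           n_null = 1500L) {
  ov <- up_overlaps
  reg <- c(d1_d3_d7 = ov$d1_d3_d7, d1_d3 = ov$d1_d3, d1_d7 = ov$d1_d7,
           d3_d7 = ov$d3_d7,
           d1_only = up[["d1"]] - ov$d1_d3 - ov$d1_d7 - ov$d1_d3_d7,
           d3_only = up[["d3"]] - ov$d1_d3 - ov$d3_d7 - ov$d1_d3_d7,
           d7_only = up[["d7"]] - ov$d1_d7 - ov$d3_d7 - ov$d1_d3_d7)
  if (any(reg < 0L))
    stop("infeasible overlap structure: a Venn region would be negative")
  if (any(up_ge4 > up) || any(down_ge4 > down))
    stop(">= 4-fold subset larger than its significant set")

  .with_seed(seed, function() {
    mk_ids <- function(prefix, n) if (n > 0L) sprintf("%s%04d", prefix, seq_len(n)) else character(0)
    up_regions <- Map(mk_ids,
                      paste0("UP", names(reg), "_"), as.integer(reg))
    names(up_regions) <- names(reg)
    up_sets <- list(
      d1 = unlist(up_regions[c("d1_only", "d1_d3", "d1_d7", "d1_d3_d7")],
                  use.names = FALSE),
      d3 = unlist(up_regions[c("d3_only", "d1_d3", "d3_d7", "d1_d3_d7")],
                  use.names = FALSE),
      d7 = unlist(up_regions[c("d7_only", "d1_d7", "d3_d7", "d1_d3_d7")],
                  use.names = FALSE))
    down_sets <- list(d1 = mk_ids("DNd1_", down[["d1"]]),
                      d3 = mk_ids("DNd3_", down[["d3"]]),
                      d7 = mk_ids("DNd7_", down[["d7"]]))
    null_ids <- mk_ids("NULL_", n_null)
    universe <- c(unlist(up_sets, use.names = FALSE),
                  unlist(down_sets, use.names = FALSE), null_ids)
    universe <- unique(universe)

    base_mean_of <- function(m) {
      strata <- sample(1:3, m, replace = TRUE, prob = c(0.25, 0.25, 0.5))
      round(c(stats::runif(m, 10, 69), stats::runif(m, 70, 99),
              stats::runif(m, 100, 600))[(strata - 1L) * m + seq_len(m)], 2)
    }

    days <- c("d1", "d3", "d7")
    tables <- list()
    for (d in days) {
      upg <- sort(up_sets[[d]])
      dng <- sort(down_sets[[d]])
      m <- length(universe)
      dt <- data.table(gene_id = universe,
                       base_mean = base_mean_of(m),
                       log2fc = 0, pvalue = NA_real_, padj = NA_real_)
      # non-significant bulk: mostly padj >= 0.11, some p_only rows
      dt[, padj := round(stats::runif(m, 0.11, 0.97), 5)]
      bulk <- which(!dt$gene_id %in% c(upg, dng))
      pick <- function(cand, k) cand[sample.int(length(cand), min(k, length(cand)))]
      p_only <- pick(bulk, max(1L, m %/% 20L))
      dt[p_only, padj := round(stats::runif(length(p_only), 0.001, 0.089), 5)]
      dt[, log2fc := round(stats::runif(m, -0.58, 0.58), 3)]
      fc_only <- setdiff(pick(bulk, max(1L, m %/% 20L)), p_only)
      dt[fc_only, log2fc := round(sample(c(-1, 1), length(fc_only),
                                         replace = TRUE) *
                                    stats::runif(length(fc_only), 0.62, 3), 3)]
      # significant sets: first *_ge4 of each sorted set get |lfc| >= 2
      set_vals <- function(genes, n4, sign) {
        idx <- match(genes, dt$gene_id)
        nlo <- length(genes) - n4
        lfc <- c(stats::runif(n4, 2.2, 8),
                 stats::runif(nlo, 0.62, 1.9))
        dt[idx, log2fc := round(sign * lfc, 3)]
        dt[idx, padj := round(stats::runif(length(idx), 0.001, 0.089), 5)]
        if (n4 >= 2L) dt[idx[1:2], padj := 1e-30]  # exercises volcano clamp
      }
      set_vals(upg, up_ge4[[d]], 1)
      set_vals(dng, down_ge4[[d]], -1)
      dt[, pvalue := padj / 2]
      tables[[paste0("day", sub("d", "", d))]] <- dt
    }

    truth <- list(
      up = lapply(up_sets, sort), down = lapply(down_sets, sort),
      up_ge4 = as.list(up_ge4), down_ge4 = as.list(down_ge4),
      up_regions = lengths(up_regions),
      down_regions = c(d1_only = length(down_sets$d1),
                       d3_only = length(down_sets$d3),
                       d7_only = length(down_sets$d7),
                       d1_d3 = 0L, d1_d7 = 0L, d3_d7 = 0L, d1_d3_d7 = 0L))
    list(tables = tables, truth = truth)
  })
}
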