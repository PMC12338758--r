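test_that("all-exact evidence plans no change and applies as the identity", {
  p <- make_annotation_pair(scenario_spec(seed = 2, n_exact = 4,
                                          n_novel_isoforms = 0,
                                          merge_groups = integer(0),
                                          n_novel_genes = 0,
                                          n_opposite_strand = 0,
                                          n_intergenic_discard = 0,
                                          n_ref_genes = 8))
  cmp <- classify_all(p$evidence, p$reference)
  plan <- plan_updates(cmp, p$reference, p$evidence)
  expect_length(plan$actions, 0L)
  expect_equal(length(plan$discarded), nrow(p$evidence$transcripts))
  res <- apply_updates(p$reference, p$evidence, plan)
  expect_true(anno_equal(res$annotation, p$reference))
  expect_equal(res$report$n_isoforms_added, 0L)
  expect_equal(res$report$n_novel_genes, 0L)
  expect_equal(sum(res$report$merge_distribution), 0L)
})

test_that("pairwise spanning evidence closes transitively into one merge", {
  # g1--tA--g2--tB--g3: no single transcript spans all three
  ref <- annotation_set(rbind(
    exon_rows("s", "+", "g1", "g1.t1", 100L, 300L),
    exon_rows("s", "+", "g2", "g2.t1", 1000L, 1200L),
    exon_rows("s", "+", "g3", "g3.t1", 2000L, 2200L)), "reference",
    gene_attrs = list(g1 = c(note = "one"), g2 = c(note = "two"),
                      g3 = c(note = "three")))
  ev <- annotation_set(rbind(
    exon_rows("s", "+", "eA", "tA", c(200L, 1000L), c(300L, 1100L)),
    exon_rows("s", "+", "eB", "tB", c(1100L, 2000L), c(1200L, 2100L))),
    "evidence")
  cmp <- classify_all(ev, ref)
  expect_true(all(cmp$code == "SPANS_MULTIPLE"))
  plan <- plan_updates(cmp, ref, ev)
  expect_length(plan$actions, 1L)
  a <- plan$actions[[1L]]
  expect_identical(a$kind, "MERGE")
  expect_identical(a$target_gene_ids, c("g1", "g2", "g3"))
  expect_setequal(a$evidence_transcript_ids, c("tA", "tB"))
  expect_identical(a$new_gene_id, "GBIG_000000")

  res <- apply_updates(ref, ev, plan)
  expect_equal(nrow(res$annotation$genes), 1L)
  g <- res$annotation$genes
  expect_identical(g$gene_id, "GBIG_000000")
  # annotation text of the subunits concatenated in genomic order
  expect_identical(g$attributes[[1L]][["note"]], "one;two;three")
  # subunit transcript ids retained verbatim, joiners renamed
  expect_setequal(res$annotation$transcripts$transcript_id,
                  c("g1.t1", "g2.t1", "g3.t1", "GBIG_000000.t4",
                    "GBIG_000000.t5"))
  expect_equal(res$report$merge_distribution, c(`3` = 1L))
})

test_that("a merge of two genes plus joiner yields three transcripts", {
  ref <- annotation_set(rbind(
    exon_rows("s", "-", "gx", "gx.t1", 100L, 400L),
    exon_rows("s", "-", "gy", "gy.t1", 900L, 1300L)), "reference")
  ev <- annotation_set(
    exon_rows("s", "-", "e", "join1", c(300L, 900L), c(400L, 1000L)),
    "evidence")
  out <- update_annotation(ref, ev)
  expect_equal(nrow(out$annotation$genes), 1L)
  txs <- out$annotation$transcripts$transcript_id
  expect_equal(length(txs), 3L)
  expect_true(all(c("gx.t1", "gy.t1") %in% txs))
})

test_that("planted scenarios are recovered exactly and obey the count law", {
  for (seed in c(1, 5, 12)) {
    p <- make_annotation_pair(random_scenario(seed))
    out <- update_annotation(p$reference, p$evidence)
    expect_identical(norm_actions(out$plan$actions),
                     norm_actions(p$truth$actions), label = paste("seed", seed))
    rep <- out$report
    exp <- p$truth$expected
    expect_equal(rep$n_isoforms_added, exp$n_isoforms_added)
    expect_equal(rep$n_genes_gaining_isoforms, exp$n_genes_gaining_isoforms)
    expect_equal(unname(rep$merge_distribution),
                 unname(exp$merge_distribution))
    expect_equal(rep$n_novel_genes, exp$n_novel_genes)
    expect_equal(rep$n_discarded, exp$n_discarded)
    k <- as.integer(names(rep$merge_distribution))
    expect_equal(nrow(out$annotation$genes),
                 nrow(p$reference$genes) -
                   sum((k - 1L) * rep$merge_distribution) +
                   rep$n_novel_genes)
  }
})

test_that("every reference transcript survives and untouched genes are byte-identical", {
  p <- make_annotation_pair(scenario_spec(seed = 10))
  out <- update_annotation(p$reference, p$evidence)
  upd <- out$annotation
  expect_true(all(p$reference$transcripts$transcript_id %in%
                    upd$transcripts$transcript_id))
  expect_equal(anyDuplicated(upd$transcripts$transcript_id), 0L)
  touched <- unlist(lapply(out$plan$actions, `[[`, "target_gene_ids"))
  for (g in setdiff(p$reference$genes$gene_id, touched)) {
    expect_identical(
      upd$genes$attributes[[which(upd$genes$gene_id == g)]],
      p$reference$genes$attributes[[which(p$reference$genes$gene_id == g)]])
  }
})

test_that("re-running the update on its own output is a no-op", {
  for (seed in c(1, 5)) {
    p <- make_annotation_pair(random_scenario(seed))
    out <- update_annotation(p$reference, p$evidence)
    again <- update_annotation(out$annotation, p$evidence)
    expect_length(again$plan$actions, 0L)
    expect_true(anno_equal(again$annotation, out$annotation))
  }
})

test_that("an eleven-gene chain is representable and recovered", {
  p <- make_annotation_pair(scenario_spec(seed = 21, n_ref_genes = 15,
                                          merge_groups = 11L,
                                          n_novel_isoforms = 1,
                                          n_exact = 1, n_novel_genes = 1,
                                          n_opposite_strand = 0,
                                          n_intergenic_discard = 0))
  out <- update_annotation(p$reference, p$evidence)
  expect_equal(unname(out$report$merge_distribution["11"]), 1L)
  merged <- Filter(function(a) a$kind == "MERGE", out$plan$actions)[[1L]]
  expect_length(merged$target_gene_ids, 11L)
  expect_length(merged$evidence_transcript_ids, 10L)  # chained pairwise spans
})

test_that("new gene identifiers are sequential, padded, and collision-free", {
  expect_identical(format_gene_id(14732), "GBIG_014732")
  expect_identical(format_gene_id(0), "GBIG_000000")
  ids <- format_gene_id(0:999)
  expect_equal(anyDuplicated(ids), 0L)
  expect_identical(ids, sort(ids))  # call order == sorted order
  expect_error(format_gene_id(10^6), "exhausted")

  # assignment skips identifiers already present in the reference
  ref <- annotation_set(rbind(
    exon_rows("s", "+", "GBIG_000000", "a.t1", 100L, 200L),
    exon_rows("s", "+", "g2", "g2.t1", 1000L, 1100L)), "reference")
  ev <- annotation_set(
    exon_rows("s", "+", "n", "n.t1", c(5000L, 5400L), c(5200L, 5600L)),
    "evidence")
  out <- update_annotation(ref, ev)
  novel <- Filter(function(a) a$kind == "NEW_GENE", out$plan$actions)[[1L]]
  expect_identical(novel$new_gene_id, "GBIG_000001")
})

test_that("merge distribution table tallies instances with a total row", {
  tab <- merge_distribution_table(
    list(`2` = 1082, `3` = 233, `4` = 53, `5` = 27, `6` = 9, `7` = 4,
         `11` = 1))
  expect_identical(tab$k, c("2", "3", "4", "5", "6", "7", "11", "total"))
  expect_equal(tab$count[tab$k == "total"], 1409L)

  empty <- merge_distribution_table(list())
  expect_equal(empty$count, 0L)

  p <- make_annotation_pair(scenario_spec(seed = 13,
                                          merge_groups = c(2L, 2L, 4L),
                                          n_ref_genes = 20))
  out <- update_annotation(p$reference, p$evidence)
  tab <- merge_distribution_table(out$report)
  sizes <- table(vapply(Filter(function(a) a$kind == "MERGE",
                               out$plan$actions),
                        function(a) length(a$target_gene_ids), 0L))
  expect_equal(tab$count[tab$k != "total"], unname(as.integer(sizes)))
  expect_equal(tab$count[tab$k == "total"], sum(sizes))
})

test_that("inconsistent plans and comparisons are rejected", {
  ref <- mini_reference()
  ev <- one_tx("t1", "chr1", "+", 101, 200, gene_id = "e")
  cmp <- data.table::data.table(
    transcript_id = "t1", code = "NOVEL_ISOFORM",
    ref_gene_ids = list("no_such_gene"),
    matched_ref_transcript_id = NA_character_)
  expect_error(plan_updates(cmp, ref, ev), "absent from the reference")

  plan <- structure(list(actions = list(list(
    kind = "NEW_GENE", evidence_transcript_ids = "t1",
    target_gene_ids = character(0), new_gene_id = "gA")),
    id_counter_start = 0L, discarded = character(0),
    config = update_config()), class = "UpdatePlan")
  expect_error(apply_updates(ref, ev, plan), "collides")
})
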