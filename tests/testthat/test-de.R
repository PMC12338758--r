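de_row <- function(gene_id, log2fc, padj, base_mean = 100) {
  data.frame(gene_id = gene_id, base_mean = base_mean, log2fc = log2fc,
             pvalue = padj / 2, padj = padj)
}

test_that("significance thresholds are strict inequalities", {
  tab <- rbind(
    de_row("clear_up", 1.0, 0.05),
    de_row("clear_dn", -1.0, 0.05),
    de_row("lfc_at_cut", 0.6, 0.05),    # log2fc == cutoff: excluded
    de_row("padj_at_cut", 1.0, 0.1),    # padj == cutoff: excluded
    de_row("na_padj", 3.0, NA),
    de_row("ns", 0.1, 0.9))
  sig <- filter_significant(tab)
  expect_identical(sig$up, "clear_up")
  expect_identical(sig$down, "clear_dn")
  # relaxing either threshold is monotone: sets only grow
  for (pm in c(0.1, 0.2, 0.5)) for (lm in c(0.6, 0.3)) {
    wider <- filter_significant(tab, padj_max = pm, lfc_min = lm)
    expect_true(all(sig$up %in% wider$up))
    expect_true(all(sig$down %in% wider$down))
  }
})

test_that("fold bins and their printed percentages are reproduced", {
  d <- make_de_tables(seed = 1)
  expected <- list(
    day1 = list(up = 263L, down = 173L, up4 = 75L, dn4 = 14L,
                up_pct = 29, dn_pct = 8),
    day3 = list(up = 218L, down = 71L, up4 = 131L, dn4 = 22L,
                up_pct = 60, dn_pct = 31),
    day7 = list(up = 24L, down = 14L, up4 = 15L, dn4 = 13L,
                up_pct = 62.5, dn_pct = 93))
  for (day in names(expected)) {
    tab <- d$tables[[day]]
    sig <- filter_significant(tab)
    fb <- fold_bin_summary(sig, tab, day = day)
    e <- expected[[day]]
    expect_length(fb$up, e$up)
    expect_length(fb$down, e$down)
    expect_equal(fb$up_ge4fold, e$up4)
    expect_equal(fb$down_ge4fold, e$dn4)
    expect_equal(fb$up_ge4fold_pct, e$up_pct)
    expect_equal(fb$down_ge4fold_pct, e$dn_pct)
    # recount with an independent scan of the table
    lfc <- setNames(tab$log2fc, tab$gene_id)
    expect_equal(fb$up_ge4fold, sum(lfc[fb$up] >= 2))
    expect_equal(fb$down_ge4fold, sum(lfc[fb$down] <= -2))
  }
})

test_that("overlap regions form the planted disjoint partition", {
  mk <- function(up, down) structure(list(up = up, down = down),
                                     class = "timepoint_summary")
  # enumerable by hand
  ov <- overlap_sets(mk(c("a", "b", "c"), character(0)),
                     mk(c("b", "c", "d"), character(0)),
                     mk("c", character(0)))
  up <- ov[ov$direction == "up", ]
  expect_equal(up$count[up$region == "d1_d3_d7"], 1L)  # {c}
  expect_equal(up$count[up$region == "d1_d3"], 1L)     # {b}
  expect_equal(up$count[up$region == "d3_only"], 1L)   # {d}
  expect_equal(up$count[up$region == "d1_d7"], 0L)
  expect_equal(sum(up$count), 4L)  # |union|

  d <- make_de_tables(seed = 2)
  ss <- lapply(d$tables, function(tab)
    fold_bin_summary(filter_significant(tab), tab))
  ov <- overlap_sets(ss$day1, ss$day3, ss$day7)
  up <- ov[ov$direction == "up", ]
  dn <- ov[ov$direction == "down", ]
  expect_equal(setNames(up$count, up$region),
               d$truth$up_regions[up$region])
  expect_equal(unname(setNames(dn$count, dn$region)[c("d1_d3", "d1_d7",
                                                      "d3_d7", "d1_d3_d7")]),
               rep(0L, 4L))
  # regions are a partition of the union
  members <- attr(ov, "members")$up
  expect_equal(sum(lengths(members)),
               length(unique(c(ss$day1$up, ss$day3$up, ss$day7$up))))
  expect_equal(anyDuplicated(unlist(members)), 0L)
})

test_that("top tables filter low expression, rank by fold change, and flag NSS", {
  tab <- rbind(
    de_row("g_hi", 5.0, 0.01, base_mean = 500),
    de_row("g_tie_b", 3.0, 0.01, base_mean = 100),
    de_row("g_tie_a", 3.0, 0.01, base_mean = 100),
    de_row("g_low_expr", 8.0, 0.01, base_mean = 69),  # below the floor
    de_row("g_down", -4.0, 0.01, base_mean = 90),
    de_row("g_ns", 6.0, 0.5, base_mean = 400))
  sig <- filter_significant(tab)
  ann <- data.frame(gene_id = c("g_hi", "g_tie_a", "g_down"),
                    description = c("Vitellogenin-like", "weak hit",
                                    "Ionotropic receptor"),
                    evalue = c(1e-30, 0.5, 1e-12))
  tt <- top_table(tab, sig, annotation = ann)
  expect_identical(tt$up$gene_id, c("g_hi", "g_tie_a", "g_tie_b"))
  expect_identical(tt$down$gene_id, "g_down")
  expect_identical(tt$up$description, c("Vitellogenin-like", "NSS", NA))
  expect_identical(tt$down$description, "Ionotropic receptor")
  # no padding beyond the available genes
  expect_lte(nrow(tt$up), 10L)

  d <- make_de_tables(seed = 3)
  tab <- d$tables$day1
  sig <- filter_significant(tab)
  tt <- top_table(tab, sig, n = 10)
  keep <- tab[tab$gene_id %in% c(sig$up, sig$down) & tab$base_mean >= 70, ]
  ord <- keep[order(-keep$log2fc, keep$gene_id), ]
  expect_identical(tt$up$gene_id, head(ord$gene_id[ord$gene_id %in% sig$up], 10))
  ord2 <- keep[order(keep$log2fc, keep$gene_id), ]
  expect_identical(tt$down$gene_id,
                   head(ord2$gene_id[ord2$gene_id %in% sig$down], 10))
})

test_that("volcano preparation clamps p-values and categorizes points", {
  tab <- rbind(
    de_row("clamped", 3.0, 1e-30),
    de_row("sig", 2.0, 0.01),
    de_row("p_only", 0.2, 0.01),
    de_row("fc_only", 2.0, 0.5),
    de_row("ns", 0.0, 0.5))
  v <- volcano_prep(tab)
  expect_equal(v$neglog10_padj[v$gene_id == "clamped"], 10)
  got <- setNames(v$category, v$gene_id)
  expect_identical(unname(got[c("clamped", "sig", "p_only", "fc_only", "ns")]),
                   c("significant", "significant", "p_only", "fc_only", "ns"))

  d <- make_de_tables(seed = 4)
  tab <- d$tables$day3
  v <- volcano_prep(tab)
  # independent predicate recount
  p_ok <- tab$padj < 0.1
  fc_ok <- abs(tab$log2fc) > 0.6
  expect_equal(sum(v$category == "significant"), sum(p_ok & fc_ok))
  expect_equal(sum(v$category == "p_only"), sum(p_ok & !fc_ok))
  expect_equal(sum(v$category == "fc_only"), sum(!p_ok & fc_ok))
  expect_equal(sum(v$category == "ns"), sum(!p_ok & !fc_ok))
  sig <- filter_significant(tab)
  expect_setequal(v$gene_id[v$category == "significant"],
                  c(sig$up, sig$down))
})

test_that("ranked export filters on expression and sorts by fold change", {
  tab <- rbind(de_row("a", 1.0, 0.5, base_mean = 99),
               de_row("b", -2.0, 0.5, base_mean = 100),
               de_row("tie2", 3.0, 0.5, base_mean = 150),
               de_row("tie1", 3.0, 0.5, base_mean = 150))
  r <- ranked_export(tab)
  expect_identical(r$gene_id, c("tie1", "tie2", "b"))
  expect_equal(nrow(ranked_export(de_row("x", 1, 0.5, base_mean = 10))), 0L)

  d <- make_de_tables(seed = 5)
  tab <- d$tables$day7
  r <- ranked_export(tab)
  keep <- tab[tab$base_mean >= 100, ]
  expect_equal(nrow(r), nrow(keep))
  ord <- keep[order(-keep$log2fc, keep$gene_id), ]
  expect_identical(r$gene_id, ord$gene_id)
  f <- withr::local_tempfile(fileext = ".tsv")
  ranked_export(tab, file = f)
  expect_equal(nrow(read.delim(f, header = FALSE)), nrow(r))
})

test_that("'both'-direction enrichment rows are copied into both lists", {
  rows <- data.frame(term = c("A", "B", "C"),
                     direction = c("up", "both", "down"))
  sp <- split_enrichment_directions(rows)
  expect_identical(sp$up$term, c("A", "B"))
  expect_identical(sp$down$term, c("B", "C"))
  # counting identity |up out| + |down out| = |up| + |down| + 2|both|
  set.seed(1)
  rows <- data.frame(term = sprintf("T%02d", 1:20),
                     direction = sample(c("up", "down", "both"), 20,
                                        replace = TRUE))
  sp <- split_enrichment_directions(rows)
  expect_equal(nrow(sp$up) + nrow(sp$down),
               sum(rows$direction == "up") + sum(rows$direction == "down") +
                 2L * sum(rows$direction == "both"))
  expect_error(split_enrichment_directions(data.frame(direction = "sideways")),
               "unknown direction")
})

test_that("DESeq2-style result files read back with normalized columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tbaseMean\tlog2FoldChange\tpvalue\tpadj",
               "g1\t120.5\t2.25\t0.001\t0.004",
               "g2\t15\t-0.2\t0.8\t0.9"), f)
  dt <- read_de_table(f)
  expect_identical(names(dt),
                   c("gene_id", "base_mean", "log2fc", "pvalue", "padj"))
  expect_equal(dt$base_mean[1L], 120.5)
  writeLines(c("gene_id\tbaseMean\tlog2FoldChange\tpvalue\tpadj",
               "g1\t120.5\t2.25\t0.001\t1.4"), f)
  expect_error(read_de_table(f), "outside")
})
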