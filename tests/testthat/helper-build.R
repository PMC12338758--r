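# Small hand-built annotations used across tests.

exon_rows <- function(seqid, strand, gene_id, transcript_id, starts, ends) {
  data.frame(seqid = seqid, start = starts, end = ends, strand = strand,
             gene_id = gene_id, transcript_id = transcript_id)
}

# A compact reference: two '+' multi-exon genes, one '-' single-exon gene.
#   gA chr1:+  exons 101-200, 301-400, 501-600
#   gB chr1:+  exons 1001-1100, 1201-1300
#   gC chr1:-  exon 2001-2300
mini_reference <- function() {
  annotation_set(rbind(
    exon_rows("chr1", "+", "gA", "gA.t1", c(101L, 301L, 501L),
              c(200L, 400L, 600L)),
    exon_rows("chr1", "+", "gB", "gB.t1", c(1001L, 1201L),
              c(1100L, 1300L)),
    exon_rows("chr1", "-", "gC", "gC.t1", 2001L, 2300L)),
    provenance = "reference",
    gene_attrs = list(gA = c(note = "locus A"), gB = c(note = "locus B"),
                      gC = c(note = "locus C")))
}

one_tx <- function(transcript_id, seqid, strand, starts, ends,
                   gene_id = paste0(transcript_id, ".g")) {
  annotation_set(exon_rows(seqid, strand, gene_id, transcript_id,
                           as.integer(starts), as.integer(ends)),
                 provenance = "evidence")
}

# Order-insensitive normalization of an action list for truth comparison;
# new_gene_id is dropped (assignment order is the implementation's own).
norm_actions <- function(actions) {
  a <- lapply(actions, function(x) {
    list(kind = x$kind,
         tx = sort(unname(unlist(x$evidence_transcript_ids))),
         genes = sort(unname(unlist(x$target_gene_ids))))
  })
  key <- vapply(a, function(x) paste(x$kind, x$tx[1]), "")
  a[order(key)]
}

random_scenario <- function(seed) {
  set.seed(seed)
  ks <- sample(2:7, sample(1:4, 1), replace = TRUE)
  if (seed %% 5L == 0L) ks <- c(ks, 11L)
  scenario_spec(
    seed = seed,
    n_ref_genes = sum(ks) + sample(8:15, 1),
    n_exact = sample(0:6, 1),
    n_novel_isoforms = sample(0:5, 1),
    merge_groups = ks,
    n_novel_genes = sample(0:4, 1),
    n_opposite_strand = sample(0:3, 1),
    n_intergenic_discard = sample(0:3, 1))
}
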