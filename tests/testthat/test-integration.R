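mk_tx2gene <- function(tx, gene) data.frame(transcript_id = tx, gene_id = gene,
                                            stringsAsFactors = FALSE)

test_that("collapse_to_gene joins feature levels and flags conflicts", {
  tx2gene <- mk_tx2gene(c("t1", "t2", "t3"), c("gA", "gA", "gB"))
  prot2gene <- data.frame(protein_id = c("p1", "p2"), gene_id = c("gA", "gB"),
                          stringsAsFactors = FALSE)
  dmg <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    label = c("liver", "liver", "none"),
                    stringsAsFactors = FALSE)
  dep <- data.frame(protein_id = c("p1", "p2"),
                    label = c("liver", "muscle_only"),
                    stringsAsFactors = FALSE)
  tbl <- collapse_to_gene(dmg = dmg, dep = dep, tx2gene = tx2gene,
                          prot2gene = prot2gene,
                          tissues = c("liver", "muscle"))
  expect_equal(tbl$dmg[tbl$gene_id == "gA"], "liver")
  expect_equal(tbl$dep[tbl$gene_id == "gA"], "liver")
  expect_equal(tbl$dep[tbl$gene_id == "gB"], "muscle")
  expect_true(tbl$dep_only[tbl$gene_id == "gB"])
  # two transcripts of one gene with opposing directions: conflict
  dmg2 <- data.frame(transcript_id = c("t1", "t2"),
                     label = c("liver", "muscle"), stringsAsFactors = FALSE)
  tbl2 <- collapse_to_gene(dmg = dmg2, tx2gene = tx2gene,
                           tissues = c("liver", "muscle"))
  expect_equal(tbl2$dmg[tbl2$gene_id == "gA"], "conflict")
  # unmapped IDs are excluded with a warning
  expect_warning(
    tbl3 <- collapse_to_gene(dmg = dmg, tx2gene = mk_tx2gene("zz", "gZ"),
                             tissues = c("liver", "muscle")),
    "excluded")
  expect_equal(nrow(tbl3), 0)
  expect_setequal(attr(tbl3, "excluded"), c("t1", "t2", "t3"))
})

test_that("derive_composites applies direction-consistent set algebra", {
  tbl <- data.frame(
    gene_id = sprintf("g%02d", 1:6),
    dmg = c("liver", "liver", "muscle", "none", "liver", "none"),
    deg = c("liver", "muscle", "muscle", "none", "liver", "liver"),
    dep = c("liver", "liver", "muscle", "none", "muscle", "liver"),
    drp = c("none", "none", "muscle", "none", "liver", "liver"),
    dtg = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  attr(tbl, "tissues") <- c("liver", "muscle")
  out <- derive_composites(tbl)
  expect_equal(out$dm_deg, c("liver", "none", "muscle", "none", "liver", "none"))
  expect_equal(out$dm_dep, c("liver", "none", "muscle", "none", "none", "none"))
  expect_equal(out$dr_dep, c("none", "none", "muscle", "none", "none", "liver"))
  expect_equal(out$dt_dep, c("liver", "none", "muscle", "none", "none", "liver"))
  venn <- attr(out, "venn")
  expect_equal(unname(venn$liver["dm_deg"]), 2)
  expect_equal(unname(venn$cross_direction["dmg1_deg2"]), 1)
  # empty input: zero counts
  empty <- tbl[0, ]
  attr(empty, "tissues") <- c("liver", "muscle")
  venn0 <- attr(derive_composites(empty), "venn")
  expect_true(all(unlist(venn0) == 0))
})

test_that("overlap_significance cross-tabulates exactly and respects tails", {
  set.seed(28)
  n <- 300
  tbl <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    dmg = sample(c("liver", "none"), n, TRUE, c(0.2, 0.8)),
                    deg = sample(c("liver", "none"), n, TRUE, c(0.3, 0.7)),
                    stringsAsFactors = FALSE)
  res <- overlap_significance(tbl, "dmg", "liver", "deg", "liver", "right")
  a <- sum(tbl$dmg == "liver" & tbl$deg == "liver")
  b <- sum(tbl$dmg == "liver" & tbl$deg != "liver")
  c_ <- sum(tbl$dmg != "liver" & tbl$deg == "liver")
  d <- sum(tbl$dmg != "liver" & tbl$deg != "liver")
  expect_equal(unname(as.vector(res$table)), c(a, c_, b, d))
  expect_equal(res$p, fisher_oracle(a, b, c_, d, "right"), tolerance = 1e-12)
  # perfectly nested classes give an extreme right-tail p
  tbl$deg2 <- ifelse(tbl$dmg == "liver", "liver", "none")
  res2 <- overlap_significance(tbl, "dmg", "liver", "deg2", "liver", "right")
  expect_lt(res2$p, 1e-30)
})

test_that("cpg_density_analysis bins strand-aware offsets and conserves totals", {
  tr <- simple_exons(c("gp", "gm"), "chr1", c("+", "-"),
                     c(5000, 20000), c(6000, 21000))
  models <- make_models(tr)
  # plus gene: CpGs at offsets -200 and +399 (bins 1 and 15)
  # minus gene (tss = 20999): offsets -200 -> pos 21199, +399 -> pos 20600
  cpgs <- data.frame(chrom = "chr1", pos = c(4800, 5399, 21199, 20600))
  res <- cpg_density_analysis(models, cpgs)
  expect_equal(unname(res$vectors["gp", c(1, 15)]), c(1, 1))
  expect_equal(unname(res$vectors["gm", c(1, 15)]), c(1, 1))
  expect_equal(sum(res$vectors["gp", ]), 2)
  expect_equal(unname(res$total), unname(rowSums(res$vectors)))
})

test_that("cpg_density_analysis separates planted density classes and contrasts DMGs", {
  cfg <- sim_config(n_genes = 300, seed = 4, multi_tss_frac = 0)
  ann <- generate_annotation(cfg)
  met <- generate_methylome(cfg, ann)
  cpg_sites <- ann$cpgs[ann$cpgs$context == "CpG", c("chrom", "pos")]
  dmg_lab <- setNames(met$truth$dmg_label, ann$tx2gene$transcript_id[
    match(met$truth$gene_id, ann$tx2gene$gene_id)])
  res <- cpg_density_analysis(ann$models, cpg_sites, dmg_lab)
  got <- res$density_class[ann$tx2gene$transcript_id[
    match(ann$truth$gene_id, ann$tx2gene$gene_id)]]
  expect_gte(mean(got == ann$truth$density_class), 0.95)
  # DMGs sit mostly in the low-density class: lower median CpG count
  expect_lt(res$dmg_test$median_dmg, res$dmg_test$median_non)
  expect_lt(res$dmg_test$p, 0.001)
})

test_that("enrichment computes Fisher tails over the right universe", {
  universe <- sprintf("g%03d", 1:200)
  genes <- universe[1:40]
  sets <- list(hit = universe[1:30], miss = universe[101:130])
  res <- enrichment(genes, sets, universe)
  expect_equal(res$n_overlap[res$set == "hit"], 30)
  expect_lt(res$q[res$set == "hit"], 1e-10)
  expect_gt(res$q[res$set == "miss"], 0.05)
  expect_error(enrichment(c(genes, "not_there"), sets, universe),
               "not contained")
  expect_error(enrichment(genes, list(empty = character(0)), universe),
               "empty")
  # class map is joined through
  cm <- data.frame(set = c("hit", "miss"), class = c("Metabolism", "Other"))
  res2 <- enrichment(genes, sets, universe, class_map = cm)
  expect_equal(res2$class[res2$set == "hit"], "Metabolism")
})
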