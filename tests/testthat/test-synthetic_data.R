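test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(n_genes = 50), "sim_config")
  expect_error(sim_config(frac_liver_dmg = 0.6, frac_muscle_dmg = 0.6), "<= 1")
  expect_error(sim_config(hypo_mean = 0.9, hyper_mean = 0.2), "hypo_mean")
  expect_error(sim_config(meth_replicates = 0), ">= 1")
  expect_error(sim_config(coverage_mean = 0), "positive")
  expect_error(sim_config(dropout_rate = 1.5), "proportions")
  expect_error(generate_annotation(sim_config(n_genes = 100,
                                              chrom_length = 1000)),
               "do not fit")
})

test_that("generation is deterministic for identical configs", {
  cfg <- sim_config(n_genes = 60, seed = 5)
  a <- generate_annotation(cfg)
  b <- generate_annotation(cfg)
  expect_identical(a, b)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$meth$meth, s2$meth$meth)
  # bundles are byte-identical
  d1 <- file.path(tempdir(), "bd1"); d2 <- file.path(tempdir(), "bd2")
  write_bundle(s1, d1); write_bundle(s2, d2)
  for (f in c("annotation.gtf", "meth_liver_rep1.tsv", "rna_counts_muscle.tsv",
              "protein_liver.tsv", "truth.tsv", "gene_sets.gmt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("truth labels are consistent with planted parameters", {
  cfg <- sim_config(n_genes = 300, seed = 6)
  sim <- simulate_study(cfg)
  tr <- sim$truth
  liver_dmg <- tr$dmg_label == "liver"
  expect_true(all(tr$planted_meth_liver[liver_dmg] <
                    tr$planted_meth_muscle[liver_dmg]))
  muscle_dmg <- tr$dmg_label == "muscle"
  expect_true(all(tr$planted_meth_muscle[muscle_dmg] <
                    tr$planted_meth_liver[muscle_dmg]))
  deg_liver <- tr$deg_label == "liver"
  expect_true(all(tr$planted_log2tpm_liver[deg_liver] >
                    tr$planted_log2tpm_muscle[deg_liver]))
  # replicate structure as configured: 3 / 11 / 5 per tissue
  expect_equal(ncol(sim$meth$meth$liver), 3)
  expect_equal(ncol(sim$rna$counts$liver), 11)
  expect_equal(ncol(sim$rna$counts$muscle), 11)
  expect_equal(ncol(sim$prot$intensity$liver), 5)
  expect_equal(ncol(sim$prot$intensity$muscle), 5)
})

test_that("null configurations plant no labels", {
  cfg0 <- sim_config(n_genes = 120, seed = 7, deg_log2fc = 0,
                     tf_effect_log2 = 0, frac_deg_extra = 0)
  sim0 <- simulate_study(cfg0)
  expect_true(all(sim0$truth$deg_label == "none"))
  expect_true(all(sim0$truth$dtg_label == "none"))
  cfg1 <- sim_config(n_genes = 120, seed = 7, drp_shift = 0,
                     dropout_rate = 0, frac_tissue_absent = 0)
  sim1 <- simulate_study(cfg1)
  expect_true(all(sim1$truth$drp_label == "none"))
  expect_true(all(is.na(sim1$truth$tissue_absent)))
  expect_false(anyNA(sim1$prot$intensity$liver))
})

test_that("window CpG counts track the density classes and non-CpG sites are hypomethylated", {
  cfg <- sim_config(n_genes = 400, seed = 8)
  ann <- generate_annotation(cfg)
  med <- tapply(ann$truth$window_cpgs, ann$truth$density_class, median)
  expect_equal(unname(med["low"]), 10, tolerance = 0.2)
  expect_equal(unname(med["high"]), 47, tolerance = 0.05)
  met <- generate_methylome(cfg, ann)
  non_cpg <- met$counts$sites$context != "CpG"
  for (tissue in c("liver", "muscle")) {
    r <- pooled_ratio(met$counts, tissue)
    expect_lt(mean(r[non_cpg], na.rm = TRUE), 0.1)
  }
})

test_that("minus-strand geometry emits the annotated 3' end as the TSS", {
  cfg <- sim_config(n_genes = 40, seed = 9)
  ann <- generate_annotation(cfg)
  minus <- ann$truth[ann$truth$strand == "-", ][1, ]
  tx <- ann$models$transcripts
  unit <- tx[tx$gene_id == minus$gene_id, ][1, ]
  expect_equal(unit$tss, unit$end - 1L)
  w <- tss_window(ann$models, 200, 400)
  ww <- w[w$transcript_id == unit$transcript_id, ]
  expect_equal(ww$start, unit$end - 400L)
  expect_equal(ww$end, unit$end + 200L)
})

test_that("pooled window ratios are bimodal and anticorrelated with expression", {
  cfg <- sim_config(n_genes = 400, seed = 1)
  sim <- simulate_study(cfg)
  wm <- window_methylation(sim$meth, sim$annotation$models)
  pooled <- wm$mean_ratio[!is.na(wm$mean_ratio)]
  st <- silverman_test(pooled, k_modes = 1, B = 200, seed = 1)
  expect_lt(st$p, 0.01)
  # per-tissue Spearman between window ratio and log TPM is clearly negative
  tpm_mean <- rowMeans(sim$rna$tpm$liver)
  wl <- wm[wm$tissue == "liver", ]
  rho <- spearman_rho(log1p(tpm_mean[wl$transcript_id]), wl$mean_ratio)$rho
  expect_lt(rho, -0.2)
})

test_that("planted peaks follow the binding, accessibility, and island rules", {
  cfg <- sim_config(n_genes = 300, seed = 10)
  sim <- simulate_study(cfg)
  tr <- sim$truth
  pk <- sim$peaks$tf_peaks
  dtg <- tr[!is.na(tr$dtg_tf), ]
  for (i in seq_len(min(nrow(dtg), 20))) {
    hits <- pk$tf == dtg$dtg_tf[i] & pk$chrom == dtg$chrom[i] &
      pk$start < dtg$tss[i] + 1000 & pk$end > dtg$tss[i] - 1000
    expect_equal(sort(unique(pk$tissue[hits])), dtg$dtg_tissue[i])
  }
  # ATAC covers hypomethylated genes more often than hypermethylated genes
  mid <- 0.45
  for (tissue in c("liver", "muscle")) {
    atac <- sim$peaks$atac[[tissue]]
    hypo <- tr$planted_meth_liver < mid
    if (tissue == "muscle") hypo <- tr$planted_meth_muscle < mid
    covered <- vapply(seq_len(nrow(tr)), function(i) {
      any(atac$chrom == tr$chrom[i] & atac$start < tr$tss[i] + 400 &
            atac$end > tr$tss[i] - 200)
    }, TRUE)
    expect_gt(mean(covered[hypo]), mean(covered[!hypo]))
  }
  # CpG islands sit mostly on high-density genes
  cgi <- sim$peaks$cgi
  on_cgi <- vapply(seq_len(nrow(tr)), function(i) {
    any(cgi$chrom == tr$chrom[i] & cgi$start < tr$tss[i] + 400 &
          cgi$end > tr$tss[i] - 200)
  }, TRUE)
  expect_gt(mean(on_cgi[tr$density_class == "high"]),
            mean(on_cgi[tr$density_class == "low"]))
})

test_that("written bundles round-trip losslessly through the readers", {
  cfg <- sim_config(n_genes = 50, seed = 12)
  sim <- simulate_study(cfg)
  dir <- file.path(tempdir(), "roundtrip")
  write_bundle(sim, dir)
  # methylation tables
  files <- list(liver = file.path(dir, sprintf("meth_liver_rep%d.tsv", 1:3)),
                muscle = file.path(dir, sprintf("meth_muscle_rep%d.tsv", 1:3)))
  mc <- read_meth_tables(files)
  ord <- order(sim$meth$sites$chrom, sim$meth$sites$pos)
  expect_equal(mc$meth$liver, sim$meth$meth$liver[ord, ], ignore_attr = TRUE)
  expect_equal(mc$total$muscle, sim$meth$total$muscle[ord, ],
               ignore_attr = TRUE)
  # count matrices
  cnt <- read_matrix_tsv(file.path(dir, "rna_counts_liver.tsv"))
  expect_equal(cnt, sim$rna$counts$liver, ignore_attr = FALSE,
               tolerance = 1e-12)
  # protein matrices preserve NAs
  prot <- read_matrix_tsv(file.path(dir, "protein_muscle.tsv"))
  expect_identical(is.na(prot), is.na(sim$prot$intensity$muscle))
  # GTF: same transcripts and TSSs
  models <- read_gene_models(file.path(dir, "annotation.gtf"))
  expect_setequal(models$transcripts$transcript_id,
                  sim$annotation$models$transcripts$transcript_id)
  m0 <- sim$annotation$models$transcripts
  expect_equal(models$transcripts$tss[match(m0$transcript_id,
                                            models$transcripts$transcript_id)],
               m0$tss)
  # GMT
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_identical(sets$TOP_motif, sim$gene_sets$sets$TOP_motif)
  # BED peaks (0-based half-open preserved)
  atac <- read_peaks(file.path(dir, "peaks", "atac_liver.bed"))
  expect_setequal(paste(atac$chrom, atac$start, atac$end),
                  paste(sim$peaks$atac$liver$chrom, sim$peaks$atac$liver$start,
                        sim$peaks$atac$liver$end))
  unlink(dir, recursive = TRUE)
})

test_that("minus-strand CpG records collapse onto the plus-strand dyad position", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(chrom = "chr1", pos = c(100L, 101L, 200L),
                   strand = c("+", "-", "+"), context = "CpG",
                   n_meth = c(3L, 2L, 5L), n_total = c(10L, 8L, 10L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mc <- read_meth_tables(list(liver = path, muscle = path))
  expect_equal(mc$sites$pos, c(100L, 200L))
  expect_equal(mc$meth$liver[, 1], c(5L, 5L))
  expect_equal(mc$total$liver[, 1], c(18L, 10L))
})
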