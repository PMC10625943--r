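test_that("GTF parsing converts coordinates and derives strand-aware regions", {
  path <- write_test_gtf()
  models <- read_gene_models(path)
  tA <- models$transcripts[models$transcripts$transcript_id == "tA", ]
  expect_equal(tA$tss, 99)
  expect_equal(tA$start, 99)
  expect_equal(tA$end, 400)
  tB <- models$transcripts[models$transcripts$transcript_id == "tB", ]
  expect_equal(tB$tss, 399)
  reg <- gene_regions(models)
  fe <- reg[reg$transcript_id == "tA" & reg$region == "first_exon", ]
  expect_equal(c(fe$start, fe$end), c(99, 200))
  fi <- reg[reg$transcript_id == "tA" & reg$region == "first_intron", ]
  expect_equal(c(fi$start, fi$end), c(200, 299))
  # on the minus strand the first exon is the rightmost one
  feB <- reg[reg$transcript_id == "tB" & reg$region == "first_exon", ]
  expect_equal(c(feB$start, feB$end), c(299, 400))
  # promoter excludes the TSS base and is upstream in transcription direction
  prA <- reg[reg$transcript_id == "tA" & reg$region == "promoter", ]
  expect_equal(prA$end, 99)
  prB <- reg[reg$transcript_id == "tB" & reg$region == "promoter", ]
  expect_equal(prB$start, 400)
})

test_that("BED12 input yields the same gene model as GTF", {
  gtf <- write_test_gtf()
  bed <- tempfile(fileext = ".bed")
  # same two transcripts as BED12 (0-based half-open, blocks relative)
  writeLines(c(
    "chr1\t99\t400\ttA\t0\t+\t99\t400\t0\t2\t101,101\t0,200",
    "chr1\t99\t400\ttB\t0\t-\t99\t400\t0\t2\t101,101\t0,200"
  ), bed)
  mg <- read_gene_models(gtf)
  mb <- read_gene_models(bed, format = "bed12")
  for (id in c("tA", "tB")) {
    a <- mg$exons[mg$exons$transcript_id == id, c("start", "end", "strand")]
    b <- mb$exons[mb$exons$transcript_id == id, c("start", "end", "strand")]
    expect_equal(a[order(a$start), ], b[order(b$start), ],
                 ignore_attr = TRUE)
    expect_equal(mg$transcripts$tss[mg$transcripts$transcript_id == id],
                 mb$transcripts$tss[mb$transcripts$transcript_id == id])
  }
})

test_that("tss_window is strand-symmetric, half-open, and clips at zero", {
  tr <- simple_exons(c("p", "m"), "chr1", c("+", "-"),
                     c(1000, 500), c(2000, 1001))
  models <- make_models(tr)
  w <- tss_window(models, 200, 400)
  wp <- w[w$transcript_id == "p", ]
  expect_equal(c(wp$start, wp$end), c(800, 1400))
  wm <- w[w$transcript_id == "m", ]
  # minus strand, tss = 1000: mirrored half-open window of the same length
  expect_equal(wm$end - wm$start, 600)
  expect_equal(c(wm$start, wm$end), c(601, 1201))
  # degenerate (0, 0) window assigns no CpGs
  w0 <- tss_window(models, 0, 0)
  expect_true(all(w0$end - w0$start == 0))
  cpgs <- data.frame(chrom = "chr1", pos = c(999, 1000, 1001))
  expect_equal(nrow(assign_cpgs_to_windows(cpgs, w0)), 0)
  # clipping
  near0 <- make_models(simple_exons("z", "chr1", "+", 50, 300))
  wz <- tss_window(near0, 200, 400)
  expect_true(wz$clipped)
  expect_equal(wz$start, 0)
})

test_that("window offsets are strand-aware and boundaries half-open", {
  tr <- simple_exons(c("p", "m"), "chr1", c("+", "-"),
                     c(1000, 5000), c(2000, 6000))
  models <- make_models(tr)
  w <- tss_window(models, 200, 400)
  # minus-strand gene with annotation end 6000: tss = 5999,
  # window covers genomic [5600, 6200)
  expect_equal(w$start[w$transcript_id == "m"], 5600)
  expect_equal(w$end[w$transcript_id == "m"], 6200)
  cpgs <- data.frame(chrom = "chr1",
                     pos = c(1399, 1400, 800, 799, 5600, 5599, 6199))
  asn <- assign_cpgs_to_windows(cpgs, w)
  got <- asn[order(asn$site), ]
  # +399 inside, +400 outside (half-open); upstream edge -200 inside
  expect_equal(got$site, c(1, 3, 5, 7))
  expect_equal(got$offset, c(399, -200, 399, -200))
})

test_that("merge_same_tss combines same-TSS transcripts, sums expression, and is idempotent", {
  tr <- rbind(
    simple_exons(c("t1", "t2"), "chr1", "+", c(100, 100), c(500, 900), "g1"),
    simple_exons("t3", "chr1", "+", 2000, 2500, "g2"),
    simple_exons("t4", "chr1", "+", 100, 700, "g1")
  )
  models <- make_models(tr)
  merged <- merge_same_tss(models)
  expect_equal(nrow(merged$transcripts), 2)
  unit <- merged$transcripts[merged$transcripts$tss == 100, ]
  expect_equal(sort(strsplit(unit$members, ",")[[1]]), c("t1", "t2", "t4"))
  # idempotence
  again <- merge_same_tss(merged)
  expect_equal(again$transcripts, merged$transcripts)
  # all-distinct TSSs: identity (plus members column)
  distinct <- make_models(simple_exons(c("a", "b"), "chr1", "+",
                                       c(10, 5000), c(100, 5100)))
  md <- merge_same_tss(distinct)
  expect_equal(sort(md$transcripts$transcript_id), c("a", "b"))
  # merged expression: 3 transcripts at one TSS with TPM 1, 2, 3 -> 6
  tpm <- matrix(c(1, 2, 3, 10), 4, 1,
                dimnames = list(c("t1", "t2", "t4", "t3"), "r1"))
  agg <- merge_expression(merged, tpm)
  expect_equal(agg[unit$transcript_id, 1], 6)
  expect_equal(agg["t3", 1], 10)
  agg_max <- merge_expression(merged, tpm, how = "max")
  expect_equal(agg_max[unit$transcript_id, 1], 3)
})

test_that("CpG-to-region assignment equals an exhaustive interval check and is order-invariant", {
  set.seed(5)
  tr <- simple_exons(c("g1", "g2", "g3"), c("chr1", "chr1", "chr2"),
                     c("+", "-", "+"), c(5000, 9000, 3000),
                     c(6000, 10000, 4200))
  models <- make_models(tr)
  reg <- gene_regions(models)
  cpgs <- data.frame(chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
                     pos = sample(2000:11000, 20))
  asn <- assign_cpgs_to_regions(cpgs, reg)
  # brute-force oracle: double loop over CpGs and region intervals
  oracle <- do.call(rbind, lapply(seq_len(nrow(cpgs)), function(i) {
    hit <- reg$chrom == cpgs$chrom[i] & reg$start <= cpgs$pos[i] &
      cpgs$pos[i] < reg$end
    if (!any(hit)) return(NULL)
    data.frame(site = i, transcript_id = reg$transcript_id[hit],
               region = reg$region[hit], stringsAsFactors = FALSE)
  }))
  key <- function(d) sort(paste(d$site, d$transcript_id, d$region))
  expect_equal(key(asn), key(oracle))
  # CpG far from any gene is unmapped
  far <- assign_cpgs_to_regions(data.frame(chrom = "chr1", pos = 100000L), reg)
  expect_equal(nrow(far), 0)
  # invariance under permutation of region rows
  perm <- reg[sample(nrow(reg)), ]
  expect_equal(key(assign_cpgs_to_regions(cpgs, perm)), key(asn))
  # chromosome mismatch is an error
  expect_error(assign_cpgs_to_regions(data.frame(chrom = "chrX", pos = 1L), reg),
               "mismatch")
})

test_that("per-gene promoter, first exon, and first intron are disjoint", {
  cfg <- sim_config(n_genes = 40, seed = 3)
  ann <- generate_annotation(cfg)
  reg <- gene_regions(ann$models)
  for (id in unique(reg$transcript_id)) {
    sub <- reg[reg$transcript_id == id &
                 reg$region %in% c("promoter", "first_exon", "first_intron"), ]
    covered <- unlist(apply(sub, 1, function(r) {
      seq(as.integer(r["start"]), as.integer(r["end"]) - 1L)
    }))
    expect_equal(anyDuplicated(covered), 0)
  }
})
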