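make_binding_models <- function(n = 6, spacing = 10000) {
  tr <- simple_exons(sprintf("g%02d", 1:n), "chr1", "+",
                     (1:n) * spacing, (1:n) * spacing + 1000)
  make_models(tr)
}

test_that("assign_binding uses half-open TSS flanks and collapses multiple peaks", {
  models <- make_binding_models(3)
  tss <- models$transcripts$tss
  peaks <- data.frame(
    chrom = "chr1",
    start = c(tss[1] - 50, tss[2] - 1100, tss[3] - 30, tss[3] + 10),
    end = c(tss[1] + 50, tss[2] - 1000, tss[3] + 10, tss[3] + 60),
    tf = "A", tissue = "liver", stringsAsFactors = FALSE)
  bs <- assign_binding(peaks, models, flank = 1000)
  expect_equal(bs$states$state_liver, c("A", "", "A"))
  # peak ending exactly at TSS - 1000 does not reach the half-open flank
  expect_false("g02" %in% bs$bound$transcript_id)
  # brute-force all-pairs oracle
  oracle <- vapply(seq_len(3), function(i) {
    any(peaks$start < tss[i] + 1000 & peaks$end > tss[i] - 1000)
  }, TRUE)
  expect_equal(bs$states$state_liver != "", oracle)
  # invariance to peak order and to splitting a peak into adjacent halves
  bs2 <- assign_binding(peaks[sample(nrow(peaks)), ], models, flank = 1000)
  expect_equal(bs2$states, bs$states)
  split_peaks <- rbind(
    data.frame(chrom = "chr1", start = tss[1] - 50, end = tss[1], tf = "A",
               tissue = "liver"),
    data.frame(chrom = "chr1", start = tss[1], end = tss[1] + 50, tf = "A",
               tissue = "liver"),
    peaks[-1, ])
  bs3 <- assign_binding(split_peaks, models, flank = 1000)
  expect_equal(bs3$states, bs$states)
  expect_error(assign_binding(transform(peaks, chrom = "chrX"), models),
               "mismatch")
})

test_that("binding_group_tests match the Welch formula and flag planted TF effects", {
  set.seed(27)
  n <- 80
  models <- make_binding_models(n, spacing = 8000)
  tss <- models$transcripts$tss
  ids <- models$transcripts$transcript_id
  bound <- 1:20
  peaks <- data.frame(chrom = "chr1", start = tss[bound] - 100,
                      end = tss[bound] + 100, tf = "A", tissue = "liver",
                      stringsAsFactors = FALSE)
  bs <- assign_binding(peaks, models, tissues = c("liver", "muscle"))
  expr <- list(liver = setNames(c(2^6 * rep(1, 20) * exp(rnorm(20, 0, 0.2)),
                                  2^2 * exp(rnorm(60, 0, 0.2))), ids),
               muscle = setNames(2^2 * exp(rnorm(n, 0, 0.2)), ids))
  tests <- binding_group_tests(bs, expr)
  marg <- tests[tests$family == "marginal" & tests$tissue == "liver" &
                  tests$comparison == "A", ]
  expect_lt(marg$q, 0.01)
  # p equals the direct Welch formula on the same groups
  e <- log2(expr$liver + 1)
  want <- welch_oracle(e[bound], e[-bound])
  expect_equal(marg$p, want$p, tolerance = 1e-12)
  # identical distributions: no significance
  null_tests <- binding_group_tests(bs, list(
    liver = setNames(2^3 * exp(rnorm(n, 0, 0.2)), ids),
    muscle = setNames(2^3 * exp(rnorm(n, 0, 0.2)), ids)))
  expect_true(all(null_tests$q[!null_tests$skipped] > 0.01))
})

test_that("call_dtgs applies the direct and combination inference rules", {
  models <- make_binding_models(30, spacing = 8000)
  ids <- models$transcripts$transcript_id
  states <- data.frame(transcript_id = ids,
                       state_liver = "", state_muscle = "",
                       stringsAsFactors = FALSE)
  # gene 1: {A} vs {} (pair tested significant); gene 2: {A,B} vs {} with A
  # and B individually significant but the pair untested; gene 3: states
  # equal; gene 4: {C} vs {} with nothing significant
  states$state_liver[1] <- "A"
  states$state_liver[2] <- "A+B"
  states$state_liver[3] <- states$state_muscle[3] <- "A"
  states$state_liver[4] <- "C"
  binding <- structure(list(bound = NULL, states = states,
                            tissues = c("liver", "muscle"),
                            tfs = c("A", "B", "C")),
                       class = "binding_state")
  tests <- data.frame(
    family = c("pair", "marginal", "marginal", "marginal"),
    comparison = c("A|", "A", "B", "C"),
    tissue = "liver", n1 = 10, n2 = 10, t = c(8, 8, 8, 0),
    p = c(1e-8, 1e-8, 1e-8, 0.9), skipped = FALSE,
    q = c(1e-6, 1e-6, 1e-6, 0.9), stringsAsFactors = FALSE)
  out <- call_dtgs(binding, tests)
  expect_equal(out$label[1], "dtg")
  expect_equal(out$basis[1], "direct_test")
  expect_equal(out$label[2], "dtg")
  expect_equal(out$basis[2], "combination_inference")
  expect_equal(out$label[3], "non_dtg")   # equal states regardless of tests
  expect_equal(out$label[4], "non_dtg")
  expect_equal(out$differing_tfs[2], "A,B")
})

test_that("genes_with_peaks supports multi-file consistency requirements", {
  models <- make_binding_models(4)
  tss <- models$transcripts$tss
  f1 <- data.frame(chrom = "chr1", start = tss[1:2] - 10, end = tss[1:2] + 10)
  f2 <- data.frame(chrom = "chr1", start = tss[2:3] - 10, end = tss[2:3] + 10)
  both <- genes_with_peaks(list(f1, f2), models)
  expect_equal(both, "g02")
  any_of <- genes_with_peaks(list(f1, f2), models, min_files = 1)
  expect_equal(sort(any_of), c("g01", "g02", "g03"))
})

test_that("peak_class_overlap builds exact contingency tables with Fisher tails", {
  universe <- sprintf("g%03d", 1:100)
  class_a <- universe[1:30]
  s <- universe[c(1:25, 60:70)]
  res <- peak_class_overlap(class_a, s, universe, tail = "right")
  expect_equal(unname(res$table[1, 1]), 25)
  expect_equal(unname(res$table[1, 2]), 5)
  expect_equal(unname(res$table[2, 1]), 11)
  expect_equal(unname(res$table[2, 2]), 59)
  expect_equal(res$p, fisher_oracle(25, 5, 11, 59, "right"), tolerance = 1e-12)
  # S identical to the class: maximal enrichment for these margins
  res_max <- peak_class_overlap(class_a, class_a, universe, tail = "right")
  expect_equal(res_max$p, fisher_oracle(30, 0, 0, 70, "right"),
               tolerance = 1e-12)
  expect_lt(res_max$p, 1e-20)
  expect_error(peak_class_overlap(class_a, s, character(0)), "empty")
})
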