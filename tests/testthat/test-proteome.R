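# simulate intensities with known VSN parameters: noise is Gaussian in
# h-space with unit variance, so gamma is identifiable
sim_vsn_data <- function(n = 400, reps = 5, a = 0.5, b = 1e-3, gamma = 2.5,
                         mu_range = c(8, 18)) {
  mu <- runif(n, mu_range[1], mu_range[2])
  mk <- function() {
    h <- matrix(mu + rnorm(n * reps), n, reps,
                dimnames = list(sprintf("p%04d", 1:n), paste0("r", 1:reps)))
    x <- (sinh(h / gamma) - a) / b
    x
  }
  list(liver = mk(), muscle = mk())
}

test_that("detect_proteins applies the replicate-presence rule", {
  a <- matrix(c(1, 2, 3, NA, NA,
                1, 2, NA, NA, NA,
                1, 2, 3, 4, 5), 3, 5, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), NULL))
  b <- matrix(NA_real_, 3, 5, dimnames = dimnames(a))
  b[1, ] <- 1
  det <- detect_proteins(list(liver = a, muscle = b))
  expect_equal(det$detected_liver, c(TRUE, FALSE, TRUE))
  expect_equal(det$detected_muscle, c(TRUE, FALSE, FALSE))
  # 5/5 in liver, 0/5 in muscle: liver_only candidate
  expect_true(det$detected_liver[3] & !det$detected_muscle[3])
  expect_error(detect_proteins(list(liver = a, muscle = b), n_reps = 4),
               "mismatch")
})

test_that("the arcsinh transform is increasing with the documented asymptote", {
  params <- list(a = 0.3, b = 2, gamma = 1.5)
  x <- seq(0, 100, length.out = 200)
  h <- vsn_transform(x, params)
  expect_true(all(diff(h) > 0))
  expect_equal(vsn_transform(0, list(a = 0, b = 1, gamma = 1)), 0)
  # h(x) ~ gamma * (log x + log 2b) for large x
  big <- 1e8
  expect_lt(abs(vsn_transform(big, params) -
                  params$gamma * (log(big) + log(2 * params$b))), 1e-6)
})

test_that("vsn_fit recovers the gain and decouples variance from mean", {
  set.seed(21)
  dat <- sim_vsn_data(n = 400, a = 0.5, b = 1e-3, gamma = 2.5)
  fit <- vsn_fit(dat)
  expect_lt(abs(fit$gamma - 2.5) / 2.5, 0.10)
  # after transformation, per-protein |residual| is independent of the mean
  h <- fit$transformed$liver
  mu <- rowMeans(h)
  res <- abs(h - mu)[, 1]
  expect_lt(abs(cor(mu, res, method = "spearman")), 0.1)
  expect_error(vsn_fit(list(liver = dat$liver[1:5, ], muscle = dat$muscle[1:5, ])),
               ">= 20")
})

test_that("moderated_test reduces to the pooled t at d0 = 0 and moderates otherwise", {
  set.seed(22)
  n <- 60
  xa <- matrix(rnorm(n * 5, 10), n, 5, dimnames = list(sprintf("p%03d", 1:n), NULL))
  xb <- matrix(rnorm(n * 5, 10), n, 5, dimnames = dimnames(xa))
  res0 <- moderated_test(list(liver = xa, muscle = xb), prior_df = 0)
  # oracle: ordinary pooled-variance two-sample t
  i <- 7
  sp2 <- (sum((xa[i, ] - mean(xa[i, ]))^2) + sum((xb[i, ] - mean(xb[i, ]))^2)) / 8
  t_or <- (mean(xa[i, ]) - mean(xb[i, ])) / sqrt(sp2 * (2 / 5))
  expect_equal(res0$t[res0$protein_id == sprintf("p%03d", i)], t_or,
               tolerance = 1e-12)
  expect_equal(res0$df[1], 8)
  # moment-matched moderation pulls variances together and increases df
  res <- moderated_test(list(liver = xa, muscle = xb))
  expect_gt(attr(res, "d0"), 0)
  expect_true(all(res$df > 8))
})

test_that("moderated_test matches limma's moderated t on complete data", {
  skip_if_not_installed("limma")
  set.seed(23)
  n <- 200
  xa <- matrix(rnorm(n * 5, 10, 0.7), n, 5,
               dimnames = list(sprintf("p%03d", 1:n), paste0("la", 1:5)))
  xb <- matrix(rnorm(n * 5, 10, 0.7), n, 5, dimnames = list(rownames(xa), paste0("lb", 1:5)))
  xa[1:20, ] <- xa[1:20, ] + 1.5
  res <- moderated_test(list(liver = xa, muscle = xb))
  design <- cbind(1, rep(c(1, 0), each = 5))
  fit <- limma::eBayes(limma::lmFit(cbind(xa, xb), design))
  tl <- fit$t[, 2]
  expect_gt(cor(res$t, tl), 0.999)
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 0.3)
})

test_that("moderated_test recovers planted 3-fold shifts with controlled FDR", {
  set.seed(24)
  n <- 500
  base <- runif(n, 8, 16)
  xa <- matrix(base + rnorm(n * 5, 0, 0.4), n, 5,
               dimnames = list(sprintf("p%04d", 1:n), NULL))
  xb <- matrix(base + rnorm(n * 5, 0, 0.4), n, 5, dimnames = dimnames(xa))
  idx <- 1:50
  xa[idx, ] <- xa[idx, ] + log(3)   # 3-fold on the natural-log scale
  res <- moderated_test(list(liver = xa, muscle = xb))
  called <- res$q < 0.01 & res$diff > 0
  expect_gte(sum(called[idx]) / 50, 0.85)
  expect_lte(sum(called[-idx]) / max(sum(called), 1), 0.05)
})

test_that("call_deps labels dominant, only-in-one-tissue, and non-DEP proteins", {
  det <- data.frame(protein_id = c("p1", "p2", "p3", "p4"),
                    n_liver = c(5, 5, 0, 5), detected_liver = c(TRUE, TRUE, FALSE, TRUE),
                    n_muscle = c(5, 0, 5, 5), detected_muscle = c(TRUE, FALSE, TRUE, TRUE),
                    stringsAsFactors = FALSE)
  attr(det, "tissues") <- c("liver", "muscle")
  mod <- data.frame(protein_id = c("p1", "p4"), mean_liver = c(10, 10),
                    mean_muscle = c(8, 10), diff = c(2, 0), t = c(8, 0),
                    df = 10, p = c(1e-5, 1), q = c(0.005, 0.5),
                    stringsAsFactors = FALSE)
  attr(mod, "tissues") <- c("liver", "muscle")
  out <- call_deps(det, mod)
  expect_equal(out$label, c("liver", "liver_only", "muscle_only", "non_dep"))
})

test_that("protein_mrna_ratio is the log of mean intensity over TPM with missing rules", {
  intens <- list(liver = matrix(1000, 1, 5, dimnames = list("p1", NULL)),
                 muscle = matrix(1000, 1, 5, dimnames = list("p1", NULL)))
  tpm <- list(liver = c(g1 = 10), muscle = c(g1 = 0))
  map <- data.frame(protein_id = "p1", gene_id = "g1")
  det <- detect_proteins(intens)
  r <- protein_mrna_ratio(intens, tpm, map, det)
  expect_equal(r$ratio_liver, log(100))
  expect_true(is.na(r$ratio_muscle))  # TPM 0 -> missing
  # doubling both numerator and denominator leaves the ratio unchanged
  intens2 <- lapply(intens, function(m) m * 2)
  tpm2 <- lapply(tpm, function(v) v * 2)
  r2 <- protein_mrna_ratio(intens2, tpm2, map, det)
  expect_equal(r2$ratio_liver, r$ratio_liver)
})

test_that("call_drps flags leave-one-out MSE improvements with direction by residual", {
  # all points exactly on a line: no DRPs
  x <- seq(-2, 2, length.out = 50)
  ratios <- data.frame(protein_id = sprintf("p%02d", 1:50),
                       gene_id = sprintf("g%02d", 1:50),
                       ratio_liver = 1 + 0.5 * x, ratio_muscle = x,
                       stringsAsFactors = FALSE)
  attr(ratios, "tissues") <- c("liver", "muscle")
  expect_true(all(call_drps(ratios)$label == "none"))
  # one planted outlier far off the line among collinear + noise points
  set.seed(25)
  n <- 100
  x <- rnorm(n)
  y <- x + rnorm(n, 0, 0.1)
  y[1] <- x[1] + 5 * 0.1 * 10   # 5 sigma above
  ratios2 <- data.frame(protein_id = sprintf("p%03d", 1:n),
                        gene_id = sprintf("g%03d", 1:n),
                        ratio_liver = y, ratio_muscle = x,
                        stringsAsFactors = FALSE)
  attr(ratios2, "tissues") <- c("liver", "muscle")
  out <- call_drps(ratios2)
  expect_equal(out$label[1], "liver")
  # shifting one tissue by a constant changes no flags
  ratios3 <- ratios2
  ratios3$ratio_liver <- ratios3$ratio_liver + 3
  expect_equal(call_drps(ratios3)$label, out$label)
  # shuffled-pairs null: flags bounded by the rule's Gaussian operating
  # point (|r| > RMSE, i.e. about 16% per side) and symmetric in direction
  set.seed(26)
  ratios4 <- ratios2
  ratios4$ratio_liver <- rnorm(n)
  out4 <- call_drps(ratios4)
  expect_lt(mean(out4$label == "liver"), 0.20)
  expect_lt(mean(out4$label == "muscle"), 0.20)
  expect_lt(abs(mean(out4$label == "liver") - mean(out4$label == "muscle")),
            0.10)
  expect_error(call_drps(ratios2[1:5, ]), ">= 10")
})

test_that("top_motif_overlap counts equal an exhaustive membership check", {
  drps <- data.frame(protein_id = sprintf("p%02d", 1:20),
                     gene_id = sprintf("g%02d", 1:20),
                     x = rnorm(20), y = rnorm(20), residual = rnorm(20),
                     label = c(rep("liver", 5), rep("none", 15)),
                     stringsAsFactors = FALSE)
  attr(drps, "tissues") <- c("liver", "muscle")
  set <- c("g01", "g02", "g03", "g10", "g11")
  out <- top_motif_overlap(drps, set)
  lv <- out[out$direction == "liver", ]
  expect_equal(lv$in_set_drp, 3)
  expect_equal(lv$in_set_other, 2)
  expect_equal(lv$out_set_drp, 2)
  expect_equal(lv$out_set_other, 13)
  # disjoint set: zero overlap
  out0 <- top_motif_overlap(drps, c("zz1", "zz2"))
  expect_true(all(out0$in_set_drp == 0))
  expect_error(top_motif_overlap(drps, character(0)), "empty")
})
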