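#' Expression filter: present in enough replicates
#'
#' A gene counts as expressed when its read count is positive in at least
#' `min_reps` replicates in at least one tissue.
#'
#' @param counts named list of two count matrices (genes x replicates,
#'   shared rownames).
#' @param min_reps minimum number of positive replicates.
#' @param n_reps optional expected replicate count per tissue; a mismatch
#'   with the matrices is an error.
#' @return named logical vector (one per gene).
#' @export
filter_expressed <- function(counts, min_reps = 6, n_reps = NULL) {
  stopifnot(length(counts) == 2,
            identical(rownames(counts[[1]]), rownames(counts[[2]])))
  if (!is.null(n_reps)) {
    if (any(vapply(counts, ncol, 1L) != n_reps)) {
      stop("replicate count mismatch: expected ", n_reps, " columns per tissue")
    }
  }
  pos <- lapply(counts, function(m) rowSums(m > 0))
  stats::setNames(pos[[1]] >= min_reps | pos[[2]] >= min_reps,
                  rownames(counts[[1]]))
}

# median-of-ratios size factors (reference = geometric mean over genes with
# all-positive counts), rescaled to geometric mean 1
.size_factors <- function(mat) {
  pos <- rowSums(mat == 0) == 0
  if (sum(pos) < 10) {
    sf <- colSums(mat) / mean(colSums(mat))
    return(sf)
  }
  lref <- rowMeans(log(mat[pos, , drop = FALSE]))
  sf <- apply(mat[pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - lref))
  })
  sf / exp(mean(log(sf)))
}

.nb_ll_group <- function(y, sf, size) {
  # profile NB log-likelihood at the MLE of the group mean (offsets sf)
  if (sum(y) == 0) return(0)  # mu -> 0 gives dnbinom(0, mu=0) = 1
  f <- function(lq) -sum(stats::dnbinom(y, size = size, mu = exp(lq) * sf, log = TRUE))
  q0 <- sum(y) / sum(sf)
  opt <- stats::optimize(f, interval = log(q0) + c(-4, 4))
  -opt$objective
}

#' Two-group negative-binomial differential expression test
#'
#' In-repo two-group NB test: median-of-ratios normalization of library
#' sizes, tagwise method-of-moments dispersion shrunk toward a fitted
#' mean-dispersion trend, a likelihood-ratio statistic referred to
#' chi-square(1), and Benjamini-Hochberg q-values.  Genes pass through the
#' expression filter first; labels require `q < q_cut` and take the
#' fold-change sign.  Parity with dedicated count-model packages is claimed
#' at the level of operating characteristics (FDR control, power), not
#' per-gene p-values.
#'
#' @param counts named list of two count matrices (genes x replicates); the
#'   first element is the "numerator" tissue for log2 fold-changes.
#' @param expressed optional logical vector from [filter_expressed()];
#'   computed with defaults when missing.
#' @param q_cut q-value cutoff for labels.
#' @param prior_df weight (pseudo-degrees of freedom) of the dispersion
#'   trend in the tagwise shrinkage.
#' @param min_reps expression-filter threshold when `expressed` is missing.
#' @return data.frame per gene: `gene_id`, `expressed`, `log2fc`
#'   (first/second tissue, 0.5 pseudo-count, reporting only), `statistic`,
#'   `p`, `q`, `label` (tissue name or `"none"`), `dispersion`.
#' @export
deg_test <- function(counts, expressed = NULL, q_cut = 0.01, prior_df = 20,
                     min_reps = 6) {
  stopifnot(length(counts) == 2)
  tissues <- names(counts)
  if (is.null(tissues)) tissues <- c("A", "B")
  if (any(vapply(counts, ncol, 1L) < 2)) {
    stop("each tissue needs >= 2 replicates (dispersion unidentifiable)")
  }
  if (is.null(expressed)) expressed <- filter_expressed(counts, min_reps)
  ids <- rownames(counts[[1]])
  ya <- counts[[1]][expressed, , drop = FALSE]
  yb <- counts[[2]][expressed, , drop = FALSE]
  all_counts <- cbind(ya, yb)
  sf <- .size_factors(all_counts)
  sfa <- sf[seq_len(ncol(ya))]; sfb <- sf[ncol(ya) + seq_len(ncol(yb))]
  na_ <- ncol(ya); nb_ <- ncol(yb)
  norm_a <- sweep(ya, 2, sfa, "/"); norm_b <- sweep(yb, 2, sfb, "/")
  mu_a <- rowMeans(norm_a); mu_b <- rowMeans(norm_b)
  v_a <- apply(norm_a, 1, stats::var); v_b <- apply(norm_b, 1, stats::var)
  # method-of-moments tagwise dispersion, pooled over groups
  phi_of <- function(v, m) ifelse(m > 0, (v - m) / m^2, 0)
  w_a <- na_ - 1; w_b <- nb_ - 1
  phi_raw <- (w_a * phi_of(v_a, mu_a) + w_b * phi_of(v_b, mu_b)) / (w_a + w_b)
  phi_raw <- pmax(phi_raw, 0)
  mu_bar <- (mu_a + mu_b) / 2
  # mean-dispersion trend phi ~ a0 + a1/mu, coefficients clamped >= 0
  okt <- mu_bar > 0
  tr <- tryCatch(stats::lm(phi_raw[okt] ~ I(1 / mu_bar[okt]))$coefficients,
                 error = function(e) c(mean(phi_raw[okt]), 0))
  tr[!is.finite(tr)] <- 0
  phi_trend <- pmax(tr[1], 0) + pmax(tr[2], 0) / pmax(mu_bar, 1e-8)
  d <- w_a + w_b
  phi_use <- pmax((d * phi_raw + prior_df * phi_trend) / (d + prior_df), 1e-6)
  n_genes <- nrow(ya)
  lr <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    size <- 1 / phi_use[i]
    ll1 <- .nb_ll_group(ya[i, ], sfa, size) + .nb_ll_group(yb[i, ], sfb, size)
    ll0 <- .nb_ll_group(c(ya[i, ], yb[i, ]), c(sfa, sfb), size)
    lr[i] <- max(2 * (ll1 - ll0), 0)
  }
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  q <- bh_adjust(p)
  log2fc <- log2((mu_a + 0.5) / (mu_b + 0.5))
  label <- ifelse(q < q_cut, ifelse(log2fc > 0, tissues[1], tissues[2]), "none")
  out <- data.frame(
    gene_id = ids, expressed = as.logical(expressed),
    log2fc = NA_real_, statistic = NA_real_, p = NA_real_, q = NA_real_,
    label = "none", dispersion = NA_real_, stringsAsFactors = FALSE
  )
  idx <- match(rownames(ya), ids)
  out$log2fc[idx] <- log2fc
  out$statistic[idx] <- lr
  out$p[idx] <- p
  out$q[idx] <- q
  out$label[idx] <- label
  out$dispersion[idx] <- phi_use
  attr(out, "tissues") <- tissues
  attr(out, "size_factors") <- sf
  out
}

#' Correlation of methylation and expression fold-changes over DEGs
#'
#' Pearson correlation between `log2(window methylation ratio A / B)` and
#' `log2(expression A / B)` across DEGs with valid (positive) window ratios
#' in both tissues.
#'
#' @param degs data.frame from [deg_test()] (DEG rows are `label != "none"`).
#' @param window_meth long window-methylation data.frame
#'   ([window_methylation()]), covering both tissues.
#' @return list with `r`, `p`, `n`, and the per-gene data.frame `data`
#'   (`gene_id`, `log2fc_expr`, `log2fc_meth`).
#' @export
fc_methylation_correlation <- function(degs, window_meth) {
  tissues <- attr(degs, "tissues")
  wa <- window_meth[window_meth$tissue == tissues[1], ]
  wb <- window_meth[window_meth$tissue == tissues[2], ]
  deg <- degs[degs$label != "none" & !is.na(degs$q), , drop = FALSE]
  ra <- wa$mean_ratio[match(deg$gene_id, wa$transcript_id)]
  rb <- wb$mean_ratio[match(deg$gene_id, wb$transcript_id)]
  ok <- !is.na(ra) & !is.na(rb) & ra > 0 & rb > 0
  if (sum(ok) < 3) stop("fewer than 3 DEGs with valid window ratios in both tissues")
  lfc_meth <- log2(ra[ok] / rb[ok])
  lfc_expr <- deg$log2fc[ok]
  ct <- pearson_r(lfc_expr, lfc_meth)
  list(r = ct$r, p = ct$p, n = ct$n,
       data = data.frame(gene_id = deg$gene_id[ok],
                         log2fc_expr = lfc_expr, log2fc_meth = lfc_meth,
                         stringsAsFactors = FALSE))
}
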