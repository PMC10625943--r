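#' Methylation count container
#'
#' Bundles per-cytosine methylation counts for two tissues with replicate
#' structure. `sites` holds one row per cytosine (position 0-based, context
#' `CpG`/`CHG`/`CHH`); `meth` and `total` are per-tissue matrices
#' (sites x replicates) of methylated and total read counts.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`, `context`.
#' @param meth,total named lists (one entry per tissue) of integer matrices,
#'   rows aligned with `sites`.
#' @return object of class `meth_counts`.
#' @export
meth_counts <- function(sites, meth, total) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "context") %in% names(sites)),
            identical(names(meth), names(total)))
  for (tissue in names(meth)) {
    stopifnot(nrow(meth[[tissue]]) == nrow(sites),
              nrow(total[[tissue]]) == nrow(sites),
              all(meth[[tissue]] <= total[[tissue]], na.rm = TRUE),
              all(meth[[tissue]] >= 0, na.rm = TRUE))
  }
  structure(list(sites = sites, meth = meth, total = total),
            class = "meth_counts")
}

#' @export
print.meth_counts <- function(x, ...) {
  cat("meth_counts:", nrow(x$sites), "sites;",
      paste(sprintf("%s (%d reps)", names(x$meth),
                    vapply(x$meth, ncol, 1L)), collapse = ", "), "\n")
  invisible(x)
}

#' Tissue names of a methylation count container
#' @param counts a `meth_counts` object.
#' @export
meth_tissues <- function(counts) names(counts$meth)

#' Replicate-pooled methylation ratio per site
#'
#' Sum of methylated counts over replicates divided by the sum of total
#' counts.  Sites whose pooled coverage falls below `min_coverage` get `NA`
#' (missing is a value, not an error).
#'
#' @param counts a `meth_counts` object.
#' @param tissue tissue name.
#' @param min_coverage minimum pooled total reads for a valid ratio.
#' @return numeric vector (one per site) in \[0, 1\] or `NA`.
#' @export
pooled_ratio <- function(counts, tissue, min_coverage = 5) {
  m <- rowSums(counts$meth[[tissue]], na.rm = TRUE)
  t <- rowSums(counts$total[[tissue]], na.rm = TRUE)
  out <- ifelse(t >= min_coverage & t > 0, m / t, NA_real_)
  out
}

#' Mean TSS-window methylation per gene and tissue
#'
#' Assigns CpG-context sites to strand-aware TSS windows and averages the
#' replicate-pooled per-CpG ratios within each window.
#'
#' @param counts a `meth_counts` object.
#' @param models a `gene_models` object.
#' @param upstream,downstream window extents around the TSS (bp).
#' @param min_coverage per-site pooled coverage threshold.
#' @return data.frame `transcript_id`, `tissue`, `mean_ratio`, `n_cpg`
#'   (covered CpGs contributing to the mean; 0 with `NA` ratio when none).
#' @export
window_methylation <- function(counts, models, upstream = 200,
                               downstream = 400, min_coverage = 5) {
  win <- tss_window(models, upstream, downstream)
  is_cpg <- counts$sites$context == "CpG"
  sites <- counts$sites[is_cpg, , drop = FALSE]
  idx_map <- which(is_cpg)
  asn <- assign_cpgs_to_windows(sites, win)
  tr_ids <- win$transcript_id
  out <- lapply(meth_tissues(counts), function(tissue) {
    ratio_all <- pooled_ratio(counts, tissue, min_coverage)
    r <- ratio_all[idx_map[asn$site]]
    ok <- !is.na(r)
    g <- factor(asn$transcript_id[ok], levels = tr_ids)
    sums <- rowsum(r[ok], g)[, 1]
    ns <- as.integer(rowsum(rep(1, sum(ok)), g)[, 1])
    data.frame(transcript_id = tr_ids, tissue = tissue,
               mean_ratio = ifelse(ns > 0, sums / pmax(ns, 1), NA_real_),
               n_cpg = ns, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean region methylation per gene and tissue
#'
#' @param counts a `meth_counts` object.
#' @param regions data.frame from [gene_regions()].
#' @param tissue tissue name.
#' @param min_coverage per-site pooled coverage threshold.
#' @return data.frame `transcript_id`, `region`, `mean_ratio`, `n_cpg`.
#' @export
region_methylation <- function(counts, regions, tissue, min_coverage = 5) {
  is_cpg <- counts$sites$context == "CpG"
  sites <- counts$sites[is_cpg, , drop = FALSE]
  idx_map <- which(is_cpg)
  asn <- assign_cpgs_to_regions(sites, regions)
  ratio_all <- pooled_ratio(counts, tissue, min_coverage)
  r <- ratio_all[idx_map[asn$site]]
  ok <- !is.na(r)
  key <- paste(asn$transcript_id, asn$region, sep = "\r")[ok]
  sums <- rowsum(r[ok], key)
  ns <- rowsum(rep(1, sum(ok)), key)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  data.frame(
    transcript_id = vapply(parts, `[`, "", 1),
    region = vapply(parts, `[`, "", 2),
    mean_ratio = sums[, 1] / ns[, 1],
    n_cpg = as.integer(ns[, 1]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Expression deciles versus region methylation
#'
#' Splits genes into ten equal-size sets by expression and reports the
#' per-decile distribution of region methylation ratios, plus the Spearman
#' correlation (with t-approximation p-value) between per-gene expression
#' and per-gene region mean methylation.
#'
#' @param expression named numeric vector of per-gene expression (e.g. TPM).
#' @param region_ratio named numeric vector of per-gene region mean
#'   methylation ratios (names matched against `expression`).
#' @param n_deciles number of expression bins (default 10).
#' @return list with `deciles` (data.frame: `decile`, `n`, `median_ratio`,
#'   `mean_ratio`), `assignment` (named decile per gene), `rho`, `p`, `n`.
#' @export
region_decile_correlation <- function(expression, region_ratio, n_deciles = 10) {
  common <- intersect(names(expression), names(region_ratio))
  common <- common[is.finite(expression[common]) & is.finite(region_ratio[common])]
  if (length(common) < n_deciles) {
    stop("need at least ", n_deciles, " genes with expression and methylation")
  }
  e <- expression[common]; m <- region_ratio[common]
  dec <- ceiling(rank(e, ties.method = "first") / (length(e) / n_deciles))
  dec <- pmin(dec, n_deciles)
  by_dec <- split(m, dec)
  deciles <- data.frame(
    decile = as.integer(names(by_dec)),
    n = lengths(by_dec),
    median_ratio = vapply(by_dec, stats::median, numeric(1)),
    mean_ratio = vapply(by_dec, mean, numeric(1)),
    row.names = NULL
  )
  ct <- spearman_rho(e, m)
  list(deciles = deciles, assignment = stats::setNames(dec, common),
       rho = ct$rho, p = ct$p, n = ct$n)
}

#' Sliding-window methylation-expression correlation scan around the TSS
#'
#' For each fixed-width bin of strand-aware TSS offsets, computes the
#' Spearman correlation between per-gene expression and the bin's mean
#' methylation ratio over genes with at least one covered CpG in the bin.
#' Also reports the bin minimizing rho and the longest contiguous run of
#' bins with p below `p_cut`.
#'
#' @param expression named numeric vector of per-gene expression.
#' @param counts a `meth_counts` object.
#' @param models a `gene_models` object.
#' @param tissue tissue name.
#' @param win bin width in bp.
#' @param upstream,downstream scan range (bp before / after the TSS).
#' @param p_cut significance cutoff defining the significant range.
#' @param min_coverage per-site pooled coverage threshold.
#' @return list with `profile` (data.frame `bin_start`, `bin_end`, `rho`,
#'   `p`, `n_genes`; offsets strand-aware, bin_start inclusive), `argmin`
#'   (offset range of the most negative rho), `significant_range` (offset
#'   range of the longest contiguous p < p_cut run, or NULL).
#' @export
sliding_window_scan <- function(expression, counts, models, tissue,
                                win = 100, upstream = 1500, downstream = 2000,
                                p_cut = 0.001, min_coverage = 5) {
  windows <- tss_window(models, upstream, downstream)
  is_cpg <- counts$sites$context == "CpG"
  sites <- counts$sites[is_cpg, , drop = FALSE]
  idx_map <- which(is_cpg)
  asn <- assign_cpgs_to_windows(sites, windows)
  ratio <- pooled_ratio(counts, tissue, min_coverage)[idx_map[asn$site]]
  ok <- !is.na(ratio) & asn$transcript_id %in% names(expression)
  bin <- (asn$offset[ok] + upstream) %/% win
  key <- paste(asn$transcript_id[ok], bin, sep = "\r")
  sums <- rowsum(ratio[ok], key); ns <- rowsum(rep(1, sum(ok)), key)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1)
  binid <- as.integer(vapply(parts, `[`, "", 2))
  mean_r <- sums[, 1] / ns[, 1]
  n_bins <- (upstream + downstream) %/% win
  prof <- data.frame(bin_start = seq_len(n_bins) * win - win - upstream,
                     bin_end = seq_len(n_bins) * win - upstream,
                     rho = NA_real_, p = NA_real_, n_genes = 0L)
  for (bi in seq_len(n_bins) - 1L) {
    sel <- binid == bi
    if (sum(sel) < 3) next
    e <- expression[gene[sel]]; m <- mean_r[sel]
    prof$n_genes[bi + 1L] <- sum(sel)
    ct <- tryCatch(spearman_rho(e, m), error = function(err) NULL)
    if (!is.null(ct)) {
      prof$rho[bi + 1L] <- ct$rho
      prof$p[bi + 1L] <- ct$p
    }
  }
  argmin <- if (all(is.na(prof$rho))) NULL else {
    i <- which.min(prof$rho)
    c(prof$bin_start[i], prof$bin_end[i])
  }
  sig <- !is.na(prof$p) & prof$p < p_cut & !is.na(prof$rho) & prof$rho < 0
  sig_range <- NULL
  if (any(sig)) {
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    sig_range <- c(prof$bin_start[starts[best]], prof$bin_end[ends[best]])
  }
  list(profile = prof, argmin = argmin, significant_range = sig_range)
}

#' Otsu threshold of a one-dimensional sample
#'
#' Exact sample-based Otsu threshold: candidate cut-points are midpoints of
#' consecutive sorted unique values, and the threshold maximizing the
#' between-class variance `w1 * w2 * (m1 - m2)^2` is returned.  Ties break
#' toward the smaller threshold; the result is deterministic.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return the threshold (scalar).
#' @export
otsu_threshold <- function(values) {
  x <- sort(values[is.finite(values)])
  u <- unique(x)
  if (length(u) < 2) stop("degenerate distribution: fewer than 2 distinct values")
  n <- length(x)
  csum <- cumsum(x)
  # evaluate at each split after position i (i values below, n - i above)
  last_idx <- cumsum(tabulate(match(x, u), nbins = length(u)))  # index of last x <= u[j]
  i <- last_idx[-length(u)]
  w1 <- i / n; w2 <- 1 - w1
  m1 <- csum[i] / i
  m2 <- (csum[n] - csum[i]) / (n - i)
  bcv <- w1 * w2 * (m1 - m2)^2
  thr <- (u[-length(u)] + u[-1]) / 2
  thr[which.max(bcv)]
}

.count_modes <- function(x, h, gridsize = 512) {
  d <- stats::density(x, bw = h, n = gridsize,
                      from = min(x) - 3 * h, to = max(x) + 3 * h)
  s <- sign(diff(d$y))
  s <- s[s != 0]
  if (length(s) == 0) return(1L)
  sum(s[-length(s)] > 0 & s[-1] < 0) + as.integer(s[length(s)] > 0)
}

.critical_bandwidth <- function(x, k, gridsize = 512, tol = 1e-4) {
  lo <- 1e-4 * stats::sd(x)
  if (.count_modes(x, lo, gridsize) <= k) return(lo)
  hi <- stats::sd(x)
  while (.count_modes(x, hi, gridsize) > k) hi <- hi * 2
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (.count_modes(x, mid, gridsize) <= k) hi <- mid else lo <- mid
    if ((hi - lo) < tol * hi) break
  }
  hi
}

#' Silverman bootstrap test for the number of modes
#'
#' Tests H0 "the density has at most `k_modes` modes" via the critical
#' bandwidth: the smallest Gaussian-kernel bandwidth `h_k` whose KDE has at
#' most `k_modes` modes is found by bisection, and the p-value is the
#' fraction of variance-rescaled smoothed-bootstrap resamples whose KDE at
#' `h_k` has more than `k_modes` modes (equivalently whose critical
#' bandwidth exceeds `h_k`).  A small p rejects unimodality (for k = 1).
#'
#' @param values numeric sample (n >= 10, finite).
#' @param k_modes null number of modes (1 or 2).
#' @param B number of bootstrap resamples (>= 100).
#' @param seed optional integer seed for the bootstrap.
#' @param gridsize KDE grid resolution for mode counting.
#' @return list with `p`, `h_crit`, `k_modes`, `B`.
#' @references Silverman (1981) JRSS-B 43:97.
#' @export
silverman_test <- function(values, k_modes = 1, B = 200, seed = NULL,
                           gridsize = 512) {
  x <- values
  if (any(!is.finite(x))) stop("non-finite values in sample")
  n <- length(x)
  if (n < 10) stop("need at least 10 observations")
  if (B < 100) stop("need at least 100 bootstrap resamples")
  if (!is.null(seed)) set.seed(seed)
  h <- .critical_bandwidth(x, k_modes, gridsize)
  sigma2 <- stats::var(x)
  scale <- 1 / sqrt(1 + h^2 / sigma2)
  exceed <- 0L
  for (b in seq_len(B)) {
    xb <- x[sample.int(n, n, replace = TRUE)]
    y <- mean(xb) + scale * (xb - mean(xb) + h * stats::rnorm(n))
    if (.count_modes(y, h, gridsize) > k_modes) exceed <- exceed + 1L
  }
  list(p = exceed / B, h_crit = h, k_modes = k_modes, B = B)
}

#' Classify genes as hypo- or hypermethylated
#'
#' @param window_meth data.frame from [window_methylation()].
#' @param threshold methylation-ratio threshold (e.g. from
#'   [otsu_threshold()] on the pooled two-tissue window ratios).
#' @return `window_meth` with a `state` column: `"hypo"` when
#'   `mean_ratio < threshold`, `"hyper"` when `>= threshold` (ties go to
#'   hyper), `NA` when the window has no covered CpG.
#' @export
classify_hypo_hyper <- function(window_meth, threshold) {
  window_meth$state <- ifelse(is.na(window_meth$mean_ratio), NA_character_,
                              ifelse(window_meth$mean_ratio < threshold,
                                     "hypo", "hyper"))
  window_meth
}
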