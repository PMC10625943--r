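#' Protein detection by replicate presence
#'
#' A protein is detected in a tissue when its intensity is non-missing in at
#' least `min_reps` of that tissue's replicates.
#'
#' @param intensities named list of two intensity matrices
#'   (proteins x replicates, `NA` = not observed, shared rownames).
#' @param min_reps minimum non-missing replicates.
#' @param n_reps optional expected replicate count; mismatch is an error.
#' @return data.frame `protein_id`, `n_<tissue>` and `detected_<tissue>` per
#'   tissue.
#' @export
detect_proteins <- function(intensities, min_reps = 3, n_reps = NULL) {
  stopifnot(length(intensities) == 2,
            identical(rownames(intensities[[1]]), rownames(intensities[[2]])))
  if (!is.null(n_reps) && any(vapply(intensities, ncol, 1L) != n_reps)) {
    stop("replicate count mismatch: expected ", n_reps, " columns per tissue")
  }
  out <- data.frame(protein_id = rownames(intensities[[1]]),
                    stringsAsFactors = FALSE)
  for (tissue in names(intensities)) {
    n <- rowSums(!is.na(intensities[[tissue]]))
    out[[paste0("n_", tissue)]] <- n
    out[[paste0("detected_", tissue)]] <- n >= min_reps
  }
  attr(out, "tissues") <- names(intensities)
  out
}

#' Apply a fitted arcsinh variance-stabilizing transform
#'
#' `h(x) = gamma * arcsinh(a + b * x)`; strictly increasing in `x` for
#' `b, gamma > 0`.
#'
#' @param x numeric vector/matrix of raw intensities.
#' @param params list with `a`, `b`, `gamma` (e.g. from [vsn_fit()]).
#' @return transformed values, same shape as `x`.
#' @export
vsn_transform <- function(x, params) {
  params$gamma * asinh(params$a + params$b * x)
}

#' Fit the arcsinh variance-stabilizing normalization
#'
#' Fits `h(x) = gamma * arcsinh(a + b x)` so that transformed replicate
#' intensities scatter around per-(protein, tissue) means with unit
#' variance: `(a, b)` maximize the transformation profile likelihood
#' (Gaussian residual term plus the Jacobian of `h`), and `gamma` is the
#' reciprocal residual standard deviation in arcsinh space, which fixes the
#' transformed error variance at 1.  Robustness comes from least-trimmed-
#' squares iterations: the `trim` fraction of proteins with the largest
#' mean squared residuals is excluded and the fit repeated until the kept
#' set stabilizes.
#'
#' @param intensities named list of two intensity matrices; only proteins
#'   detected in both tissues (per `detections`) enter the fit, but the
#'   returned transform is applied to all values.
#' @param detections data.frame from [detect_proteins()].
#' @param trim fraction of proteins trimmed per robustness iteration.
#' @param max_iter maximum number of trimming iterations.
#' @return list with `a`, `b`, `gamma`, `transformed` (named list of
#'   matrices), `n_fit` (proteins in the final fit), `converged`,
#'   `iterations`.
#' @export
vsn_fit <- function(intensities, detections = NULL, trim = 0.1, max_iter = 10) {
  tissues <- names(intensities)
  if (is.null(detections)) detections <- detect_proteins(intensities)
  both <- detections[[paste0("detected_", tissues[1])]] &
    detections[[paste0("detected_", tissues[2])]]
  if (sum(both) < 20) stop("need >= 20 proteins detected in both tissues")
  x_list <- lapply(intensities, function(m) m[both, , drop = FALSE])
  # group index: one mean per (protein, tissue)
  xs <- cbind(x_list[[1]], x_list[[2]])
  grp_tissue <- rep(1:2, times = vapply(x_list, ncol, 1L))

  profile_obj <- function(par, rows) {
    a <- par[1]; b <- exp(par[2])
    nll_terms <- 0; ss <- 0; nobs <- 0; ngrp <- 0
    for (tis in 1:2) {
      g <- asinh(a + b * xs[rows, grp_tissue == tis, drop = FALSE])
      mu <- rowMeans(g, na.rm = TRUE)
      r <- g - mu
      ss <- ss + sum(r^2, na.rm = TRUE)
      nobs <- nobs + sum(!is.na(g))
      ngrp <- ngrp + sum(rowSums(!is.na(g)) > 0)
      arg <- a + b * xs[rows, grp_tissue == tis, drop = FALSE]
      nll_terms <- nll_terms +
        sum(log(b) - 0.5 * log1p(arg^2), na.rm = TRUE)
    }
    dfree <- max(nobs - ngrp, 1)
    v <- ss / dfree
    # negative profile log-likelihood (residual variance profiled out)
    0.5 * nobs * log(v) - nll_terms
  }

  rows <- seq_len(nrow(xs))
  med <- stats::median(xs, na.rm = TRUE)
  par <- c(0, -log(med))
  iter <- 0; converged <- FALSE
  repeat {
    iter <- iter + 1
    opt <- stats::optim(par, profile_obj, rows = rows, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    par <- opt$par
    a <- par[1]; b <- exp(par[2])
    # per-protein mean squared residual for trimming
    msr <- rep(0, nrow(xs)); nr <- rep(0, nrow(xs))
    for (tis in 1:2) {
      g <- asinh(a + b * xs[, grp_tissue == tis, drop = FALSE])
      r <- g - rowMeans(g, na.rm = TRUE)
      msr <- msr + rowSums(r^2, na.rm = TRUE)
      nr <- nr + rowSums(!is.na(r))
    }
    msr <- msr / pmax(nr, 1)
    keep_n <- max(20, ceiling((1 - trim) * nrow(xs)))
    new_rows <- order(msr)[seq_len(keep_n)]
    if (identical(sort(new_rows), sort(rows)) || iter >= max_iter) {
      converged <- identical(sort(new_rows), sort(rows))
      rows <- new_rows
      break
    }
    rows <- new_rows
  }
  if (!converged && iter >= max_iter) {
    # the trimmed set cycling between near-identical sets is acceptable;
    # only a failed optimizer is fatal
    if (!is.finite(opt$value)) stop("vsn_fit failed to converge: ",
                                    "objective non-finite after ", iter,
                                    " iterations")
  }
  # gamma from the residual variance of the final kept set
  ss <- 0; nobs <- 0; ngrp <- 0
  for (tis in 1:2) {
    g <- asinh(a + b * xs[rows, grp_tissue == tis, drop = FALSE])
    r <- g - rowMeans(g, na.rm = TRUE)
    ss <- ss + sum(r^2, na.rm = TRUE)
    nobs <- nobs + sum(!is.na(g))
    ngrp <- ngrp + sum(rowSums(!is.na(g)) > 0)
  }
  v <- ss / max(nobs - ngrp, 1)
  params <- list(a = a, b = b, gamma = 1 / sqrt(v))
  transformed <- lapply(intensities, vsn_transform, params = params)
  c(params, list(transformed = transformed, n_fit = length(rows),
                 converged = TRUE, iterations = iter))
}

# Newton inversion of the trigamma function (used by the moderated test)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-8 * y) break
  }
  y
}

#' Moderated two-group test for transformed protein intensities
#'
#' Per-protein two-group t-test with empirical-Bayes variance moderation:
#' the prior variance `s0^2` and prior degrees of freedom `d0` are fitted by
#' moment matching on the log sample variances (matching the mean and
#' variance of `log s^2` to the scaled-F model), the per-protein variance is
#' shrunk to `(d0 s0^2 + d s^2) / (d0 + d)`, and the moderated t is referred
#' to a t distribution on `d + d0` degrees of freedom.  With `d0 = 0` the
#' statistic reduces to the ordinary pooled-variance t.  q-values are
#' Benjamini-Hochberg.
#'
#' @param transformed named list of two transformed intensity matrices
#'   (e.g. `vsn_fit()$transformed`); `NA` allowed.
#' @param proteins optional character vector restricting the tested set
#'   (default: proteins with >= 2 observations per tissue).
#' @param prior_df override the moment-matched `d0` (mainly for testing;
#'   `0` disables moderation).
#' @return data.frame `protein_id`, `mean_<tissue>` columns, `diff`, `t`,
#'   `df`, `p`, `q`; attributes `d0`, `s0_2`.
#' @export
moderated_test <- function(transformed, proteins = NULL, prior_df = NULL) {
  tissues <- names(transformed)
  xa <- transformed[[1]]; xb <- transformed[[2]]
  na_ <- rowSums(!is.na(xa)); nb_ <- rowSums(!is.na(xb))
  ok <- na_ >= 2 & nb_ >= 2
  if (!is.null(proteins)) ok <- ok & rownames(xa) %in% proteins
  if (!any(ok)) stop("no proteins with >= 2 observations per tissue")
  xa <- xa[ok, , drop = FALSE]; xb <- xb[ok, , drop = FALSE]
  na_ <- na_[ok]; nb_ <- nb_[ok]
  ma <- rowMeans(xa, na.rm = TRUE); mb <- rowMeans(xb, na.rm = TRUE)
  ssa <- rowSums((xa - ma)^2, na.rm = TRUE)
  ssb <- rowSums((xb - mb)^2, na.rm = TRUE)
  d <- na_ + nb_ - 2
  if (any(d < 1)) stop("zero residual degrees of freedom")
  s2 <- (ssa + ssb) / d
  s2 <- pmax(s2, 1e-12)
  if (is.null(prior_df)) {
    z <- log(s2)
    d_med <- stats::median(d)
    excess <- stats::var(z) - mean(trigamma(d / 2))
    if (is.na(excess) || excess <= 0) {
      d0 <- Inf
      s0_2 <- exp(mean(z) - mean(digamma(d / 2) - log(d / 2)))
    } else {
      d0 <- 2 * .trigamma_inverse(excess)
      s0_2 <- exp(mean(z) - mean(digamma(d / 2) - log(d / 2)) +
                    digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    d0 <- prior_df
    s0_2 <- if (d0 > 0) exp(mean(log(s2))) else 0
  }
  s2_mod <- if (is.infinite(d0)) rep(s0_2, length(s2)) else {
    (d0 * s0_2 + d * s2) / (d0 + d)
  }
  tstat <- (ma - mb) / sqrt(s2_mod * (1 / na_ + 1 / nb_))
  df_tot <- d + d0
  p <- 2 * stats::pt(-abs(tstat), df = pmin(df_tot, 1e6))
  out <- data.frame(protein_id = rownames(xa), stringsAsFactors = FALSE)
  out[[paste0("mean_", tissues[1])]] <- ma
  out[[paste0("mean_", tissues[2])]] <- mb
  out$diff <- ma - mb
  out$t <- tstat
  out$df <- df_tot
  out$p <- p
  out$q <- bh_adjust(p)
  attr(out, "tissues") <- tissues
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

#' Call differentially expressed proteins (DEPs)
#'
#' Proteins detected in both tissues are labelled by the moderated test
#' (`q < q_cut`, direction by sign); proteins detected in exactly one
#' tissue are `"<tissue>_only"` DEPs without a test; proteins detected in
#' neither tissue are dropped.
#'
#' @param detections data.frame from [detect_proteins()].
#' @param mod_results data.frame from [moderated_test()].
#' @param q_cut q-value cutoff.
#' @return data.frame `protein_id`, `label` (`"<tissueA>"`, `"<tissueB>"`,
#'   `"<tissue>_only"`, or `"non_dep"`), `q`, `detected_<tissue>` columns.
#' @export
call_deps <- function(detections, mod_results, q_cut = 0.01) {
  tissues <- attr(detections, "tissues")
  da <- detections[[paste0("detected_", tissues[1])]]
  db <- detections[[paste0("detected_", tissues[2])]]
  keep <- da | db
  out <- detections[keep, c("protein_id",
                            paste0("detected_", tissues[1]),
                            paste0("detected_", tissues[2]))]
  q <- mod_results$q[match(out$protein_id, mod_results$protein_id)]
  diff <- mod_results$diff[match(out$protein_id, mod_results$protein_id)]
  da <- da[keep]; db <- db[keep]
  out$q <- q
  out$label <- ifelse(da & !db, paste0(tissues[1], "_only"),
                ifelse(db & !da, paste0(tissues[2], "_only"),
                  ifelse(!is.na(q) & q < q_cut,
                         ifelse(diff > 0, tissues[1], tissues[2]),
                         "non_dep")))
  rownames(out) <- NULL
  attr(out, "tissues") <- tissues
  out
}

#' Per-tissue protein/mRNA log-ratios
#'
#' `log(mean intensity / mean TPM)` per protein per tissue; missing when
#' the protein is not detected in that tissue or the gene's TPM is 0.
#'
#' @param intensities named list of two raw intensity matrices.
#' @param tpm_means named list of two named numeric vectors of per-gene mean
#'   TPM.
#' @param id_map data.frame `protein_id`, `gene_id`.
#' @param detections data.frame from [detect_proteins()].
#' @param flip if `TRUE` compute log(mRNA/protein) instead (labels swap
#'   under the global flip; the deviation calls do not).
#' @return data.frame `protein_id`, `gene_id`, `ratio_<tissue>` columns.
#' @export
protein_mrna_ratio <- function(intensities, tpm_means, id_map, detections,
                               flip = FALSE) {
  tissues <- names(intensities)
  out <- data.frame(protein_id = rownames(intensities[[1]]),
                    stringsAsFactors = FALSE)
  out$gene_id <- id_map$gene_id[match(out$protein_id, id_map$protein_id)]
  for (tissue in tissues) {
    prot <- rowMeans(intensities[[tissue]], na.rm = TRUE)
    det <- detections[[paste0("detected_", tissue)]][
      match(out$protein_id, detections$protein_id)]
    tpm <- tpm_means[[tissue]][out$gene_id]
    r <- ifelse(det & !is.na(tpm) & tpm > 0 & prot > 0,
                log(prot / tpm), NA_real_)
    out[[paste0("ratio_", tissue)]] <- if (flip) -r else r
  }
  attr(out, "tissues") <- tissues
  out
}

#' Call different protein/mRNA-ratio proteins (DRPs)
#'
#' Regresses the first tissue's protein/mRNA log-ratio on the second
#' tissue's over all proteins with both-tissue ratios, then flags protein
#' `i` as a DRP when the mean squared error of the line refit without `i`
#' (evaluated on the remaining n-1 points) is smaller than the full-fit MSE
#' - i.e. when excluding the protein improves the fit even slightly.
#' Direction: residual above the line means a relatively higher
#' protein/mRNA ratio in the first (y-axis) tissue.
#'
#' @param ratios data.frame from [protein_mrna_ratio()].
#' @param criterion `"full"` (default; compare against the full-fit MSE) or
#'   `"refit"` (compare against the MSE of the leave-one-out refit evaluated
#'   on all n points).
#' @return data.frame `protein_id`, `gene_id`, `x` (second tissue ratio),
#'   `y` (first tissue ratio), `residual`, `label` (tissue or `"none"`);
#'   attribute `fit` carries intercept, slope, MSE and n.
#' @export
call_drps <- function(ratios, criterion = c("full", "refit")) {
  criterion <- match.arg(criterion)
  tissues <- attr(ratios, "tissues")
  y <- ratios[[paste0("ratio_", tissues[1])]]
  x <- ratios[[paste0("ratio_", tissues[2])]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 10) stop("need >= 10 proteins with both-tissue ratios")
  if (stats::var(x[ok]) == 0) stop("degenerate regression: zero variance in x")
  fit <- stats::lm(y[ok] ~ x[ok])
  r <- stats::residuals(fit)
  h <- stats::hatvalues(fit)
  n <- sum(ok)
  ss <- sum(r^2)
  mse_full <- ss / n
  loo_drop <- r^2 / (1 - h)           # SS decrease from deleting point i
  if (criterion == "full") {
    flag <- (ss - loo_drop) / (n - 1) < mse_full
  } else {
    press <- r / (1 - h)
    flag <- (ss - loo_drop) / (n - 1) < (ss - loo_drop + press^2) / n
  }
  if (mse_full <= 1e-12 * stats::var(y[ok])) {
    flag[] <- FALSE  # (numerically) exact collinearity: nothing to improve
  }
  label <- rep("none", nrow(ratios))
  label[which(ok)[flag & r > 0]] <- tissues[1]
  label[which(ok)[flag & r < 0]] <- tissues[2]
  out <- data.frame(protein_id = ratios$protein_id, gene_id = ratios$gene_id,
                    x = x, y = y, residual = NA_real_, label = label,
                    stringsAsFactors = FALSE)
  out$residual[ok] <- r
  attr(out, "fit") <- list(intercept = unname(stats::coef(fit)[1]),
                           slope = unname(stats::coef(fit)[2]),
                           mse = mse_full, n = n)
  attr(out, "tissues") <- tissues
  out
}

#' Overlap of DRP calls with a gene set (e.g. 5'-TOP motif genes)
#'
#' Builds, per DRP direction, the 2x2 contingency of DRP membership against
#' gene-set membership over all proteins with both-tissue ratios, with a
#' right-tailed Fisher test for enrichment.
#'
#' @param drps data.frame from [call_drps()].
#' @param gene_set character vector of gene IDs (e.g. one GMT entry).
#' @return data.frame, one row per direction: `direction`, `in_set_drp`,
#'   `in_set_other`, `out_set_drp`, `out_set_other`, `p_right`.
#' @export
top_motif_overlap <- function(drps, gene_set) {
  if (length(gene_set) == 0) stop("empty gene set")
  tissues <- attr(drps, "tissues")
  usable <- !is.na(drps$residual)
  in_set <- drps$gene_id %in% gene_set
  out <- lapply(tissues, function(tissue) {
    is_drp <- drps$label == tissue
    a <- sum(usable & is_drp & in_set)
    b <- sum(usable & !is_drp & in_set)
    c_ <- sum(usable & is_drp & !in_set)
    d <- sum(usable & !is_drp & !in_set)
    p <- fisher_exact(matrix(c(a, c_, b, d), 2, byrow = TRUE), tail = "right")
    data.frame(direction = tissue, in_set_drp = a, in_set_other = b,
               out_set_drp = c_, out_set_other = d, p_right = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
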