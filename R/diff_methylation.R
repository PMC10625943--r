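#' Per-CpG differential methylation test between two tissues
#'
#' Beta-binomial likelihood-ratio test on replicate-level
#' (methylated, total) counts: H0 a single methylation mean shared by both
#' tissues, H1 tissue-specific means; the beta-binomial precision is shared
#' and profiled on a grid under H1.  The statistic is referred to
#' chi-square(1) after a genomic-control calibration: with few replicates
#' the raw likelihood-ratio statistic is slightly tail-inflated, so it is
#' rescaled by the ratio of its median over tested sites to the
#' chi-square(1) median, floored at 1 (strong differential sites barely
#' move the median, so the rescaling is driven by the null bulk; the factor
#' is returned as attribute `lambda_gc`).
#' When both tissues have a single replicate the test falls
#' back to Fisher's exact test (two-sided) on the pooled 2x2 count table.
#' Sites below `min_coverage` pooled reads in either tissue are skipped and
#' reported untested.
#'
#' @param counts a `meth_counts` object with exactly two tissues.
#' @param min_coverage minimum pooled total reads per tissue.
#' @param s_grid grid of beta-binomial precision values profiled under H1.
#' @return data.frame, one row per CpG-context site: `chrom`, `pos`,
#'   `ratio_<tissueA>`, `ratio_<tissueB>`, `statistic`, `p`, `tested`.
#' @export
dmcpg_test <- function(counts, min_coverage = 5,
                       s_grid = c(2, 5, 10, 20, 50, 100, 300, 1000, 1e5)) {
  tissues <- meth_tissues(counts)
  if (length(tissues) != 2) stop("dmcpg_test needs exactly two tissues")
  ta <- tissues[1]; tb <- tissues[2]
  is_cpg <- counts$sites$context == "CpG"
  sites <- counts$sites[is_cpg, , drop = FALSE]
  ma <- counts$meth[[ta]][is_cpg, , drop = FALSE]
  ca <- counts$total[[ta]][is_cpg, , drop = FALSE]
  mb <- counts$meth[[tb]][is_cpg, , drop = FALSE]
  cb <- counts$total[[tb]][is_cpg, , drop = FALSE]
  pa <- rowSums(ca); pb <- rowSums(cb)
  tested <- pa >= min_coverage & pb >= min_coverage
  out <- data.frame(
    chrom = sites$chrom, pos = sites$pos,
    ratio_a = ifelse(pa > 0, rowSums(ma) / pa, NA_real_),
    ratio_b = ifelse(pb > 0, rowSums(mb) / pb, NA_real_),
    statistic = NA_real_, p = NA_real_, tested = tested,
    stringsAsFactors = FALSE
  )
  names(out)[3:4] <- paste0("ratio_", c(ta, tb))
  if (any(tested)) {
    if (ncol(ma) == 1 && ncol(mb) == 1) {
      idx <- which(tested)
      pv <- vapply(idx, function(i) {
        tab <- matrix(c(ma[i, 1], ca[i, 1] - ma[i, 1],
                        mb[i, 1], cb[i, 1] - mb[i, 1]), 2, byrow = TRUE)
        fisher_exact(tab, tail = "two")
      }, numeric(1))
      out$p[idx] <- pv
      out$statistic[idx] <- stats::qchisq(pmax(1 - pv, 0), df = 1)
    } else {
      res <- .bb_lrt_cpp(ma[tested, , drop = FALSE], ca[tested, , drop = FALSE],
                         mb[tested, , drop = FALSE], cb[tested, , drop = FALSE],
                         as.numeric(s_grid))
      # the genomic-control factor needs enough sites for a stable null
      # median; on small batches the raw chi-square reference is used
      lambda <- if (sum(tested) >= 200) {
        max(stats::median(res$stat) / stats::qchisq(0.5, 1), 1)
      } else 1

      out$statistic[tested] <- res$stat / lambda
      out$p[tested] <- stats::pchisq(res$stat / lambda, df = 1,
                                     lower.tail = FALSE)
      attr(out, "lambda_gc") <- lambda
    }
  }
  attr(out, "tissues") <- tissues
  out
}

#' Flag differentially methylated CpGs
#'
#' Adds Storey q-values (over tested sites only), the DMCpG flag
#' (`q < q_cut`), and the hypomethylation direction (the tissue with the
#' lower pooled ratio).
#'
#' @param results data.frame from [dmcpg_test()].
#' @param q_cut q-value cutoff (default 0.01).
#' @return `results` with `q`, `is_dmcpg`, `direction` columns (`direction`
#'   is `"<tissue>_hypo"`, defined only for DMCpGs).
#' @export
call_dmcpgs <- function(results, q_cut = 0.01) {
  tissues <- attr(results, "tissues")
  ra <- results[[paste0("ratio_", tissues[1])]]
  rb <- results[[paste0("ratio_", tissues[2])]]
  results$q <- NA_real_
  if (any(results$tested)) {
    results$q[results$tested] <- as.numeric(storey_qvalue(results$p[results$tested]))
  }
  results$is_dmcpg <- !is.na(results$q) & results$q < q_cut
  results$direction <- ifelse(results$is_dmcpg,
                              ifelse(ra < rb, paste0(tissues[1], "_hypo"),
                                     paste0(tissues[2], "_hypo")),
                              NA_character_)
  attr(results, "tissues") <- tissues
  results
}

#' Call differentially hypomethylated genes (DMGs)
#'
#' A gene is a DMG for a tissue when (a) its TSS window is hypomethylated in
#' at least one tissue, (b) at least one DMCpG with that tissue's
#' hypomethylation direction lies inside the strand-aware window
#' `[TSS - upstream, TSS + downstream)`, and (c) the window mean ratio in
#' that tissue is lower than in the other tissue.  Genes without any covered
#' window CpG are labelled `none` and flagged untested.
#'
#' @param models a `gene_models` object.
#' @param dmcpgs data.frame from [call_dmcpgs()].
#' @param window_meth classified window methylation (long data.frame from
#'   [classify_hypo_hyper()]).
#' @param upstream,downstream window extents (bp).
#' @return data.frame per transcript unit: `transcript_id`, `label`
#'   (tissue name or `"none"`), `n_dmcpg`, per-direction DMCpG counts,
#'   per-tissue window ratios and states, `untested`, `conflict`.
#' @export
call_dmgs <- function(models, dmcpgs, window_meth,
                      upstream = 200, downstream = 400) {
  tissues <- attr(dmcpgs, "tissues")
  ta <- tissues[1]; tb <- tissues[2]
  win <- tss_window(models, upstream, downstream)
  dm <- dmcpgs[dmcpgs$is_dmcpg %in% TRUE, , drop = FALSE]
  asn <- assign_cpgs_to_windows(dm[, c("chrom", "pos")], win)
  dir_in_win <- data.frame(transcript_id = asn$transcript_id,
                           direction = dm$direction[asn$site])
  cnt <- function(direction) {
    t0 <- table(dir_in_win$transcript_id[dir_in_win$direction == direction])
    v <- stats::setNames(as.integer(t0), names(t0))
    out <- v[win$transcript_id]
    out[is.na(out)] <- 0L
    stats::setNames(out, win$transcript_id)
  }
  n_a <- cnt(paste0(ta, "_hypo")); n_b <- cnt(paste0(tb, "_hypo"))
  wa <- window_meth[window_meth$tissue == ta, , drop = FALSE]
  wb <- window_meth[window_meth$tissue == tb, , drop = FALSE]
  ids <- win$transcript_id
  ra <- wa$mean_ratio[match(ids, wa$transcript_id)]
  rb <- wb$mean_ratio[match(ids, wb$transcript_id)]
  sa <- wa$state[match(ids, wa$transcript_id)]
  sb <- wb$state[match(ids, wb$transcript_id)]
  untested <- is.na(ra) & is.na(rb)
  hypo_any <- (sa %in% "hypo") | (sb %in% "hypo")
  a_ok <- hypo_any & n_a[ids] >= 1 & !is.na(ra) & !is.na(rb) & ra < rb
  b_ok <- hypo_any & n_b[ids] >= 1 & !is.na(ra) & !is.na(rb) & rb < ra
  conflict <- hypo_any & n_a[ids] >= 1 & n_b[ids] >= 1 & !a_ok & !b_ok
  label <- ifelse(a_ok, ta, ifelse(b_ok, tb, "none"))
  out <- data.frame(
    transcript_id = ids, label = label,
    n_dmcpg = as.integer(n_a[ids] + n_b[ids]),
    stringsAsFactors = FALSE
  )
  out[[paste0("n_dmcpg_", ta, "_hypo")]] <- as.integer(n_a[ids])
  out[[paste0("n_dmcpg_", tb, "_hypo")]] <- as.integer(n_b[ids])
  out[[paste0("ratio_", ta)]] <- ra
  out[[paste0("ratio_", tb)]] <- rb
  out[[paste0("state_", ta)]] <- sa
  out[[paste0("state_", tb)]] <- sb
  out$untested <- untested
  out$conflict <- conflict
  attr(out, "tissues") <- tissues
  out
}
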