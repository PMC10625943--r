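# shared fixture builders (everything generated in code)

# small meth_counts object from explicit per-replicate count lists
make_meth_fixture <- function(meth_a, tot_a, meth_b, tot_b,
                              chrom = "chr1", pos = NULL, context = "CpG",
                              tissues = c("liver", "muscle")) {
  n <- nrow(meth_a)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  sites <- data.frame(chrom = chrom, pos = pos, strand = "+",
                      context = rep_len(context, n), stringsAsFactors = FALSE)
  meth_counts(sites,
              stats::setNames(list(meth_a, meth_b), tissues),
              stats::setNames(list(tot_a, tot_b), tissues))
}

# simulated beta-binomial counts for n sites with given per-tissue means
sim_meth_sites <- function(n, mu_a, mu_b, reps = 3, coverage = 30, s = 50) {
  draw <- function(mu) {
    tot <- matrix(rpois(n * reps, coverage), n, reps)
    pr <- matrix(rbeta(n * reps, mu * s, (1 - mu) * s), n, reps)
    list(m = matrix(rbinom(n * reps, tot, pr), n, reps), t = tot)
  }
  a <- draw(rep_len(mu_a, n)); b <- draw(rep_len(mu_b, n))
  make_meth_fixture(a$m, a$t, b$m, b$t)
}

# write a small GTF with two transcripts (plus/minus strand) and return path
write_test_gtf <- function(path = tempfile(fileext = ".gtf")) {
  lines <- c(
    'chr1\ttest\texon\t100\t200\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\ttest\texon\t300\t400\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\ttest\texon\t100\t200\t.\t-\t.\tgene_id "gB"; transcript_id "tB";',
    'chr1\ttest\texon\t300\t400\t.\t-\t.\tgene_id "gB"; transcript_id "tB";'
  )
  writeLines(lines, path)
  path
}

# gene_models object built directly from an exon table
make_models <- function(exons) tissuedom:::.build_gene_models(exons)

# a simple single-exon transcript table
simple_exons <- function(ids, chrom, strand, start, end, gene = ids) {
  data.frame(transcript_id = ids, gene_id = gene, chrom = chrom,
             strand = strand, start = start, end = end,
             stringsAsFactors = FALSE)
}

# brute-force Otsu: direct two-pass between-class variance at every midpoint
otsu_oracle <- function(x) {
  x <- sort(x)
  u <- unique(x)
  thr <- (u[-length(u)] + u[-1]) / 2
  bcv <- vapply(thr, function(t) {
    lo <- x[x < t]; hi <- x[x >= t]
    w1 <- length(lo) / length(x); w2 <- 1 - w1
    w1 * w2 * (mean(lo) - mean(hi))^2
  }, numeric(1))
  thr[which.max(bcv)]
}

# brute-force Fisher tails by hypergeometric summation over all tables with
# the observed margins
fisher_oracle <- function(a, b, c, d, tail) {
  m <- a + b; n <- c + d; k <- a + c
  ks <- max(0, k - n):min(k, m)
  probs <- dhyper(ks, m, n, k)
  if (tail == "right") sum(probs[ks >= a]) else sum(probs[ks <= a])
}

# textbook Welch statistic
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Spearman rho as Pearson on mid-ranks
spearman_oracle <- function(x, y) {
  cor(rank(x), rank(y))
}

# greedy Ward agglomeration: at every step evaluate the within-cluster
# sum-of-squares increase of every candidate merge and take the smallest
ward_oracle_partitions <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  ss <- function(idx) {
    if (length(idx) == 1) return(0)
    sum(sweep(X[idx, , drop = FALSE], 2,
              colMeans(X[idx, , drop = FALSE]))^2)
  }
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_inc <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        inc <- ss(c(clusters[[i]], clusters[[j]])) -
          ss(clusters[[i]]) - ss(clusters[[j]])
        if (inc < best_inc) { best_inc <- inc; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    labels <- integer(nrow(X))
    for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1]] <- labels
  }
  partitions  # element i: partition into n - i clusters
}

# compare two flat partitions up to label permutation
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 1L))]),
            unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 1L))]))
}
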