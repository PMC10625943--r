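#' Configuration for the synthetic two-tissue multi-omics study
#'
#' Defines the study conditions the generator emulates: a miniature
#' two-tissue design with bimodal promoter methylation (hypomethylated
#' genes near `hypo_mean`, hypermethylated near `hyper_mean`;
#' beta-binomial counts), tissue-specific hypomethylation probabilistically
#' coupled to elevated expression, negative-binomial RNA counts (11
#' replicates per tissue), log-normal protein intensities coupled to mRNA
#' with a planted post-transcriptionally shifted subset and detection
#' dropout (5 replicates per tissue), and TF peaks whose presence shifts
#' expression.
#'
#' @param n_genes number of genes.
#' @param n_chromosomes number of synthetic chromosomes.
#' @param seed integer seed; identical configs give bit-identical output.
#' @param frac_liver_dmg,frac_muscle_dmg planted DMG fractions per tissue.
#' @param hypo_mean,hyper_mean methylation ratios of the hypo/hyper states.
#' @param bb_overdispersion beta-binomial overdispersion (precision is
#'   `1/bb_overdispersion`).
#' @param coverage_mean mean reads per CpG per replicate.
#' @param meth_replicates,rna_replicates,prot_replicates replicates per
#'   tissue for each assay.
#' @param deg_log2fc expression log2 fold-change planted for coupled DMGs,
#'   independent DEGs, and the hypomethylation expression boost.
#' @param nb_dispersion negative-binomial dispersion of RNA counts.
#' @param drp_shift multiplicative (natural-log) protein/mRNA shift of
#'   planted DRPs.
#' @param frac_drp planted DRP fraction per tissue.
#' @param dropout_rate per-cell protein missingness.
#' @param frac_tissue_absent fraction of proteins absent from one tissue.
#' @param cpg_density_low,cpg_density_high mean CpGs per 600-bp TSS window
#'   in the low/high density classes.
#' @param tf_effect_log2 expression log2 shift of TF-bound DTG genes.
#' @param p_couple probability that a planted DMG receives the expression
#'   shift (methylation-expression coupling is probabilistic, so composite
#'   overlaps are partial).
#' @param frac_deg_extra fraction of non-DMG genes given an independent
#'   expression shift (DEGs without hypomethylation).
#' @param frac_dtg fraction of genes with a differential TF peak.
#' @param prot_noise_sd replicate noise SD of log protein intensity.
#' @param trans_eff_sd SD of the per-protein translation-efficiency offset
#'   shared by both tissues (spreads the protein/mRNA regression).
#' @param expr_base_log2,expr_sd mean and SD of baseline log2 expression.
#' @param frac_low_density marginal fraction of genes in the low CpG
#'   density class.
#' @param p_low_given_dmg probability that a planted DMG is low-density.
#' @param both_hypo_high,both_hypo_low probability that a non-DMG gene is
#'   hypomethylated in both tissues, by density class.
#' @param gene_length transcript length in bp (fixed; expression ratios and
#'   ranks are unaffected).
#' @param flank_cpg_rate mean CpGs per flank region per gene (outside the
#'   window, within the -1500..+2000 scan range).
#' @param chh_frac non-CpG (CHG/CHH) sites as a fraction of CpG sites.
#' @param chh_mean methylation ratio of non-CpG sites.
#' @param multi_tss_frac fraction of genes with two transcripts sharing a
#'   TSS.
#' @param tf_names TF names used for peak files.
#' @param tf_background_rate fraction of genes bound by each TF in both
#'   tissues (no differential state).
#' @param atac_hypo_prob,atac_hyper_prob probability that a hypo-/hyper-
#'   methylated gene is covered by an ATAC peak in that tissue.
#' @param cgi_high_prob,cgi_low_prob probability that a high-/low-density
#'   gene overlaps a CpG island.
#' @param tissues character(2): tissue names.
#' @param chrom_length optional fixed chromosome length (bp); too small for
#'   the genes is an error.  Default sizes chromosomes to fit.
#' @return validated `sim_config` object (a list).
#' @export
sim_config <- function(n_genes = 2000, n_chromosomes = 4, seed = 1,
                       frac_liver_dmg = 0.1, frac_muscle_dmg = 0.1,
                       hypo_mean = 0.1, hyper_mean = 0.8,
                       bb_overdispersion = 0.02, coverage_mean = 30,
                       meth_replicates = 3, rna_replicates = 11,
                       prot_replicates = 5,
                       deg_log2fc = 2, nb_dispersion = 0.025,
                       drp_shift = log(3), frac_drp = 0.05,
                       dropout_rate = 0.05, frac_tissue_absent = 0.05,
                       cpg_density_low = 10, cpg_density_high = 47,
                       tf_effect_log2 = 2, p_couple = 0.8,
                       frac_deg_extra = 0.1, frac_dtg = 0.06,
                       prot_noise_sd = 0.15, trans_eff_sd = 1,
                       expr_base_log2 = 5, expr_sd = 1,
                       frac_low_density = 0.45, p_low_given_dmg = 0.85,
                       both_hypo_high = 0.8, both_hypo_low = 0.3,
                       gene_length = 1000, flank_cpg_rate = 6,
                       chh_frac = 0.1, chh_mean = 0.02,
                       multi_tss_frac = 0.05,
                       tf_names = c("Cebpb", "Foxa1", "Ctcf", "Myod1",
                                    "Brd4", "Rest"),
                       tf_background_rate = 0.1,
                       atac_hypo_prob = 0.9, atac_hyper_prob = 0.2,
                       cgi_high_prob = 0.9, cgi_low_prob = 0.05,
                       tissues = c("liver", "muscle"),
                       chrom_length = NULL) {
  cfg <- as.list(environment())
  props <- c(frac_liver_dmg, frac_muscle_dmg, frac_drp, dropout_rate,
             frac_tissue_absent, p_couple, frac_deg_extra, frac_dtg,
             frac_low_density, p_low_given_dmg, both_hypo_high,
             both_hypo_low, tf_background_rate, atac_hypo_prob,
             atac_hyper_prob, cgi_high_prob, cgi_low_prob, chh_frac,
             multi_tss_frac)
  if (any(props < 0 | props > 1)) stop("all proportions must lie in [0, 1]")
  if (frac_liver_dmg + frac_muscle_dmg > 1) {
    stop("frac_liver_dmg + frac_muscle_dmg must be <= 1")
  }
  if (!(hypo_mean >= 0 && hyper_mean <= 1 && hypo_mean < hyper_mean)) {
    stop("need 0 <= hypo_mean < hyper_mean <= 1")
  }
  if (any(c(meth_replicates, rna_replicates, prot_replicates) < 1)) {
    stop("all replicate counts must be >= 1")
  }
  if (coverage_mean <= 0) stop("coverage_mean must be positive")
  if (bb_overdispersion <= 0 || nb_dispersion <= 0) {
    stop("dispersions must be positive")
  }
  if (length(tissues) != 2 || anyDuplicated(tissues) > 0) {
    stop("tissues must be two distinct names")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_chromosomes,
      "chromosomes, seed", x$seed, "\n")
  invisible(x)
}

# slot geometry: each gene owns a fixed slot wide enough for the
# -1500..+2000 scan flank on either side of the TSS
.SLOT <- 6000L
.TSS_AT <- 2500L

#' Generate the synthetic genome annotation
#'
#' Places genes non-overlapping on synthetic chromosomes (both strands),
#' assigns each gene a CpG-density class and window CpG count drawn from
#' that class, and scatters additional CpGs in the flanks out to
#' -1500/+2000 bp for the sliding-window scan.  A fraction of genes get a
#' second transcript sharing the TSS.
#'
#' @param cfg a `sim_config`.
#' @return list with `models` (a `gene_models`), `cpgs` (data.frame
#'   `chrom`, `pos`, `strand`, `context`, `gene_id`, `offset`,
#'   `in_window`), `truth` (data.frame `gene_id`, `density_class`,
#'   `window_cpgs`), `tx2gene`, `tx_weights` (per-transcript expression
#'   shares).
#' @export
generate_annotation <- function(cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_genes
  per_chrom <- ceiling(n / cfg$n_chromosomes)
  needed <- per_chrom * .SLOT + 1000L
  if (!is.null(cfg$chrom_length)) {
    if (cfg$chrom_length < needed) {
      stop("genes do not fit: need chromosomes of >= ", needed, " bp")
    }
  }
  gene_id <- sprintf("G%05d", seq_len(n))
  chrom <- paste0("chr", (seq_len(n) - 1L) %/% per_chrom + 1L)
  slot <- ((seq_len(n) - 1L) %% per_chrom) * .SLOT
  strand <- sample(c("+", "-"), n, replace = TRUE)
  L <- cfg$gene_length
  body_start <- slot + .TSS_AT
  body_end <- body_start + L
  tss <- as.integer(ifelse(strand == "+", body_start, body_end - 1L))

  # exon chains: first exon 200 bp, intron, remainder
  exon_rows <- function(tx, g_i, intron) {
    s <- body_start[g_i]; e <- body_end[g_i]
    if (strand[g_i] == "+") {
      data.frame(transcript_id = tx, gene_id = gene_id[g_i],
                 chrom = chrom[g_i], strand = "+",
                 start = c(s, s + 200L + intron), end = c(s + 200L, e),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(transcript_id = tx, gene_id = gene_id[g_i],
                 chrom = chrom[g_i], strand = "-",
                 start = c(e - 200L, s), end = c(e, e - 200L - intron),
                 stringsAsFactors = FALSE)
    }
  }
  multi <- stats::runif(n) < cfg$multi_tss_frac
  ex <- vector("list", n + sum(multi))
  k <- 0
  for (i in seq_len(n)) {
    k <- k + 1
    ex[[k]] <- exon_rows(sprintf("T%05d.1", i), i, 300L)
    if (multi[i]) {
      k <- k + 1
      ex[[k]] <- exon_rows(sprintf("T%05d.2", i), i, 400L)
    }
  }
  ex <- do.call(rbind, ex)
  models <- .build_gene_models(ex)

  # per-transcript expression shares within a gene
  tx2gene <- unique(models$exons[, c("transcript_id", "gene_id")])
  tx2gene <- tx2gene[order(tx2gene$gene_id, tx2gene$transcript_id), , drop = FALSE]
  rownames(tx2gene) <- NULL
  w <- stats::runif(nrow(tx2gene), 0.3, 1)
  tot <- tapply(w, tx2gene$gene_id, sum)
  tx_weights <- stats::setNames(w / as.numeric(tot[tx2gene$gene_id]),
                                tx2gene$transcript_id)

  density_class <- ifelse(stats::runif(n) < cfg$frac_low_density, "low", "high")
  lam <- ifelse(density_class == "low", cfg$cpg_density_low, cfg$cpg_density_high)
  window_cpgs <- pmax(stats::rpois(n, lam), 1L)

  cpg_rows <- vector("list", n)
  for (i in seq_len(n)) {
    off_w <- sort(sample(-200:399, min(window_cpgs[i], 600L)))
    n_fl <- stats::rpois(2, cfg$flank_cpg_rate)
    off_f <- c(if (n_fl[1] > 0) sample(-1500:-201, min(n_fl[1], 1300L)),
               if (n_fl[2] > 0) sample(400:1999, min(n_fl[2], 1600L)))
    off_f <- setdiff(off_f, off_w)
    off <- c(off_w, off_f)
    pos <- as.integer(if (strand[i] == "+") tss[i] + off else tss[i] - off)
    cpg_rows[[i]] <- data.frame(
      chrom = chrom[i], pos = pos, strand = "+", context = "CpG",
      gene_id = gene_id[i], offset = off,
      in_window = off >= -200L & off < 400L, stringsAsFactors = FALSE)
  }
  cpgs <- do.call(rbind, cpg_rows)
  # non-CpG cytosines, hypomethylated everywhere
  n_chh <- ceiling(cfg$chh_frac * nrow(cpgs))
  if (n_chh > 0) {
    gi <- sample(seq_len(n), n_chh, replace = TRUE)
    off <- sample(-1500:1999, n_chh, replace = TRUE)
    chh <- data.frame(
      chrom = chrom[gi],
      pos = as.integer(ifelse(strand[gi] == "+", tss[gi] + off, tss[gi] - off)),
      strand = "+", context = sample(c("CHG", "CHH"), n_chh, replace = TRUE),
      gene_id = gene_id[gi], offset = off, in_window = FALSE,
      stringsAsFactors = FALSE)
    cpgs <- rbind(cpgs, chh)
  }
  # on position collisions keep the CpG-context record
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos, cpgs$context != "CpG"), , drop = FALSE]
  cpgs <- cpgs[!duplicated(cpgs[, c("chrom", "pos")]), , drop = FALSE]
  rownames(cpgs) <- NULL

  truth <- data.frame(gene_id = gene_id, strand = strand, tss = tss,
                      chrom = chrom, density_class = density_class,
                      window_cpgs = window_cpgs, stringsAsFactors = FALSE)
  list(models = models, cpgs = cpgs, truth = truth, tx2gene = tx2gene,
       tx_weights = tx_weights)
}

#' Generate the synthetic methylome
#'
#' Assigns each gene a methylation state per tissue (planted DMG fractions
#' get discordant states, preferentially in the low-density class; the rest
#' are hypo- or hypermethylated in both tissues, high-density genes mostly
#' both-hypo) and draws per-CpG beta-binomial counts around the planted
#' window ratio.  Flank CpGs get their own tissue-shared random ratios;
#' non-CpG sites are uniformly hypomethylated.  Pooled window ratios over
#' all genes form a bimodal distribution by construction.
#'
#' @param cfg a `sim_config`.
#' @param annotation result of [generate_annotation()].
#' @return list with `counts` (a `meth_counts`), `truth` (annotation truth
#'   plus `dmg_label` and planted per-tissue window ratios).
#' @export
generate_methylome <- function(cfg, annotation) {
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be positive")
  set.seed(cfg$seed + 2L)
  truth <- annotation$truth
  n <- nrow(truth)
  t1 <- cfg$tissues[1]; t2 <- cfg$tissues[2]
  w_dens <- ifelse(truth$density_class == "low",
                   cfg$p_low_given_dmg / cfg$frac_low_density,
                   (1 - cfg$p_low_given_dmg) / (1 - cfg$frac_low_density))
  n_l <- round(cfg$frac_liver_dmg * n); n_m <- round(cfg$frac_muscle_dmg * n)
  dmg_label <- rep("none", n)
  if (n_l + n_m > 0) {
    pick <- sample(seq_len(n), n_l + n_m, prob = w_dens)
    dmg_label[pick[seq_len(n_l)]] <- t1
    if (n_m > 0) dmg_label[pick[n_l + seq_len(n_m)]] <- t2
  }
  p_both_hypo <- ifelse(truth$density_class == "high",
                        cfg$both_hypo_high, cfg$both_hypo_low)
  both_hypo <- dmg_label == "none" & stats::runif(n) < p_both_hypo
  state <- function(tissue) {
    ifelse(dmg_label == tissue, "hypo",
           ifelse(dmg_label != "none", "hyper",
                  ifelse(both_hypo, "hypo", "hyper")))
  }
  st1 <- state(t1); st2 <- state(t2)
  # one planted ratio per gene per state, shared across tissues, so genes
  # with concordant states are exact methylation nulls
  jit_hypo <- pmin(pmax(cfg$hypo_mean + stats::rnorm(n, 0, 0.02), 0.02), 0.98)
  jit_hyper <- pmin(pmax(cfg$hyper_mean + stats::rnorm(n, 0, 0.02), 0.02), 0.98)
  mu_for <- function(st) ifelse(st == "hypo", jit_hypo, jit_hyper)
  mu1 <- mu_for(st1); mu2 <- mu_for(st2)
  truth[[paste0("planted_meth_", t1)]] <- mu1
  truth[[paste0("planted_meth_", t2)]] <- mu2
  truth$dmg_label <- dmg_label

  cpgs <- annotation$cpgs
  gi <- match(cpgs$gene_id, truth$gene_id)
  flank_mu <- stats::runif(nrow(cpgs), 0.05, 0.95)  # tissue-shared
  site_mu <- function(mu_gene) {
    m <- ifelse(cpgs$context != "CpG", cfg$chh_mean,
                ifelse(cpgs$in_window, mu_gene[gi], flank_mu))
    pmin(pmax(m, 0.005), 0.995)
  }
  s <- 1 / cfg$bb_overdispersion
  draw <- function(mu_site) {
    reps <- cfg$meth_replicates
    tot <- matrix(stats::rpois(nrow(cpgs) * reps, cfg$coverage_mean),
                  nrow(cpgs), reps)
    p <- matrix(stats::rbeta(nrow(cpgs) * reps, mu_site * s, (1 - mu_site) * s),
                nrow(cpgs), reps)
    meth <- matrix(stats::rbinom(nrow(cpgs) * reps, tot, p), nrow(cpgs), reps)
    list(meth = meth, total = tot)
  }
  d1 <- draw(site_mu(mu1)); d2 <- draw(site_mu(mu2))
  counts <- meth_counts(
    sites = cpgs[, c("chrom", "pos", "strand", "context")],
    meth = stats::setNames(list(d1$meth, d2$meth), cfg$tissues),
    total = stats::setNames(list(d1$total, d2$total), cfg$tissues)
  )
  list(counts = counts, truth = truth)
}

#' Generate synthetic RNA counts and TPM
#'
#' Baseline log2 expression is shared between tissues; hypomethylation adds
#' an expression boost (`deg_log2fc`) in the hypomethylated tissue - for
#' planted DMGs with probability `p_couple` only, so methylation-expression
#' coupling is partial.  Independent DEGs (`frac_deg_extra`) and TF-effect
#' genes (`frac_dtg`, shift `tf_effect_log2`) are planted on top.  Counts
#' are negative-binomial with per-replicate library factors; TPM is
#' computed from counts at fixed transcript length.  DEG truth labels
#' follow the sign of the planted between-tissue difference.
#'
#' @param cfg a `sim_config`.
#' @param annotation result of [generate_annotation()].
#' @param truth truth table from [generate_methylome()].
#' @return list with `counts`, `tpm` (named lists of transcript x replicate
#'   matrices per tissue), `truth` (plus `deg_label`, planted log2 means,
#'   `dtg_label`, `dtg_tf`, `dtg_tissue`).
#' @export
generate_expression <- function(cfg, annotation, truth) {
  set.seed(cfg$seed + 3L)
  n <- nrow(truth)
  t1 <- cfg$tissues[1]; t2 <- cfg$tissues[2]
  base <- stats::rnorm(n, cfg$expr_base_log2, cfg$expr_sd)
  shift1 <- numeric(n); shift2 <- numeric(n)
  hypo1 <- truth[[paste0("planted_meth_", t1)]] < (cfg$hypo_mean + cfg$hyper_mean) / 2
  hypo2 <- truth[[paste0("planted_meth_", t2)]] < (cfg$hypo_mean + cfg$hyper_mean) / 2
  coupled <- stats::runif(n) < cfg$p_couple
  # both-hypo genes: boost in both tissues (ubiquitously expressed, non-DEG);
  # planted DMGs: boost only in the hypomethylated tissue when coupled
  is_dmg <- truth$dmg_label != "none"
  shift1 <- shift1 + cfg$deg_log2fc * (hypo1 & (!is_dmg | coupled))
  shift2 <- shift2 + cfg$deg_log2fc * (hypo2 & (!is_dmg | coupled))
  # independent DEGs without methylation difference
  extra <- truth$dmg_label == "none" & stats::runif(n) < cfg$frac_deg_extra
  extra_t1 <- extra & stats::runif(n) < 0.5
  shift1 <- shift1 + cfg$deg_log2fc * extra_t1
  shift2 <- shift2 + cfg$deg_log2fc * (extra & !extra_t1)
  # TF binding carries the expression effect: genes bound in both tissues
  # (background binding) shift in both and stay non-DEG; planted DTG genes
  # are bound - and shifted - in one tissue only
  dtg_pick <- stats::runif(n) < cfg$frac_dtg
  dtg_tf <- ifelse(dtg_pick, sample(cfg$tf_names, n, replace = TRUE),
                   NA_character_)
  dtg_tissue <- ifelse(dtg_pick, sample(cfg$tissues, n, replace = TRUE),
                       NA_character_)
  bg <- matrix(stats::runif(n * length(cfg$tf_names)) < cfg$tf_background_rate,
               n, length(cfg$tf_names), dimnames = list(NULL, cfg$tf_names))
  bg[dtg_pick, ] <- FALSE
  tf_background <- apply(bg, 1, function(v) {
    paste(cfg$tf_names[v], collapse = ",")
  })
  bound_bg <- rowSums(bg) > 0
  bound1 <- (dtg_pick & !is.na(dtg_tissue) & dtg_tissue == t1) | bound_bg
  bound2 <- (dtg_pick & !is.na(dtg_tissue) & dtg_tissue == t2) | bound_bg
  shift1 <- shift1 + cfg$tf_effect_log2 * bound1
  shift2 <- shift2 + cfg$tf_effect_log2 * bound2

  l2_1 <- base + shift1; l2_2 <- base + shift2
  delta <- l2_1 - l2_2
  truth$deg_label <- ifelse(delta > 0, t1, ifelse(delta < 0, t2, "none"))
  truth[[paste0("planted_log2tpm_", t1)]] <- l2_1
  truth[[paste0("planted_log2tpm_", t2)]] <- l2_2
  truth$dtg_tf <- dtg_tf
  truth$dtg_tissue <- dtg_tissue
  truth$tf_background <- tf_background
  truth$dtg_label <- ifelse(dtg_pick & cfg$tf_effect_log2 != 0,
                            dtg_tissue, "none")
  truth$dtg_label[is.na(truth$dtg_label)] <- "none"

  tx2gene <- annotation$tx2gene
  wts <- annotation$tx_weights
  gi <- match(tx2gene$gene_id, truth$gene_id)
  draw_counts <- function(l2) {
    reps <- cfg$rna_replicates
    mu_tx <- 2^l2[gi] * wts
    lib <- exp(stats::rnorm(reps, 0, 0.1))
    m <- matrix(stats::rnbinom(length(mu_tx) * reps,
                               mu = rep(mu_tx, reps) * rep(lib, each = length(mu_tx)),
                               size = 1 / cfg$nb_dispersion),
                length(mu_tx), reps,
                dimnames = list(tx2gene$transcript_id,
                                paste0("rep", seq_len(reps))))
    m
  }
  cnt1 <- draw_counts(l2_1); cnt2 <- draw_counts(l2_2)
  to_tpm <- function(m) {
    rate <- m / cfg$gene_length
    sweep(rate, 2, colSums(rate), "/") * 1e6
  }
  list(counts = stats::setNames(list(cnt1, cnt2), cfg$tissues),
       tpm = stats::setNames(list(to_tpm(cnt1), to_tpm(cnt2)), cfg$tissues),
       truth = truth)
}

#' Generate synthetic protein intensities
#'
#' One protein per gene.  Log intensity follows the planted mRNA level
#' (`alpha + beta * log(mRNA)`) plus a per-protein translation-efficiency
#' offset shared by both tissues, a `drp_shift` for the planted DRP subset,
#' and Gaussian replicate noise; per-cell detection dropout plus a planted
#' tissue-absent subset produce missing values.  DEP truth labels follow
#' the planted protein mean difference (tissue-absent proteins are
#' `"<tissue>_only"`).
#'
#' @param cfg a `sim_config`.
#' @param truth truth table from [generate_expression()].
#' @return list with `intensity` (named list of protein x replicate
#'   matrices, `NA` = undetected), `map` (data.frame `protein_id`,
#'   `gene_id`), `truth` (plus `drp_label`, `dep_label`, `tissue_absent`).
#' @export
generate_proteome <- function(cfg, truth) {
  set.seed(cfg$seed + 4L)
  n <- nrow(truth)
  t1 <- cfg$tissues[1]; t2 <- cfg$tissues[2]
  protein_id <- sub("^G", "P", truth$gene_id)
  alpha <- log(1e4); beta <- 1
  u <- stats::rnorm(n, 0, cfg$trans_eff_sd)
  drp_label <- rep("none", n)
  n_drp <- round(cfg$frac_drp * n)
  if (n_drp > 0 && cfg$drp_shift != 0) {
    pick <- sample(seq_len(n), 2 * n_drp)
    drp_label[pick[seq_len(n_drp)]] <- t1
    drp_label[pick[n_drp + seq_len(n_drp)]] <- t2
  }
  absent <- rep(NA_character_, n)
  n_abs <- round(cfg$frac_tissue_absent * n)
  if (n_abs > 0) {
    cand <- which(drp_label == "none")
    pick <- sample(cand, min(2 * n_abs, length(cand)))
    absent[pick[seq_len(n_abs)]] <- t2   # present only in t1
    absent[pick[n_abs + seq_len(min(n_abs, length(pick) - n_abs))]] <- t1
  }
  l2_1 <- truth[[paste0("planted_log2tpm_", t1)]]
  l2_2 <- truth[[paste0("planted_log2tpm_", t2)]]
  ln_mu1 <- alpha + beta * l2_1 * log(2) + u + cfg$drp_shift * (drp_label == t1)
  ln_mu2 <- alpha + beta * l2_2 * log(2) + u + cfg$drp_shift * (drp_label == t2)
  draw <- function(ln_mu, absent_here) {
    reps <- cfg$prot_replicates
    m <- matrix(exp(ln_mu + stats::rnorm(n * reps, 0, cfg$prot_noise_sd)),
                n, reps,
                dimnames = list(protein_id, paste0("rep", seq_len(reps))))
    drop <- matrix(stats::runif(n * reps) < cfg$dropout_rate, n, reps)
    m[drop] <- NA_real_
    m[absent_here, ] <- NA_real_
    m
  }
  x1 <- draw(ln_mu1, !is.na(absent) & absent == t1)
  x2 <- draw(ln_mu2, !is.na(absent) & absent == t2)
  dp <- ln_mu1 - ln_mu2
  dep_label <- ifelse(!is.na(absent),
                      ifelse(absent == t2, paste0(t1, "_only"),
                             paste0(t2, "_only")),
                      ifelse(dp > 0, t1, ifelse(dp < 0, t2, "none")))
  truth$drp_label <- drp_label
  truth$dep_label <- dep_label
  truth$tissue_absent <- absent
  list(intensity = stats::setNames(list(x1, x2), cfg$tissues),
       map = data.frame(protein_id = protein_id, gene_id = truth$gene_id,
                        stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate synthetic peak files and CpG islands
#'
#' Planted DTG genes get a TF peak within the TSS flank in exactly one
#' tissue; each TF additionally binds a background fraction of genes in
#' both tissues.  ATAC peaks preferentially cover hypomethylated genes;
#' H3K4me3/H3K27ac marks come as two consistent source files per tissue;
#' CpG islands cover mostly high-density gene windows.
#'
#' @param cfg a `sim_config`.
#' @param annotation result of [generate_annotation()].
#' @param truth truth table from [generate_proteome()] (or any stage after
#'   [generate_expression()]).
#' @return list with `tf_peaks` (data.frame `chrom`, `start`, `end`, `tf`,
#'   `tissue`), `atac`, `hm` (nested per mark/tissue/file), `cgi`
#'   (data.frames `chrom`, `start`, `end`).
#' @export
generate_peaks <- function(cfg, annotation, truth) {
  set.seed(cfg$seed + 5L)
  n <- nrow(truth)
  tss <- truth$tss
  t1 <- cfg$tissues[1]; t2 <- cfg$tissues[2]
  rows <- list()
  # differential TF peaks (one tissue only)
  dtg <- !is.na(truth$dtg_tf)
  if (any(dtg)) {
    rows[[1]] <- data.frame(chrom = truth$chrom[dtg], start = tss[dtg] - 200L,
                            end = tss[dtg] + 200L, tf = truth$dtg_tf[dtg],
                            tissue = truth$dtg_tissue[dtg],
                            stringsAsFactors = FALSE)
  }
  # background binding planted at expression time, identical in both tissues
  bg_tfs <- strsplit(truth$tf_background, ",", fixed = TRUE)
  for (tf in cfg$tf_names) {
    bg <- which(vapply(bg_tfs, function(v) tf %in% v, TRUE))
    if (length(bg) == 0) next
    for (tissue in cfg$tissues) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = truth$chrom[bg], start = tss[bg] - 500L, end = tss[bg] + 500L,
        tf = tf, tissue = tissue, stringsAsFactors = FALSE)
    }
  }
  tf_peaks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               tf = character(), tissue = character())

  mid <- (cfg$hypo_mean + cfg$hyper_mean) / 2
  peak_df <- function(sel) {
    data.frame(chrom = truth$chrom[sel], start = tss[sel] - 200L,
               end = tss[sel] + 400L, stringsAsFactors = FALSE)
  }
  atac <- lapply(stats::setNames(cfg$tissues, cfg$tissues), function(tissue) {
    hypo <- truth[[paste0("planted_meth_", tissue)]] < mid
    p <- ifelse(hypo, cfg$atac_hypo_prob, cfg$atac_hyper_prob)
    peak_df(stats::runif(n) < p)
  })
  hm <- lapply(stats::setNames(c("h3k4me3", "h3k27ac"),
                               c("h3k4me3", "h3k27ac")), function(mark) {
    lapply(stats::setNames(cfg$tissues, cfg$tissues), function(tissue) {
      hypo <- truth[[paste0("planted_meth_", tissue)]] < mid
      in_set <- stats::runif(n) < ifelse(hypo, 0.8, 0.1)
      lapply(1:2, function(f) peak_df(in_set & stats::runif(n) < 0.95))
    })
  })
  cgi_p <- ifelse(truth$density_class == "high", cfg$cgi_high_prob,
                  cfg$cgi_low_prob)
  cgi <- peak_df(stats::runif(n) < cgi_p)
  list(tf_peaks = tf_peaks, atac = atac, hm = hm, cgi = cgi)
}

#' Generate synthetic gene sets (GMT) and their class map
#'
#' A 5'-TOP-motif-like set enriched in the first tissue's planted DRPs, a
#' pathway set enriched in the first tissue's planted DEGs, and random
#' background sets, with a KEGG-like category per set.
#'
#' @param cfg a `sim_config`.
#' @param truth truth table from [generate_proteome()].
#' @return list with `sets` (named list of gene ID vectors) and
#'   `class_map` (data.frame `set`, `class`).
#' @export
generate_gene_sets <- function(cfg, truth) {
  set.seed(cfg$seed + 6L)
  t1 <- cfg$tissues[1]
  genes <- truth$gene_id
  drp1 <- genes[truth$drp_label == t1]
  deg1 <- genes[truth$deg_label == t1]
  top_set <- unique(c(
    drp1[stats::runif(length(drp1)) < 0.8],
    sample(setdiff(genes, drp1), max(5, round(0.02 * length(genes))))
  ))
  liver_path <- unique(c(
    if (length(deg1)) sample(deg1, min(30, length(deg1))),
    sample(genes, 5)
  ))
  rand_sets <- lapply(1:8, function(i) sample(genes, 30))
  names(rand_sets) <- sprintf("Pathway_%02d", seq_along(rand_sets))
  sets <- c(list(TOP_motif = top_set, Dominant_metabolism = liver_path),
            rand_sets)
  classes <- c("Genetic Information Processing", "Metabolism",
               sample(c("Metabolism", "Organismal Systems",
                        "Cellular Process",
                        "Environmental Information Processing"),
                      length(rand_sets), replace = TRUE))
  list(sets = sets,
       class_map = data.frame(set = names(sets), class = classes,
                              stringsAsFactors = FALSE))
}

#' Simulate the full two-tissue study
#'
#' Runs all generator stages under the config's seed and returns the
#' in-memory bundle (identical configs give identical bundles).
#'
#' @param cfg a `sim_config`.
#' @return object of class `sim_study`: list with `cfg`, `annotation`,
#'   `meth`, `rna`, `prot`, `peaks`, `gene_sets`, and the completed `truth`
#'   table.
#' @export
simulate_study <- function(cfg) {
  ann <- generate_annotation(cfg)
  met <- generate_methylome(cfg, ann)
  rna <- generate_expression(cfg, ann, met$truth)
  prot <- generate_proteome(cfg, rna$truth)
  peaks <- generate_peaks(cfg, ann, prot$truth)
  sets <- generate_gene_sets(cfg, prot$truth)
  structure(list(cfg = cfg, annotation = ann, meth = met$counts,
                 rna = rna[c("counts", "tpm")], prot = prot[c("intensity", "map")],
                 peaks = peaks, gene_sets = sets, truth = prot$truth),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("sim_study:", nrow(x$truth), "genes;",
      nrow(x$meth$sites), "cytosine sites; tissues:",
      paste(x$cfg$tissues, collapse = ", "), "\n")
  invisible(x)
}
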