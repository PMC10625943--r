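#' Run configuration for a bundled input directory
#'
#' Collects input paths from a bundle directory (layout as written by
#' [write_bundle()]) together with the analysis parameters, all defaulting
#' to the study's canonical values: TSS window -200..+400 bp, scan
#' -1500..+2000 bp in 100-bp bins, q cutoffs 0.01, Fisher cutoff 0.001,
#' expression filter 6 replicates, protein detection 3 replicates, TF and
#' histone-mark flanks 1000 bp.
#'
#' @param dir bundle directory.
#' @param tissues character(2) tissue names.
#' @param ... parameter overrides (see Details in the source).
#' @return a `run_config` list with `paths` and `params`; input files are
#'   checked for existence.
#' @export
bundle_config <- function(dir, tissues = c("liver", "muscle"), ...) {
  find1 <- function(pattern, required = TRUE) {
    f <- list.files(dir, pattern = pattern, full.names = TRUE)
    if (length(f) == 0) {
      if (required) stop("missing input matching ", pattern, " in ", dir)
      return(NULL)
    }
    sort(f)
  }
  paths <- list(
    gtf = find1("^annotation\\.gtf$"),
    meth = stats::setNames(lapply(tissues, function(t) {
      find1(sprintf("^meth_%s_rep[0-9]+\\.tsv$", t))
    }), tissues),
    rna_counts = stats::setNames(lapply(tissues, function(t) {
      find1(sprintf("^rna_counts_%s\\.tsv$", t))
    }), tissues),
    rna_tpm = stats::setNames(lapply(tissues, function(t) {
      find1(sprintf("^rna_tpm_%s\\.tsv$", t))
    }), tissues),
    protein = {
      p <- lapply(tissues, function(t) {
        find1(sprintf("^protein_%s\\.tsv$", t), required = FALSE)
      })
      if (any(vapply(p, is.null, TRUE))) NULL else stats::setNames(p, tissues)
    },
    protein_map = find1("^protein_gene_map\\.tsv$", required = FALSE),
    peaks_dir = file.path(dir, "peaks"),
    gmt = find1("^gene_sets\\.gmt$", required = FALSE),
    set_classes = find1("^set_classes\\.tsv$", required = FALSE)
  )
  params <- utils::modifyList(list(
    window_upstream = 200, window_downstream = 400,
    scan_upstream = 1500, scan_downstream = 2000, scan_win = 100,
    scan_p_cut = 0.001,
    q_dm = 0.01, q_deg = 0.01, q_dep = 0.01, q_dtg = 0.01,
    fisher_cut = 0.001,
    min_reps_rna = 6, min_reps_prot = 3,
    tf_flank = 1000, hm_flank = 1000,
    min_coverage = 5, promoter_upstream = 1500,
    silverman_B = 200, seed = 1
  ), list(...))
  structure(list(dir = dir, tissues = tissues, paths = paths,
                 params = params), class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full two-tissue classification pipeline
#'
#' Executes annotation reading and TSS merging, window methylation with
#' Otsu/Silverman analysis, decile and sliding-window correlations,
#' per-CpG differential methylation and DMG calling, differential
#' expression, proteome normalization with DEP and DRP calling, TF-binding
#' DTG calling, peak-class overlaps, gene-level integration with composite
#' classes, CpG-density clustering, and gene-set enrichment.  Protein
#' stages are skipped (with a notice in the summary) when the bundle has no
#' proteome.
#'
#' @param config a `run_config` from [bundle_config()].
#' @param out_dir output directory for per-stage TSVs, the master
#'   classification table, and the JSON summary.
#' @return list with `master` (the gene-level classification table),
#'   `summary` (the summary list written as JSON), and the per-stage
#'   results (`window_meth`, `dmg`, `deg`, `dep`, `drp`, `dtg`, `scan`,
#'   `density`, ...).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  tissues <- config$tissues
  t1 <- tissues[1]; t2 <- tissues[2]
  cfg_hash <- rlang::hash(list(config$paths, config$params, config$tissues))
  summary <- list(config_hash = cfg_hash, tissues = tissues, notices = list())

  # --- annotation ---------------------------------------------------------
  merged <- .stage("annotation", {
    models <- read_gene_models(config$paths$gtf)
    merge_same_tss(models)
  })
  unit2gene <- merged$transcripts[, c("transcript_id", "gene_id")]

  # --- expression matrices at merged-unit level ---------------------------
  rna <- .stage("expression_input", {
    cnt <- lapply(config$paths$rna_counts, function(f) read_matrix_tsv(f[1]))
    tpm <- lapply(config$paths$rna_tpm, function(f) read_matrix_tsv(f[1]))
    list(counts = lapply(cnt, function(m) merge_expression(merged, m)),
         tpm = lapply(tpm, function(m) merge_expression(merged, m)))
  })
  mean_tpm <- lapply(rna$tpm, rowMeans)

  # --- methylome ----------------------------------------------------------
  meth <- .stage("methylome_input", read_meth_tables(config$paths$meth))
  wm <- .stage("window_methylation", {
    window_methylation(meth, merged, p$window_upstream, p$window_downstream,
                       p$min_coverage)
  })
  pooled <- wm$mean_ratio[!is.na(wm$mean_ratio)]
  thr <- .stage("otsu", otsu_threshold(pooled))
  silv <- .stage("silverman", {
    silverman_test(pooled, k_modes = 1, B = p$silverman_B, seed = p$seed)
  })
  wm <- classify_hypo_hyper(wm, thr)
  summary$otsu_threshold <- thr
  summary$silverman_p_unimodal <- silv$p

  # --- region/decile correlations and sliding-window scan -----------------
  regions <- .stage("regions", gene_regions(merged, p$promoter_upstream))
  region_cors <- list(); scans <- list()
  for (tissue in tissues) {
    rm_ <- region_methylation(meth, regions, tissue, p$min_coverage)
    expr <- mean_tpm[[tissue]]
    region_cors[[tissue]] <- lapply(
      stats::setNames(unique(rm_$region), unique(rm_$region)),
      function(reg) {
        sub <- rm_[rm_$region == reg, ]
        ratios <- stats::setNames(sub$mean_ratio, sub$transcript_id)
        tryCatch({
          rc <- region_decile_correlation(expr, ratios)
          list(rho = rc$rho, p = rc$p, n = rc$n)
        }, error = function(e) NULL)
      })
    scans[[tissue]] <- .stage("sliding_window_scan", {
      sliding_window_scan(expr, meth, merged, tissue,
                          win = p$scan_win, upstream = p$scan_upstream,
                          downstream = p$scan_downstream,
                          p_cut = p$scan_p_cut,
                          min_coverage = p$min_coverage)
    })
  }
  summary$region_decile_rho <- lapply(region_cors, function(x) {
    lapply(x, function(v) if (is.null(v)) NULL else v$rho)
  })
  summary$scan_argmin <- lapply(scans, `[[`, "argmin")
  summary$scan_significant_range <- lapply(scans, `[[`, "significant_range")

  # --- differential methylation ------------------------------------------
  dmg <- .stage("differential_methylation", {
    dmc <- dmcpg_test(meth, min_coverage = p$min_coverage)
    dmc <- call_dmcpgs(dmc, q_cut = p$q_dm)
    utils::write.table(dmc, file.path(out_dir, "dmcpg.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    call_dmgs(merged, dmc, wm, p$window_upstream, p$window_downstream)
  })
  summary$n_dmcpg <- sum(grepl("_hypo$",
    utils::read.table(file.path(out_dir, "dmcpg.tsv"), header = TRUE,
                      sep = "\t")$direction), na.rm = TRUE)
  summary$dmg_counts <- as.list(table(factor(dmg$label,
                                             levels = c(tissues, "none"))))

  # --- differential expression -------------------------------------------
  deg <- .stage("differential_expression", {
    deg_test(rna$counts, q_cut = p$q_deg, min_reps = p$min_reps_rna)
  })
  summary$deg_counts <- as.list(table(factor(
    deg$label[deg$expressed], levels = c(tissues, "none"))))
  fc_cor <- tryCatch(fc_methylation_correlation(deg, wm),
                     error = function(e) NULL)
  summary$fc_methylation_r <- if (is.null(fc_cor)) NULL else fc_cor$r

  # --- proteome -----------------------------------------------------------
  dep <- drp <- NULL; gene_sets <- NULL
  if (!is.null(config$paths$gmt)) gene_sets <- read_gmt(config$paths$gmt)
  if (!is.null(config$paths$protein)) {
    prot_res <- .stage("proteome", {
      intens <- lapply(config$paths$protein, function(f) read_matrix_tsv(f[1]))
      id_map <- utils::read.table(config$paths$protein_map, header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
      det <- detect_proteins(intens, min_reps = p$min_reps_prot)
      vsn <- vsn_fit(intens, det)
      mod <- moderated_test(vsn$transformed)
      dep_ <- call_deps(det, mod, q_cut = p$q_dep)
      gene_tpm_means <- lapply(mean_tpm, function(v) {
        out <- tapply(v, unit2gene$gene_id[match(names(v),
                                                 unit2gene$transcript_id)], sum)
        stats::setNames(as.numeric(out), names(out))
      })
      ratios <- protein_mrna_ratio(intens, gene_tpm_means, id_map, det)
      drp_ <- call_drps(ratios)
      list(dep = dep_, drp = drp_, vsn = vsn, map = id_map)
    })
    dep <- prot_res$dep; drp <- prot_res$drp
    summary$vsn <- prot_res$vsn[c("a", "b", "gamma")]
    summary$dep_counts <- as.list(table(factor(
      dep$label, levels = c(tissues, paste0(tissues, "_only"), "non_dep"))))
    summary$drp_counts <- as.list(table(factor(
      drp$label, levels = c(tissues, "none"))))
    if (!is.null(gene_sets) && "TOP_motif" %in% names(gene_sets)) {
      top <- top_motif_overlap(drp, gene_sets$TOP_motif)
      summary$top_motif <- top
    }
  } else {
    summary$notices <- c(summary$notices,
                         "no proteome in bundle: DEP/DRP stages skipped")
  }

  # --- TF binding / DTG ---------------------------------------------------
  dtg <- NULL
  tf_files <- list.files(config$paths$peaks_dir, pattern = "^tf_.*\\.bed$",
                         full.names = TRUE)
  if (length(tf_files) > 0) {
    dtg <- .stage("dtg", {
      pk <- do.call(rbind, lapply(tf_files, function(f) {
        base <- sub("\\.bed$", "", basename(f))
        parts <- strsplit(base, "_")[[1]]
        df <- read_peaks(f)
        if (nrow(df) == 0) return(NULL)
        df$tf <- parts[2]; df$tissue <- parts[3]
        df
      }))
      binding <- assign_binding(pk, merged, flank = p$tf_flank,
                                tissues = tissues)
      expr_l <- lapply(mean_tpm, function(v) v)
      tests <- binding_group_tests(binding, expr_l)
      utils::write.table(tests, file.path(out_dir, "binding_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      call_dtgs(binding, tests, q_cut = p$q_dtg)
    })
    summary$dtg_counts <- as.list(table(factor(dtg$label,
                                               levels = c("dtg", "non_dtg"))))
  }

  # --- peak-class overlaps (ATAC / histone marks / CpG islands) -----------
  overlaps <- list()
  classified_units <- function(tissue, state) {
    sub <- wm[wm$tissue == tissue & wm$state %in% state, ]
    sub$transcript_id
  }
  universe_units <- unique(wm$transcript_id[!is.na(wm$state)])
  atac_files <- file.path(config$paths$peaks_dir,
                          sprintf("atac_%s.bed", tissues))
  for (i in seq_along(tissues)) {
    if (file.exists(atac_files[i])) {
      open_genes <- genes_with_peaks(read_peaks(atac_files[i]), merged,
                                     flank = p$hm_flank)
      overlaps[[paste0("atac_hypo_", tissues[i])]] <-
        peak_class_overlap(classified_units(tissues[i], "hypo"), open_genes,
                           universe_units, tail = "right")$p
      overlaps[[paste0("atac_hyper_", tissues[i])]] <-
        peak_class_overlap(classified_units(tissues[i], "hyper"), open_genes,
                           universe_units, tail = "left")$p
    }
    for (mark in c("h3k4me3", "h3k27ac")) {
      mf <- list.files(config$paths$peaks_dir,
                       pattern = sprintf("^%s_%s_[0-9]+\\.bed$", mark,
                                         tissues[i]),
                       full.names = TRUE)
      if (length(mf) > 0) {
        marked <- genes_with_peaks(lapply(mf, read_peaks), merged,
                                   flank = p$hm_flank)
        overlaps[[paste0(mark, "_hypo_", tissues[i])]] <-
          peak_class_overlap(classified_units(tissues[i], "hypo"), marked,
                             universe_units, tail = "right")$p
      }
    }
  }
  cgi_file <- file.path(config$paths$peaks_dir, "cpg_islands.bed")
  density <- .stage("cpg_density", {
    cpg_sites <- meth$sites[meth$sites$context == "CpG", c("chrom", "pos")]
    dmg_lab <- stats::setNames(dmg$label, dmg$transcript_id)
    cpg_density_analysis(merged, cpg_sites, dmg_lab,
                         upstream = p$window_upstream,
                         downstream = p$window_downstream)
  })
  if (file.exists(cgi_file)) {
    cgi_genes <- genes_with_peaks(read_peaks(cgi_file), merged,
                                  flank = p$hm_flank)
    dmg_units <- dmg$transcript_id[dmg$label != "none"]
    overlaps$cgi_dmg_left <- peak_class_overlap(
      dmg_units, cgi_genes, universe_units, tail = "left")$p
  }
  summary$peak_overlap_p <- overlaps
  summary$density_median_dmg <- if (!is.null(density$dmg_test))
    density$dmg_test$median_dmg else NULL
  summary$density_median_non <- if (!is.null(density$dmg_test))
    density$dmg_test$median_non else NULL

  # --- integration --------------------------------------------------------
  master <- .stage("integration", {
    prot_map <- if (!is.null(dep))
      utils::read.table(config$paths$protein_map, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE) else NULL
    ct <- collapse_to_gene(dmg = dmg, deg = deg, dep = dep, drp = drp,
                           dtg = dtg, tx2gene = unit2gene,
                           prot2gene = prot_map, tissues = tissues)
    derive_composites(ct)
  })
  venn <- attr(master, "venn")
  summary$venn <- venn
  for (tissue in tissues) {
    ok <- tryCatch(overlap_significance(master, "dmg", tissue, "deg", tissue,
                                        tail = "right"),
                   error = function(e) NULL)
    summary[[paste0("dmg_deg_overlap_p_", tissue)]] <-
      if (is.null(ok)) NULL else ok$p
  }

  # --- enrichment ---------------------------------------------------------
  if (!is.null(gene_sets)) {
    class_map <- if (!is.null(config$paths$set_classes)) {
      utils::read.table(config$paths$set_classes, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    } else NULL
    enr <- .stage("enrichment", {
      universe <- master$gene_id[!is.na(master$deg)]
      out <- list()
      for (tissue in tissues) {
        lst <- master$gene_id[master$dm_deg %in% tissue]
        if (length(lst) >= 3) {
          out[[paste0("dm_deg_", tissue)]] <-
            enrichment(lst, gene_sets, universe, class_map)
        }
      }
      out
    })
    for (nm in names(enr)) {
      utils::write.table(enr[[nm]],
                         file.path(out_dir, paste0("enrichment_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary$enrichment_top <- lapply(enr, function(e) {
      utils::head(e[e$significant, c("set", "class", "q")], 5)
    })
  }

  # --- outputs ------------------------------------------------------------
  aug <- master
  for (tissue in tissues) {
    sub <- wm[wm$tissue == tissue, ]
    g <- unit2gene$gene_id[match(sub$transcript_id, unit2gene$transcript_id)]
    agg <- tapply(sub$mean_ratio, g, mean, na.rm = TRUE)
    aug[[paste0("window_ratio_", tissue)]] <-
      round(as.numeric(agg[aug$gene_id]), 6)
  }
  dens_gene <- tapply(density$total,
                      unit2gene$gene_id[match(names(density$total),
                                              unit2gene$transcript_id)], sum)
  aug$window_cpgs <- as.integer(dens_gene[aug$gene_id])
  dcls <- tapply(density$density_class,
                 unit2gene$gene_id[match(names(density$density_class),
                                         unit2gene$transcript_id)],
                 function(v) if (any(v == "high")) "high" else "low")
  aug$density_class <- as.character(dcls[aug$gene_id])
  aug <- aug[order(aug$gene_id), , drop = FALSE]
  master_path <- file.path(out_dir, "master_table.tsv")
  con <- file(master_path, "w")
  writeLines(paste0("# config_hash: ", cfg_hash), con)
  suppressWarnings(utils::write.table(aug, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  utils::write.table(wm, file.path(out_dir, "window_methylation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dmg, file.path(out_dir, "dmg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(deg, file.path(out_dir, "deg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(dep)) {
    utils::write.table(dep, file.path(out_dir, "dep.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(drp, file.path(out_dir, "drp.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(dtg)) {
    utils::write.table(dtg, file.path(out_dir, "dtg.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (tissue in tissues) {
    utils::write.table(scans[[tissue]]$profile,
                       file.path(out_dir, paste0("scan_", tissue, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  invisible(list(master = aug, summary = summary, window_meth = wm,
                 dmg = dmg, deg = deg, dep = dep, drp = drp, dtg = dtg,
                 scan = scans, density = density, threshold = thr,
                 region_cors = region_cors))
}
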