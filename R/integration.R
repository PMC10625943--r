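#' Collapse feature-level calls to gene level
#'
#' Maps transcript-level (DMG, DEG, DTG) and protein-level (DEP, DRP) calls
#' to gene IDs and aggregates.  For directional classes, a gene whose
#' members carry opposing tissue directions is flagged `"conflict"` and is
#' excluded from directional overlaps downstream; the DTG class is a
#' per-gene boolean (any member DTG).  IDs missing from the maps are
#' excluded with a warning (exclusion list in attribute `"excluded"`).
#'
#' @param dmg,deg,dtg transcript-level call data.frames ([call_dmgs()],
#'   [deg_test()], [call_dtgs()]); any may be `NULL`.
#' @param dep,drp protein-level call data.frames ([call_deps()],
#'   [call_drps()]); any may be `NULL`.
#' @param tx2gene data.frame `transcript_id`, `gene_id`.
#' @param prot2gene data.frame `protein_id`, `gene_id`.
#' @param tissues character(2): tissue names (directions).
#' @return data.frame, one row per gene: `gene_id` and columns `dmg`,
#'   `deg`, `dep`, `drp` (tissue name, `"none"`, `"conflict"`, or `NA` when
#'   unmeasured), `dtg` (logical or `NA`), `dep_only` (logical: any member
#'   detected in only one tissue).
#' @export
collapse_to_gene <- function(dmg = NULL, deg = NULL, dep = NULL, drp = NULL,
                             dtg = NULL, tx2gene, prot2gene = NULL, tissues) {
  excluded <- character(0)
  map_ids <- function(ids, map, id_col) {
    g <- map$gene_id[match(ids, map[[id_col]])]
    bad <- ids[is.na(g)]
    if (length(bad) > 0) excluded <<- c(excluded, bad)
    g
  }
  # directional collapse: unique non-null directions -> tissue | conflict | none
  collapse_dir <- function(ids, labels, map, id_col) {
    g <- map_ids(ids, map, id_col)
    keep <- !is.na(g)
    labs <- labels[keep]; g <- g[keep]
    dir <- ifelse(labs %in% tissues, labs,
                  ifelse(labs == paste0(tissues[1], "_only"), tissues[1],
                         ifelse(labs == paste0(tissues[2], "_only"), tissues[2],
                                NA_character_)))
    per_gene <- split(dir, g)
    vapply(per_gene, function(v) {
      u <- unique(v[!is.na(v)])
      if (length(u) == 0) "none" else if (length(u) == 1) u else "conflict"
    }, "")
  }
  genes <- character(0)
  cols <- list()
  if (!is.null(dmg)) {
    cols$dmg <- collapse_dir(dmg$transcript_id, dmg$label, tx2gene, "transcript_id")
    genes <- union(genes, names(cols$dmg))
  }
  if (!is.null(deg)) {
    cols$deg <- collapse_dir(deg$gene_id, deg$label, tx2gene, "transcript_id")
    genes <- union(genes, names(cols$deg))
  }
  if (!is.null(dep)) {
    cols$dep <- collapse_dir(dep$protein_id, dep$label, prot2gene, "protein_id")
    genes <- union(genes, names(cols$dep))
    only <- dep$label %in% paste0(tissues, "_only")
    g <- map_ids(dep$protein_id, prot2gene, "protein_id")
    cols$dep_only <- vapply(split(only[!is.na(g)], g[!is.na(g)]), any, TRUE)
  }
  if (!is.null(drp)) {
    cols$drp <- collapse_dir(drp$protein_id, drp$label, prot2gene, "protein_id")
    genes <- union(genes, names(cols$drp))
  }
  if (!is.null(dtg)) {
    g <- map_ids(dtg$transcript_id, tx2gene, "transcript_id")
    keep <- !is.na(g)
    cols$dtg <- vapply(split(dtg$label[keep] == "dtg", g[keep]), any, TRUE)
    genes <- union(genes, names(cols$dtg))
  }
  genes <- sort(genes)
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (nm in c("dmg", "deg", "dep", "drp")) {
    if (!is.null(cols[[nm]])) {
      out[[nm]] <- unname(cols[[nm]][genes])
    }
  }
  if (!is.null(cols$dtg)) out$dtg <- unname(cols$dtg[genes])
  if (!is.null(cols$dep_only)) {
    v <- unname(cols$dep_only[genes]); v[is.na(v) & !is.na(out$dep)] <- FALSE
    out$dep_only <- v
  }
  excluded <- unique(excluded)
  if (length(excluded) > 0) {
    warning(length(excluded), " feature ID(s) had no gene mapping and were excluded")
  }
  attr(out, "excluded") <- excluded
  attr(out, "tissues") <- tissues
  out
}

#' Derive composite classes and Venn counts
#'
#' Adds the direction-consistent composite flags:
#' \itemize{
#'   \item `dm_deg`: DMG and DEG in the same tissue;
#'   \item `dm_dep`: DM-DEG whose protein is a DEP in the same tissue;
#'   \item `dr_dep`: DRP and DEP in the same tissue;
#'   \item `dt_dep`: DTG gene that is a DEG and DEP in the same tissue;
#'   \item `non_overlap`: non-DMG and non-DEG (and non-DEP when measured).
#' }
#' Composite direction columns hold the tissue name or `"none"`.
#'
#' @param tbl gene-level table from [collapse_to_gene()].
#' @return `tbl` with composite columns; attribute `"venn"` carries the
#'   per-direction and cross-direction overlap counts.
#' @export
derive_composites <- function(tbl) {
  tissues <- attr(tbl, "tissues")
  has <- function(col) !is.null(tbl[[col]])
  dir_match <- function(a, b) {
    ifelse(!is.na(a) & !is.na(b) & a %in% tissues & a == b, a, "none")
  }
  if (has("dmg") && has("deg")) tbl$dm_deg <- dir_match(tbl$dmg, tbl$deg)
  if (has("dm_deg") && has("dep")) {
    tbl$dm_dep <- ifelse(tbl$dm_deg != "none" & !is.na(tbl$dep) &
                           tbl$dep == tbl$dm_deg, tbl$dm_deg, "none")
  }
  if (has("drp") && has("dep")) tbl$dr_dep <- dir_match(tbl$drp, tbl$dep)
  if (has("dtg") && has("deg") && has("dep")) {
    de_pair <- dir_match(tbl$deg, tbl$dep)
    tbl$dt_dep <- ifelse(!is.na(tbl$dtg) & tbl$dtg & de_pair != "none",
                         de_pair, "none")
  }
  if (has("dmg") && has("deg")) {
    tbl$non_overlap <- !is.na(tbl$dmg) & tbl$dmg == "none" &
      !is.na(tbl$deg) & tbl$deg == "none"
  }
  venn <- list()
  count_dir <- function(col, tissue) sum(tbl[[col]] %in% tissue)
  for (tissue in tissues) {
    venn[[tissue]] <- c(
      dmg = if (has("dmg")) count_dir("dmg", tissue) else NA,
      deg = if (has("deg")) count_dir("deg", tissue) else NA,
      dep = if (has("dep")) count_dir("dep", tissue) else NA,
      drp = if (has("drp")) count_dir("drp", tissue) else NA,
      dm_deg = if (has("dm_deg")) count_dir("dm_deg", tissue) else NA,
      dm_dep = if (has("dm_dep")) count_dir("dm_dep", tissue) else NA,
      dr_dep = if (has("dr_dep")) count_dir("dr_dep", tissue) else NA,
      dt_dep = if (has("dt_dep")) count_dir("dt_dep", tissue) else NA
    )
  }
  if (has("dmg") && has("deg")) {
    venn$cross_direction <- c(
      dmg1_deg2 = sum(tbl$dmg %in% tissues[1] & tbl$deg %in% tissues[2]),
      dmg2_deg1 = sum(tbl$dmg %in% tissues[2] & tbl$deg %in% tissues[1])
    )
  }
  attr(tbl, "venn") <- venn
  attr(tbl, "tissues") <- tissues
  tbl
}

#' Fisher test for overlap of two gene classes
#'
#' 2x2 Fisher test of membership in class A against class B over the genes
#' where both classifications are defined (non-`NA`).
#'
#' @param tbl gene-level classification table.
#' @param col_a,col_b column names.
#' @param val_a,val_b values defining membership (e.g. a tissue name; for
#'   logical columns use `TRUE`).
#' @param tail Fisher tail (`"right"` = enrichment, `"left"` = depletion).
#' @return list with `table`, `p`, `tail`, `n_universe`.
#' @export
overlap_significance <- function(tbl, col_a, val_a, col_b, val_b,
                                 tail = c("right", "left", "two")) {
  tail <- match.arg(tail)
  ok <- !is.na(tbl[[col_a]]) & !is.na(tbl[[col_b]])
  if (!any(ok)) stop("degenerate universe: no gene has both classifications")
  a <- tbl[[col_a]][ok] %in% val_a
  b <- tbl[[col_b]][ok] %in% val_b
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                2, byrow = TRUE,
                dimnames = list(c("A", "not_A"), c("B", "not_B")))
  list(table = tab, p = fisher_exact(tab, tail = tail), tail = tail,
       n_universe = sum(ok))
}

#' CpG density vectors, clustering, and DMG density contrast
#'
#' Counts CpG positions in fixed-width strand-aware bins across the TSS
#' window (default fifteen 40-bp bins over `[-200, +400)`), Ward-clusters
#' the density vectors into two groups named `low`/`high` by mean total
#' count, and (when DMG labels are supplied) contrasts window CpG totals
#' between DMGs and non-DMGs with a Wilcoxon rank-sum test.
#'
#' @param models a `gene_models` object.
#' @param cpgs data.frame of CpG positions (`chrom`, `pos`; CpG context
#'   only).
#' @param dmg_labels optional named vector of DMG labels per transcript
#'   (tissue or `"none"`).
#' @param upstream,downstream window extents (bp).
#' @param binwidth bin width (bp; must divide the window length).
#' @return list with `vectors` (genes x bins count matrix), `total` (named
#'   vector), `density_class` (named `"low"`/`"high"`), and `dmg_test`
#'   (list `p`, `median_dmg`, `median_non`; `NULL` without labels).
#' @export
cpg_density_analysis <- function(models, cpgs, dmg_labels = NULL,
                                 upstream = 200, downstream = 400,
                                 binwidth = 40) {
  stopifnot((upstream + downstream) %% binwidth == 0)
  n_bins <- (upstream + downstream) %/% binwidth
  win <- tss_window(models, upstream, downstream)
  asn <- assign_cpgs_to_windows(cpgs, win)
  ids <- win$transcript_id
  vectors <- matrix(0L, length(ids), n_bins,
                    dimnames = list(ids, paste0("bin", seq_len(n_bins))))
  if (nrow(asn) > 0) {
    bin <- (asn$offset + upstream) %/% binwidth + 1L
    t0 <- table(factor(asn$transcript_id, levels = ids), factor(bin, levels = seq_len(n_bins)))
    vectors <- matrix(as.integer(t0), nrow = length(ids),
                      dimnames = list(ids, paste0("bin", seq_len(n_bins))))
  }
  total <- rowSums(vectors)
  cl <- ward_cluster(vectors, k = 2)
  means <- tapply(total, cl, mean)
  low_cl <- as.integer(names(means)[which.min(means)])
  density_class <- stats::setNames(ifelse(cl == low_cl, "low", "high"), ids)
  dmg_test <- NULL
  if (!is.null(dmg_labels)) {
    is_dmg <- dmg_labels[ids] != "none" & !is.na(dmg_labels[ids])
    if (any(is_dmg) && any(!is_dmg)) {
      wt <- stats::wilcox.test(total[is_dmg], total[!is_dmg], exact = FALSE)
      dmg_test <- list(p = wt$p.value,
                       median_dmg = stats::median(total[is_dmg]),
                       median_non = stats::median(total[!is_dmg]))
    }
  }
  list(vectors = vectors, total = total, density_class = density_class,
       dmg_test = dmg_test)
}

#' Gene-set enrichment by Fisher's exact test
#'
#' Right-tailed Fisher enrichment of a gene list in each gene set against a
#' background universe (all measured genes/proteins at the relevant level),
#' with Benjamini-Hochberg correction across sets and optional grouping by
#' a set-to-category class map.
#'
#' @param genes character vector (the list of interest; must be a subset of
#'   `universe`).
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector: background gene IDs.
#' @param class_map optional data.frame `set`, `class`.
#' @param q_cut significance cutoff recorded in the `significant` column.
#' @return data.frame per set: `set`, `class`, `n_set`, `n_overlap`, `p`,
#'   `q`, `significant`, sorted by p.
#' @export
enrichment <- function(genes, gene_sets, universe, class_map = NULL,
                       q_cut = 0.01) {
  stray <- setdiff(genes, universe)
  if (length(stray) > 0) {
    stop("gene list not contained in universe: ",
         paste(utils::head(stray, 5), collapse = ", "),
         if (length(stray) > 5) " ..." else "")
  }
  if (any(lengths(gene_sets) == 0)) stop("empty gene set supplied")
  n_u <- length(universe)
  n_g <- length(genes)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    a <- length(intersect(genes, s))
    tab <- matrix(c(a, n_g - a, length(s) - a, n_u - n_g - length(s) + a),
                  2, byrow = TRUE)
    data.frame(set = nm, n_set = length(s), n_overlap = a,
               p = fisher_exact(tab, tail = "right"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_cut
  out$class <- if (!is.null(class_map)) {
    class_map$class[match(out$set, class_map$set)]
  } else NA_character_
  out[order(out$p), c("set", "class", "n_set", "n_overlap", "p", "q",
                      "significant")]
}
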