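#' Assign TF peaks to genes by TSS-flank intersection
#'
#' A TF is bound to a gene in a tissue when at least one of its peaks
#' intersects the strand-agnostic flank `[TSS - flank, TSS + flank)`
#' (half-open, genomic orientation).  Multiple peaks collapse to one bound
#' flag.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `tf`, `tissue`.
#' @param models a `gene_models` object.
#' @param flank flank size in bp on each side of the TSS.
#' @param tissues tissue names; defaults to those present in `peaks`, but
#'   should be given explicitly when a tissue may have no peaks at all.
#' @return object of class `binding_state`: list with `bound` (data.frame
#'   `transcript_id`, `tissue`, `tf`, unique rows), `states` (data.frame
#'   `transcript_id` and one state string per tissue: sorted TF names
#'   joined by `+`, `""` when unbound), `tissues`, `tfs`.
#' @export
assign_binding <- function(peaks, models, flank = 1000,
                           tissues = sort(unique(peaks$tissue))) {
  tr <- models$transcripts
  if (nrow(peaks) > 0 && !any(peaks$chrom %in% tr$chrom)) {
    stop("chromosome name mismatch between peaks and annotation")
  }
  gr_flank <- .intervals_to_granges(tr$chrom, tr$tss - flank, tr$tss + flank)
  bound <- data.frame(transcript_id = character(), tissue = character(),
                      tf = character(), stringsAsFactors = FALSE)
  if (nrow(peaks) > 0) {
    gr_peaks <- .intervals_to_granges(peaks$chrom, peaks$start, peaks$end)
    hits <- GenomicRanges::findOverlaps(gr_peaks, gr_flank, ignore.strand = TRUE)
    bound <- unique(data.frame(
      transcript_id = tr$transcript_id[S4Vectors::subjectHits(hits)],
      tissue = peaks$tissue[S4Vectors::queryHits(hits)],
      tf = peaks$tf[S4Vectors::queryHits(hits)],
      stringsAsFactors = FALSE
    ))
  }
  states <- data.frame(transcript_id = tr$transcript_id, stringsAsFactors = FALSE)
  for (tissue in tissues) {
    sub <- bound[bound$tissue == tissue, , drop = FALSE]
    st <- vapply(split(sub$tf, sub$transcript_id),
                 function(v) paste(sort(unique(v)), collapse = "+"), "")
    col <- st[states$transcript_id]
    col[is.na(col)] <- ""
    states[[paste0("state_", tissue)]] <- unname(col)
  }
  structure(list(bound = bound, states = states, tissues = tissues,
                 tfs = sort(unique(peaks$tf))),
            class = "binding_state")
}

#' Welch tests over TF-binding-state gene groups
#'
#' Two families of comparisons of gene-expression distributions
#' (`log2(TPM + 1)` by default), each within each tissue:
#' \itemize{
#'   \item marginal: per TF, genes bound vs unbound by that TF;
#'   \item pairwise: for every ordered pair of binding states observed as a
#'     cross-tissue difference in some gene, the gene group in the first
#'     state vs the group in the second state.
#' }
#' All p-values are corrected together with Storey q-values.  Groups with
#' fewer than `min_group` genes are skipped and recorded.
#'
#' @param binding a `binding_state` object from [assign_binding()].
#' @param expression named list (per tissue) of named per-gene expression
#'   vectors (linear TPM; log2(TPM+1) is taken internally unless
#'   `log_transform = FALSE`).
#' @param min_group minimum genes per compared group.
#' @param log_transform take log2(x + 1) before testing.
#' @return data.frame: `family` (`"marginal"`/`"pair"`), `comparison`
#'   (TF name, or `"stateA|stateB"`), `tissue`, `n1`, `n2`, `t`, `p`, `q`,
#'   `skipped`.
#' @export
binding_group_tests <- function(binding, expression, min_group = 3,
                                log_transform = TRUE) {
  states <- binding$states
  tissues <- binding$tissues
  expr <- lapply(expression, function(e) {
    if (log_transform) log2(e + 1) else e
  })
  rows <- list()
  for (tissue in tissues) {
    st <- states[[paste0("state_", tissue)]]
    e <- expr[[tissue]][states$transcript_id]
    for (tf in binding$tfs) {
      has <- vapply(strsplit(st, "+", fixed = TRUE), function(v) tf %in% v, TRUE)
      g1 <- e[has & !is.na(e)]; g2 <- e[!has & !is.na(e)]
      skipped <- length(g1) < min_group || length(g2) < min_group
      res <- if (skipped) list(t = NA_real_, p = NA_real_) else welch_t(g1, g2)
      rows[[length(rows) + 1]] <- data.frame(
        family = "marginal", comparison = tf, tissue = tissue,
        n1 = length(g1), n2 = length(g2), t = res$t, p = res$p,
        skipped = skipped, stringsAsFactors = FALSE)
    }
  }
  # state pairs observed as a cross-tissue difference
  sa <- states[[paste0("state_", tissues[1])]]
  sb <- states[[paste0("state_", tissues[2])]]
  diff_pairs <- unique(data.frame(s1 = sa, s2 = sb,
                                  stringsAsFactors = FALSE)[sa != sb, ])
  if (nrow(diff_pairs) > 0) {
    for (i in seq_len(nrow(diff_pairs))) {
      s1 <- diff_pairs$s1[i]; s2 <- diff_pairs$s2[i]
      for (tissue in tissues) {
        st <- states[[paste0("state_", tissue)]]
        e <- expr[[tissue]][states$transcript_id]
        g1 <- e[st == s1 & !is.na(e)]; g2 <- e[st == s2 & !is.na(e)]
        skipped <- length(g1) < min_group || length(g2) < min_group
        res <- if (skipped) list(t = NA_real_, p = NA_real_) else welch_t(g1, g2)
        rows[[length(rows) + 1]] <- data.frame(
          family = "pair", comparison = paste(s1, s2, sep = "|"),
          tissue = tissue, n1 = length(g1), n2 = length(g2),
          t = res$t, p = res$p, skipped = skipped, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- !out$skipped & !is.na(out$p)
  if (any(tested)) out$q[tested] <- as.numeric(storey_qvalue(out$p[tested]))
  out
}

#' Call differentially TF-bound genes (DTGs)
#'
#' A gene whose binding states differ between tissues is a DTG when its
#' specific state pair is significant in the pairwise family
#' (`basis = "direct_test"`), or, failing that, when its state difference
#' decomposes entirely into TFs that are each individually significant in
#' the marginal family (`basis = "combination_inference"`).  Genes with
#' identical states in both tissues are `non_dtg` regardless of tests.
#'
#' @param binding a `binding_state` object.
#' @param tests data.frame from [binding_group_tests()].
#' @param q_cut q-value cutoff.
#' @return data.frame `transcript_id`, `label` (`"dtg"`/`"non_dtg"`),
#'   `basis`, `differing_tfs` (comma-joined), `state_<tissue>` columns.
#' @export
call_dtgs <- function(binding, tests, q_cut = 0.01) {
  states <- binding$states
  tissues <- binding$tissues
  sa <- states[[paste0("state_", tissues[1])]]
  sb <- states[[paste0("state_", tissues[2])]]
  sig <- tests[!tests$skipped & !is.na(tests$q) & tests$q < q_cut, , drop = FALSE]
  sig_pairs <- unique(sig$comparison[sig$family == "pair"])
  sig_tfs <- unique(sig$comparison[sig$family == "marginal"])
  split_state <- function(s) if (s == "") character(0) else strsplit(s, "+", fixed = TRUE)[[1]]
  n <- nrow(states)
  label <- rep("non_dtg", n); basis <- rep(NA_character_, n)
  differing <- character(n)
  for (i in seq_len(n)) {
    if (sa[i] == sb[i]) next
    d <- c(setdiff(split_state(sa[i]), split_state(sb[i])),
           setdiff(split_state(sb[i]), split_state(sa[i])))
    differing[i] <- paste(sort(d), collapse = ",")
    if (paste(sa[i], sb[i], sep = "|") %in% sig_pairs) {
      label[i] <- "dtg"; basis[i] <- "direct_test"
    } else if (length(d) > 0 && all(d %in% sig_tfs)) {
      label[i] <- "dtg"; basis[i] <- "combination_inference"
    }
  }
  out <- data.frame(transcript_id = states$transcript_id, label = label,
                    basis = basis, differing_tfs = differing,
                    stringsAsFactors = FALSE)
  out[[paste0("state_", tissues[1])]] <- sa
  out[[paste0("state_", tissues[2])]] <- sb
  attr(out, "tissues") <- tissues
  out
}

#' Genes covered by peaks around the TSS
#'
#' Returns the genes with at least one peak intersecting
#' `[TSS - flank, TSS + flank)`.  When several peak files (replicate
#' sources) are given, a gene must be covered in at least `min_files` of
#' them (default: all), mirroring a consistency requirement across sources.
#'
#' @param peak_list list of peak data.frames (`chrom`, `start`, `end`).
#' @param models a `gene_models` object.
#' @param flank flank in bp.
#' @param min_files minimum number of files covering the gene.
#' @return character vector of transcript IDs.
#' @export
genes_with_peaks <- function(peak_list, models, flank = 1000,
                             min_files = length(peak_list)) {
  if (is.data.frame(peak_list)) peak_list <- list(peak_list)
  tr <- models$transcripts
  gr_flank <- .intervals_to_granges(tr$chrom, tr$tss - flank, tr$tss + flank)
  hits_per_file <- vapply(peak_list, function(pk) {
    if (nrow(pk) == 0) return(rep(FALSE, nrow(tr)))
    gr <- .intervals_to_granges(pk$chrom, pk$start, pk$end)
    GenomicRanges::countOverlaps(gr_flank, gr, ignore.strand = TRUE) > 0
  }, logical(nrow(tr)))
  hits_per_file <- matrix(hits_per_file, nrow = nrow(tr))
  tr$transcript_id[rowSums(hits_per_file) >= min_files]
}

#' Fisher overlap of a gene class with a peak-derived gene set
#'
#' 2x2 contingency of membership in gene class `class_genes` against
#' membership in set `set_genes` over `universe`, with a one- or two-tailed
#' Fisher test (right tail = enrichment, left = depletion).
#'
#' @param class_genes,set_genes character vectors of gene IDs.
#' @param universe character vector: the gene universe (both inputs are
#'   intersected with it).
#' @param tail Fisher tail.
#' @return list with `table` (2x2 matrix), `p`, `tail`.
#' @export
peak_class_overlap <- function(class_genes, set_genes, universe,
                               tail = c("right", "left", "two")) {
  tail <- match.arg(tail)
  if (length(universe) == 0) stop("empty gene universe")
  in_class <- universe %in% class_genes
  in_set <- universe %in% set_genes
  tab <- matrix(c(sum(in_class & in_set), sum(in_class & !in_set),
                  sum(!in_class & in_set), sum(!in_class & !in_set)),
                2, byrow = TRUE,
                dimnames = list(c("class", "not_class"), c("set", "not_set")))
  list(table = tab, p = fisher_exact(tab, tail = tail), tail = tail)
}
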