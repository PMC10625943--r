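#' Read gene models from GTF or BED12
#'
#' Parses transcript gene models into the package's internal representation:
#' one record per transcript with a strand-aware TSS and its exon chain.
#' All internal coordinates are 0-based half-open; GTF input (1-based
#' closed, Ensembl dialect) and BED12 input are converted at this boundary.
#'
#' @param path path to a `.gtf` or `.bed` (BED12) file.
#' @param format `"auto"` (by extension), `"gtf"`, or `"bed12"`.
#' @return a `gene_models` object: list with data.frames `transcripts`
#'   (`transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`)
#'   and `exons` (`transcript_id`, `chrom`, `strand`, `start`, `end`,
#'   `rank`; rank is 5'-to-3' in strand order).
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0) stop("no exon records found in ", path)
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(strand == "*")) {
      warning("rejecting ", sum(strand == "*"), " exon record(s) with unknown strand")
      gr <- gr[strand != "*"]
    }
    ex <- data.frame(
      transcript_id = as.character(gr$transcript_id),
      gene_id = if (!is.null(gr$gene_id)) as.character(gr$gene_id)
                else as.character(gr$transcript_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(strand == "*")) {
      warning("rejecting ", sum(strand == "*"), " BED record(s) with unknown strand")
      gr <- gr[strand != "*"]
    }
    blocks <- gr$blocks
    if (is.null(blocks)) stop("BED input lacks block (exon) structure; need BED12")
    ex <- do.call(rbind, lapply(seq_along(gr), function(i) {
      bl <- blocks[[i]]
      abs_start <- GenomicRanges::start(gr[i]) - 1L + (IRanges::start(bl) - 1L)
      data.frame(
        transcript_id = as.character(gr$name[i]),
        gene_id = as.character(gr$name[i]),
        chrom = as.character(GenomicRanges::seqnames(gr[i])),
        strand = as.character(GenomicRanges::strand(gr[i])),
        start = abs_start,
        end = abs_start + IRanges::width(bl),
        stringsAsFactors = FALSE
      )
    }))
  }
  .build_gene_models(ex)
}

.build_gene_models <- function(ex) {
  ord <- order(ex$transcript_id, ex$start)
  ex <- ex[ord, , drop = FALSE]
  ranks <- unlist(lapply(split(seq_len(nrow(ex)), ex$transcript_id), function(idx) {
    if (ex$strand[idx[1]] == "+") seq_along(idx) else rev(seq_along(idx))
  }))
  ex$rank <- NA_integer_
  ex$rank[unlist(split(seq_len(nrow(ex)), ex$transcript_id))] <- ranks
  tx_split <- split(ex, ex$transcript_id)
  tr <- do.call(rbind, lapply(tx_split, function(e) {
    s <- min(e$start); en <- max(e$end)
    data.frame(
      transcript_id = e$transcript_id[1], gene_id = e$gene_id[1],
      chrom = e$chrom[1], strand = e$strand[1],
      start = s, end = en,
      tss = if (e$strand[1] == "+") s else en - 1L,
      stringsAsFactors = FALSE
    )
  }))
  rownames(tr) <- NULL; rownames(ex) <- NULL
  structure(list(transcripts = tr, exons = ex), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons on",
      length(unique(x$transcripts$chrom)), "chromosome(s)\n")
  invisible(x)
}

# strand-aware half-open window around a 0-based TSS position.
# "+": [tss - up, tss + down); "-": mirrored, [tss - down + 1, tss + up + 1).
# Both contain the TSS base when down >= 1 (or up >= 1 on "-").
.window0 <- function(tss, strand, upstream, downstream) {
  plus <- strand == "+"
  start <- ifelse(plus, tss - upstream, tss - downstream + 1)
  end <- ifelse(plus, tss + downstream, tss + upstream + 1)
  cbind(start = start, end = end)
}

#' TSS windows for gene models
#'
#' Strand-aware half-open windows `[TSS - upstream, TSS + downstream)`
#' (in transcription direction) around each transcript's TSS.  Windows
#' extending past the chromosome start are clipped and flagged.
#'
#' @param models a `gene_models` object (or its `transcripts` data.frame).
#' @param upstream,downstream extents in bp (>= 0).
#' @return data.frame with `transcript_id`, `chrom`, `strand`, `tss`,
#'   `start`, `end`, `clipped`.
#' @export
tss_window <- function(models, upstream = 200, downstream = 400) {
  stopifnot(upstream >= 0, downstream >= 0)
  tr <- if (inherits(models, "gene_models")) models$transcripts else models
  w <- .window0(tr$tss, tr$strand, upstream, downstream)
  clipped <- w[, "start"] < 0
  data.frame(
    transcript_id = tr$transcript_id, chrom = tr$chrom, strand = tr$strand,
    tss = tr$tss, start = pmax(w[, "start"], 0L), end = pmax(w[, "end"], 0L),
    clipped = clipped, stringsAsFactors = FALSE
  )
}

#' Genomic regions of a gene model
#'
#' Computes, per transcript, the canonical region intervals used for
#' region-level methylation summaries: `promoter` (default
#' `[TSS-1500, TSS)` strand-aware, excluding the TSS base), `first_exon`,
#' `first_intron`, `other_exons`, `other_introns`, and `gene_body`.
#'
#' @param models a `gene_models` object.
#' @param promoter_upstream promoter length in bp upstream of the TSS.
#' @return data.frame `transcript_id`, `region`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open; one row per interval).
#' @export
gene_regions <- function(models, promoter_upstream = 1500) {
  stopifnot(inherits(models, "gene_models"))
  ex <- models$exons
  out <- lapply(split(ex, ex$transcript_id), function(e) {
    e <- e[order(e$rank), , drop = FALSE]
    strand <- e$strand[1]; chrom <- e$chrom[1]; id <- e$transcript_id[1]
    tss <- if (strand == "+") min(e$start) else max(e$end) - 1L
    prom <- .window0(tss, strand, promoter_upstream, 0)
    rows <- list(data.frame(region = "promoter",
                            start = max(prom[1, "start"], 0), end = prom[1, "end"]))
    rows <- c(rows, list(data.frame(region = "first_exon",
                                    start = e$start[1], end = e$end[1])))
    if (nrow(e) > 1) {
      # introns in strand order: gap between exon rank i and i+1
      gaps <- lapply(seq_len(nrow(e) - 1), function(i) {
        a <- e[i, ]; b <- e[i + 1, ]
        if (strand == "+") c(a$end, b$start) else c(b$end, a$start)
      })
      rows <- c(rows, list(data.frame(region = "first_intron",
                                      start = gaps[[1]][1], end = gaps[[1]][2])))
      if (length(gaps) > 1) {
        g <- do.call(rbind, gaps[-1])
        rows <- c(rows, list(data.frame(region = "other_introns",
                                        start = g[, 1], end = g[, 2])))
      }
      rows <- c(rows, list(data.frame(region = "other_exons",
                                      start = e$start[-1], end = e$end[-1])))
    }
    rows <- c(rows, list(data.frame(region = "gene_body",
                                    start = min(e$start), end = max(e$end))))
    df <- do.call(rbind, rows)
    df$transcript_id <- id; df$chrom <- chrom; df$strand <- strand
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("transcript_id", "region", "chrom", "strand", "start", "end")]
}

#' Merge transcripts sharing a TSS
#'
#' Transcripts with identical (chromosome, strand, TSS) are collapsed into
#' one unit carrying all member transcript IDs.  Idempotent.  Expression of
#' a merged unit is aggregated separately with [merge_expression()].
#'
#' @param models a `gene_models` object.
#' @return a `gene_models` object whose `transcripts` gain a `members`
#'   column (comma-separated member transcript IDs); the representative
#'   `transcript_id` is the lexicographically first member.  Exons of all
#'   members are retained.
#' @export
merge_same_tss <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  tr <- models$transcripts
  if (is.null(tr$members)) tr$members <- tr$transcript_id
  key <- paste(tr$chrom, tr$strand, tr$tss, sep = "\r")
  groups <- split(seq_len(nrow(tr)), key)
  merged <- do.call(rbind, lapply(groups, function(idx) {
    members <- sort(unique(unlist(strsplit(tr$members[idx], ","))))
    rep_idx <- idx[order(tr$transcript_id[idx])][1]
    out <- tr[rep_idx, , drop = FALSE]
    out$start <- min(tr$start[idx]); out$end <- max(tr$end[idx])
    out$members <- paste(members, collapse = ",")
    out
  }))
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  structure(list(transcripts = merged, exons = models$exons),
            class = "gene_models")
}

#' Aggregate an expression matrix over merged-TSS units
#'
#' @param models a merged `gene_models` object (from [merge_same_tss()]).
#' @param mat matrix with rownames = member transcript IDs.
#' @param how `"sum"` (default: total signal preserved) or `"max"`.
#' @return matrix with one row per merged unit (rownames = representative
#'   transcript IDs). Members absent from `mat` are treated as all-zero.
#' @export
merge_expression <- function(models, mat, how = c("sum", "max")) {
  how <- match.arg(how)
  tr <- models$transcripts
  if (is.null(tr$members)) stop("models are not merged; run merge_same_tss() first")
  out <- matrix(0, nrow(tr), ncol(mat),
                dimnames = list(tr$transcript_id, colnames(mat)))
  for (i in seq_len(nrow(tr))) {
    members <- strsplit(tr$members[i], ",")[[1]]
    members <- members[members %in% rownames(mat)]
    if (length(members) == 0) next
    sub <- mat[members, , drop = FALSE]
    out[i, ] <- if (how == "sum") colSums(sub) else apply(sub, 2, max)
  }
  out
}

.intervals_to_granges <- function(chrom, start, end, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = pmax(end, start + 1L)),
    strand = if (is.null(strand)) "*" else strand
  )
}

.positions_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos + 1L, width = 1L))
}

#' Assign CpG sites to gene regions
#'
#' Maps every CpG position falling inside any region interval of any gene to
#' (transcript, region); a CpG may map to several genes and regions.
#'
#' @param cpgs data.frame with columns `chrom`, `pos` (0-based).
#' @param regions data.frame from [gene_regions()] (or any data.frame with
#'   `transcript_id`, `region`, `chrom`, `start`, `end`).
#' @return data.frame `site` (row index into `cpgs`), `transcript_id`,
#'   `region`.
#' @export
assign_cpgs_to_regions <- function(cpgs, regions) {
  if (!any(cpgs$chrom %in% regions$chrom)) {
    stop("chromosome name mismatch: CpG chromosomes ",
         paste(utils::head(setdiff(unique(cpgs$chrom), regions$chrom), 5),
               collapse = ", "),
         " absent from the annotation")
  }
  keep <- regions$end > regions$start
  regions <- regions[keep, , drop = FALSE]
  gr_reg <- .intervals_to_granges(regions$chrom, regions$start, regions$end)
  gr_cpg <- .positions_to_granges(cpgs$chrom, cpgs$pos)
  hits <- GenomicRanges::findOverlaps(gr_cpg, gr_reg, ignore.strand = TRUE)
  data.frame(
    site = S4Vectors::queryHits(hits),
    transcript_id = regions$transcript_id[S4Vectors::subjectHits(hits)],
    region = regions$region[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
}

#' Assign CpG sites to TSS windows
#'
#' @param cpgs data.frame with `chrom`, `pos` (0-based).
#' @param windows data.frame from [tss_window()].
#' @return data.frame `site`, `transcript_id`, `offset` (strand-aware bp
#'   offset of the CpG from the TSS; 0 at the TSS, positive downstream).
#' @export
assign_cpgs_to_windows <- function(cpgs, windows) {
  keep <- windows$end > windows$start
  windows <- windows[keep, , drop = FALSE]
  if (nrow(windows) == 0) {
    return(data.frame(site = integer(), transcript_id = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  }
  gr_w <- .intervals_to_granges(windows$chrom, windows$start, windows$end)
  gr_cpg <- .positions_to_granges(cpgs$chrom, cpgs$pos)
  hits <- GenomicRanges::findOverlaps(gr_cpg, gr_w, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  offset <- ifelse(windows$strand[si] == "+",
                   cpgs$pos[qi] - windows$tss[si],
                   windows$tss[si] - cpgs$pos[qi])
  data.frame(site = qi, transcript_id = windows$transcript_id[si],
             offset = offset, stringsAsFactors = FALSE)
}
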