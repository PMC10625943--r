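#' Write gene models as GTF
#'
#' Emits one `exon` feature line per exon (Ensembl attribute dialect,
#' 1-based closed coordinates).
#'
#' @param models a `gene_models` object.
#' @param path output path.
#' @export
write_gtf <- function(models, path) {
  ex <- models$exons
  ex <- ex[order(ex$chrom, ex$start, ex$transcript_id), , drop = FALSE]
  lines <- sprintf(
    '%s\ttissuedom\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, as.integer(ex$start) + 1L, as.integer(ex$end), ex$strand,
    ex$gene_id, ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write per-tissue, per-replicate methylation count tables
#'
#' One TSV per tissue and replicate with columns `chrom`, `pos` (0-based),
#' `strand`, `context`, `n_meth`, `n_total`.
#'
#' @param counts a `meth_counts` object.
#' @param dir output directory.
#' @return named list (per tissue) of written file paths.
#' @export
write_meth_tables <- function(counts, dir) {
  out <- lapply(meth_tissues(counts), function(tissue) {
    reps <- ncol(counts$meth[[tissue]])
    vapply(seq_len(reps), function(k) {
      df <- data.frame(counts$sites[, c("chrom", "pos", "strand", "context")],
                       n_meth = as.integer(counts$meth[[tissue]][, k]),
                       n_total = as.integer(counts$total[[tissue]][, k]))
      df$pos <- as.integer(df$pos)
      path <- file.path(dir, sprintf("meth_%s_rep%d.tsv", tissue, k))
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      path
    }, "")
  })
  stats::setNames(out, meth_tissues(counts))
}

#' Read methylation count tables into a `meth_counts` object
#'
#' All files must cover the same sites (matched by chromosome and
#' position).  CpG records reported on the minus strand are collapsed onto
#' the plus-strand position of the CpG dyad (position minus one) and their
#' counts summed with any plus-strand record, making counts
#' strand-symmetric across input dialects.
#'
#' @param files named list (per tissue) of character vectors of replicate
#'   file paths.
#' @return a `meth_counts` object.
#' @export
read_meth_tables <- function(files) {
  read_one <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "integer", "character",
                                           "character", "integer", "integer"))
    minus <- df$strand == "-" & df$context == "CpG"
    df$pos[minus] <- df$pos[minus] - 1L
    df$strand[minus] <- "+"
    if (any(minus)) {
      key <- paste(df$chrom, df$pos, df$context, sep = "\r")
      df <- data.frame(
        do.call(rbind, lapply(split(df, key), function(g) {
          data.frame(chrom = g$chrom[1], pos = g$pos[1], strand = "+",
                     context = g$context[1], n_meth = sum(g$n_meth),
                     n_total = sum(g$n_total), stringsAsFactors = FALSE)
        })), stringsAsFactors = FALSE)
    }
    df[order(df$chrom, df$pos), , drop = FALSE]
  }
  tissues <- names(files)
  first <- read_one(files[[1]][1])
  sites <- first[, c("chrom", "pos", "strand", "context")]
  rownames(sites) <- NULL
  key0 <- paste(sites$chrom, sites$pos, sep = "\r")
  meth <- list(); total <- list()
  for (tissue in tissues) {
    reps <- files[[tissue]]
    m <- matrix(NA_integer_, nrow(sites), length(reps))
    t_ <- matrix(NA_integer_, nrow(sites), length(reps))
    for (k in seq_along(reps)) {
      df <- read_one(reps[k])
      idx <- match(key0, paste(df$chrom, df$pos, sep = "\r"))
      if (any(is.na(idx))) stop("site mismatch across methylation tables: ", reps[k])
      m[, k] <- df$n_meth[idx]
      t_[, k] <- df$n_total[idx]
    }
    meth[[tissue]] <- m; total[[tissue]] <- t_
  }
  meth_counts(sites, meth, total)
}

#' Write a feature-by-replicate matrix as TSV
#' @param mat numeric matrix with rownames.
#' @param path output path.
#' @param id_col name for the ID column.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), as.data.frame(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-replicate matrix from TSV
#' @param path input path.
#' @return numeric matrix with rownames from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write intervals as BED6
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open);
#'   optional `name`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  name <- if (!is.null(df$name)) df$name else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.", df$chrom, as.integer(df$start),
                   as.integer(df$end), name)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED peak file
#' @param path input path.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), `name`.
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) as.character(gr$name) else ".",
             stringsAsFactors = FALSE)
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from GMT
#' @param path input path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a simulated study to a self-contained input bundle
#'
#' Writes the annotation (GTF), methylation tables, RNA count/TPM and
#' protein intensity matrices, ID maps, peak BED files, gene sets (GMT)
#' with their class map, and the ground-truth table, in the plain-text
#' formats the pipeline readers consume.
#'
#' @param sim a `sim_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  write_gtf(sim$annotation$models, file.path(dir, "annotation.gtf"))
  write_meth_tables(sim$meth, dir)
  for (tissue in sim$cfg$tissues) {
    write_matrix_tsv(sim$rna$counts[[tissue]],
                     file.path(dir, sprintf("rna_counts_%s.tsv", tissue)),
                     id_col = "transcript_id")
    write_matrix_tsv(sim$rna$tpm[[tissue]],
                     file.path(dir, sprintf("rna_tpm_%s.tsv", tissue)),
                     id_col = "transcript_id")
    write_matrix_tsv(sim$prot$intensity[[tissue]],
                     file.path(dir, sprintf("protein_%s.tsv", tissue)),
                     id_col = "protein_id")
  }
  utils::write.table(sim$prot$map, file.path(dir, "protein_gene_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$annotation$tx2gene, file.path(dir, "tx2gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pk <- sim$peaks$tf_peaks
  for (tf in unique(pk$tf)) {
    for (tissue in sim$cfg$tissues) {
      sub <- pk[pk$tf == tf & pk$tissue == tissue, , drop = FALSE]
      sub <- sub[order(sub$chrom, sub$start), , drop = FALSE]
      sub$name <- tf
      write_bed(sub, file.path(dir, "peaks",
                               sprintf("tf_%s_%s.bed", tf, tissue)))
    }
  }
  for (tissue in sim$cfg$tissues) {
    write_bed(sim$peaks$atac[[tissue]],
              file.path(dir, "peaks", sprintf("atac_%s.bed", tissue)))
    for (mark in names(sim$peaks$hm)) {
      for (f in seq_along(sim$peaks$hm[[mark]][[tissue]])) {
        write_bed(sim$peaks$hm[[mark]][[tissue]][[f]],
                  file.path(dir, "peaks",
                            sprintf("%s_%s_%d.bed", mark, tissue, f)))
      }
    }
  }
  write_bed(sim$peaks$cgi, file.path(dir, "peaks", "cpg_islands.bed"))
  write_gmt(sim$gene_sets$sets, file.path(dir, "gene_sets.gmt"))
  utils::write.table(sim$gene_sets$class_map,
                     file.path(dir, "set_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Build a bundled synthetic dataset on disk
#'
#' `tiny` (200 genes) suits unit tests; `default` (2,000 genes,
#' ~60,000-70,000 cytosines) is the full validation bundle.
#'
#' @param size `"tiny"` or `"default"`.
#' @param dir output directory.
#' @param seed integer seed.
#' @param ... further [sim_config()] overrides.
#' @return the run configuration for the bundle (see [bundle_config()]),
#'   invisibly.
#' @export
make_fixtures <- function(size = c("tiny", "default"), dir, seed = 1, ...) {
  size <- match.arg(size)
  n_genes <- if (size == "tiny") 200 else 2000
  cfg <- sim_config(n_genes = n_genes, seed = seed, ...)
  sim <- simulate_study(cfg)
  write_bundle(sim, dir)
  invisible(bundle_config(dir, tissues = cfg$tissues))
}
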