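# tissuedom

Integrative classification of tissue-dominant genes and proteins from
paired methylome, transcriptome, and proteome data in two tissues.

## The problem

Each tissue expresses a dominant set of functional proteins. Promoter DNA
hypomethylation, transcription-factor (TF) binding, and post-transcriptional
regulation all contribute, and disentangling them requires joint
classification of every gene across omics layers. Given whole-genome
bisulfite sequencing (WGBS) counts, RNA counts/TPM, protein intensities
(iBAQ-like), and TF/chromatin peak sets from two tissues (canonically liver
and skeletal muscle), `tissuedom` classifies each gene or protein into:

- **DMG** — differentially hypomethylated gene: hypomethylated in at least
  one tissue, with ≥ 1 differentially methylated CpG (DMCpG, beta-binomial
  likelihood-ratio test, Storey *q* < 0.01) in the TSS window
  `[TSS − 200, TSS + 400)`, and a consistent window-mean difference;
- **DEG** — differentially expressed gene: negative-binomial two-group test
  on genes with reads in ≥ 6 of 11 replicates in a tissue, BH *q* < 0.01;
- **DEP** — differentially expressed protein: arcsinh variance-stabilizing
  normalization `h(x) = γ·arcsinh(a + b·x)` followed by an empirical-Bayes
  moderated *t*-test (*q* < 0.01), plus proteins detected (≥ 3 of 5
  replicates) in only one tissue;
- **DRP** — different protein/mRNA-ratio protein: regressing one tissue's
  `log(protein/mRNA)` on the other's, a protein is a DRP when excluding it
  lowers the mean squared error of the leave-one-out refit below the
  full-fit MSE — i.e. the fit improves even slightly without it;
- **DTG** — differentially TF-bound gene: binding states from peak overlap
  with `[TSS − 1000, TSS + 1000)`; a gene with differing states is a DTG
  when its state pair differs significantly in expression (two-tailed
  Welch, Storey *q* < 0.01) or when the difference decomposes into
  individually significant TFs.

Direction-consistent composites (DM-DEG, DM-DEP, DR-DEP, DT-DEP) are
derived with Fisher overlap tests, alongside expression-decile and 100-bp
sliding-window Spearman correlations around the TSS, Otsu thresholding and
the Silverman bootstrap bimodality test on pooled window methylation
ratios, CpG-density clustering (fifteen 40-bp bins, Ward), and Fisher
gene-set enrichment.

Because the real datasets are deposited raw sequencing archives, the
package ships a first-class synthetic-data module that generates a
miniature two-tissue study with planted ground truth (bimodal promoter
methylation, methylation-coupled expression, mRNA-coupled protein
abundance with planted post-transcriptional shifts, TF peaks that shift
expression), so the whole pipeline is validated end to end by parameter
recovery.

## Worked example

```r
library(tissuedom)

# a 200-gene two-tissue study written as a plain-text bundle
run_cfg <- make_fixtures("tiny", dir = "bundle", seed = 42)
res <- run_pipeline(run_cfg, "results_tiny")

res$summary$otsu_threshold        # 0.4394
res$summary$silverman_p_unimodal  # 0
unlist(res$summary$dmg_counts)    # liver 21, muscle 20, none 159
unlist(res$summary$deg_counts)    # liver 26, muscle 28, none 146
unlist(res$summary$drp_counts)    # liver 11, muscle 11, none 178
res$summary$fc_methylation_r      # -0.793
res$summary$scan_significant_range$liver  # -200 400
```

Reading the output: pooled TSS-window methylation ratios are bimodal
(Silverman rejects unimodality, p = 0) and the Otsu threshold 0.4394 splits
hypo- from hypermethylated genes. Roughly 10% of genes per tissue are
called DMGs, matching the planted fractions; the log2 fold-change of
methylation correlates negatively (r = −0.79) with the log2 fold-change of
expression over DEGs; and the sliding-window scan localizes the
significantly anticorrelated region to −200..+400 bp around the TSS, the
window the planted coupling uses. The master gene-level table with all
class labels and composites is written to `results_tiny/master_table.tsv`.

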