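# Count normalization, the exact conditional-binomial differential test,
# derepressed-set calling, and the gene-set summaries (tissue overlap,
# repeat proximity, RPKM-expressed sets).

#' Library-size normalize a count matrix
#'
#' Each column is scaled by (mean of all column totals) / (its own total),
#' so that afterwards every column total equals the original mean total.
#' Within-column rank order is conserved.
#'
#' @param counts Non-negative numeric matrix, features x samples.
#' @return Real-valued matrix of the same shape.
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  totals <- colSums(counts)
  if (any(totals == 0)) stop("degenerate library: zero column total")
  sweep(counts, 2, mean(totals) / totals, `*`)
}

#' Pseudo-counted log2 transform
#'
#' `log2(x + pseudo)` with the pipeline-wide pseudo-count of 8, which damps
#' large fold-change estimates at low counts.
#'
#' @param x Non-negative numeric vector.
#' @param pseudo Pseudo-count (default 8).
#' @return `log2(x + pseudo)`.
#' @export
log2_pseudo <- function(x, pseudo = 8) {
  if (any(x < 0)) stop("log2_pseudo: negative input")
  log2(x + pseudo)
}

#' Exact conditional-binomial count test
#'
#' Two-sided exact test for a difference between two pooled counts. Given
#' the total `t = a + b`, the p-value is the sum of `Binomial(t, prob)`
#' probabilities over all outcomes `k` whose probability mass does not
#' exceed that of the observed `a` (with a small relative tolerance for
#' floating-point ties). `t = 0` returns 1.
#'
#' @param a,b Non-negative integer vectors (pooled scaled counts, rounded).
#' @param prob Expected proportion of the total falling in `a` under the
#'   null (e.g. the first condition's share of replicates after library
#'   scaling); strictly between 0 and 1.
#' @return Vector of two-sided p-values in (0, 1].
#' @export
exact_count_test <- function(a, b, prob = 0.5) {
  stopifnot(length(a) == length(b), prob > 0, prob < 1)
  if (any(a < 0) || any(b < 0)) stop("negative counts")
  if (any(a != round(a)) || any(b != round(b)))
    stop("counts must be integers (round pooled scaled counts first)")
  vapply(seq_along(a), function(i) {
    t <- a[i] + b[i]
    if (t == 0) return(1)
    d <- dbinom(0:t, t, prob)
    min(1, sum(d[d <= d[a[i] + 1] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} (m p_(j) / j)`, capped at 1 and
#' order-preserving with respect to input positions.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of FDR values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  p.adjust(pvalues, method = "BH")
}

# Round half-up: the deterministic integerization used before the exact test.
round_half_up <- function(x) floor(x + 0.5)

#' Differential count test between two genotypes
#'
#' Implements the pipeline's differential analysis: library-scale the whole
#' matrix, pool the scaled counts over replicates per condition (rounded
#' half-up), run the exact conditional-binomial test with the condition's
#' replicate share as the null proportion, BH-adjust, and compute
#' `log2fc = log2(mean scaled mutant + 8) - log2(mean scaled reference + 8)`
#' (the pseudo-count applied after averaging replicates).
#'
#' @param counts Feature x sample count matrix.
#' @param samples `data.frame` with columns `sample` (matching `colnames`)
#'   and `genotype`.
#' @param contrast Character vector `c(mutant, reference)`.
#' @param pseudo Pseudo-count for the fold change (default 8).
#' @return `data.frame` with `id`, `mean_ref`, `mean_mut` (scaled means),
#'   `log2fc`, `pvalue`, `fdr`.
#' @export
de_test <- function(counts, samples, contrast, pseudo = 8) {
  stopifnot(length(contrast) == 2,
            all(c("sample", "genotype") %in% names(samples)))
  if (!all(colnames(counts) %in% samples$sample))
    stop("samples sheet does not cover all count columns")
  geno <- samples$genotype[match(colnames(counts), samples$sample)]
  mut_cols <- which(geno == contrast[1])
  ref_cols <- which(geno == contrast[2])
  if (!length(mut_cols) || !length(ref_cols))
    stop("contrast genotype(s) absent from samples sheet")
  norm <- normalize_counts(counts)
  mean_mut <- rowMeans(norm[, mut_cols, drop = FALSE])
  mean_ref <- rowMeans(norm[, ref_cols, drop = FALSE])
  a <- round_half_up(rowSums(norm[, mut_cols, drop = FALSE]))
  b <- round_half_up(rowSums(norm[, ref_cols, drop = FALSE]))
  prob <- length(mut_cols) / (length(mut_cols) + length(ref_cols))
  p <- exact_count_test(a, b, prob)
  data.frame(id = rownames(counts), mean_ref = mean_ref, mean_mut = mean_mut,
             log2fc = log2_pseudo(mean_mut, pseudo) -
               log2_pseudo(mean_ref, pseudo),
             pvalue = p, fdr = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call derepressed genes
#'
#' Genes with `fdr < fdr_max` and `log2fc > log2fc_min` (defaults 0.01 and
#' 2, the thresholds used throughout the analysis).
#'
#' @param de Result of [de_test()].
#' @param fdr_max,log2fc_min Positive thresholds.
#' @return Character vector of gene ids with a `provenance` attribute
#'   recording the thresholds.
#' @export
call_derepressed <- function(de, fdr_max = 0.01, log2fc_min = 2) {
  stopifnot(fdr_max > 0, log2fc_min > 0)
  ids <- de$id[de$fdr < fdr_max & de$log2fc > log2fc_min]
  structure(ids, provenance = list(fdr_max = fdr_max,
                                   log2fc_min = log2fc_min))
}

#' Reads per kilobase per million (RPKM)
#'
#' `count / (exon_kb * library_millions)`.
#'
#' @param counts Numeric vector of per-gene counts.
#' @param exon_lengths Per-gene total exon length in bp (> 0).
#' @param library_total Total mapped reads in the library.
#' @return Per-gene RPKM vector.
#' @export
compute_rpkm <- function(counts, exon_lengths, library_total) {
  if (any(exon_lengths <= 0)) stop("non-positive exon length")
  counts / ((exon_lengths / 1000) * (library_total / 1e6))
}

#' Expressed-gene set by RPKM cutoff
#'
#' @param rpkm Named RPKM vector.
#' @param min_rpkm Cutoff; genes with `rpkm > min_rpkm` are kept (default 8,
#'   the embryo-expressed definition).
#' @return Character vector of gene ids.
#' @export
expressed_genes <- function(rpkm, min_rpkm = 8) {
  names(rpkm)[rpkm > min_rpkm]
}

#' Per-tissue overlap of a gene set
#'
#' For each tissue: `100 * |set intersect tissue genes| / |tissue genes|`.
#' Optionally also returns the set x cell-type expression submatrix.
#'
#' @param set Character vector of gene ids.
#' @param atlas `data.frame` with columns `gene_id` and `tissue`.
#' @param expression Optional gene x cell-type matrix to subset by `set`.
#' @return List with `fractions` (`tissue`, `n_tissue`, `n_in_set`, `pct`;
#'   `pct` is `NA` for empty tissues) and `expression` (matrix or NULL).
#' @export
tissue_overlap <- function(set, atlas, expression = NULL) {
  stopifnot(all(c("gene_id", "tissue") %in% names(atlas)))
  tissues <- unique(atlas$tissue)
  if (!length(tissues)) stop("atlas covers no tissue")
  if (length(set) && !any(set %in% atlas$gene_id))
    warning("gene set is disjoint from the atlas")
  fr <- do.call(rbind, lapply(tissues, function(tt) {
    g <- atlas$gene_id[atlas$tissue == tt]
    data.frame(tissue = tt, n_tissue = length(g),
               n_in_set = sum(g %in% set),
               pct = if (length(g)) 100 * sum(g %in% set) / length(g)
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
  expr <- if (!is.null(expression))
    expression[intersect(set, rownames(expression)), , drop = FALSE]
  list(fractions = fr, expression = expr)
}

#' Repeat-element proximity of gene starts
#'
#' Fraction of genes whose TSS lies within `window` bp of any repeat
#' interval (distance 0 when overlapping), reported for a gene set alongside
#' the all-genes fraction.
#'
#' @param models `gene_models` object.
#' @param repeats Repeat interval `data.frame`.
#' @param set Optional character vector of gene ids (default: all genes).
#' @param window Distance cutoff in bp (default 1000).
#' @return List with `frac_set`, `frac_all`, and `per_gene`
#'   (`gene_id`, `distance`, `within`).
#' @export
re_proximity <- function(models, repeats, set = NULL, window = 1000) {
  stopifnot(window > 0)
  g <- models$genes
  tss_iv <- data.frame(chrom = g$chrom, start = g$tss, end = g$tss + 1L)
  d <- nearest_distance(tss_iv, repeats)
  within <- !is.na(d) & d <= window
  per_gene <- data.frame(gene_id = g$gene_id, distance = d, within = within,
                         stringsAsFactors = FALSE)
  in_set <- if (is.null(set)) rep(TRUE, nrow(g)) else g$gene_id %in% set
  list(frac_set = if (any(in_set)) mean(within[in_set]) else NA_real_,
       frac_all = mean(within),
       per_gene = per_gene)
}
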