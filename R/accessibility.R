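# Post-alignment ATAC processing: Tn5 cut-site shifting, differential peak
# accessibility, peak feature annotation, intergenic peak selection,
# promoter accessibility, and the Group A/B/C classification.

#' Shift ATAC fragments to Tn5 cut sites
#'
#' `+` strand reads are shifted +4 bp from the fragment start; `-` strand
#' reads -5 bp from the last covered base (`end - 1`), correcting the Tn5
#' 9-bp duplication offset. Positions shifted past chromosome bounds are
#' clipped with a warning.
#'
#' @param fragments Interval `data.frame` with a `strand` column.
#' @param chrom_lengths Optional named lengths for clipping.
#' @return `data.frame` with `chrom`, `pos` (single-base 0-based cut site),
#'   `strand`.
#' @export
shift_tn5 <- function(fragments, chrom_lengths = NULL) {
  if (!"strand" %in% names(fragments) || any(is.na(fragments$strand)))
    stop("shift_tn5 requires a known strand for every fragment")
  pos <- ifelse(fragments$strand == "+",
                fragments$start + 4L,
                fragments$end - 1L - 5L)
  lo <- pos < 0
  pos[lo] <- 0L
  hi <- rep(FALSE, length(pos))
  if (!is.null(chrom_lengths)) {
    chrom_lengths <- genome_lengths(chrom_lengths)
    lim <- chrom_lengths[fragments$chrom] - 1L
    hi <- pos > lim
    pos[hi] <- lim[hi]
  }
  if (any(lo | hi))
    warning(sum(lo | hi), " shifted position(s) clipped to chromosome bounds")
  data.frame(chrom = fragments$chrom, pos = as.integer(pos),
             strand = fragments$strand, stringsAsFactors = FALSE)
}

#' Differential peak accessibility
#'
#' Runs the exact conditional-binomial test ([de_test()]) on peak counts
#' and flags peaks significantly more (`up`) or less (`down`) accessible.
#'
#' @param peak_counts Peak x sample count matrix.
#' @param samples Sample sheet (`sample`, `genotype`).
#' @param contrast `c(mutant, reference)`.
#' @param fdr_max FDR cutoff (default 0.01).
#' @return [de_test()] result with logical `up` and `down` columns.
#' @export
differential_peaks <- function(peak_counts, samples, contrast,
                               fdr_max = 0.01) {
  de <- de_test(peak_counts, samples, contrast)
  de$up <- de$fdr < fdr_max & de$log2fc > 0
  de$down <- de$fdr < fdr_max & de$log2fc < 0
  de
}

#' Annotate peaks with genomic features
#'
#' Assigns each peak one label from promoter, repeat, exon, intron,
#' intergenic, by any-overlap under that precedence order (a peak touching
#' both a promoter and a repeat is "promoter"). The promoter here is the
#' accessibility definition: 1 kb upstream and 100 bp downstream of the
#' TSS. Intron means within a gene span but not overlapping an exon.
#'
#' @param peaks Peak interval `data.frame`.
#' @param models `gene_models` object.
#' @param repeats Repeat interval `data.frame`.
#' @param promoter_up,promoter_down Promoter extents (defaults 1000/100).
#' @param chrom_lengths Optional named lengths for promoter clipping.
#' @param precedence Label order, highest priority first.
#' @return `peaks` with a `feature` column.
#' @export
annotate_peak_features <- function(peaks, models, repeats,
                                   promoter_up = 1000, promoter_down = 100,
                                   chrom_lengths = NULL,
                                   precedence = c("promoter", "repeat",
                                                  "exon", "intron",
                                                  "intergenic")) {
  stopifnot(setequal(precedence, c("promoter", "repeat", "exon", "intron",
                                   "intergenic")))
  prom <- promoter_windows(models, promoter_up, promoter_down, chrom_lengths)
  spans <- data.frame(chrom = models$genes$chrom,
                      start = models$genes$span_start,
                      end = models$genes$span_end)
  feature_sets <- list(
    promoter = prom,
    "repeat" = repeats,
    exon = models$exons,
    intron = spans)   # resolved below: intron only when no exon overlap
  feature <- rep("intergenic", nrow(peaks))
  assigned <- rep(FALSE, nrow(peaks))
  for (f in setdiff(precedence, "intergenic")) {
    iv <- feature_sets[[f]]
    hit <- if (nrow(iv)) overlap_counts(peaks, iv) > 0 else
      rep(FALSE, nrow(peaks))
    if (f == "intron") {
      in_exon <- if (nrow(models$exons))
        overlap_counts(peaks, models$exons) > 0 else
        rep(FALSE, nrow(peaks))
      hit <- hit & !in_exon
    }
    sel <- hit & !assigned
    feature[sel] <- f
    assigned <- assigned | hit
  }
  peaks$feature <- feature
  peaks
}

#' Genome base fraction per feature class
#'
#' Assigns every genome base one feature class under the same precedence
#' as [annotate_peak_features()], for computing peak-class percentages
#' relative to genome-wide occurrence.
#'
#' @inheritParams annotate_peak_features
#' @param chrom_lengths Named chromosome lengths (required).
#' @return Named vector of base fractions summing to 1.
#' @export
feature_base_fractions <- function(models, repeats, chrom_lengths,
                                   promoter_up = 1000, promoter_down = 100,
                                   precedence = c("promoter", "repeat",
                                                  "exon", "intron",
                                                  "intergenic")) {
  chrom_lengths <- genome_lengths(chrom_lengths)
  total <- sum(as.numeric(chrom_lengths))
  prom <- promoter_windows(models, promoter_up, promoter_down, chrom_lengths)
  spans <- data.frame(chrom = models$genes$chrom,
                      start = models$genes$span_start,
                      end = models$genes$span_end)
  exons <- models$exons
  grs <- list(
    promoter = GenomicRanges::reduce(as_granges0(prom), ignore.strand = TRUE),
    "repeat" = GenomicRanges::reduce(as_granges0(repeats),
                                     ignore.strand = TRUE),
    exon = GenomicRanges::reduce(as_granges0(exons), ignore.strand = TRUE),
    intron = GenomicRanges::setdiff(
      GenomicRanges::reduce(as_granges0(spans), ignore.strand = TRUE),
      GenomicRanges::reduce(as_granges0(exons), ignore.strand = TRUE)))
  taken <- GenomicRanges::GRanges()
  out <- setNames(numeric(length(precedence)), precedence)
  for (f in setdiff(precedence, "intergenic")) {
    g <- GenomicRanges::setdiff(grs[[f]], taken)
    out[f] <- sum(as.numeric(GenomicRanges::width(g))) / total
    taken <- GenomicRanges::reduce(c(taken, g))
  }
  out["intergenic"] <- 1 - sum(out)
  out
}

#' Feature-class enrichment of a peak subset
#'
#' Per class: (fraction of selected peaks in the class) / (fraction of
#' genome bases in the class) -- the "relative to genome-wide occurrence"
#' percentage.
#'
#' @param annotated Peaks with a `feature` column.
#' @param select Logical vector choosing the peaks (e.g. the up peaks).
#' @param base_fractions From [feature_base_fractions()].
#' @return `data.frame` with `feature`, `n_peaks`, `peak_fraction`,
#'   `genome_fraction`, `relative_enrichment`.
#' @export
feature_enrichment <- function(annotated, select, base_fractions) {
  sel <- annotated$feature[select]
  classes <- names(base_fractions)
  n <- vapply(classes, function(f) sum(sel == f), numeric(1))
  pf <- if (length(sel)) n / length(sel) else rep(NA_real_, length(classes))
  data.frame(feature = classes, n_peaks = n, peak_fraction = pf,
             genome_fraction = as.numeric(base_fractions),
             relative_enrichment = pf / as.numeric(base_fractions),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select intergenic peaks
#'
#' Keeps peaks more than `min_dist` bp (default 1,500) away from any
#' promoter (overlap counts as distance 0) and with no overlapping repeat.
#' Peaks on chromosomes without any promoter are kept.
#'
#' @param peaks Peak interval `data.frame`.
#' @param promoters Promoter windows (accessibility definition, 1 kb/100 bp).
#' @param repeats Repeat interval `data.frame`.
#' @param min_dist Distance cutoff in bp.
#' @return The qualifying subset of `peaks`.
#' @export
select_intergenic_peaks <- function(peaks, promoters, repeats,
                                    min_dist = 1500) {
  d <- nearest_distance(peaks, promoters)
  far <- is.na(d) | d > min_dist
  no_repeat <- if (nrow(repeats)) overlap_counts(peaks, repeats) == 0 else
    rep(TRUE, nrow(peaks))
  peaks[far & no_repeat, , drop = FALSE]
}

#' Count Tn5 cut sites per promoter
#'
#' @param positions List (one element per sample, named) of shifted
#'   cut-site tables from [shift_tn5()].
#' @param promoters Promoter windows with `gene_id`.
#' @return Gene x sample count matrix.
#' @export
promoter_cut_counts <- function(positions, promoters) {
  stopifnot(!is.null(names(positions)))
  m <- vapply(positions, function(p) {
    pts <- data.frame(chrom = p$chrom, start = p$pos, end = p$pos + 1L)
    overlap_counts(promoters, pts)
  }, numeric(nrow(promoters)))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(promoters))
  dimnames(m) <- list(promoters$gene_id, names(positions))
  m
}

#' Per-gene promoter accessibility test
#'
#' Differential test of promoter counts (cut sites or promoter peak counts
#' keyed by gene) between genotypes; `up` means `fdr < fdr_max` and
#' `log2fc > log2fc_min`.
#'
#' @param promoter_counts Gene x sample count matrix.
#' @param samples Sample sheet.
#' @param contrast `c(mutant, reference)`.
#' @param fdr_max FDR cutoff (default 0.01).
#' @param log2fc_min Fold-change floor for `up` (default 0).
#' @return [de_test()] result with an `up` column.
#' @export
promoter_accessibility <- function(promoter_counts, samples, contrast,
                                   fdr_max = 0.01, log2fc_min = 0) {
  de <- de_test(promoter_counts, samples, contrast)
  de$up <- de$fdr < fdr_max & de$log2fc > log2fc_min
  de
}

#' Classify genes into Groups A, B and C
#'
#' Group A: increased expression without increased promoter accessibility;
#' Group B: both increased; Group C: increased accessibility without
#' increased expression; `none` otherwise. Expression-up uses the
#' derepression thresholds (FDR < 0.01, log2FC > 2 by default);
#' accessibility-up uses FDR < 0.01 and log2FC > 0.
#'
#' @param expr_de Expression [de_test()] table.
#' @param acc_de Promoter accessibility [de_test()] table on the same gene
#'   universe.
#' @param expr_fdr,expr_log2fc,acc_fdr,acc_log2fc Thresholds.
#' @return `data.frame` with `gene_id`, `expr_up`, `acc_up`, `group`.
#' @export
classify_groups <- function(expr_de, acc_de, expr_fdr = 0.01,
                            expr_log2fc = 2, acc_fdr = 0.01,
                            acc_log2fc = 0) {
  if (!setequal(expr_de$id, acc_de$id))
    stop("expression and accessibility tables cover different genes")
  acc_de <- acc_de[match(expr_de$id, acc_de$id), ]
  expr_up <- expr_de$fdr < expr_fdr & expr_de$log2fc > expr_log2fc
  acc_up <- acc_de$fdr < acc_fdr & acc_de$log2fc > acc_log2fc
  group <- rep("none", nrow(expr_de))
  group[expr_up & !acc_up] <- "A"
  group[expr_up & acc_up] <- "B"
  group[!expr_up & acc_up] <- "C"
  data.frame(gene_id = expr_de$id, expr_up = expr_up, acc_up = acc_up,
             group = group, stringsAsFactors = FALSE)
}
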