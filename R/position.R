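# Subnuclear positioning: DamID bin log-ratios, the rank-sum statistic for
# group comparisons, and the gene-group position contrast.

#' DamID bin log-ratio track
#'
#' Library-scales the fusion (e.g. EMR-1::Dam) and control (free Dam)
#' counts jointly, then reports per bin
#' `log2((scaled fusion + 8) / (scaled control + 8))` -- the same
#' pseudo-count-8 convention as every other ratio in the pipeline.
#'
#' @param fusion,control Per-bin count vectors on the same tiling.
#' @param bins Bin intervals from [tile_genome()] (10 kb by convention).
#' @param pseudo Pseudo-count (default 8).
#' @return `bins` with a `log2_ratio` column.
#' @export
damid_bin_ratio <- function(fusion, control, bins, pseudo = 8) {
  if (length(fusion) != nrow(bins) || length(control) != nrow(bins))
    stop("counts do not match the bin tiling")
  m <- normalize_counts(cbind(fusion = fusion, control = control))
  bins$log2_ratio <- log2((m[, 1] + pseudo) / (m[, 2] + pseudo))
  bins
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the pooled sample size is at most 12 and there
#' are no ties; otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  use_exact <- (length(x) + length(y)) <= 12 &&
    !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)$p.value)
  if (is.nan(p)) 1 else p   # fully tied samples carry no evidence
}

#' Compare DamID positioning across gene groups
#'
#' Maps each gene to the 10-kb bins its span overlaps (any-overlap; a
#' multi-bin gene contributes each overlapped bin once), pools the bin
#' log-ratios per group, and tests every group pair with the two-sided
#' rank-sum test. Groups contributing fewer than two values are skipped
#' with a warning.
#'
#' @param track DamID track from [damid_bin_ratio()].
#' @param groups Group table from [classify_groups()].
#' @param models `gene_models` object.
#' @param which_groups Group labels to compare (default A, B, C).
#' @return List with `values` (named list of per-group bin log-ratios) and
#'   `pvalues` (symmetric matrix of pairwise p-values).
#' @export
group_position_compare <- function(track, groups, models,
                                   which_groups = c("A", "B", "C")) {
  g <- models$genes
  spans <- data.frame(chrom = g$chrom, start = g$span_start,
                      end = g$span_end)
  pairs <- overlap_pairs(spans, track)
  values <- lapply(which_groups, function(grp) {
    ids <- groups$gene_id[groups$group == grp]
    rows <- which(g$gene_id[pairs$query] %in% ids)
    # each overlapped bin once per gene
    keep <- !duplicated(pairs[rows, , drop = FALSE])
    track$log2_ratio[pairs$subject[rows][keep]]
  })
  names(values) <- which_groups
  usable <- vapply(values, length, integer(1)) >= 2
  if (any(!usable))
    warning("group(s) skipped (fewer than 2 values): ",
            paste(which_groups[!usable], collapse = ", "))
  p <- matrix(NA_real_, length(which_groups), length(which_groups),
              dimnames = list(which_groups, which_groups))
  for (i in seq_along(which_groups)) for (j in seq_along(which_groups)) {
    if (i < j && usable[i] && usable[j]) {
      p[i, j] <- p[j, i] <- rank_sum_test(values[[i]], values[[j]])
    }
  }
  diag(p) <- 1
  list(values = values, pvalues = p)
}
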