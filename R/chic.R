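# ChIC-seq window quantification, MNase-control normalization, consecutive
# window heterochromatin domain calling, per-gene mark enrichment, and
# chromosome arm/centre annotation.

#' Count fragments in genome windows
#'
#' A fragment is assigned to every window its interval overlaps by at least
#' one base; strand is ignored. Fragments on chromosomes absent from the
#' tiling are skipped with a message.
#'
#' @param fragments Interval `data.frame` of aligned fragments.
#' @param windows Tiling from [tile_genome()].
#' @return `windows` with a `count` column (the window track).
#' @export
count_fragments <- function(fragments, windows) {
  known <- fragments$chrom %in% unique(windows$chrom)
  if (any(!known))
    message(sum(!known), " fragment(s) on unknown chromosomes skipped")
  fragments <- fragments[known, , drop = FALSE]
  windows$count <- if (nrow(fragments))
    overlap_counts(windows, fragments) else 0L
  windows
}

#' Normalize antibody window tracks to the MNase control
#'
#' All tracks (antibody replicates and control) are first library-scaled on
#' their window totals ([normalize_counts()] semantics); the per-window
#' ratio is then `(mean over antibody tracks of scaled count + pseudo) /
#' (scaled control count + pseudo)` with the pipeline pseudo-count of 8 in
#' both numerator and denominator, so empty windows give a ratio of 1.
#'
#' @param ab_tracks A window track (from [count_fragments()]) or list of
#'   replicate tracks on identical tilings.
#' @param control Control window track on the same tiling.
#' @param pseudo Pseudo-count (default 8).
#' @return Window `data.frame` with a `ratio` column.
#' @export
control_normalize <- function(ab_tracks, control, pseudo = 8) {
  if (is.data.frame(ab_tracks)) ab_tracks <- list(ab_tracks)
  for (tr in ab_tracks) check_same_tiling(tr, control)
  m <- cbind(vapply(ab_tracks, `[[`, numeric(nrow(control)), "count"),
             control$count)
  m <- normalize_counts(m)
  n_ab <- length(ab_tracks)
  num <- rowMeans(m[, seq_len(n_ab), drop = FALSE] + pseudo)
  out <- control[, c("chrom", "start", "end")]
  out$ratio <- num / (m[, n_ab + 1] + pseudo)
  attr(out, "width") <- attr(control, "width")
  out
}

#' Call enriched domains from a ratio track
#'
#' Maximal runs of at least `min_run` consecutive windows with
#' `ratio > fc_min` are merged into one domain each; the mean window ratio
#' is recorded as the domain's enrichment.
#'
#' @param ratio_track Window `data.frame` with a `ratio` column.
#' @param fc_min Enrichment cutoff (default 2, the gene-marking threshold).
#' @param min_run Minimum number of consecutive enriched windows (default 2).
#' @param mark Optional mark label stored on the result.
#' @return Interval `data.frame` with `mean_enrichment`, `n_windows` and
#'   (if given) `mark` columns; zero rows when nothing is enriched.
#' @export
call_domains <- function(ratio_track, fc_min = 2, min_run = 2, mark = NULL) {
  stopifnot("ratio" %in% names(ratio_track), min_run >= 1)
  out <- lapply(split(ratio_track, ratio_track$chrom), function(tr) {
    tr <- tr[order(tr$start), ]
    r <- rle(tr$ratio > fc_min)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    keep <- which(r$values & r$lengths >= min_run)
    if (!length(keep)) return(NULL)
    data.frame(chrom = tr$chrom[1],
               start = tr$start[starts[keep]],
               end = tr$end[stops[keep]],
               mean_enrichment = vapply(keep, function(k)
                 mean(tr$ratio[starts[k]:stops[k]]), numeric(1)),
               n_windows = r$lengths[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), mean_enrichment = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(mark) && nrow(out)) out$mark <- mark
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Per-gene mark enrichment over the MNase control
#'
#' Counts fragments overlapping any exon of each gene (a fragment counts
#' once per gene), library-scales antibody and control on their total
#' fragment counts, and reports
#' `(mean scaled antibody exon count + 8) / (scaled control exon count + 8)`.
#' A gene is flagged `marked` when its enrichment exceeds `fc_min`.
#'
#' @param ab_fragments Fragment `data.frame` or list of replicate fragment
#'   tables for the antibody.
#' @param control_fragments Fragment `data.frame` for the MNase control.
#' @param models `gene_models` object.
#' @param fc_min Marked threshold (default 2).
#' @param pseudo Pseudo-count (default 8).
#' @return `data.frame` with `gene_id`, `enrichment`, `marked`.
#' @export
gene_mark_enrichment <- function(ab_fragments, control_fragments, models,
                                 fc_min = 2, pseudo = 8) {
  if (is.data.frame(ab_fragments)) ab_fragments <- list(ab_fragments)
  g <- models$genes
  if (!nrow(models$exons)) stop("gene models contain no exons")
  if (!all(g$gene_id %in% models$exons$gene_id))
    stop("gene(s) without exons")
  exon_gene <- models$exons$gene_id
  count_per_gene <- function(frags) {
    hits <- overlap_pairs(models$exons, frags)
    # one count per (gene, fragment) pair even when several exons overlap
    key <- unique(paste(exon_gene[hits$query], hits$subject))
    tab <- table(sub(" .*$", "", key))
    cnt <- setNames(numeric(nrow(g)), g$gene_id)
    cnt[names(tab)] <- as.numeric(tab)
    cnt
  }
  ab_counts <- vapply(ab_fragments, count_per_gene, numeric(nrow(g)))
  if (!is.matrix(ab_counts))
    ab_counts <- matrix(ab_counts, nrow = nrow(g))
  ctrl_counts <- count_per_gene(control_fragments)
  totals <- c(vapply(ab_fragments, nrow, integer(1)), nrow(control_fragments))
  if (any(totals == 0)) stop("empty fragment set")
  fac <- mean(totals) / totals
  scaled_ab <- sweep(ab_counts, 2, fac[-length(fac)], `*`)
  scaled_ctrl <- ctrl_counts * fac[length(fac)]
  enr <- rowMeans(scaled_ab + pseudo) / (scaled_ctrl + pseudo)
  data.frame(gene_id = g$gene_id, enrichment = unname(enr),
             marked = unname(enr > fc_min), stringsAsFactors = FALSE)
}

#' C. elegans (ce10) chromosome arm/centre border coordinates
#'
#' Left/right centre borders per chromosome; chromosome X carries a single
#' border and is treated as a left-arm/centre split (positions at or beyond
#' the border are "centre").
#'
#' @return `data.frame` with `chrom`, `left`, `right` (right is `NA` for X).
#' @export
celegans_arm_borders <- function() {
  data.frame(
    chrom = c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrX"),
    left = c(3745632, 4708341, 3508994, 7317812, 8125434, 41919369),
    right = c(10809938, 11877168, 9947268, 12176625, 13849337, NA),
    stringsAsFactors = FALSE)
}

# Accept chr1/1/I/chrI spellings for the worm assembly.
normalize_worm_chrom <- function(chrom) {
  key <- toupper(sub("^CHR", "", toupper(chrom)))
  map <- c("1" = "chrI", "I" = "chrI", "2" = "chrII", "II" = "chrII",
           "3" = "chrIII", "III" = "chrIII", "4" = "chrIV", "IV" = "chrIV",
           "5" = "chrV", "V" = "chrV", "X" = "chrX")
  out <- unname(map[key])
  out[is.na(out)] <- chrom[is.na(out)]
  out
}

#' Annotate positions as chromosome arm or centre
#'
#' A position is "centre" when `left <= pos <= right` for its chromosome's
#' border coordinates (for chromosome X, when `pos >= left`), otherwise
#' "arm". Defaults to the worm (ce10) borders; custom borders may be
#' supplied for other assemblies.
#'
#' @param chrom Chromosome names (worm spellings `chr1`/`chrI`/`I`
#'   accepted under the default borders).
#' @param pos Positions (0-based, any within-chromosome coordinate).
#' @param borders Border table as from [celegans_arm_borders()].
#' @return Character vector of `"arm"` / `"centre"`.
#' @export
arm_centre_annotate <- function(chrom, pos,
                                borders = celegans_arm_borders()) {
  if (identical(borders, celegans_arm_borders()))
    chrom <- normalize_worm_chrom(chrom)
  i <- match(chrom, borders$chrom)
  if (any(is.na(i)))
    stop("no border coordinates for chromosome(s): ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  left <- borders$left[i]; right <- borders$right[i]
  centre <- ifelse(is.na(right), pos >= left, pos >= left & pos <= right)
  ifelse(centre, "centre", "arm")
}
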