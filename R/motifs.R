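# PWM genome scanning under the min-score-10 rule, promoter/region hit
# counting, and the set-versus-genome motif enrichment statistic.

#' Promoter windows around gene starts
#'
#' `+` strand: `[tss - upstream, tss + downstream)`; `-` strand the mirror
#' image `[tss - downstream, tss + upstream)`; clipped to chromosome bounds.
#' Defaults are the motif-analysis promoter (1,500 bp 5' and 500 bp 3' of
#' the TSS); the accessibility promoter uses 1,000/100.
#'
#' @param models `gene_models` object.
#' @param upstream,downstream Extents in bp (>= 0).
#' @param chrom_lengths Optional named lengths for right-clipping.
#' @return Interval `data.frame` with `gene_id` and `strand`.
#' @export
promoter_windows <- function(models, upstream = 1500, downstream = 500,
                             chrom_lengths = NULL) {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0)
  g <- models$genes
  plus <- g$strand == "+"
  start <- ifelse(plus, g$tss - upstream, g$tss - downstream)
  end <- ifelse(plus, g$tss + downstream, g$tss + upstream)
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    chrom_lengths <- genome_lengths(chrom_lengths)
    end <- pmin(end, chrom_lengths[g$chrom])
  }
  data.frame(chrom = g$chrom, start = as.integer(start),
             end = as.integer(end), strand = g$strand,
             gene_id = g$gene_id, stringsAsFactors = FALSE)
}

# Encode a sequence as 1..4 over A,C,G,T; N (or anything else) -> NA so any
# window containing it scores NA and never reaches a threshold.
encode_dna <- function(seq) {
  match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
}

# Reverse complement of a PWM: complement the base rows, reverse the columns.
revcomp_pwm_weights <- function(w) {
  out <- w[c("T", "G", "C", "A"), rev(seq_len(ncol(w))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

# Scores of all length-L windows of an encoded sequence under weights w.
pwm_window_scores <- function(code, w) {
  L <- ncol(w)
  npos <- length(code) - L + 1L
  if (npos < 1L) return(numeric(0))
  s <- numeric(npos)
  for (i in seq_len(L)) s <- s + w[, i][code[i:(i + npos - 1L)]]
  s
}

#' Scan a genome with a position weight matrix
#'
#' Window score is the direct sum of matrix entries at matched bases (the
#' matrices are used as distributed, not log-odds converted). The effective
#' threshold is `min(min_score, max_score)`: hits need a minimum score of
#' `min_score` unless the matrix cannot reach it, in which case a perfect
#' (maximum obtainable) score is required. Both strands are scanned; hits
#' are reported at the forward-strand start of the matched window. Windows
#' containing `N` never hit.
#'
#' @param genome Named character vector (from [read_fasta()]).
#' @param pwm A `pwm` object.
#' @param min_score Score threshold (default 10).
#' @return `data.frame` with `chrom`, `start`, `strand`, `score`,
#'   `motif_id`; the motif length is attached as attribute `L`.
#' @export
scan_pwm <- function(genome, pwm, min_score = 10) {
  stopifnot(inherits(pwm, "pwm"))
  thr <- min(min_score, pwm$max_score)
  w_fwd <- pwm$weights
  w_rev <- revcomp_pwm_weights(pwm$weights)
  out <- lapply(names(genome), function(ch) {
    code <- encode_dna(genome[[ch]])
    res <- lapply(c("+", "-"), function(st) {
      s <- pwm_window_scores(code, if (st == "+") w_fwd else w_rev)
      hit <- which(!is.na(s) & s >= thr)
      if (!length(hit)) return(NULL)
      data.frame(chrom = ch, start = hit - 1L, strand = st,
                 score = s[hit], stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  out$motif_id <- rep(pwm$id, nrow(out))
  attr(out, "L") <- ncol(pwm$weights)
  out
}

#' Scan a genome with a PWM library
#'
#' @param genome Named character vector.
#' @param pwms List of `pwm` objects (as from [read_pwm_set()]).
#' @param min_score Score threshold (default 10).
#' @return Combined hit `data.frame` with an `end` column
#'   (`start + motif length`).
#' @export
scan_pwm_set <- function(genome, pwms, min_score = 10) {
  out <- lapply(pwms, function(p) {
    h <- scan_pwm(genome, p, min_score)
    h$end <- h$start + ncol(p$weights)
    h
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "strand", "score", "motif_id")]
}

#' Count motif hits per region and motif
#'
#' A hit counts for a region when the matched window overlaps it by at
#' least one base; a hit overlapping several regions counts for each.
#' Multiple hits of one motif in one region each count (site-count
#' weighting).
#'
#' @param hits Hit table from [scan_pwm_set()] (needs `end` and `motif_id`).
#' @param regions Interval `data.frame`; rows are identified by a `gene_id`
#'   or `name` column, else by row index.
#' @return Integer matrix, regions x motifs.
#' @export
region_hit_counts <- function(hits, regions) {
  ids <- if ("gene_id" %in% names(regions)) regions$gene_id
         else if ("name" %in% names(regions)) regions$name
         else as.character(seq_len(nrow(regions)))
  motifs <- unique(hits$motif_id)
  m <- matrix(0L, nrow(regions), length(motifs),
              dimnames = list(ids, motifs))
  if (nrow(hits)) {
    pairs <- overlap_pairs(regions, hits)
    if (nrow(pairs)) {
      tab <- table(factor(pairs$query, levels = seq_len(nrow(regions))),
                   factor(hits$motif_id[pairs$subject], levels = motifs))
      m[] <- as.integer(tab)
    }
  }
  m
}

#' @rdname region_hit_counts
#' @param promoters Promoter windows from [promoter_windows()].
#' @export
promoter_hit_counts <- function(hits, promoters) {
  region_hit_counts(hits, promoters)
}

#' Motif enrichment of a gene set versus all promoters
#'
#' Per motif, the per-gene hit rate in the set is compared with the rate
#' over the whole universe:
#' `log2_enrichment = log2((rate_set + eps) / (rate_all + eps))` with
#' `eps = 1 / |universe|` by default, and
#' `log2_abundance = log2(genome-wide hits + 1)`. A motif is called
#' enriched when `log2_enrichment > enr_min` and `log2_abundance >
#' abund_min` (defaults 0.5 and 8).
#'
#' @param hit_counts Region x motif count matrix over the gene universe
#'   (from [promoter_hit_counts()]; rownames are gene ids).
#' @param set Character vector of gene ids (non-empty subset of the
#'   universe).
#' @param genome_hits Named vector of genome-wide hit totals per motif.
#' @param tf_map Optional named list mapping motif id to TF names.
#' @param enr_min,abund_min Calling thresholds.
#' @param eps Rate regularizer; default `1 / nrow(hit_counts)`.
#' @return `data.frame` per motif: `motif_id`, `tf`, `hits_set`,
#'   `hits_all`, `hits_genomewide`, `log2_abundance`, `log2_enrichment`,
#'   `enriched`.
#' @export
motif_enrichment <- function(hit_counts, set, genome_hits, tf_map = NULL,
                             enr_min = 0.5, abund_min = 8, eps = NULL) {
  if (!length(set)) stop("empty gene set")
  if (!all(set %in% rownames(hit_counts)))
    stop("set contains ids outside the universe")
  n_all <- nrow(hit_counts)
  if (is.null(eps)) eps <- 1 / n_all
  set_counts <- colSums(hit_counts[unique(set), , drop = FALSE])
  region_motif_enrichment(set_counts, length(unique(set)),
                          colSums(hit_counts), n_all,
                          genome_hits, tf_map, enr_min, abund_min, eps)
}

#' Motif enrichment of arbitrary regions (e.g. intergenic peaks)
#'
#' Same statistic as [motif_enrichment()] with a region set (such as
#' newly accessible intergenic peaks) in place of set promoters, compared
#' against the promoter universe.
#'
#' @param set_counts Region x motif count matrix for the set regions, or a
#'   named per-motif total.
#' @param n_set Number of set regions (taken from the matrix if omitted).
#' @param universe_counts Region x motif count matrix over the comparison
#'   universe (all promoters), or a named per-motif total.
#' @param n_universe Number of universe regions (from the matrix if
#'   omitted).
#' @inheritParams motif_enrichment
#' @export
motif_enrichment_regions <- function(set_counts, universe_counts,
                                     genome_hits, n_set = NULL,
                                     n_universe = NULL, tf_map = NULL,
                                     enr_min = 0.5, abund_min = 8,
                                     eps = NULL) {
  if (is.matrix(set_counts)) {
    if (is.null(n_set)) n_set <- nrow(set_counts)
    set_counts <- colSums(set_counts)
  }
  if (is.matrix(universe_counts)) {
    if (is.null(n_universe)) n_universe <- nrow(universe_counts)
    universe_counts <- colSums(universe_counts)
  }
  stopifnot(!is.null(n_set), !is.null(n_universe))
  if (is.null(eps)) eps <- 1 / n_universe
  region_motif_enrichment(set_counts, n_set, universe_counts, n_universe,
                          genome_hits, tf_map, enr_min, abund_min, eps)
}

region_motif_enrichment <- function(set_counts, n_set, all_counts, n_all,
                                    genome_hits, tf_map, enr_min,
                                    abund_min, eps) {
  motifs <- names(all_counts)
  stopifnot(!is.null(motifs), all(motifs %in% names(genome_hits)))
  set_counts <- set_counts[motifs]
  set_counts[is.na(set_counts)] <- 0
  rate_set <- set_counts / n_set
  rate_all <- all_counts / n_all
  log2_enr <- log2((rate_set + eps) / (rate_all + eps))
  log2_ab <- log2(genome_hits[motifs] + 1)
  tf <- if (is.null(tf_map)) motifs
        else vapply(motifs, function(m)
          paste(tf_map[[m]], collapse = "/"), character(1))
  data.frame(motif_id = motifs, tf = tf,
             hits_set = as.numeric(set_counts),
             hits_all = as.numeric(all_counts),
             hits_genomewide = as.numeric(genome_hits[motifs]),
             log2_abundance = as.numeric(log2_ab),
             log2_enrichment = as.numeric(log2_enr),
             enriched = as.numeric(log2_enr) > enr_min &
               as.numeric(log2_ab) > abund_min,
             row.names = NULL, stringsAsFactors = FALSE)
}
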