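# Count and fragment simulators over the synthetic world. Each function
# draws from a deterministic RNG substream of the config seed, so the same
# world yields byte-identical outputs on re-run.

nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu,
                                                 size = 1 / dispersion)
}

#' Simulate RNA-seq counts
#'
#' Negative-binomial counts per gene and sample. Derepressible genes have
#' their baseline multiplied by `derepression_fc` in `met-2` and
#' `met-2 set-25` samples only (`set-25` behaves like WT). Library sizes
#' are drawn per sample (uniform 0.8-1.2 factor).
#'
#' @param world From [generate_world()].
#' @param config The world's [sim_config()] (defaults to `world$config`).
#' @return List with `counts` (gene x sample integer matrix) and `samples`
#'   (`sample`, `genotype`, `replicate`).
#' @export
simulate_expression_counts <- function(world, config = world$config) {
  set.seed(stream_seed(config$seed, "expression"))
  truth <- world$truth
  samples <- expand.grid(replicate = seq_len(config$replicates),
                         genotype = config$genotypes,
                         stringsAsFactors = FALSE)
  samples$sample <- paste0(gsub("[^A-Za-z0-9]+", ".", samples$genotype),
                           "_", samples$replicate)
  samples <- samples[, c("sample", "genotype", "replicate")]
  fc_on <- c("met-2", "met-2 set-25")
  counts <- vapply(seq_len(nrow(samples)), function(j) {
    lib <- runif(1, 0.8, 1.2)
    fc <- if (samples$genotype[j] %in% fc_on) truth$derepression_fc else 1
    mu <- truth$baseline_expression * fc * lib
    nb_draw(nrow(truth), mu, config$dispersion)
  }, numeric(nrow(truth)))
  dimnames(counts) <- list(truth$gene_id, samples$sample)
  list(counts = counts, samples = samples)
}

# Interval-union complement within chromosomes.
complement_intervals <- function(iv, chrom_lengths) {
  full <- data.frame(chrom = names(chrom_lengths), start = 0,
                     end = as.numeric(chrom_lengths))
  out <- GenomicRanges::setdiff(as_granges0(full),
                                GenomicRanges::reduce(as_granges0(iv)))
  as_intervals0(out)
}

# Uniform positions within a set of intervals, length-weighted.
sample_positions_in <- function(iv, n) {
  if (n == 0 || !nrow(iv))
    return(data.frame(chrom = character(), pos = integer()))
  w <- iv$end - iv$start
  i <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
  data.frame(chrom = iv$chrom[i],
             pos = iv$start[i] + floor(runif(n) * w[i]),
             stringsAsFactors = FALSE)
}

# Which regions emit a mark in a genotype, and at what in-domain rate
# multiplier relative to background. H3K9me2 requires MET-2 (lost in met-2
# and the double mutant); H3K9me3 requires both writers and is emitted at
# half rate in met-2 (partial maintenance); H3K27ac appears at Group B/C
# promoters only in the double mutant. MNase is the uniform control.
chic_emission <- function(world, mark, genotype, config) {
  r <- config$chic_ratio
  if (mark == "MNase") return(list(regions = world$domains[0, ], rate = 1))
  if (mark == "H3K27ac") {
    active <- genotype == "met-2 set-25"
    bc <- world$truth$gene_id[world$truth$group %in% c("B", "C")]
    m <- world$models
    prom <- promoter_windows(m, 1000, 100, world$chrom_lengths)
    regions <- prom[prom$gene_id %in% bc, c("chrom", "start", "end")]
    return(list(regions = regions, rate = if (active) r else 1))
  }
  rate <- switch(mark,
    "H3K9me2" = if (genotype %in% c("WT", "set-25")) r else 1,
    "H3K9me3" = if (genotype == "WT") r
                else if (genotype == "met-2") 1 + (r - 1) / 2 else 1,
    stop("unknown mark: ", mark))
  list(regions = world$domains, rate = rate)
}

#' Simulate ChIC-seq fragments
#'
#' Fragment start positions are sampled with rate `rate` inside the mark's
#' emitting regions and 1 outside (see the genotype rules in the details),
#' then extended to `fragment_length` and clipped. The MNase control is
#' uniform.
#'
#' @details Emission rules: H3K9me2 is emitted in WT and `set-25` (MET-2
#'   dependent); H3K9me3 in WT, at half the in-domain excess in `met-2`,
#'   and not at all in `set-25` or the double mutant; H3K27ac at Group B/C
#'   promoters in the double mutant only.
#'
#' @param world From [generate_world()].
#' @param mark `"H3K9me2"`, `"H3K9me3"`, `"H3K27ac"` or `"MNase"`.
#' @param genotype One of the config genotypes.
#' @param config The world's config.
#' @param depth Fragments to draw (default `config$chic_depth`).
#' @return Fragment interval `data.frame`.
#' @export
simulate_chic_fragments <- function(world, mark, genotype,
                                    config = world$config,
                                    depth = config$chic_depth) {
  stopifnot(genotype %in% config$genotypes || mark == "MNase")
  set.seed(stream_seed(config$seed, "chic", mark, genotype))
  em <- chic_emission(world, mark, genotype, config)
  lens <- world$chrom_lengths
  G <- sum(as.numeric(lens))
  regions <- em$regions
  Ld <- if (nrow(regions)) sum(regions$end - regions$start) else 0
  p_in <- em$rate * Ld / (em$rate * Ld + (G - Ld))
  n_in <- rbinom(1, depth, p_in)
  inside <- sample_positions_in(regions, n_in)
  outside <- sample_positions_in(complement_intervals(regions, lens),
                                 depth - n_in)
  pos <- rbind(inside, outside)
  frag <- data.frame(chrom = pos$chrom, start = as.integer(pos$pos),
                     end = as.integer(pmin(pos$pos +
                                             config$fragment_length,
                                           lens[pos$chrom])),
                     stringsAsFactors = FALSE)
  frag <- frag[frag$end > frag$start, ]
  frag[order(frag$chrom, frag$start), ]
}

#' Simulate ATAC peak counts and DamID bin counts
#'
#' Peak counts: every peak starts at `peak_baseline`; promoter peaks of
#' Group B/C genes gain `accessibility_fold` in `met-2 set-25` samples;
#' intergenic peaks gain `intergenic_fold` in the double mutant and
#' `intergenic_fold_met2` in `met-2` (Group A promoter peaks never gain).
#' DamID: 10-kb bins; fusion counts are elevated over the control by
#' `2^periphery_bias` in bins overlapping biased genes.
#'
#' @param world From [generate_world()].
#' @param config The world's config.
#' @return List with `peak_counts`, `samples` (shared with the peak
#'   matrix), `damid` (list: `bins`, `fusion`, `control` matrices with
#'   `damid_replicates` columns).
#' @export
simulate_accessibility_and_damid <- function(world, config = world$config) {
  set.seed(stream_seed(config$seed, "atac"))
  truth <- world$truth
  peaks <- world$peaks
  samples <- expand.grid(replicate = seq_len(config$replicates),
                         genotype = config$genotypes,
                         stringsAsFactors = FALSE)
  samples$sample <- paste0(gsub("[^A-Za-z0-9]+", ".", samples$genotype),
                           "_", samples$replicate)
  samples <- samples[, c("sample", "genotype", "replicate")]
  bc <- truth$gene_id[truth$group %in% c("B", "C")]
  fold_for <- function(genotype) {
    f <- rep(1, nrow(peaks))
    if (genotype == "met-2 set-25") {
      f[peaks$type == "promoter" & peaks$gene_id %in% bc] <-
        config$accessibility_fold
      f[peaks$type == "intergenic"] <- config$intergenic_fold
    } else if (genotype == "met-2") {
      f[peaks$type == "intergenic"] <- config$intergenic_fold_met2
    }
    f
  }
  peak_counts <- vapply(seq_len(nrow(samples)), function(j) {
    lib <- runif(1, 0.8, 1.2)
    mu <- config$peak_baseline * fold_for(samples$genotype[j]) * lib
    nb_draw(nrow(peaks), mu, config$dispersion)
  }, numeric(nrow(peaks)))
  dimnames(peak_counts) <- list(peaks$name, samples$sample)

  set.seed(stream_seed(config$seed, "damid"))
  bins <- tile_genome(world$chrom_lengths, config$damid_bin)
  g <- world$models$genes
  spans <- data.frame(chrom = g$chrom, start = g$span_start,
                      end = g$span_end)
  pairs <- overlap_pairs(bins, spans)
  bias <- rep(0, nrow(bins))
  if (nrow(pairs)) {
    bp <- tapply(truth$periphery_bias[pairs$subject], pairs$query, max)
    bias[as.integer(names(bp))] <- bp
  }
  fusion <- vapply(seq_len(config$damid_replicates), function(j) {
    lib <- runif(1, 0.8, 1.2)
    rpois(nrow(bins), config$damid_baseline * 2^bias * lib)
  }, numeric(nrow(bins)))
  control <- vapply(seq_len(config$damid_replicates), function(j) {
    lib <- runif(1, 0.8, 1.2)
    rpois(nrow(bins), config$damid_baseline * lib)
  }, numeric(nrow(bins)))
  colnames(fusion) <- paste0("fusion_", seq_len(config$damid_replicates))
  colnames(control) <- paste0("control_", seq_len(config$damid_replicates))
  list(peak_counts = peak_counts, samples = samples,
       damid = list(bins = bins, bias = bias, fusion = fusion,
                    control = control))
}
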