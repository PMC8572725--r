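# Synthetic "worm world" generator: a small genome with planted ground
# truth (silenced genes inside H3K9me domains, promoter motifs that
# derepress on H3K9me loss, Group A/B/C accessibility structure,
# periphery-biased DamID signal) so every downstream stage is testable
# without any external data.

#' Simulation configuration
#'
#' All defaults define the package's reference study conditions; every
#' value is a free parameter of the generator, not an estimate of the
#' biology (see the methods vignette).
#'
#' @param seed Integer seed (mandatory); all generator functions derive
#'   deterministic substreams from it.
#' @param n_chromosomes,chrom_length World size (3 x 300 kb default).
#' @param n_muscle,n_derepressible,n_silenced_stable,n_background Genes
#'   per truth class.
#' @param genotypes Genotype labels; the four-genotype design is assumed
#'   by the emission rules.
#' @param replicates Replicates per genotype for count simulation.
#' @param dispersion Negative-binomial dispersion (0 = Poisson).
#' @param baseline_silenced,baseline_muscle,baseline_background Mean counts.
#' @param derepression_fc Fold change of derepressible genes in `met-2`
#'   and `met-2 set-25` samples.
#' @param gene_span,gene_spacing,gene_margin Gene layout in bp.
#' @param domain_pad H3K9me domain padding around silenced gene spans (bp).
#' @param chic_depth Fragments per ChIC sample.
#' @param chic_ratio In-domain / background fragment rate ratio.
#' @param fragment_length ChIC fragment length (bp).
#' @param n_planted_motifs,n_decoy_motifs,motif_length,motif_weight,motif_copies
#'   PWM library design; planted consensi are inserted `motif_copies`
#'   times upstream of every derepressible TSS.
#' @param n_repeats_per_chrom,repeat_length Repeat annotation design.
#' @param peak_baseline,accessibility_fold ATAC promoter-peak counts and
#'   the met-2 set-25 gain at Group B/C promoters.
#' @param n_intergenic_peaks,intergenic_fold,intergenic_fold_met2
#'   Intergenic enhancer-like peaks per chromosome and their gains.
#' @param damid_bin,damid_baseline,damid_replicates DamID design.
#' @param bias_A,bias_BC Target DamID log2-ratios for Group A vs B/C genes.
#' @param n_nuclei,img_dim,voxel_size,nucleus_radius,foci_per_nucleus,
#'   focus_sigma,focus_amp,envelope_amp,snr,frac_outside Imaging design
#'   (physical units are arbitrary microns; `snr` is focus amplitude over
#'   Gaussian read noise).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 3, chrom_length = 300000,
                       n_muscle = 60, n_derepressible = 30,
                       n_silenced_stable = 30, n_background = 180,
                       genotypes = c("WT", "met-2", "set-25",
                                     "met-2 set-25"),
                       replicates = 3, dispersion = 0.1,
                       baseline_silenced = 20, baseline_muscle = 200,
                       baseline_background = 50, derepression_fc = 16,
                       gene_span = 1500, gene_spacing = 2400,
                       gene_margin = 2000, domain_pad = 250,
                       chic_depth = 90000, chic_ratio = 8,
                       fragment_length = 150,
                       n_planted_motifs = 3, n_decoy_motifs = 3,
                       motif_length = 12, motif_weight = 1.2,
                       motif_copies = 2,
                       n_repeats_per_chrom = 30, repeat_length = 200,
                       peak_baseline = 50, accessibility_fold = 8,
                       n_intergenic_peaks = 20, intergenic_fold = 8,
                       intergenic_fold_met2 = 2,
                       damid_bin = 10000, damid_baseline = 200,
                       damid_replicates = 3, bias_A = 2, bias_BC = 0.5,
                       n_nuclei = 6, img_dim = c(48, 48, 24),
                       voxel_size = c(0.1, 0.1, 0.2),
                       nucleus_radius = 1.8, foci_per_nucleus = 2,
                       focus_sigma = 0.15, focus_amp = 200,
                       envelope_amp = 100, snr = 10, frac_outside = 0.1) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  counts <- c(cfg$n_chromosomes, cfg$chrom_length, cfg$replicates,
              cfg$n_muscle, cfg$n_derepressible, cfg$n_silenced_stable,
              cfg$n_background, cfg$chic_depth)
  if (any(counts < 0)) stop("negative size parameter")
  if (cfg$derepression_fc < 1) stop("derepression_fc must be >= 1")
  structure(cfg, class = "sim_config")
}

# Deterministic RNG substream per generator stage: keeps independent
# stages reproducible regardless of call order.
stream_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((seed * 7919 + h) %% 2147483587)
}

n_genes_total <- function(config) {
  config$n_muscle + config$n_derepressible + config$n_silenced_stable +
    config$n_background
}

#' Generate the synthetic world
#'
#' Builds the genome (uniform random sequence), gene models on a regular
#' layout, repeat annotation, the PWM library (planted + decoy motifs),
#' H3K9me domains covering the silenced genes, ATAC peak intervals
#' (promoter peaks for every gene plus intergenic enhancer-like peaks in a
#' gene-free zone per chromosome), and the per-gene truth table. Planted
#' motif consensi are embedded at recorded promoter offsets of every
#' derepressible gene. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `synth_world` list: `genome`, `chrom_lengths`, `models`,
#'   `repeats`, `pwms`, `domains`, `peaks`, `truth`, `planted_sites`,
#'   `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "world"))
  n_genes <- n_genes_total(config)
  per_chrom <- ceiling(n_genes / config$n_chromosomes)
  zone_end <- config$gene_margin + per_chrom * config$gene_spacing
  if (zone_end + config$gene_margin > config$chrom_length)
    stop("genes do not fit on chromosomes; enlarge chrom_length or reduce ",
         "gene count/spacing")
  chroms <- paste0("chrS", seq_len(config$n_chromosomes))
  genome <- setNames(vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                 replace = TRUE), collapse = ""), character(1)), chroms)
  lens <- genome_lengths(genome)

  # gene layout on a regular grid; classes shuffled over slots
  slot <- seq_len(n_genes) - 1L
  chrom <- chroms[slot %/% per_chrom + 1L]
  s <- config$gene_margin + (slot %% per_chrom) * config$gene_spacing
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  gene_id <- sprintf("g%03d", seq_len(n_genes))
  classes <- sample(rep(c("muscle_expressed", "silenced_derepressible",
                          "silenced_stable", "background"),
                        c(config$n_muscle, config$n_derepressible,
                          config$n_silenced_stable, config$n_background)))
  # two exons per gene: [0,600) and [900, span) relative to the span start
  e2_start <- min(900L, config$gene_span - 100L)
  exons <- rbind(
    data.frame(gene_id = gene_id, chrom = chrom, start = s,
               end = s + min(600L, e2_start - 100L), strand = strand),
    data.frame(gene_id = gene_id, chrom = chrom, start = s + e2_start,
               end = s + config$gene_span, strand = strand))
  models <- gene_models(exons, chrom_lengths = lens)
  g <- models$genes

  # H3K9me domains: padded silenced-gene spans snapped to the 500 bp
  # window grid, merged
  sil <- g$gene_id %in% gene_id[classes %in%
           c("silenced_derepressible", "silenced_stable")]
  domains <- data.frame(
    chrom = g$chrom[sil],
    start = pmax(0, (g$span_start[sil] - config$domain_pad) %/% 500 * 500),
    end = pmin(lens[g$chrom[sil]],
               ceiling((g$span_end[sil] + config$domain_pad) / 500) * 500))
  domains <- as_intervals0(GenomicRanges::reduce(as_granges0(domains)))

  # repeats: confined to the gene zone so the intergenic peak zone stays
  # repeat-free
  repeats <- do.call(rbind, lapply(chroms, function(ch) {
    st <- sort(sample.int(zone_end - config$repeat_length,
                          config$n_repeats_per_chrom))
    data.frame(chrom = ch, start = st, end = st + config$repeat_length,
               name = sprintf("rep_%s_%02d", ch,
                              seq_len(config$n_repeats_per_chrom)),
               stringsAsFactors = FALSE)
  }))

  # PWM library: planted + decoy motifs (uniform per-base weight on a
  # random consensus; threshold 10 then requires ceiling(10/weight)
  # consensus matches)
  n_motifs <- config$n_planted_motifs + config$n_decoy_motifs
  pwms <- lapply(seq_len(n_motifs), function(i) {
    consensus <- sample(c("A", "C", "G", "T"), config$motif_length,
                        replace = TRUE)
    w <- matrix(0, 4, config$motif_length,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    w[cbind(match(consensus, rownames(w)), seq_len(config$motif_length))] <-
      config$motif_weight
    planted <- i <= config$n_planted_motifs
    p <- pwm(id = sprintf("M%02d", i),
             tf_names = sprintf("%s-%d", if (planted) "TFP" else "TFD", i),
             weights = w)
    p$consensus <- paste(consensus, collapse = "")
    p$planted <- planted
    p
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "id")

  # plant every planted motif's consensus `motif_copies` times upstream of
  # each derepressible TSS; offsets recorded
  derep <- g[g$gene_id %in% gene_id[classes == "silenced_derepressible"], ]
  offsets <- 250 + (seq_len(config$n_planted_motifs * config$motif_copies) -
                      1L) * 150L
  planted_sites <- NULL
  if (nrow(derep) && config$n_planted_motifs > 0) {
    planted <- pwms[vapply(pwms, `[[`, logical(1), "planted")]
    motif_of <- rep(names(planted), each = config$motif_copies)
    sites <- do.call(rbind, lapply(seq_len(nrow(derep)), function(i) {
      tss <- derep$tss[i]; st <- derep$strand[i]
      pos <- if (st == "+") tss - offsets - config$motif_length
             else tss + offsets
      data.frame(gene_id = derep$gene_id[i], chrom = derep$chrom[i],
                 start = pos, motif_id = motif_of,
                 strand = st, stringsAsFactors = FALSE)
    }))
    sites <- sites[sites$start >= 0 &
                     sites$start + config$motif_length <=
                       lens[sites$chrom], ]
    for (i in seq_len(nrow(sites))) {
      p <- pwms[[sites$motif_id[i]]]
      ins <- if (sites$strand[i] == "+") p$consensus
             else revcomp_string(p$consensus)
      substr(genome[[sites$chrom[i]]], sites$start[i] + 1L,
             sites$start[i] + config$motif_length) <- ins
    }
    planted_sites <- sites
  }

  # ATAC peaks: a promoter peak per gene plus intergenic peaks in the
  # gene-free zone
  ppeaks <- data.frame(chrom = g$chrom,
                       start = pmax(0L, g$tss - 250L),
                       end = pmin(lens[g$chrom], g$tss + 150L),
                       name = paste0("pk_", g$gene_id),
                       gene_id = g$gene_id, type = "promoter",
                       stringsAsFactors = FALSE)
  ig_zone_start <- zone_end + 2000L
  ig_space <- (config$chrom_length - 1000L - ig_zone_start) %/%
    max(1L, config$n_intergenic_peaks)
  igpeaks <- do.call(rbind, lapply(chroms, function(ch) {
    st <- ig_zone_start + (seq_len(config$n_intergenic_peaks) - 1L) *
      ig_space
    data.frame(chrom = ch, start = st, end = st + 400L,
               name = sprintf("ig_%s_%02d", ch,
                              seq_len(config$n_intergenic_peaks)),
               gene_id = NA_character_, type = "intergenic",
               stringsAsFactors = FALSE)
  }))
  peaks <- rbind(ppeaks, igpeaks)
  rownames(peaks) <- NULL

  # group labels: derepressible -> A (2/3) or B (1/3);
  # silenced_stable -> C (2/3) or none
  group <- rep("none", n_genes)
  idx_d <- which(classes == "silenced_derepressible")
  idx_s <- which(classes == "silenced_stable")
  n_b <- round(length(idx_d) / 3)
  b_sel <- idx_d[sample.int(length(idx_d), n_b)]
  group[idx_d] <- "A"; group[b_sel] <- "B"
  group[idx_s[sample.int(length(idx_s), round(length(idx_s) * 2 / 3))]] <- "C"

  truth <- data.frame(
    gene_id = gene_id, class = classes, group = group,
    h3k9_domain = classes %in% c("silenced_derepressible",
                                 "silenced_stable"),
    planted_motifs = ifelse(classes == "silenced_derepressible",
      paste(vapply(pwms[vapply(pwms, `[[`, logical(1), "planted")],
                   function(p) p$tf_names[1], character(1)),
            collapse = ","), ""),
    periphery_bias = ifelse(group == "A", config$bias_A,
                            ifelse(group %in% c("B", "C"),
                                   config$bias_BC, 0)),
    baseline_expression = ifelse(classes == "muscle_expressed",
                                 config$baseline_muscle,
                          ifelse(classes == "background",
                                 config$baseline_background,
                                 config$baseline_silenced)),
    derepression_fc = ifelse(classes == "silenced_derepressible",
                             config$derepression_fc, 1),
    stringsAsFactors = FALSE)
  truth <- truth[match(g$gene_id, truth$gene_id), ]
  rownames(truth) <- NULL

  structure(list(genome = genome, chrom_lengths = lens, models = models,
                 repeats = repeats, pwms = pwms, domains = domains,
                 peaks = peaks, truth = truth,
                 planted_sites = planted_sites, config = config),
            class = "synth_world")
}

# Reverse complement of a plain character string.
revcomp_string <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
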