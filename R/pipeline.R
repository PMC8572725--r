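# End-to-end run over the synthetic world: one call that exercises every
# stage and returns the result tables. Used by the examples, the
# determinism checks and the acceptance script.

#' Jaccard overlap of two interval sets
#'
#' Base-level intersection over union of the two interval unions.
#'
#' @param a,b Interval `data.frame`s.
#' @return Scalar in \[0, 1\] (1 when both are empty).
#' @export
interval_jaccard <- function(a, b) {
  ga <- GenomicRanges::reduce(as_granges0(a))
  gb <- GenomicRanges::reduce(as_granges0(b))
  inter <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(ga, gb))))
  uni <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::union(ga, gb))))
  if (uni == 0) 1 else inter / uni
}

#' Run the full pipeline on a synthetic world
#'
#' Generates the world, simulates every assay, and runs the complete
#' analysis: differential expression (`met-2` and `met-2 set-25` vs WT)
#' and derepressed-set calling; ChIC-seq H3K9me3 window quantification,
#' MNase normalization, domain calling and per-gene marking (WT);
#' promoter motif scanning and enrichment over the derepressed set;
#' differential peak accessibility, feature annotation, intergenic peak
#' selection, promoter accessibility and Group A/B/C classification;
#' DamID bin ratios with the group position comparison; and (optionally)
#' nucleus rendering with focus-to-periphery measurement.
#'
#' @param config A [sim_config()].
#' @param run_imaging Render and analyse nucleus scenes (default TRUE).
#' @return Named list of result tables plus the `world`.
#' @export
run_pipeline <- function(config, run_imaging = TRUE) {
  world <- generate_world(config)
  lens <- world$chrom_lengths

  ## expression
  expr <- simulate_expression_counts(world, config)
  de_met2 <- de_test(expr$counts, expr$samples, c("met-2", "WT"))
  de_double <- de_test(expr$counts, expr$samples, c("met-2 set-25", "WT"))
  derepressed <- call_derepressed(de_double)

  ## ChIC-seq (WT H3K9me3 over MNase)
  windows <- tile_genome(lens, 500)
  ab <- simulate_chic_fragments(world, "H3K9me3", "WT")
  ctrl <- simulate_chic_fragments(world, "MNase", "WT")
  ratio <- control_normalize(count_fragments(ab, windows),
                             count_fragments(ctrl, windows))
  domains <- call_domains(ratio, fc_min = 2, min_run = 2,
                          mark = "H3K9me3")
  gene_marks <- gene_mark_enrichment(ab, ctrl, world$models)

  ## motifs
  hits <- scan_pwm_set(world$genome, world$pwms, min_score = 10)
  promoters <- promoter_windows(world$models, 1500, 500, lens)
  hit_counts <- promoter_hit_counts(hits, promoters)
  genome_hits <- table(factor(hits$motif_id, levels = names(world$pwms)))
  genome_hits <- setNames(as.numeric(genome_hits), names(genome_hits))
  tf_map <- lapply(world$pwms, `[[`, "tf_names")
  enrichment <- motif_enrichment(hit_counts, derepressed, genome_hits,
                                 tf_map = tf_map)

  ## accessibility + groups
  atac <- simulate_accessibility_and_damid(world, config)
  peak_de <- differential_peaks(atac$peak_counts, atac$samples,
                                c("met-2 set-25", "WT"))
  annotated <- annotate_peak_features(world$peaks, world$models,
                                      world$repeats,
                                      chrom_lengths = lens)
  acc_prom <- promoter_windows(world$models, 1000, 100, lens)
  intergenic <- select_intergenic_peaks(world$peaks, acc_prom,
                                        world$repeats)
  prom_peaks <- world$peaks$type == "promoter"
  prom_counts <- atac$peak_counts[prom_peaks, , drop = FALSE]
  rownames(prom_counts) <- world$peaks$gene_id[prom_peaks]
  acc_de <- promoter_accessibility(prom_counts, atac$samples,
                                   c("met-2 set-25", "WT"))
  groups <- classify_groups(de_double, acc_de)

  ## DamID positioning
  damid <- damid_bin_ratio(rowSums(atac$damid$fusion),
                           rowSums(atac$damid$control),
                           atac$damid$bins)
  position <- group_position_compare(damid, groups, world$models)

  ## imaging
  imaging <- NULL
  if (run_imaging) {
    scenes <- render_nuclei(config)
    imaging <- do.call(rbind, lapply(seq_along(scenes), function(s) {
      sc <- scenes[[s]]
      masks <- segment_nuclei(sc$stack[, , , 1], sc$voxel_size)
      foci <- detect_foci(sc$stack[, , , 2], sc$voxel_size,
                          sigma = config$focus_sigma,
                          quality_min = config$focus_amp / 4)
      meas <- focus_periphery_distance(masks, foci, sc$voxel_size)
      if (nrow(meas)) meas$scene <- s
      meas
    }))
  }

  list(world = world,
       expression = list(counts = expr$counts, samples = expr$samples,
                         de_met2 = de_met2, de_double = de_double,
                         derepressed = derepressed),
       chic = list(ratio = ratio, domains = domains,
                   gene_marks = gene_marks),
       motifs = list(hits = hits, hit_counts = hit_counts,
                     genome_hits = genome_hits, enrichment = enrichment),
       accessibility = list(peak_de = peak_de, annotated = annotated,
                            intergenic = intergenic, acc_de = acc_de,
                            groups = groups),
       position = list(damid = damid, compare = position),
       imaging = imaging)
}
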