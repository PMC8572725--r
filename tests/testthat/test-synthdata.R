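test_that("world generation is deterministic and validates capacity", {
  cfg <- tiny_config()
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$genome, w2$genome)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$models, w2$models)
  expect_identical(w1$peaks, w2$peaks)
  expect_error(generate_world(tiny_config(chrom_length = 20000)),
               "do not fit")
})

test_that("truth table invariants hold", {
  w <- generate_world(tiny_config())
  tr <- w$truth
  expect_true(all(tr$derepression_fc[tr$class != "silenced_derepressible"]
                  == 1))
  expect_true(all(tr$derepression_fc[tr$class == "silenced_derepressible"]
                  > 1))
  expect_true(all(tr$group[tr$group %in% c("A", "B")] %in%
                    tr$group[tr$derepression_fc > 1]))
  expect_true(all(nzchar(
    tr$planted_motifs[tr$class == "silenced_derepressible"])))
  expect_true(all(tr$planted_motifs[tr$class != "silenced_derepressible"]
                  == ""))
  # domains cover every silenced gene span
  g <- w$models$genes
  sil <- tr$h3k9_domain
  spans <- data.frame(chrom = g$chrom[sil], start = g$span_start[sil],
                      end = g$span_end[sil])
  expect_equal(interval_jaccard(spans, w$domains) > 0, TRUE)
  cov <- k9me:::overlap_counts(spans, w$domains)
  expect_true(all(cov >= 1))
})

test_that("a world without derepressible genes has no planted motifs", {
  cfg <- tiny_config(n_derepressible = 0, n_background = 40)
  w <- generate_world(cfg)
  expect_null(w$planted_sites)
  expect_true(all(w$truth$planted_motifs == ""))
})

test_that("expression counts follow the configured means", {
  # Poisson limit: per-gene sample means within 3 SE of the baseline
  cfg <- tiny_config(seed = 3, dispersion = 0, derepression_fc = 1,
                     replicates = 10)
  w <- generate_world(cfg)
  e <- simulate_expression_counts(w)
  norm <- normalize_counts(e$counts)
  base <- w$truth$baseline_expression
  se <- sqrt(base / ncol(norm))
  frac_in <- mean(abs(rowMeans(norm) - base) <= 3 * se)
  expect_gte(frac_in, 0.95)

  # derepression_fc = 16 at baseline 20: mutant mean near 320
  cfg2 <- tiny_config(seed = 4, replicates = 6)
  w2 <- generate_world(cfg2)
  e2 <- simulate_expression_counts(w2)
  mut <- e2$samples$sample[e2$samples$genotype == "met-2"]
  planted <- w2$truth$class == "silenced_derepressible"
  lib_adj <- rowMeans(normalize_counts(e2$counts))
  m <- rowMeans(e2$counts[, mut])[planted]
  expect_lt(abs(mean(m) - 320) / 320, 0.15)

  # WT vs set-25 log2FC distribution centred at zero
  de <- de_test(e2$counts, e2$samples, c("set-25", "WT"))
  expect_lt(abs(mean(de$log2fc)), 0.1)
})

test_that("ChIC fragment rates follow the planted enrichment", {
  # r_in = r_out -> ratio about 1 everywhere
  cfg <- tiny_config(seed = 6, chic_ratio = 1)
  w <- generate_world(cfg)
  windows <- tile_genome(w$chrom_lengths, 500)
  ab <- simulate_chic_fragments(w, "H3K9me3", "WT")
  ctrl <- simulate_chic_fragments(w, "MNase", "WT")
  ratio <- control_normalize(count_fragments(ab, windows),
                             count_fragments(ctrl, windows))
  expect_lt(abs(mean(ratio$ratio) - 1), 0.05)
  expect_equal(nrow(call_domains(ratio)), 0)

  # deep sampling with one small domain: in-domain ratio near r_in/r_out
  cfg2 <- sim_config(seed = 7, n_chromosomes = 2, chrom_length = 300000,
                     n_muscle = 2, n_derepressible = 1,
                     n_silenced_stable = 0, n_background = 40,
                     chic_depth = 500000)
  w2 <- generate_world(cfg2)
  win2 <- tile_genome(w2$chrom_lengths, 500)
  ab2 <- simulate_chic_fragments(w2, "H3K9me3", "WT")
  ctrl2 <- simulate_chic_fragments(w2, "MNase", "WT")
  r2 <- control_normalize(count_fragments(ab2, win2),
                          count_fragments(ctrl2, win2))
  # interior domain windows (exclude boundary bleed)
  dom <- w2$domains
  core <- data.frame(chrom = dom$chrom, start = dom$start + 500,
                     end = dom$end - 500)
  inside <- k9me:::overlap_counts(r2, core) > 0
  expect_gte(sum(inside), 2)
  expect_lt(abs(mean(r2$ratio[inside]) - 8) / 8, 0.2)

  # double mutant: no H3K9me emission anywhere
  ab3 <- simulate_chic_fragments(w2, "H3K9me3", "met-2 set-25")
  r3 <- control_normalize(count_fragments(ab3, win2),
                          count_fragments(ctrl2, win2))
  inside_all <- k9me:::overlap_counts(r3, dom) > 0
  expect_lt(abs(mean(r3$ratio[inside_all]) - 1), 0.1)
})

test_that("accessibility counts implement the group and genotype rules", {
  cfg <- tiny_config(seed = 8)
  w <- generate_world(cfg)
  atac <- simulate_accessibility_and_damid(w)
  counts <- atac$peak_counts
  s <- atac$samples
  wt <- s$sample[s$genotype == "WT"]
  dm <- s$sample[s$genotype == "met-2 set-25"]
  a_peaks <- paste0("pk_", w$truth$gene_id[w$truth$group == "A"])
  bc_peaks <- paste0("pk_", w$truth$gene_id[w$truth$group %in% c("B", "C")])
  ratio_a <- rowMeans(counts[a_peaks, dm]) / rowMeans(counts[a_peaks, wt])
  ratio_bc <- rowMeans(counts[bc_peaks, dm]) / rowMeans(counts[bc_peaks, wt])
  expect_lt(abs(mean(ratio_a) - 1), 0.25)
  expect_gt(mean(ratio_bc), 5)
  # zero-depth config gives all-zero matrices
  cfg0 <- tiny_config(seed = 9, peak_baseline = 0, damid_baseline = 0)
  w0 <- generate_world(cfg0)
  atac0 <- simulate_accessibility_and_damid(w0)
  expect_true(all(atac0$peak_counts == 0))
  expect_true(all(atac0$damid$fusion == 0))
})

test_that("chic and accessibility jointly reproduce the H3K27ac pattern", {
  cfg <- tiny_config(seed = 10)
  w <- generate_world(cfg)
  windows <- tile_genome(w$chrom_lengths, 500)
  ctrl <- simulate_chic_fragments(w, "MNase", "met-2 set-25")
  ac <- simulate_chic_fragments(w, "H3K27ac", "met-2 set-25")
  gm <- gene_mark_enrichment(ac, ctrl, w$models)
  # H3K27ac appears in the double mutant at Group C (and B) promoters;
  # enrichment is over promoters, so compare promoter-window signal
  prom <- promoter_windows(w$models, 1000, 100, w$chrom_lengths)
  tr_c <- count_fragments(ac, windows)
  ctrl_c <- count_fragments(ctrl, windows)
  r <- control_normalize(tr_c, ctrl_c)
  grp <- w$truth$group[match(prom$gene_id, w$truth$gene_id)]
  in_c <- k9me:::overlap_counts(prom[grp == "C", ], r[r$ratio > 2, ]) > 0
  in_a <- k9me:::overlap_counts(prom[grp == "A", ], r[r$ratio > 2, ]) > 0
  expect_gte(mean(in_c), 0.8)
  expect_lte(mean(in_a), 0.1)
  # in WT, H3K27ac is absent even at Group C promoters
  ac_wt <- simulate_chic_fragments(w, "H3K27ac", "WT")
  r_wt <- control_normalize(count_fragments(ac_wt, windows), ctrl_c)
  in_c_wt <- k9me:::overlap_counts(prom[grp == "C", ],
                                   r_wt[r_wt$ratio > 2, ]) > 0
  expect_lte(mean(in_c_wt), 0.1)
})

test_that("rendered nuclei carry exact truth geometry", {
  cfg <- tiny_config(seed = 12)
  scenes <- render_nuclei(cfg, n_nuclei = 3, noise = FALSE)
  for (sc in scenes) {
    tin <- sc$truth[sc$truth$inside, ]
    # truth distance equals radius minus distance from the centre
    d <- sqrt((tin$x - sc$centre[1])^2 + (tin$y - sc$centre[2])^2 +
                (tin$z - sc$centre[3])^2)
    expect_equal(tin$distance, sc$radius - d)
    expect_true(all(tin$distance > 0 & tin$distance <= sc$radius))
    # without noise the voxel nearest each focus is a local maximum
    vx <- sc$voxel_size
    for (i in seq_len(nrow(tin))) {
      iv <- pmax(1, pmin(dim(sc$stack)[1:3],
                         round(c(tin$x[i], tin$y[i], tin$z[i]) / vx + 0.5)))
      ch <- sc$stack[, , , 2]
      nb <- ch[max(1, iv[1] - 1):min(dim(ch)[1], iv[1] + 1),
               max(1, iv[2] - 1):min(dim(ch)[2], iv[2] + 1),
               max(1, iv[3] - 1):min(dim(ch)[3], iv[3] + 1)]
      expect_equal(ch[iv[1], iv[2], iv[3]], max(nb))
    }
    # outside foci have negative truth distance
    if (any(!sc$truth$inside))
      expect_true(all(sc$truth$distance[!sc$truth$inside] < 0))
  }
})

test_that("nucleus stacks round-trip through TIFF", {
  cfg <- tiny_config(seed = 13)
  sc <- render_nuclei(cfg, n_nuclei = 1)[[1]]
  f <- withr::local_tempfile(fileext = ".tif")
  write_nucleus_tiff(sc, f)
  back <- read_nucleus_tiff(f, n_channels = 2)
  expect_equal(dim(back), dim(sc$stack))
  expect_equal(back, round(sc$stack), tolerance = 1e-6, ignore_attr = TRUE)
})
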