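test_that("genome tiling covers chromosomes without gaps or overlap", {
  w <- tile_genome(c(c1 = 1250), 500)
  expect_equal(w$start, c(0, 500, 1000))
  expect_equal(w$end, c(500, 1000, 1250))
  expect_equal(nrow(tile_genome(c(c1 = 500), 500)), 1)
  w1 <- tile_genome(c(c1 = 40), 1)
  expect_equal(nrow(w1), 40)
  # tiling property over random lengths
  set.seed(4)
  for (len in sample(500:5000, 5)) {
    t <- tile_genome(c(c = len), 500)
    expect_equal(t$start[-1], t$end[-nrow(t)])
    expect_equal(t$end[nrow(t)], len)
  }
})

test_that("fragment counting assigns by any-overlap", {
  windows <- tile_genome(c(c1 = 1500), 500)
  tr <- count_fragments(data.frame(chrom = "c1", start = 100, end = 150),
                        windows)
  expect_equal(tr$count, c(1, 0, 0))
  tr2 <- count_fragments(data.frame(chrom = "c1", start = 490, end = 510),
                         windows)
  expect_equal(tr2$count, c(1, 1, 0))
  tr0 <- count_fragments(data.frame(chrom = character(), start = integer(),
                                    end = integer()), windows)
  expect_equal(tr0$count, c(0, 0, 0))
  expect_message(
    trx <- count_fragments(data.frame(chrom = "cZ", start = 0, end = 10),
                           windows), "skipped")
  expect_equal(sum(trx$count), 0)
})

test_that("window counts conserve boundary-free fragments", {
  windows <- tile_genome(c(c1 = 10000), 500)
  set.seed(8)
  # fragments strictly inside windows
  win <- sample(0:18, 200, TRUE) * 500
  start <- win + sample(0:300, 200, TRUE)
  frags <- data.frame(chrom = "c1", start = start, end = start + 100)
  tr <- count_fragments(frags, windows)
  expect_equal(sum(tr$count), nrow(frags))
  # boundary-spanning fragments count once per overlapped window
  frags2 <- data.frame(chrom = "c1", start = 450, end = 1600)
  expect_equal(sum(count_fragments(frags2, windows)$count), 4)
})

test_that("control normalization applies scaling and the pseudo-count", {
  windows <- tile_genome(c(c1 = 2000), 500)
  ab <- windows; ab$count <- c(24, 8, 0, 8)
  ctrl <- windows; ctrl$count <- c(8, 8, 0, 24)
  r <- control_normalize(ab, ctrl)
  # totals already equal: no rescaling; (24+8)/(8+8) = 2
  expect_equal(r$ratio, c(2, 1, 1, 0.5))
  # ab == control everywhere -> all ratios 1
  expect_equal(control_normalize(ctrl, ctrl)$ratio, rep(1, 4))
  # tiling mismatch rejected
  expect_error(control_normalize(ab, ctrl[1:3, ]), "tilings differ")
})

test_that("domain calling equals the run-length oracle on random tracks", {
  windows <- tile_genome(c(c1 = 2000), 500)
  tr <- windows; tr$ratio <- c(3, 3, 1, 3)
  d <- call_domains(tr, fc_min = 2, min_run = 2)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end), c(0, 1000))
  expect_equal(d$mean_enrichment, 3)
  tr$ratio <- rep(1, 4)
  expect_equal(nrow(call_domains(tr)), 0)
  tr$ratio <- rep(3, 4)
  d1 <- call_domains(tr)
  expect_equal(c(d1$start, d1$end), c(0, 2000))

  set.seed(13)
  for (trial in 1:100) {
    n <- sample(5:60, 1)
    win <- tile_genome(setNames(n * 500, "c"), 500)
    win$ratio <- sample(c(0.5, 1, 2.5, 4), n, TRUE)
    min_run <- sample(1:3, 1)
    got <- call_domains(win, fc_min = 2, min_run = min_run)
    want <- oracle_runs(win$ratio, 2, min_run)
    expect_equal(nrow(got), NROW(want))
    if (NROW(want)) {
      expect_equal(got$start, unname((want[, "from"] - 1) * 500))
      expect_equal(got$end, unname(pmin(want[, "to"] * 500, n * 500)))
    }
  }
})

test_that("planted domains are recovered and genes marked correctly", {
  cfg <- tiny_config()
  w <- generate_world(cfg)
  windows <- tile_genome(w$chrom_lengths, 500)
  ab <- simulate_chic_fragments(w, "H3K9me3", "WT")
  ctrl <- simulate_chic_fragments(w, "MNase", "WT")
  ratio <- control_normalize(count_fragments(ab, windows),
                             count_fragments(ctrl, windows))
  doms <- call_domains(ratio, mark = "H3K9me3")
  expect_gte(interval_jaccard(doms, w$domains), 0.8)
  gm <- gene_mark_enrichment(ab, ctrl, w$models)
  expect_gte(mean(gm$marked[w$truth$h3k9_domain]), 0.9)
  expect_lte(mean(gm$marked[!w$truth$h3k9_domain]), 0.05)
})

test_that("set-25 keeps H3K9me2 but loses H3K9me3; double mutant loses both", {
  cfg <- tiny_config()
  w <- generate_world(cfg)
  windows <- tile_genome(w$chrom_lengths, 500)
  ctrl <- simulate_chic_fragments(w, "MNase", "set-25")
  for (mark in c("H3K9me2", "H3K9me3")) {
    ab <- simulate_chic_fragments(w, mark, "set-25")
    doms <- call_domains(control_normalize(count_fragments(ab, windows),
                                           count_fragments(ctrl, windows)))
    if (mark == "H3K9me2") {
      expect_gte(interval_jaccard(doms, w$domains), 0.8)
    } else {
      expect_equal(nrow(doms), 0)
    }
  }
  ab_dm <- simulate_chic_fragments(w, "H3K9me3", "met-2 set-25")
  doms_dm <- call_domains(control_normalize(
    count_fragments(ab_dm, windows), count_fragments(ctrl, windows)))
  expect_equal(nrow(doms_dm), 0)
})

test_that("arm/centre annotation uses the printed border coordinates", {
  expect_equal(arm_centre_annotate("chr1", 1e6), "arm")
  expect_equal(arm_centre_annotate("chr1", 5e6), "centre")
  expect_equal(arm_centre_annotate("chr1", 12e6), "arm")
  # exact borders are inclusive for the centre
  expect_equal(arm_centre_annotate("chrI", 3745632), "centre")
  expect_equal(arm_centre_annotate("I", 10809938), "centre")
  # chromosome X: single border, left-arm/centre split
  expect_equal(arm_centre_annotate("chrX", 1e6), "arm")
  expect_equal(arm_centre_annotate("chrX", 4.2e7), "centre")
  expect_error(arm_centre_annotate("chrZ", 100), "border")
  # custom borders
  b <- data.frame(chrom = "s1", left = 100, right = 200)
  expect_equal(arm_centre_annotate(c("s1", "s1"), c(50, 150), b),
               c("arm", "centre"))
})
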