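make_pwm <- function(weights, id = "m") {
  rownames(weights) <- c("A", "C", "G", "T")
  pwm(id = id, tf_names = id, weights = weights)
}

test_that("promoter windows mirror across strands and clip at bounds", {
  ex <- data.frame(gene_id = c("p", "m", "edge"), chrom = "c1",
                   start = c(10000, 9000, 1000), end = c(11000, 10000, 1800),
                   strand = c("+", "-", "+"))
  models <- gene_models(ex)
  pr <- promoter_windows(models, 1500, 500)
  expect_equal(unlist(pr[pr$gene_id == "p", c("start", "end")],
                      use.names = FALSE), c(8500, 10500))
  expect_equal(unlist(pr[pr$gene_id == "m", c("start", "end")],
                      use.names = FALSE), c(9500, 11500))
  expect_equal(unlist(pr[pr$gene_id == "edge", c("start", "end")],
                      use.names = FALSE), c(0, 1500))
})

test_that("PWM scanning scores both strands in forward coordinates", {
  w <- matrix(0, 4, 2); w[1, 1] <- 5; w[2, 2] <- 5   # consensus AC
  p <- make_pwm(w)
  hits <- scan_pwm(c(c1 = "AC"), p, min_score = 10)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, 10)
  expect_equal(hits$start, 0)
  hits_rc <- scan_pwm(c(c1 = "GT"), p, min_score = 10)  # revcomp of AC
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$score, 10)
})

test_that("the max-obtainable-score branch requires a perfect match", {
  w <- matrix(0, 4, 2); w[1, 1] <- 3; w[2, 2] <- 3   # max score 6 < 10
  p <- make_pwm(w)
  hits <- scan_pwm(c(c1 = "ACAAAC"), p, min_score = 10)
  expect_equal(sort(hits$start[hits$strand == "+"]), c(0, 4))
  expect_true(all(hits$score == 6))
  # windows containing N never hit
  hits_n <- scan_pwm(c(c1 = "ANAC"), p, min_score = 10)
  expect_equal(hits_n$start[hits_n$strand == "+"], 2)
})

test_that("scanning equals the exhaustive oracle and is strand symmetric", {
  set.seed(21)
  for (trial in 1:5) {
    L <- sample(3:6, 1)
    w <- matrix(runif(4 * L, 0, 4), 4, L)
    p <- make_pwm(w, sprintf("r%d", trial))
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 500, TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    thr <- sample(c(4, 10), 1)
    got <- scan_pwm(c(c1 = seq), p, min_score = thr)
    want <- oracle_scan(seq, p$weights, thr)
    ord_g <- order(got$start, got$strand)
    ord_w <- order(want$start, want$strand)
    expect_equal(got$start[ord_g], want$start[ord_w])
    expect_equal(got$strand[ord_g], want$strand[ord_w])
    expect_equal(got$score[ord_g], want$score[ord_w], tolerance = 1e-9)
    # strand symmetry: scanning the reverse-complemented genome mirrors hits
    rc <- k9me:::revcomp_string(gsub("N", "A", seq))
    seq2 <- gsub("N", "A", seq)
    got2 <- scan_pwm(c(c1 = seq2), p, min_score = thr)
    got_rc <- scan_pwm(c(c1 = rc), p, min_score = thr)
    expect_equal(nrow(got2), nrow(got_rc))
    mirrored <- sort(nchar(seq2) - L - got_rc$start)
    expect_equal(sort(got2$start), mirrored)
  }
})

test_that("hit counting is per-region with multi-promoter hits counted twice", {
  hits <- data.frame(chrom = "c1", start = c(100, 950), end = c(110, 960),
                     strand = "+", score = 12, motif_id = "m1")
  regions <- data.frame(chrom = "c1", start = c(0, 900), end = c(1000, 2000),
                        gene_id = c("gA", "gB"))
  m <- region_hit_counts(hits, regions)
  expect_equal(m["gA", "m1"], 2)   # second hit overlaps both regions
  expect_equal(m["gB", "m1"], 1)
  m0 <- region_hit_counts(hits[0, ], regions)
  expect_true(all(m0 == 0) || ncol(m0) == 0)
})

test_that("enrichment statistic behaves at its fixed points", {
  universe <- paste0("g", 1:100)
  counts <- matrix(rpois(200, 1), 100, 2,
                   dimnames = list(universe, c("m1", "m2")))
  gh <- c(m1 = 600, m2 = 100)
  # set = universe -> zero enrichment everywhere
  e <- motif_enrichment(counts, universe, gh)
  expect_equal(e$log2_enrichment, c(0, 0))
  # direct ratio arithmetic with large counts
  counts2 <- matrix(0L, 100, 1, dimnames = list(universe, "m1"))
  counts2[1:10, 1] <- 20L   # rate_set = 20, rate_all = 2
  e2 <- motif_enrichment(counts2, universe[1:10], c(m1 = 600))
  expect_equal(e2$log2_enrichment, log2((20 + 0.01) / (2 + 0.01)))
  expect_equal(e2$log2_abundance, log2(601))
  expect_error(motif_enrichment(counts, character(0), gh), "empty")
})

test_that("adding a set hit never decreases enrichment", {
  set.seed(31)
  universe <- paste0("g", 1:50)
  counts <- matrix(rpois(50, 2), 50, 1, dimnames = list(universe, "m1"))
  set <- universe[1:10]
  base <- motif_enrichment(counts, set, c(m1 = 500))$log2_enrichment
  for (i in 1:5) {
    counts[sample(1:10, 1), 1] <- counts[sample(1:10, 1), 1] + 1L
    now <- motif_enrichment(counts, set, c(m1 = 500))$log2_enrichment
    expect_gte(now, base - 1e-12)
    base <- now
  }
})

test_that("planted motifs are recovered on the synthetic world", {
  w <- generate_world(tiny_config())
  hits <- scan_pwm_set(w$genome, w$pwms)
  prom <- promoter_windows(w$models, 1500, 500, w$chrom_lengths)
  hc <- promoter_hit_counts(hits, prom)
  gh <- table(factor(hits$motif_id, levels = names(w$pwms)))
  gh <- setNames(as.numeric(gh), names(gh))
  derep <- w$truth$gene_id[w$truth$class == "silenced_derepressible"]
  # the tiny world has fewer genomic hits, so lower the abundance gate;
  # the default-threshold recovery runs on the full-size world elsewhere
  enr <- motif_enrichment(hc, derep, gh, abund_min = 6,
                          tf_map = lapply(w$pwms, `[[`, "tf_names"))
  planted <- vapply(w$pwms, `[[`, logical(1), "planted")
  expect_true(all(enr$enriched[planted[enr$motif_id]]))
  expect_false(any(enr$enriched[!planted[enr$motif_id]]))
  expect_true(all(enr$log2_enrichment[planted[enr$motif_id]] > 0.5))
  # planted consensus is present verbatim at each recorded site
  for (i in sample(nrow(w$planted_sites), 10)) {
    s <- w$planted_sites[i, ]
    sub <- substr(w$genome[[s$chrom]], s$start + 1,
                  s$start + nchar(w$pwms[[s$motif_id]]$consensus))
    want <- if (s$strand == "+") w$pwms[[s$motif_id]]$consensus
            else k9me:::revcomp_string(w$pwms[[s$motif_id]]$consensus)
    expect_equal(sub, want)
  }
})
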