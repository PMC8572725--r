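# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the package's own code paths.

# Two-sided conditional binomial p-value by direct pmf summation with
# choose() arithmetic.
oracle_binom_p <- function(a, b, prob) {
  t <- a + b
  if (t == 0) return(1)
  k <- 0:t
  pmf <- choose(t, k) * prob^k * (1 - prob)^(t - k)
  min(1, sum(pmf[pmf <= pmf[a + 1] * (1 + 1e-7)]))
}

# Exhaustive per-position, per-strand PWM scan on one sequence string.
oracle_scan <- function(seq, weights, min_score) {
  thr <- min(min_score, sum(apply(weights, 2, max)))
  L <- ncol(weights)
  chars <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  for (p in seq_len(length(chars) - L + 1)) {
    win <- chars[p:(p + L - 1)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    base_of <- c(A = 1, C = 2, G = 3, T = 4)
    s_fwd <- sum(weights[cbind(base_of[win], seq_len(L))])
    rc <- rev(unname(comp[win]))
    s_rev <- sum(weights[cbind(base_of[rc], seq_len(L))])
    if (s_fwd >= thr)
      hits[[length(hits) + 1]] <- data.frame(start = p - 1, strand = "+",
                                             score = s_fwd)
    if (s_rev >= thr)
      hits[[length(hits) + 1]] <- data.frame(start = p - 1, strand = "-",
                                             score = s_rev)
  }
  if (!length(hits)) return(data.frame(start = integer(), strand = character(),
                                       score = numeric()))
  do.call(rbind, hits)
}

# Run-length domain caller on a single chromosome's ratio vector; returns
# window index ranges (1-based, inclusive).
oracle_runs <- function(values, fc_min, min_run) {
  above <- values > fc_min
  out <- NULL
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run)
        out <- rbind(out, c(from = i, to = j))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# Brute-force anisotropic EDT: per foreground voxel, min distance over all
# background voxel centres.
oracle_edt <- function(mask, vx) {
  out <- array(0, dim(mask))
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  if (!nrow(bg)) { out[mask] <- Inf; return(out) }
  for (i in seq_len(nrow(fg))) {
    d2 <- ((fg[i, 1] - bg[, 1]) * vx[1])^2 +
      ((fg[i, 2] - bg[, 2]) * vx[2])^2 +
      ((fg[i, 3] - bg[, 3]) * vx[3])^2
    out[fg[i, 1], fg[i, 2], fg[i, 3]] <- sqrt(min(d2))
  }
  out
}

# Gap distance between two 0-based half-open intervals on one chromosome
# (0 when overlapping or touching).
oracle_gap <- function(s1, e1, s2, e2) max(0, s2 - e1, s1 - e2)

# All-pairs brute-force intergenic filter.
oracle_intergenic <- function(peaks, promoters, repeats, min_dist) {
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    same_p <- promoters[promoters$chrom == peaks$chrom[i], , drop = FALSE]
    dmin <- if (nrow(same_p)) min(mapply(oracle_gap, peaks$start[i],
                                         peaks$end[i], same_p$start,
                                         same_p$end)) else Inf
    same_r <- repeats[repeats$chrom == peaks$chrom[i], , drop = FALSE]
    rep_ov <- nrow(same_r) && any(pmin(peaks$end[i], same_r$end) >
                                    pmax(peaks$start[i], same_r$start))
    keep[i] <- (dmin > min_dist) && !rep_ov
  }
  keep
}

# Small world used by several unit tests (fast but fully featured).
tiny_config <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chromosomes = 2, chrom_length = 150000,
         n_muscle = 10, n_derepressible = 10, n_silenced_stable = 10,
         n_background = 30, chic_depth = 30000,
         n_repeats_per_chrom = 10, n_intergenic_peaks = 8, n_nuclei = 2),
    list(...))
  do.call(sim_config, args)
}
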