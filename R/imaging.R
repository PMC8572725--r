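# 3D image primitives: separable Gaussian smoothing, Otsu thresholding,
# seeded watershed segmentation, Laplacian-of-Gaussian focus detection and
# an anisotropic Euclidean distance transform (Felzenszwalb's separable
# lower-envelope algorithm). All operate on plain 3D arrays indexed
# [x, y, z]; physical units enter through the voxel-size vector.

# Centered 1D convolution with replicate padding (kernel length odd).
conv1d_replicate <- function(v, k) {
  h <- (length(k) - 1L) / 2L
  n <- length(v)
  padded <- c(rep(v[1], h), v, rep(v[n], h))
  out <- stats::filter(padded, rev(k), sides = 2)
  as.numeric(out[(h + 1L):(h + n)])
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# Apply a 1D function along one dimension of a 3D array.
apply_along <- function(img, dim, fun) {
  d <- dim(img)
  if (dim == 1) {
    out <- apply(img, c(2, 3), fun)
  } else if (dim == 2) {
    out <- aperm(apply(img, c(1, 3), fun), c(2, 1, 3))
  } else {
    out <- aperm(apply(img, c(1, 2), fun), c(2, 3, 1))
  }
  array(out, d)
}

#' Separable 3D Gaussian smoothing
#'
#' @param img 3D array.
#' @param sigma Standard deviation(s) in voxels; length 1 or 3. Pass
#'   physical sigma divided by voxel size for anisotropic stacks.
#' @return Smoothed array.
#' @export
gaussian_smooth3d <- function(img, sigma) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  for (d in 1:3) {
    if (sigma[d] > 0) {
      k <- gaussian_kernel(sigma[d])
      img <- apply_along(img, d, function(v) conv1d_replicate(v, k))
    }
  }
  img
}

#' Otsu threshold
#'
#' Maximizes between-class variance on a 256-bin histogram of the values.
#'
#' @param x Numeric vector or array.
#' @param n_bins Histogram resolution.
#' @return Threshold value; `NA` for a constant input.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # well-separated modes tie across the whole gap; take the plateau middle
  top <- which(sigma_b >= max(sigma_b) - 1e-10 * abs(max(sigma_b)))
  mids[top[ceiling(length(top) / 2)]]
}

# 26-connected neighbor offsets in 3D.
neighbor_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

#' Local maxima of a 3D image
#'
#' Voxels that are at least as large as all 26 neighbors (edge voxels
#' compare against in-bounds neighbors only) and strictly above
#' `min_value`.
#'
#' @param img 3D array.
#' @param min_value Intensity floor.
#' @param mask Optional logical array restricting candidates.
#' @return Integer matrix of voxel indices (columns x, y, z).
#' @export
local_maxima3d <- function(img, min_value = -Inf, mask = NULL) {
  which(local_max_mask3d(img, min_value, mask), arr.ind = TRUE)
}

local_max_mask3d <- function(img, min_value = -Inf, mask = NULL) {
  d <- dim(img)
  ok <- img > min_value
  if (!is.null(mask)) ok <- ok & mask
  offs <- neighbor_offsets_26()
  for (k in seq_len(nrow(offs))) {
    off <- as.integer(offs[k, ])
    sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
    qx <- sx + off[1]; qy <- sy + off[2]; qz <- sz + off[3]
    vx <- qx >= 1 & qx <= d[1]; vy <- qy >= 1 & qy <= d[2]
    vz <- qz >= 1 & qz <= d[3]
    cmp <- array(FALSE, d)
    cmp[sx[vx], sy[vy], sz[vz]] <-
      img[sx[vx], sy[vy], sz[vz]] < img[qx[vx], qy[vy], qz[vz]]
    ok <- ok & !cmp
  }
  ok
}

# 26-connected component labelling of a logical array (BFS over a vector
# stack; sizes here are small).
label_components3d <- function(mask) {
  d <- dim(mask)
  offs <- neighbor_offsets_26()
  labels <- array(0L, d)
  nxt <- 0L
  todo <- which(mask)
  for (v in todo) {
    if (labels[v] != 0L) next
    nxt <- nxt + 1L
    queue <- v
    labels[v] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      v0 <- cur - 1L
      x <- v0 %% d[1]; rest <- v0 %/% d[1]
      y <- rest %% d[2]; z <- rest %/% d[2]
      for (k in seq_len(nrow(offs))) {
        nx <- x + offs[k, 1]; ny <- y + offs[k, 2]; nz <- z + offs[k, 3]
        if (nx < 0 || nx >= d[1] || ny < 0 || ny >= d[2] ||
            nz < 0 || nz >= d[3]) next
        w <- cur + offs[k, 1] + offs[k, 2] * d[1] + offs[k, 3] * d[1] * d[2]
        if (mask[w] && labels[w] == 0L) {
          labels[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

#' Seeded 3D watershed segmentation of nuclei
#'
#' The channel is Gaussian-smoothed, thresholded (Otsu unless a threshold
#' is given), and seeds are taken as local maxima of the smoothed image
#' inside the foreground. Labels then grow from the seeds by priority
#' flooding: foreground voxels are claimed in order of decreasing smoothed
#' intensity from an already-labelled 26-neighborhood (a bucket-queue
#' watershed on inverted intensity). Labels below `min_volume` voxels are
#' dropped and the rest relabelled consecutively.
#'
#' @param img 3D array (nuclear envelope/volume channel).
#' @param voxel_size Physical voxel size, length 3.
#' @param smooth_sigma Smoothing sigma in physical units (default 0.3).
#' @param threshold Foreground threshold on the smoothed image; `NULL` for
#'   Otsu.
#' @param min_volume Minimum label volume in voxels.
#' @param seed_min_dist Minimum physical distance between seeds; maxima
#'   closer than this to a stronger seed are suppressed (default
#'   `4 * smooth_sigma`). Plateau maxima (flat tops) are first merged into
#'   one seed per connected component.
#' @return Integer 3D array of labels (0 = background).
#' @export
segment_nuclei <- function(img, voxel_size = c(1, 1, 1), smooth_sigma = 0.3,
                           threshold = NULL, min_volume = 27,
                           seed_min_dist = 4 * smooth_sigma) {
  stopifnot(length(dim(img)) == 3, all(voxel_size > 0))
  sm <- gaussian_smooth3d(img, smooth_sigma / voxel_size)
  if (is.null(threshold)) threshold <- otsu_threshold(sm)
  labels <- array(0L, dim(img))
  if (is.na(threshold)) return(labels)
  fg <- sm > threshold
  if (!any(fg)) return(labels)
  mx <- local_max_mask3d(sm, min_value = threshold, mask = fg)
  comp <- label_components3d(mx)
  n_comp <- max(comp)
  if (n_comp == 0) return(labels)
  # one candidate seed per plateau component: its centroid voxel
  cand <- do.call(rbind, lapply(seq_len(n_comp), function(l) {
    vox <- which(comp == l, arr.ind = TRUE)
    ctr <- colMeans(vox)
    near <- which.min(colSums((t(vox) - ctr)^2))
    unname(c(vox[near, ], max(sm[vox])))
  }))
  cand <- cand[order(cand[, 4], decreasing = TRUE), , drop = FALSE]
  # greedy non-maximum suppression in physical units
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(keep)) { keep <- i; next }
    dists <- sqrt(colSums((t(cand[keep, 1:3, drop = FALSE]) -
                             cand[i, 1:3])^2 * voxel_size^2))
    if (all(dists > seed_min_dist)) keep <- c(keep, i)
  }
  seeds <- cand[keep, 1:3, drop = FALSE]
  labels[seeds] <- seq_len(nrow(seeds))
  labels <- flood_labels(sm, fg, labels)
  relabel_min_volume(labels, min_volume)
}

# Priority flood: grow labels over fg voxels in order of decreasing
# intensity, claiming the label of the first labelled 26-neighbor.
flood_labels <- function(intensity, fg, labels) {
  d <- dim(intensity)
  n <- prod(d)
  offs <- neighbor_offsets_26()
  lin_off <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  todo <- which(fg & labels == 0L)
  if (!length(todo)) return(labels)
  ord <- todo[order(intensity[todo], decreasing = TRUE)]
  # iterate until no voxel changes; the decreasing-intensity sweep makes
  # almost all assignments in the first pass
  repeat {
    changed <- FALSE
    remaining <- integer(0)
    for (v in ord) {
      if (labels[v] != 0L) next
      # in-bounds neighbor check via x/y/z coordinates
      v0 <- v - 1L
      x <- v0 %% d[1]; rest <- v0 %/% d[1]
      y <- rest %% d[2]; z <- rest %/% d[2]
      lab <- 0L
      for (k in seq_len(nrow(offs))) {
        nx <- x + offs[k, 1]; ny <- y + offs[k, 2]; nz <- z + offs[k, 3]
        if (nx < 0 || nx >= d[1] || ny < 0 || ny >= d[2] ||
            nz < 0 || nz >= d[3]) next
        l <- labels[v + lin_off[k]]
        if (l != 0L) { lab <- l; break }
      }
      if (lab != 0L) {
        labels[v] <- lab
        changed <- TRUE
      } else {
        remaining <- c(remaining, v)
      }
    }
    if (!changed || !length(remaining)) break
    ord <- remaining
  }
  labels
}

relabel_min_volume <- function(labels, min_volume) {
  if (!any(labels > 0L)) return(labels)
  tab <- table(labels[labels > 0L])
  keep <- as.integer(names(tab)[tab >= min_volume])
  map <- integer(max(labels))
  map[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- map[labels[pos]]
  labels
}

#' Laplacian-of-Gaussian focus detection
#'
#' Smooths the channel with an (anisotropy-aware) Gaussian of physical
#' sigma, applies the scale-normalized negative Laplacian (second central
#' differences weighted by physical spacing), and reports local maxima of
#' the response above `quality_min`. Centres are the maximal voxels (no
#' subvoxel fit).
#'
#' @param img 3D array (focus channel).
#' @param voxel_size Physical voxel size, length 3.
#' @param sigma Expected focus sigma in physical units.
#' @param quality_min Response floor for a detection.
#' @return `data.frame` with voxel indices (`vx`, `vy`, `vz`), physical
#'   centre coordinates (`x`, `y`, `z`, voxel-centre convention), `quality`
#'   (LoG response), `intensity` (raw voxel value) and `diameter`
#'   (`2 * sqrt(3) * sigma`).
#' @export
detect_foci <- function(img, voxel_size = c(1, 1, 1), sigma,
                        quality_min = 0) {
  stopifnot(length(dim(img)) == 3, all(voxel_size > 0), sigma > 0)
  sm <- gaussian_smooth3d(img, sigma / voxel_size)
  lap <- array(0, dim(img))
  for (d in 1:3) {
    second <- apply_along(sm, d, function(v) {
      n <- length(v)
      vp <- c(v[1], v[-n]); vn <- c(v[-1], v[n])
      vp + vn - 2 * v
    })
    lap <- lap + second / voxel_size[d]^2
  }
  response <- -sigma^2 * lap
  mx <- local_maxima3d(response, min_value = quality_min)
  if (!nrow(mx))
    return(data.frame(vx = integer(), vy = integer(), vz = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      quality = numeric(), intensity = numeric(),
                      diameter = numeric()))
  data.frame(vx = mx[, 1], vy = mx[, 2], vz = mx[, 3],
             x = (mx[, 1] - 0.5) * voxel_size[1],
             y = (mx[, 2] - 0.5) * voxel_size[2],
             z = (mx[, 3] - 0.5) * voxel_size[3],
             quality = response[mx], intensity = img[mx],
             diameter = 2 * sqrt(3) * sigma,
             stringsAsFactors = FALSE)
}

# 1D squared-distance transform (lower envelope of parabolas), spacing w.
# Inputs must be finite; callers use a large sentinel instead of Inf.
dt1d <- function(f, w = 1) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  w2 <- w * w
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q * w2) - (f[v[k]] + v[k] * v[k] * w2)) /
        (2 * w * (q - v[k]))
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q * w) k <- k + 1L
    d[q] <- (q - v[k])^2 * w2 + f[v[k]]
  }
  d
}

#' Anisotropic 3D Euclidean distance transform
#'
#' For each foreground voxel of a binary mask, the Euclidean distance (in
#' physical units, honouring anisotropic voxel spacing) to the nearest
#' background voxel centre. Background voxels get 0; a mask with no
#' background returns `Inf` everywhere.
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param voxel_size Physical voxel size, length 3.
#' @return Numeric 3D array of distances.
#' @export
distance_transform3d <- function(mask, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3, all(voxel_size > 0))
  dims <- dim(mask)
  big <- 4 * sum((dims * voxel_size)^2) + 1   # exceeds any true distance^2
  f <- array(ifelse(mask != 0, big, 0), dims)
  for (d in 1:3)
    f <- apply_along(f, d, function(v) dt1d(v, voxel_size[d]))
  out <- sqrt(f)
  out[f >= big] <- Inf
  out
}

#' Measure focus distances to the nuclear periphery
#'
#' Computes the Euclidean distance transform of the union nucleus mask and
#' reads its value at each focus voxel. Foci falling outside every nucleus
#' are flagged `excluded` (and get `NA` distance); all others report the
#' label of their nucleus and the physical distance to the mask boundary.
#'
#' @param masks Integer label array from [segment_nuclei()].
#' @param foci Focus table from [detect_foci()] (needs `vx`, `vy`, `vz`).
#' @param voxel_size Physical voxel size, length 3.
#' @return `foci` with `nucleus`, `distance` and `excluded` columns.
#' @export
focus_periphery_distance <- function(masks, foci, voxel_size = c(1, 1, 1)) {
  edt <- distance_transform3d(masks > 0L, voxel_size)
  idx <- cbind(foci$vx, foci$vy, foci$vz)
  lab <- masks[idx]
  foci$nucleus <- ifelse(lab > 0L, lab, NA_integer_)
  foci$distance <- ifelse(lab > 0L, edt[idx], NA_real_)
  foci$excluded <- lab == 0L
  foci
}
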