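# Renders 3D two-channel nucleus scenes with planted foci and exact truth
# distances, plus plain TIFF round-trip helpers.

#' Render synthetic nucleus stacks
#'
#' Each scene is one nucleus: channel 1 is the nuclear envelope/volume
#' signal (a filled sphere of physical radius `nucleus_radius`), channel 2
#' holds Gaussian foci at subvoxel centres drawn uniformly inside the
#' nucleus (with probability `frac_outside`, one extra focus is placed
#' outside it). Poisson shot noise plus Gaussian read noise of standard
#' deviation `focus_amp / snr` is added. The truth table records each
#' focus's exact Euclidean distance to the sphere boundary
#' (`radius - |centre - focus|`, physical units; negative outside).
#'
#' @param config A [sim_config()]; the imaging fields are used.
#' @param n_nuclei Number of scenes (default `config$n_nuclei`).
#' @param noise Add Poisson shot noise and Gaussian read noise (default
#'   TRUE); with FALSE the stacks hold the exact model intensities.
#' @return List of scenes, each with `stack` (4D array x,y,z,channel),
#'   `voxel_size`, `radius`, `centre`, and `truth`
#'   (`focus`, `x`, `y`, `z`, `inside`, `distance`).
#' @export
render_nuclei <- function(config, n_nuclei = config$n_nuclei,
                          noise = TRUE) {
  set.seed(stream_seed(config$seed, "nuclei"))
  d <- config$img_dim
  vx <- config$voxel_size
  R <- config$nucleus_radius
  if (R < 3 * min(vx)) stop("nucleus radius below 3 voxels")
  fov <- d * vx
  if (any(2 * R >= fov)) stop("nucleus does not fit in the image")
  noise_sd <- config$focus_amp / config$snr
  # voxel-centre physical coordinate grids
  cx <- (seq_len(d[1]) - 0.5) * vx[1]
  cy <- (seq_len(d[2]) - 0.5) * vx[2]
  cz <- (seq_len(d[3]) - 0.5) * vx[3]
  lapply(seq_len(n_nuclei), function(s) {
    centre <- fov / 2 + runif(3, -1, 1) * vx
    dist2 <- outer(outer((cx - centre[1])^2, (cy - centre[2])^2, `+`),
                   (cz - centre[3])^2, `+`)
    env <- config$envelope_amp * (dist2 <= R^2)
    n_in <- config$foci_per_nucleus
    extra <- runif(1) < config$frac_outside
    # uniform in the sphere (radius margin keeps foci clearly internal)
    r_max <- R - 2 * max(vx)
    u <- runif(n_in)^(1 / 3) * r_max
    theta <- runif(n_in, 0, 2 * pi)
    cphi <- runif(n_in, -1, 1)
    pts <- cbind(u * sqrt(1 - cphi^2) * cos(theta),
                 u * sqrt(1 - cphi^2) * sin(theta),
                 u * cphi)
    pts <- sweep(pts, 2, centre, `+`)
    if (extra) {
      dir <- c(1, 0, 0)
      out_pt <- centre + dir * min(R + 3 * max(vx), fov[1] / 2 - vx[1])
      pts <- rbind(pts, out_pt)
    }
    foci <- array(0, d)
    for (i in seq_len(nrow(pts))) {
      gx <- exp(-(cx - pts[i, 1])^2 / (2 * config$focus_sigma^2))
      gy <- exp(-(cy - pts[i, 2])^2 / (2 * config$focus_sigma^2))
      gz <- exp(-(cz - pts[i, 3])^2 / (2 * config$focus_sigma^2))
      foci <- foci + config$focus_amp * outer(outer(gx, gy), gz)
    }
    stack <- array(0, c(d, 2))
    if (noise) {
      stack[, , , 1] <- rpois(length(env), env) +
        rnorm(length(env), 0, noise_sd)
      stack[, , , 2] <- rpois(length(foci), foci) +
        rnorm(length(foci), 0, noise_sd)
      stack[stack < 0] <- 0
    } else {
      stack[, , , 1] <- env
      stack[, , , 2] <- foci
    }
    truth <- data.frame(
      focus = seq_len(nrow(pts)),
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      inside = c(rep(TRUE, n_in), if (extra) FALSE),
      distance = R - sqrt(rowSums(sweep(pts, 2, centre)^2)))
    list(stack = stack, voxel_size = vx, radius = R, centre = centre,
         truth = truth)
  })
}

#' Write a nucleus scene as a multi-page TIFF
#'
#' Pages are ordered channel-major (all z slices of channel 1, then
#' channel 2) and stored as 16-bit integers; intensities are rounded and
#' clipped at 65535.
#'
#' @param scene One element of [render_nuclei()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nucleus_tiff <- function(scene, path) {
  d <- dim(scene$stack)
  pages <- list()
  for (ch in seq_len(d[4])) for (z in seq_len(d[3]))
    pages[[length(pages) + 1L]] <-
      pmin(round(scene$stack[, , z, ch]), 65535) / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a nucleus stack written by [write_nucleus_tiff()]
#'
#' @param path TIFF file.
#' @param n_channels Channels in the file (default 2).
#' @return 4D array (x, y, z, channel) of integer intensities.
#' @export
read_nucleus_tiff <- function(path, n_channels = 2) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- length(pages) / n_channels
  if (nz != round(nz)) stop("page count not divisible by channel count")
  d <- dim(pages[[1]])
  out <- array(0, c(d[1], d[2], nz, n_channels))
  k <- 1L
  for (ch in seq_len(n_channels)) for (z in seq_len(nz)) {
    out[, , z, ch] <- round(pages[[k]] * 65535)
    k <- k + 1L
  }
  out
}
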