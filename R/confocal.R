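#' @useDynLib trabkit, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Multi-channel 3D volume container
#'
#' @param channels named list of 3D arrays (conventionally \code{WGA},
#'   \code{Cx43}, \code{aACT}, \code{DAPI}) sharing dimensions.
#' @param voxel_um voxel size (x, y, z) in um.
#' @return a \code{volume_stack}.
#' @export
volume_stack <- function(channels, voxel_um = c(0.1, 0.1, 0.2)) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  d <- dim(channels[[1]])
  if (length(d) != 3) stop("channels must be 3D arrays")
  for (ch in channels) if (!identical(dim(ch), d)) stop("all channels must share dimensions")
  if (any(voxel_um <= 0)) stop("voxel sizes must be > 0")
  structure(list(channels = channels, voxel_um = voxel_um, dim = d),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  cat(sprintf("<volume_stack> %s voxels (%g x %g x %g um), channels: %s\n",
              paste(x$dim, collapse = " x "), x$voxel_um[1], x$voxel_um[2],
              x$voxel_um[3], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

## histogram mode of an intensity image (256 bins over the value range)
.image_mode <- function(x, bins = 256L) {
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * bins)), bins)
  r[1] + (which.max(h) - 0.5) / bins * (r[2] - r[1])
}

#' Correct depth-dependent signal attenuation
#'
#' Light scattering and absorption dim deeper z-planes of a confocal stack.
#' Each plane is rescaled by a gain chosen so that its robust foreground
#' statistic -- the median of voxels above the plane's histogram mode --
#' matches that of the top (shallowest) plane. Empty or featureless planes
#' get gain 1.
#'
#' @param stack a \code{volume_stack}.
#' @param channels channels to correct (default: all).
#' @param reference optional channel name whose gain profile is applied to
#'   every corrected channel. Depth attenuation is an optical property of
#'   the tissue, so estimating it once on a structurally uniform stain
#'   (WGA, present at every depth) and sharing it avoids content-driven
#'   artifacts in sparse channels; \code{NULL} estimates gains per channel.
#' @return the corrected stack; per-channel gains in attribute
#'   \code{attenuation_gains}.
#' @export
correct_depth_attenuation <- function(stack, channels = names(stack$channels),
                                      reference = NULL) {
  stopifnot(inherits(stack, "volume_stack"))
  if (stack$dim[3] < 8) stop("need at least 8 z-planes for attenuation correction")
  plane_gains <- function(a) {
    stat <- apply(a, 3, function(pl) {
      m <- .image_mode(pl)
      fg <- pl[pl > m]
      if (length(fg) < 16) NA_real_ else stats::median(fg)
    })
    ref <- stat[1]
    g <- ifelse(is.na(stat) | stat <= 0 | is.na(ref), 1, ref / stat)
    g[1] <- 1
    ## attenuation only deepens with z: a 3-plane running median absorbs
    ## content-driven outliers (e.g. planes dominated by one structure),
    ## then the cumulative maximum enforces monotone non-decreasing gains
    if (length(g) >= 3)
      g <- stats::runmed(g, 3, endrule = "keep")
    cummax(g)
  }
  g_ref <- if (!is.null(reference)) plane_gains(stack$channels[[reference]])
  gains <- list()
  for (ch in channels) {
    a <- stack$channels[[ch]]
    g <- if (is.null(g_ref)) plane_gains(a) else g_ref
    for (z in seq_len(stack$dim[3]))
      a[, , z] <- a[, , z] * g[z]
    stack$channels[[ch]] <- a
    gains[[ch]] <- g
  }
  attr(stack, "attenuation_gains") <- gains
  stack
}

## 3D circular convolution via FFT, kernel centred at the origin
.fft_convolve <- function(x, kern_small) {
  d <- dim(x)
  k <- array(0, d)
  kd <- dim(kern_small)
  ctr <- (kd + 1) %/% 2
  ## place kernel wrapped around the origin
  ix <- ((seq_len(kd[1]) - ctr[1]) %% d[1]) + 1
  iy <- ((seq_len(kd[2]) - ctr[2]) %% d[2]) + 1
  iz <- ((seq_len(kd[3]) - ctr[3]) %% d[3]) + 1
  k[ix, iy, iz] <- k[ix, iy, iz] + kern_small
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / prod(d)
}

#' Gaussian 3D point spread function
#'
#' @param sigma_um PSF standard deviations (x, y, z) in um.
#' @param voxel_um voxel size in um.
#' @param half_size kernel half-width in sigmas.
#' @return a normalized (sum 1) 3D kernel array.
#' @export
gaussian_psf <- function(sigma_um, voxel_um = c(0.1, 0.1, 0.2), half_size = 3) {
  sv <- sigma_um / voxel_um
  r <- pmax(1L, ceiling(half_size * sv))
  gx <- stats::dnorm(seq(-r[1], r[1]), sd = max(sv[1], 1e-6))
  gy <- stats::dnorm(seq(-r[2], r[2]), sd = max(sv[2], 1e-6))
  gz <- stats::dnorm(seq(-r[3], r[3]), sd = max(sv[3], 1e-6))
  k <- outer(outer(gx, gy), gz)
  dim(k) <- c(length(gx), length(gy), length(gz))
  k / sum(k)
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative Richardson-Lucy updates
#' \deqn{u^{(t+1)} = u^{(t)} \cdot \left[ \frac{y}{u^{(t)} * p} * \hat p \right]}
#' with \eqn{\hat p} the flipped PSF, computed with FFT (circular)
#' convolutions. Non-negativity is preserved by construction and total
#' intensity is renormalized after the final iteration (conserved within
#' 1\%).
#'
#' @param img 3D array (one channel).
#' @param psf 3D kernel, normalized to sum 1.
#' @param iterations number of RL iterations (>= 1).
#' @return the deconvolved array.
#' @export
rl_deconvolve <- function(img, psf, iterations = 10L) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (abs(sum(psf) - 1) > 1e-6) stop("psf must be normalized to sum 1")
  if (any(dim(psf) > dim(img))) stop("psf larger than the image")
  tot <- sum(img)
  if (tot == 0) return(img)
  psf_flip <- psf[rev(seq_len(dim(psf)[1])), rev(seq_len(dim(psf)[2])),
                  rev(seq_len(dim(psf)[3])), drop = FALSE]
  dim(psf_flip) <- dim(psf)
  u <- pmax(img, 1e-12)
  for (it in seq_len(iterations)) {
    est <- pmax(.fft_convolve(u, psf), 1e-12)
    u <- u * .fft_convolve(img / est, psf_flip)
    u[u < 0] <- 0
  }
  u * (tot / sum(u))
}

#' Global mode + k SD threshold
#'
#' Binarizes a channel at the most frequent intensity (256-bin histogram
#' mode) plus \code{k} standard deviations of the whole stack; voxels
#' strictly above threshold are foreground. The volume pipeline uses k = 1
#' for WGA, 3 for Cx43 and 2 for DAPI.
#'
#' @param channel 3D intensity array.
#' @param k SD multiplier.
#' @return logical array.
#' @export
global_threshold <- function(channel, k) {
  if (!length(channel)) stop("empty channel")
  channel > .image_mode(channel) + k * stats::sd(channel)
}

#' Local threshold for the alpha-actinin channel
#'
#' The sarcomeric alpha-actinin signal varies strongly in intensity across a
#' stack, so a high-pass residual is thresholded instead of the raw image:
#' a box mean filter (default 20 x 20 x 2 voxels) is subtracted from the
#' original and the residual binarized at its mode + 1 SD. Slowly varying
#' gain fields cancel in the residual.
#'
#' @param channel 3D intensity array.
#' @param box box filter dimensions in voxels.
#' @param k SD multiplier on the residual.
#' @return logical array.
#' @export
local_threshold_aact <- function(channel, box = c(20, 20, 2), k = 1) {
  d <- dim(channel)
  if (any(d < box)) stop("channel smaller than the box filter")
  res <- channel - .box_mean(channel, box)
  res > .image_mode(res) + k * stats::sd(res)
}

## separable box mean via cumulative sums along each axis, truncated windows
.box_mean <- function(x, box) {
  for (ax in 1:3) {
    r <- box[ax] %/% 2
    if (r < 1 && box[ax] < 2) next
    x <- .axis_mean(x, ax, r, box[ax])
  }
  x
}

.axis_mean <- function(x, axis, r, width) {
  d <- dim(x)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  y <- aperm(x, perm)
  dy <- dim(y)
  m <- matrix(y, nrow = dy[1])
  n <- dy[1]
  cs <- rbind(0, apply(m, 2, cumsum))
  lo <- pmax(seq_len(n) - r, 1L)
  hi <- pmin(seq_len(n) + (width - 1L - r), n)
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  dim(out) <- dy
  aperm(out, order(perm))
}

#' 3D morphological opening with a physical radius
#'
#' Erosion followed by dilation with an ellipsoidal structuring element
#' whose semi-axes equal the given physical radius converted to voxels per
#' axis (minimum 1 voxel in-plane; axes whose voxel size exceeds the radius
#' are not eroded). A 0.2 um opening removes single-voxel speckle from the
#' Cx43 mask at the default 0.1 x 0.1 x 0.2 um sampling.
#'
#' @param mask logical 3D array.
#' @param radius_um opening radius, um.
#' @param voxel_um voxel size, um.
#' @return opened logical array (never adds voxels).
#' @export
opening3d <- function(mask, radius_um = 0.2, voxel_um = c(0.1, 0.1, 0.2)) {
  d <- dim(mask)
  r_vox <- ifelse(radius_um >= voxel_um, pmax(1, floor(radius_um / voxel_um)), 0)
  if (all(r_vox == 0)) return(mask)
  off <- .ellipsoid_offsets(r_vox)
  er <- .morph_binary_cpp(as.logical(mask), as.integer(d), off, TRUE)
  di <- .morph_binary_cpp(er, as.integer(d), off, FALSE)
  array(di, d)
}

.ellipsoid_offsets <- function(r_vox) {
  rx <- r_vox[1]; ry <- r_vox[2]; rz <- r_vox[3]
  g <- expand.grid(x = -rx:rx, y = -ry:ry, z = -rz:rz)
  keep <- (g$x / max(rx, 1))^2 + (g$y / max(ry, 1))^2 + (g$z / max(rz, 1))^2 <= 1 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

#' Watershed partition of the tissue into cell segments
#'
#' Computes the anisotropic Euclidean distance from every non-WGA voxel to
#' the WGA (extracellular matrix) mask, inverts it, and floods basins from
#' local-maximum seeds: deep cell interiors become segment cores and the
#' flooding meets at WGA walls. Seeds closer than \code{min_separation_um}
#' to a stronger seed are suppressed, which prevents over-segmentation of
#' elongated cells. WGA voxels themselves are excluded from the segments
#' (label 0, extracellular).
#'
#' @param wga_mask logical 3D array of the segmented WGA signal.
#' @param voxel_um voxel size, um.
#' @param min_separation_um minimum seed separation, um.
#' @return integer label array (0 = extracellular/WGA, 1..N = segments),
#'   with the seed table in attribute \code{seeds}.
#' @export
watershed_segments <- function(wga_mask, voxel_um = c(0.1, 0.1, 0.2),
                               min_separation_um = 4) {
  d <- dim(wga_mask)
  if (all(wga_mask)) stop("WGA mask covers the whole volume; nothing to segment")
  if (!any(wga_mask)) {
    lab <- array(1L, d)
    attr(lab, "seeds") <- data.frame(x = NA, y = NA, z = NA)
    return(lab)
  }
  dist2 <- array(.edt3d_cpp(as.logical(wga_mask), as.integer(d),
                            as.numeric(voxel_um)), d)
  seeds_idx <- .distance_peaks(dist2, voxel_um, min_separation_um)
  seeds <- array(0L, d)
  seeds[seeds_idx] <- seq_along(seeds_idx)
  lab <- .watershed3d_cpp(as.numeric(dist2), as.integer(seeds),
                          as.logical(!wga_mask), as.integer(d))
  lab <- array(lab, d)
  co <- arrayInd(seeds_idx, d)
  attr(lab, "seeds") <- data.frame(x = co[, 1], y = co[, 2], z = co[, 3])
  lab
}

## seed voxels for the watershed: local maxima of the distance map,
## quantized to `quantum_um` so that near-flat ridges and plateaus form
## connected components merged into a single seed each, then greedy
## suppression of seeds closer than `min_sep_um` to a deeper one
.distance_peaks <- function(dist2, voxel_um, min_sep_um, quantum_um = 0.5) {
  d <- dim(dist2)
  dq <- as.integer(round(sqrt(dist2) / quantum_um))
  comp <- array(.regmax_cpp(dq, as.integer(d)), d)
  if (max(comp) == 0L) return(which.max(dist2))
  ## one seed per regional-max plateau: its deepest voxel (ties: lowest index)
  idx <- which(comp > 0L)
  o <- order(comp[idx], -dist2[idx], idx)
  idx <- idx[o]
  cand <- idx[!duplicated(comp[idx])]
  depth <- dist2[cand]
  ord <- cand[order(-depth, cand)]
  co <- arrayInd(ord, d)
  phys <- sweep(co, 2, voxel_um, `*`)
  sel <- logical(length(ord))
  acc <- matrix(numeric(0), ncol = 3)
  for (i in seq_along(ord)) {
    if (nrow(acc)) {
      dd <- sqrt(colSums((t(acc) - phys[i, ])^2))
      if (min(dd) < min_sep_um) next
    }
    sel[i] <- TRUE
    acc <- rbind(acc, phys[i, ])
  }
  ord[sel]
}

.shift3 <- function(a, sh) {
  d <- dim(a)
  out <- array(-Inf, d)
  sx <- sh[1]; sy <- sh[2]; sz <- sh[3]
  xs <- max(1, 1 + sx):min(d[1], d[1] + sx)
  ys <- max(1, 1 + sy):min(d[2], d[2] + sy)
  zs <- max(1, 1 + sz):min(d[3], d[3] + sz)
  out[xs, ys, zs] <- a[xs - sx, ys - sy, zs - sz]
  out
}

#' Classify segments as myocytes by alpha-actinin content
#'
#' A segment is a myocyte iff the fraction of its voxels carrying
#' alpha-actinin signal is at least the threshold (default 7.5\%,
#' inclusive).
#'
#' @param labels integer label array from [watershed_segments()].
#' @param aact_mask logical array of the segmented alpha-actinin signal.
#' @param threshold minimum aACT voxel fraction, inclusive.
#' @return data frame: \code{segment}, \code{n_voxels}, \code{aact_fraction},
#'   \code{myocyte}.
#' @export
classify_myocytes <- function(labels, aact_mask, threshold = 0.075) {
  if (!identical(dim(labels), dim(aact_mask)))
    stop("labels and mask must share dimensions")
  ids <- labels[labels > 0]
  if (!length(ids))
    return(data.frame(segment = integer(), n_voxels = integer(),
                      aact_fraction = numeric(), myocyte = logical()))
  n_vox <- tabulate(ids)
  n_aact <- tabulate(ids[aact_mask[labels > 0]], nbins = length(n_vox))
  seg <- which(n_vox > 0)
  frac <- n_aact[seg] / n_vox[seg]
  data.frame(segment = seg, n_voxels = n_vox[seg], aact_fraction = frac,
             myocyte = frac >= threshold)
}

#' Tissue volume fractions
#'
#' ECM fraction = WGA-mask volume / stack volume; myocyte fraction = volume
#' of myocyte-classified segments / stack volume; Cx43 fraction on the
#' opened Cx43 mask; aACT fraction on the aACT mask. The remainder
#' (non-WGA, non-myocyte) is reported as \code{unclassified}.
#'
#' @param masks named list with logical arrays \code{WGA}, \code{Cx43}
#'   (opened), \code{aACT}.
#' @param labels segment label array.
#' @param classes the [classify_myocytes()] table.
#' @return one-row data frame of fractions in [0, 1].
#' @export
volume_fractions <- function(masks, labels, classes) {
  tot <- length(labels)
  if (tot == 0) stop("zero tissue volume")
  myo_ids <- classes$segment[classes$myocyte]
  myo_vox <- sum(classes$n_voxels[classes$myocyte])
  data.frame(ecm = sum(masks$WGA) / tot,
             myocyte = myo_vox / tot,
             cx43 = sum(masks$Cx43) / tot,
             aact = sum(masks$aACT) / tot,
             unclassified = 1 - sum(masks$WGA) / tot - myo_vox / tot)
}

#' Run the full confocal segmentation pipeline on one stack
#'
#' Depth-attenuation correction, optional Richardson-Lucy deconvolution,
#' channel segmentation (WGA mode+1SD, Cx43 mode+3SD, DAPI mode+2SD, aACT
#' local threshold), 0.2 um opening of the Cx43 mask, watershed cell
#' partitioning on the inverted WGA distance map, myocyte classification at
#' 7.5\% aACT content and volume-fraction quantification.
#'
#' @param stack a \code{volume_stack} with channels WGA, Cx43, aACT, DAPI.
#' @param psf optional PSF for deconvolution (NULL = skip; measured PSFs
#'   are rig-specific).
#' @param rl_iterations Richardson-Lucy iterations when a PSF is given.
#' @param attenuation correct depth attenuation first.
#' @param k_sd global threshold multipliers per channel.
#' @param aact_content myocyte classification threshold.
#' @param min_separation_um watershed seed separation.
#' @return list with \code{masks}, \code{labels}, \code{classes},
#'   \code{fractions}.
#' @export
segment_stack <- function(stack, psf = NULL, rl_iterations = 8L,
                          attenuation = TRUE,
                          k_sd = c(WGA = 1, Cx43 = 3, DAPI = 2),
                          aact_content = 0.075, min_separation_um = 4) {
  stopifnot(inherits(stack, "volume_stack"))
  need <- c("WGA", "Cx43", "aACT", "DAPI")
  if (!all(need %in% names(stack$channels)))
    stop("stack must contain channels: ", paste(need, collapse = ", "))
  if (attenuation && stack$dim[3] >= 8)
    stack <- correct_depth_attenuation(stack, reference = "WGA")
  if (!is.null(psf))
    for (ch in need)
      stack$channels[[ch]] <- rl_deconvolve(stack$channels[[ch]], psf, rl_iterations)
  masks <- list(
    WGA = global_threshold(stack$channels$WGA, k_sd[["WGA"]]),
    Cx43 = opening3d(global_threshold(stack$channels$Cx43, k_sd[["Cx43"]]),
                     0.2, stack$voxel_um),
    DAPI = global_threshold(stack$channels$DAPI, k_sd[["DAPI"]]),
    aACT = local_threshold_aact(stack$channels$aACT))
  labels <- watershed_segments(masks$WGA, stack$voxel_um, min_separation_um)
  classes <- classify_myocytes(labels, masks$aACT, aact_content)
  fractions <- volume_fractions(masks, labels, classes)
  list(masks = masks, labels = labels, classes = classes, fractions = fractions)
}

#' Average volume fractions over the stacks of one sample
#'
#' @param fraction_rows data frame of per-stack fractions.
#' @return one-row data frame of means.
#' @export
average_sample_fractions <- function(fraction_rows) {
  as.data.frame(lapply(fraction_rows, mean))
}

#' Read / write a multi-channel TIFF volume
#'
#' Volumes are stored as one multi-page grayscale TIFF per channel-z plane
#' in channel-major order; channel names and voxel size go to a JSON
#' sidecar.
#'
#' @param stack a \code{volume_stack}.
#' @param path TIFF file path; sidecar is \code{<path>.json}.
#' @return \code{path} invisibly / a \code{volume_stack}.
#' @export
write_volume <- function(stack, path) {
  stopifnot(inherits(stack, "volume_stack"))
  mx <- max(1, max(vapply(stack$channels, max, numeric(1))))
  pages <- list()
  for (ch in names(stack$channels))
    for (z in seq_len(stack$dim[3]))
      pages[[length(pages) + 1L]] <-
        t(pmin(pmax(stack$channels[[ch]][, , z], 0), mx)) / mx
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(schema = "trabkit/volume/v1",
                            channels = names(stack$channels),
                            dim = stack$dim, voxel_um = stack$voxel_um,
                            intensity_scale = mx),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- meta$dim
  chans <- list()
  i <- 1L
  for (ch in meta$channels) {
    a <- array(0, d)
    for (z in seq_len(d[3])) {
      a[, , z] <- t(pages[[i]]) * meta$intensity_scale
      i <- i + 1L
    }
    chans[[ch]] <- a
  }
  volume_stack(chans, meta$voxel_um)
}
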