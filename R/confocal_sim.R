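#' Simulate a 4-channel confocal volume with ground truth
#'
#' Builds a jittered brick lattice of cells separated by extracellular
#' matrix walls and renders the four stains: WGA on the walls, sarcomeric
#' alpha-actinin striations (approx. 2 um period along the fibre axis)
#' inside a configurable subset of cells, Cx43 puncta at longitudinal
#' junctions between two myocyte cells, and ellipsoidal DAPI nuclei near
#' cell centres. Imaging realism is added in order: Gaussian PSF blur,
#' exponential depth attenuation \code{exp(-z / lambda)}, then
#' Poisson shot noise plus Gaussian read noise. Per-voxel ground-truth
#' class labels (0 background/gap, 1 myocyte, 2 ECM wall, 3 other cell) and
#' the true volume fractions are returned alongside.
#'
#' @param dim_vox volume dimensions (x, y, z) in voxels, each >= 32 in x/y
#'   and >= 8 in z.
#' @param voxel_um voxel size in um. The default renders a field of view a
#'   few cells wide at sub-micron sampling.
#' @param cell_um nominal brick (cell) edge length, um.
#' @param wall_um ECM wall thickness, um.
#' @param aact_positive fraction of cells carrying alpha-actinin
#'   (myocytes).
#' @param striation_um sarcomere period, um.
#' @param psf_sigma_um PSF sigmas; NULL disables blurring.
#' @param attenuation_lambda_um depth attenuation length; Inf disables.
#' @param noise_gauss_sd Gaussian read noise sd (intensity units); 0 with
#'   \code{shot_noise = FALSE} gives a noiseless render.
#' @param shot_noise add Poisson shot noise.
#' @param intensities named base intensities for background and the four
#'   stains.
#' @param seed integer seed; generation is reproducible.
#' @return list with \code{stack} (a [volume_stack()]) and \code{truth}
#'   (list: \code{labels} array, \code{fractions} one-row data frame with
#'   ecm / myocyte / cx43 / aact / other, \code{n_cells},
#'   \code{n_myocytes}).
#' @export
simulate_volume <- function(dim_vox = c(64, 64, 32),
                            voxel_um = c(0.2, 0.2, 0.4),
                            cell_um = 6, wall_um = 0.8,
                            aact_positive = 1, striation_um = 2,
                            psf_sigma_um = c(0.1, 0.1, 0.25),
                            attenuation_lambda_um = 40,
                            noise_gauss_sd = 2, shot_noise = TRUE,
                            intensities = c(background = 10, WGA = 120,
                                            Cx43 = 160, aACT = 110, DAPI = 140),
                            seed = 1L) {
  if (any(dim_vox[1:2] < 32) || dim_vox[3] < 8)
    stop("volume must be at least 32 x 32 x 8 voxels")
  set.seed(as.integer(seed))
  d <- dim_vox
  ext_um <- d * voxel_um

  ## jittered brick lattice: cut positions per axis
  cuts <- lapply(1:3, function(ax) {
    n_cell <- max(1L, round(ext_um[ax] / cell_um))
    base <- seq(0, ext_um[ax], length.out = n_cell + 1L)
    jit <- stats::runif(length(base), -0.15, 0.15) * cell_um
    jit[c(1, length(base))] <- 0
    sort(base + jit)
  })
  ## cell index per voxel and per axis
  ax_pos <- lapply(1:3, function(ax) (seq_len(d[ax]) - 0.5) * voxel_um[ax])
  ax_cell <- lapply(1:3, function(ax)
    pmin(length(cuts[[ax]]) - 1L, pmax(1L, findInterval(ax_pos[[ax]], cuts[[ax]]))))
  cx <- array(ax_cell[[1]], d)
  cy <- array(rep(ax_cell[[2]], each = d[1]), d)
  cz <- array(rep(ax_cell[[3]], each = d[1] * d[2]), d)
  ncx <- length(cuts[[1]]) - 1L
  ncy <- length(cuts[[2]]) - 1L
  cell_id <- cx + ncx * (cy - 1L) + ncx * ncy * (cz - 1L)
  n_cells <- max(cell_id)

  ## wall: within wall_um/2 of any interior cut plane
  wall <- array(FALSE, d)
  for (ax in 1:3) {
    pos <- ax_pos[[ax]]
    interior <- cuts[[ax]][-c(1, length(cuts[[ax]]))]
    near <- rep(FALSE, d[ax])
    for (cpos in interior) near <- near | abs(pos - cpos) <= wall_um / 2
    wall <- wall | switch(ax, array(near, d),
                          array(rep(near, each = d[1]), d),
                          array(rep(near, each = d[1] * d[2]), d))
  }

  ## myocyte designation per cell
  myo_cell <- stats::runif(n_cells) < aact_positive
  is_myo <- array(myo_cell[cell_id], d) & !wall

  ## ground-truth labels: 1 myocyte, 2 ECM, 3 other cell
  labels <- array(3L, d)
  labels[is_myo] <- 1L
  labels[wall] <- 2L

  bg <- intensities[["background"]]

  ## WGA: walls
  wga <- array(bg, d)
  wga[wall] <- intensities[["WGA"]]

  ## aACT: striations along x inside myocyte cells -- narrow bright bands
  ## (the Z-line lattice, ~25% duty cycle of the sarcomere period)
  xs <- array(ax_pos[[1]], d)
  bright <- (xs / striation_um) %% 1 < 0.25
  aact <- array(bg, d)
  aact[is_myo & bright] <- intensities[["aACT"]]
  aact_truth <- is_myo & bright

  ## Cx43: puncta on x-walls separating two myocyte cells
  cx43 <- array(bg, d)
  cx43_truth <- array(FALSE, d)
  xwall_cuts <- cuts[[1]][-c(1, length(cuts[[1]]))]
  if (length(xwall_cuts)) {
    n_punct <- max(3L, round(n_cells * 8))
    for (p in seq_len(n_punct)) {
      cxp <- sample(xwall_cuts, 1)
      cyp <- stats::runif(1, 0.1, 0.9) * ext_um[2]
      czp <- stats::runif(1, 0.1, 0.9) * ext_um[3]
      r_um <- 0.6
      ix <- which(abs(ax_pos[[1]] - cxp) <= r_um)
      iy <- which(abs(ax_pos[[2]] - cyp) <= r_um)
      iz <- which(abs(ax_pos[[3]] - czp) <= r_um)
      for (i in ix) for (j in iy) for (k in iz) {
        if ((ax_pos[[1]][i] - cxp)^2 + (ax_pos[[2]][j] - cyp)^2 +
            (ax_pos[[3]][k] - czp)^2 <= r_um^2) {
          cx43[i, j, k] <- intensities[["Cx43"]]
          cx43_truth[i, j, k] <- TRUE
        }
      }
    }
  }

  ## DAPI: one ellipsoidal nucleus per cell, centred with jitter
  dapi <- array(bg, d)
  cell_centres <- do.call(rbind, lapply(seq_len(n_cells), function(id) {
    idx <- which(cell_id == id & !wall)
    if (!length(idx)) return(c(NA, NA, NA))
    co <- arrayInd(idx[ceiling(length(idx) / 2)], d)
    (co - 0.5) * voxel_um
  }))
  nuc_r <- c(1.5, 1.0, 1.0)
  for (id in seq_len(n_cells)) {
    ctr <- cell_centres[id, ]
    if (any(is.na(ctr))) next
    ix <- which(abs(ax_pos[[1]] - ctr[1]) <= nuc_r[1])
    iy <- which(abs(ax_pos[[2]] - ctr[2]) <= nuc_r[2])
    iz <- which(abs(ax_pos[[3]] - ctr[3]) <= nuc_r[3])
    for (i in ix) for (j in iy) for (k in iz) {
      if (((ax_pos[[1]][i] - ctr[1]) / nuc_r[1])^2 +
          ((ax_pos[[2]][j] - ctr[2]) / nuc_r[2])^2 +
          ((ax_pos[[3]][k] - ctr[3]) / nuc_r[3])^2 <= 1) {
        dapi[i, j, k] <- intensities[["DAPI"]]
      }
    }
  }

  chans <- list(WGA = wga, Cx43 = cx43, aACT = aact, DAPI = dapi)

  if (!is.null(psf_sigma_um)) {
    psf <- gaussian_psf(psf_sigma_um, voxel_um)
    chans <- lapply(chans, .fft_convolve, kern_small = psf)
  }
  if (is.finite(attenuation_lambda_um)) {
    att <- exp(-(seq_len(d[3]) - 1) * voxel_um[3] / attenuation_lambda_um)
    for (ch in names(chans))
      for (z in seq_len(d[3]))
        chans[[ch]][, , z] <- chans[[ch]][, , z] * att[z]
  }
  for (ch in names(chans)) {
    x <- chans[[ch]]
    if (shot_noise) x <- array(stats::rpois(length(x), pmax(x, 0)), d)
    if (noise_gauss_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_gauss_sd)
    chans[[ch]] <- x
  }

  fractions <- data.frame(
    ecm = mean(wall),
    myocyte = mean(labels == 1L),
    cx43 = mean(cx43_truth),
    aact = mean(aact_truth),
    other = mean(labels == 3L))

  list(stack = volume_stack(chans, voxel_um),
       truth = list(labels = labels, fractions = fractions,
                    n_cells = n_cells, n_myocytes = sum(myo_cell)))
}
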