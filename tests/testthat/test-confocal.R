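test_that("depth correction leaves uniform stacks unchanged and undoes exponential decay", {
  set.seed(1)
  d <- c(24, 24, 12)
  base <- array(20, d)
  base[sample(length(base), 2000)] <- 150     # foreground speckle at all depths
  uni <- volume_stack(list(WGA = base), voxel_um = c(0.2, 0.2, 0.4))
  g <- attr(correct_depth_attenuation(uni), "attenuation_gains")$WGA
  expect_equal(g, rep(1, d[3]), tolerance = 0.02)
  att <- base * rep(exp(-(seq_len(d[3]) - 1) * 0.4 / 10), each = d[1] * d[2])
  dec <- correct_depth_attenuation(volume_stack(list(WGA = att), c(0.2, 0.2, 0.4)))
  med <- apply(dec$channels$WGA, 3, function(pl) median(pl[pl > 50]))
  expect_true(all(abs(med / med[1] - 1) < 0.02))
  expect_true(all(diff(attr(dec, "attenuation_gains")$WGA) >= 0))  # monotone gains
})

test_that("Richardson-Lucy with a delta PSF is the identity and zero input stays zero", {
  set.seed(2)
  img <- array(runif(16 * 16 * 8, 0, 100), c(16, 16, 8))
  delta <- array(0, c(3, 3, 3)); delta[2, 2, 2] <- 1
  out <- rl_deconvolve(img, delta, iterations = 5)
  expect_equal(out, img, tolerance = 1e-6)
  expect_true(all(rl_deconvolve(array(0, c(16, 16, 8)), delta, 3) == 0))
})

test_that("Richardson-Lucy sharpens a blurred point source and conserves intensity", {
  d <- c(32, 32, 16)
  psf <- gaussian_psf(c(0.3, 0.3, 0.6), c(0.2, 0.2, 0.4))
  src <- array(0, d); src[16, 16, 8] <- 1000
  blurred <- trabkit:::.fft_convolve(src, psf)
  dec <- rl_deconvolve(blurred, psf, iterations = 20)
  expect_gt(max(dec), max(blurred))                       # peak restored
  expect_lt(sum(dec > max(dec) / 2), sum(blurred > max(blurred) / 2))  # FWHM shrinks
  expect_lt(abs(sum(dec) - sum(blurred)) / sum(blurred), 0.01)
  expect_true(all(dec >= 0))
  expect_error(rl_deconvolve(array(1, c(4, 4, 4)), gaussian_psf(c(1, 1, 1), c(0.2, 0.2, 0.4))),
               "larger")
})

test_that("global thresholding separates objects from a noisy background", {
  set.seed(3)
  d <- c(32, 32, 8)
  img <- array(rnorm(prod(d), 100, 10), d)
  obj <- array(FALSE, d); obj[10:20, 10:20, 3:6] <- TRUE
  img[obj] <- rnorm(sum(obj), 200, 10)
  m <- global_threshold(img, 3)
  expect_gt(mean(m[obj]), 0.99)
  expect_lt(mean(m[!obj]), 0.01)
  ## constant image -> empty mask; k = 0 cuts strictly above the mode
  expect_false(any(global_threshold(array(7, d), 1)))
  m0 <- global_threshold(img, 0)
  expect_true(all(img[m0] > trabkit:::.image_mode(img)))
  ## invariance to constant offset
  expect_identical(global_threshold(img + 500, 3), m)
})

test_that("the local aACT threshold ignores slowly varying gain and recovers striations", {
  d <- c(48, 48, 8)
  pos <- (seq_len(d[1]) - 0.5) * 0.2
  bands <- (pos / 2) %% 1 < 0.25                  # 2 um period, 25% duty
  img <- array(10, d)
  img[bands, , ] <- 110
  gain <- outer(seq(0.5, 1.5, length.out = d[1]),
                seq(0.8, 1.2, length.out = d[2]))
  shaded <- img * array(rep(gain, d[3]), d)
  m_flat <- local_threshold_aact(img)
  m_shaded <- local_threshold_aact(shaded)
  truth <- array(bands, d)
  expect_gt(mean(m_flat == truth), 0.95)
  expect_gt(mean(m_shaded == truth), 0.93)        # nearly unaffected by shading
  expect_false(any(local_threshold_aact(array(5, c(24, 24, 4)))))
  expect_error(local_threshold_aact(array(1, c(8, 8, 1))), "smaller")
})

test_that("morphological opening removes speckle, keeps blocks, and never adds voxels", {
  d <- c(24, 24, 12)
  vox <- c(0.1, 0.1, 0.2)
  speck <- array(FALSE, d); speck[12, 12, 6] <- TRUE
  expect_false(any(opening3d(speck, 0.2, vox)))
  block <- array(FALSE, d); block[6:16, 6:16, 3:9] <- TRUE
  opened <- opening3d(block, 0.2, vox)
  expect_true(all(opened[8:14, 8:14, 5:7]))       # interior preserved
  expect_true(all(!opened | block))               # subset of the input
  expect_false(any(opening3d(array(FALSE, d), 0.2, vox)))
})

test_that("watershed separates cavities at WGA walls and covers all interior voxels", {
  m <- array(FALSE, c(20, 10, 10)); m[10:11, , ] <- TRUE
  lab <- watershed_segments(m, voxel_um = c(1, 1, 1), min_separation_um = 2)
  expect_identical(length(setdiff(unique(as.vector(lab)), 0L)), 2L)
  expect_true(all(lab[m] == 0L))
  expect_identical(sum(lab > 0), sum(!m))         # basins partition the interior
  ## no WGA -> a single segment
  lab1 <- watershed_segments(array(FALSE, c(8, 8, 8)), c(1, 1, 1))
  expect_identical(max(lab1), 1L)
  expect_error(watershed_segments(array(TRUE, c(4, 4, 4)), c(1, 1, 1)), "whole")
})

test_that("watershed recovers the cell count of a synthetic brick lattice", {
  for (seed in 1:3) {
    sv <- simulate_volume(seed = seed)
    seg <- segment_stack(sv$stack, min_separation_um = 6)
    expect_lte(abs(max(seg$labels) - sv$truth$n_cells) / sv$truth$n_cells, 0.1)
  }
})

test_that("myocyte classification is inclusive at exactly 7.5% aACT content", {
  ## 40 segments of 200 voxels sweeping content 1%..15% in 0.5% steps
  contents <- seq(0.01, 0.15, by = 0.005)
  n_seg <- length(contents)
  labels <- array(rep(seq_len(n_seg), each = 200), c(200, n_seg, 1))
  labels <- aperm(labels, c(2, 1, 3))
  aact <- array(FALSE, dim(labels))
  for (i in seq_len(n_seg)) aact[i, seq_len(round(contents[i] * 200)), 1] <- TRUE
  cl <- classify_myocytes(labels, aact)
  expect_equal(min(cl$aact_fraction[cl$myocyte]), 0.075)
  expect_equal(max(cl$aact_fraction[!cl$myocyte]), 0.07)
  expect_true(all(cl$myocyte == (cl$aact_fraction >= 0.075)))
  ## content 0 -> non-myocyte; all-negative volume -> no myocyte segments
  expect_false(cl$myocyte[1])
  sv <- simulate_volume(aact_positive = 0, seed = 4, psf_sigma_um = NULL,
                        attenuation_lambda_um = Inf,
                        noise_gauss_sd = 0, shot_noise = FALSE)
  seg <- segment_stack(sv$stack)
  expect_identical(sum(seg$classes$myocyte), 0L)
})

test_that("volume fractions recover the generator's ground truth within 10% relative", {
  for (seed in 1:5) {
    sv <- simulate_volume(seed = seed)
    seg <- segment_stack(sv$stack)
    tr <- sv$truth$fractions
    me <- seg$fractions
    for (f in c("ecm", "myocyte", "cx43", "aact")) {
      expect_lte(abs(me[[f]] - tr[[f]]) / tr[[f]], 0.1)
      expect_gte(me[[f]], 0); expect_lte(me[[f]], 1)
    }
  }
})

test_that("an all-myocyte phantom without walls yields myocyte fraction 1", {
  d <- c(32, 32, 8)
  masks <- list(WGA = array(FALSE, d), Cx43 = array(FALSE, d),
                aACT = array(rep(c(TRUE, FALSE), length.out = prod(d)), d))
  labels <- array(1L, d)
  classes <- classify_myocytes(labels, masks$aACT)
  fr <- volume_fractions(masks, labels, classes)
  expect_equal(fr$myocyte, 1)
  expect_equal(fr$ecm, 0)
})

test_that("degenerate imaging: thresholded WGA equals the ground-truth wall mask", {
  sv <- simulate_volume(seed = 5, psf_sigma_um = NULL, attenuation_lambda_um = Inf,
                        noise_gauss_sd = 0, shot_noise = FALSE)
  m <- sv$stack$channels$WGA > 50       # any cut between bg 10 and walls 120
  expect_identical(m, sv$truth$labels == 2L)
})

test_that("volumes round-trip through multi-channel TIFF", {
  sv <- simulate_volume(dim_vox = c(32, 32, 8), seed = 6,
                        noise_gauss_sd = 0, shot_noise = FALSE)
  path <- tempfile(fileext = ".tif")
  write_volume(sv$stack, path)
  back <- read_volume(path)
  expect_identical(names(back$channels), names(sv$stack$channels))
  expect_equal(back$voxel_um, sv$stack$voxel_um)
  ## 16-bit quantization: intensities preserved to ~1 part in 2^16 of range
  mx <- max(sapply(sv$stack$channels, max))
  expect_lt(max(abs(back$channels$WGA - sv$stack$channels$WGA)), mx / 2^15)
})

test_that("unknown channels in the pipeline are refused", {
  sv <- simulate_volume(dim_vox = c(32, 32, 8), seed = 7)
  st <- sv$stack
  names(st$channels)[1] <- "WRONG"
  expect_error(segment_stack(st), "must contain channels")
})
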