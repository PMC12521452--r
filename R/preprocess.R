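# Multi-modal preprocessing: the 4-channel network input (HU passthrough,
# Canny edge map, 3-D Gaussian denoising, windowed GLCM contrast), adaptive
# intensity windowing, and training-time augmentation.

# internal: min-max rescale to [0, 1]; constant input maps to 0
rescale01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(array(0, dim(x)))
  (x - r[1]) / (r[2] - r[1])
}

# internal: 1-D truncated Gaussian kernel of odd length, normalized
gauss_kernel1 <- function(len, sigma) {
  r <- (len - 1L) / 2L
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# internal: 2-D Canny on one axial slice (already rescaled to [0,1])
canny2d <- function(img, sigma, low, high) {
  nr <- nrow(img); nc <- ncol(img)
  rad <- max(1L, ceiling(3 * sigma))
  k <- gauss_kernel1(2L * rad + 1L, sigma)
  d3 <- c(nr, nc, 1L)
  sm <- convaxis3(as.numeric(img), d3, k, 0L)
  sm <- convaxis3(sm, d3, k, 1L)
  # Sobel gradients (separable smooth [1 2 1] x derivative [-1 0 1] / 8)
  gx <- convaxis3(convaxis3(sm, d3, c(-1, 0, 1) / 2, 0L), d3, c(1, 2, 1) / 4, 1L)
  gy <- convaxis3(convaxis3(sm, d3, c(1, 2, 1) / 4, 0L), d3, c(-1, 0, 1) / 2, 1L)
  gx <- matrix(gx, nr, nc); gy <- matrix(gy, nr, nc)
  mag <- sqrt(gx^2 + gy^2)
  # non-maximum suppression: quantize gradient direction to 4 bins
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  bin <- findInterval(ang, c(pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8)) %% 4L
  shift2 <- function(m, di, dj) {
    out <- matrix(0, nr, nc)
    ri <- seq_len(nr); rj <- seq_len(nc)
    si <- ri + di; sj <- rj + dj
    ok_i <- si >= 1L & si <= nr; ok_j <- sj >= 1L & sj <= nc
    out[ri[ok_i], rj[ok_j]] <- m[si[ok_i], sj[ok_j]]
    out
  }
  # neighbor offsets per direction bin: 0 => +x (rows), 1 => diag, 2 => +y, 3 => anti-diag
  offs <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  keep <- matrix(FALSE, nr, nc)
  for (b in 0:3) {
    o <- offs[[b + 1L]]
    n1 <- shift2(mag, o[1], o[2]); n2 <- shift2(mag, -o[1], -o[2])
    sel <- bin == b & mag >= n1 & mag >= n2
    keep <- keep | sel
  }
  thin <- mag * keep
  strong <- thin > high
  weak <- thin > low
  if (!any(strong)) return(matrix(0L, nr, nc))
  hysteresis2(weak, strong)
}

#' Canny edge channel
#'
#' Computes a binary edge map from a CT volume: intensities are min-max
#' rescaled to \[0, 1\], then 2-D Canny edge detection (Gaussian smoothing,
#' Sobel gradients, non-maximum suppression, hysteresis) is applied slice by
#' slice along the axial (z) axis and restacked. Slice-wise application
#' reflects the strong in-plane/through-plane anisotropy of 3 mm slices.
#'
#' @param volume A [ct_volume()].
#' @param sigma Gaussian smoothing scale in pixels (default 1.5).
#' @param low,high Hysteresis thresholds on the gradient magnitude of the
#'   rescaled image (defaults 0.1 and 0.2); `high >= low > 0`.
#' @return 3-D array of 0/1 edge labels, same shape as the input.
#' @export
edge_channel <- function(volume, sigma = 1.5, low = 0.1, high = 0.2) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!(high >= low && low > 0))
    stop_mk("need high >= low > 0 for hysteresis thresholds",
            class = "mkunet_validation_error")
  v <- rescale01(volume$voxels)
  out <- array(0L, dim(v))
  for (z in seq_len(dim(v)[3])) out[, , z] <- canny2d(v[, , z], sigma, low, high)
  out
}

#' 3-D Gaussian denoising channel
#'
#' Smooths the volume with a normalized truncated Gaussian kernel, applied
#' separably along the three axes with edge-replication padding; the
#' separable product equals the normalized 3-D product kernel.
#'
#' @param volume A [ct_volume()].
#' @param kernel Odd cubic kernel size in voxels (default 3).
#' @param sigma Gaussian scale in voxels (default 0.8).
#' @return Smoothed 3-D array, same shape.
#' @export
denoise_channel <- function(volume, kernel = 3L, sigma = 0.8) {
  stopifnot(inherits(volume, "ct_volume"))
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop_mk("kernel size must be odd and >= 1", class = "mkunet_validation_error")
  d <- dim(volume$voxels)
  k <- gauss_kernel1(kernel, sigma)
  out <- as.numeric(volume$voxels)
  for (ax in 0:2) out <- convaxis3(out, d, k, ax)
  array(out, d)
}

# internal: cumulative-sum box sums of a 3-D array along one axis,
# window of `w` consecutive elements ending alignment handled by caller
boxsum_axis <- function(x, w, axis) {
  d <- dim(x)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, dp[1], dp[2] * dp[3])
  cs <- apply(m, 2, cumsum)
  n_out <- dp[1] - w + 1L
  top <- cs[seq(w, dp[1]), , drop = FALSE]
  bot <- rbind(0, cs)[seq_len(n_out), , drop = FALSE]
  res <- array(top - bot, c(n_out, dp[2], dp[3]))
  aperm(res, order(perm))
}

#' Windowed GLCM contrast channel
#'
#' Intensities are linearly rescaled to \[0, 255\] and quantized into
#' `levels` gray levels; within a sliding cubic window around each voxel a
#' symmetric, normalized gray-level co-occurrence matrix over the three unit
#' axis offsets is summarized by its contrast \eqn{\sum_{ij} P(i,j)(i-j)^2},
#' averaged over the offsets. Borders are handled by edge-replication
#' padding. Internally the per-window matrix is never materialized: contrast
#' equals the normalized sum of squared level differences over co-occurring
#' pairs, computed with cumulative-sum box filters (algebraically identical).
#'
#' @param volume A [ct_volume()].
#' @param window Odd cubic window size in voxels (default 5).
#' @param levels Number of gray levels after quantization (default 32).
#' @return 3-D non-negative contrast map, same shape.
#' @export
glcm_contrast_channel <- function(volume, window = 5L, levels = 32L) {
  stopifnot(inherits(volume, "ct_volume"))
  window <- as.integer(window); levels <- as.integer(levels)
  if (window %% 2L == 0L || window < 3L)
    stop_mk("window must be odd and >= 3", class = "mkunet_validation_error")
  d <- dim(volume$voxels)
  if (any(window > d))
    stop_mk("window (", window, ") larger than volume (",
            paste(d, collapse = "x"), ")", class = "mkunet_validation_error")
  x255 <- rescale01(volume$voxels) * 255
  q <- pmin(floor(x255 / (256 / levels)), levels - 1L)
  r <- (window - 1L) %/% 2L
  # replicate-pad by r on all sides
  ix <- pmin(pmax(seq_len(d[1] + 2L * r) - r, 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2] + 2L * r) - r, 1L), d[2])
  iz <- pmin(pmax(seq_len(d[3] + 2L * r) - r, 1L), d[3])
  p <- q[ix, iy, iz]
  w <- window
  acc <- array(0, d)
  for (axis in 1:3) {
    dp <- dim(p)
    # squared level difference of each unit-offset pair along `axis`
    if (axis == 1) dd <- (p[-1, , , drop = FALSE] - p[-dp[1], , , drop = FALSE])^2
    if (axis == 2) dd <- (p[, -1, , drop = FALSE] - p[, -dp[2], , drop = FALSE])^2
    if (axis == 3) dd <- (p[, , -1, drop = FALSE] - p[, , -dp[3], drop = FALSE])^2
    # sum over pairs fully inside each w^3 window: w-1 positions along the
    # offset axis, w along the others
    s <- dd
    for (ax2 in 1:3) s <- boxsum_axis(s, if (ax2 == axis) w - 1L else w, ax2)
    acc <- acc + s / (w * w * (w - 1L))
  }
  acc / 3
}

#' Build the 4-channel network input
#'
#' Stacks, in fixed order: (1) raw HU passthrough, (2) Canny edge map,
#' (3) Gaussian-denoised volume, (4) windowed GLCM contrast.
#'
#' @param volume A [ct_volume()].
#' @param edge_args,denoise_args,glcm_args Named lists of parameter overrides
#'   for the channel builders.
#' @return An object of class `multichannel_volume` with fields `channels`
#'   (4-D array, channel-last) and `spacing`.
#' @export
build_multichannel <- function(volume, edge_args = list(), denoise_args = list(),
                               glcm_args = list()) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  ch <- array(0, c(d, 4L))
  ch[, , , 1] <- volume$voxels
  ch[, , , 2] <- do.call(edge_channel, c(list(volume), edge_args))
  ch[, , , 3] <- do.call(denoise_channel, c(list(volume), denoise_args))
  ch[, , , 4] <- do.call(glcm_contrast_channel, c(list(volume), glcm_args))
  structure(list(channels = ch, spacing = volume$spacing,
                 time_days = volume$time_days, patient_id = volume$patient_id),
            class = "multichannel_volume")
}

#' @export
print.multichannel_volume <- function(x, ...) {
  cat(sprintf("<multichannel_volume> grid %s  4 channels (HU, edge, denoised, contrast)\n",
              paste(dim(x$channels)[1:3], collapse = "x")))
  invisible(x)
}

#' Adaptive intensity windowing
#'
#' Masks out low-intensity voxels using a threshold parameterized by the mean
#' and standard deviation of tumor-voxel intensities within the ROI. In the
#' default `"lower"` mode the threshold is \eqn{\mu - k\sigma}, which removes
#' background (air, aerated lung) while retaining tumor texture; in
#' `"literal"` mode the threshold is \eqn{\mu + k\sigma}, which retains only
#' the upper intensity tail of the tumor (about \eqn{1 - \Phi(k)} of roughly
#' Gaussian tumor voxels) and is provided for comparison. Masked voxels are
#' set to the sentinel value (-1024 HU, the air floor). The mode, threshold
#' and tumor statistics are recorded in the output's `windowing` attribute.
#'
#' @param volume A [ct_volume()].
#' @param roi A non-empty [seg_mask()] on the same grid (the tumor ROI).
#' @param k Threshold multiplier (default 1.5).
#' @param mode `"lower"` (default) or `"literal"`.
#' @param sentinel Replacement value for masked voxels (default -1024 HU).
#' @return A [ct_volume()] with sub-threshold voxels set to `sentinel`.
#' @export
adaptive_window <- function(volume, roi, k = 1.5, mode = c("lower", "literal"),
                            sentinel = -1024) {
  stopifnot(inherits(volume, "ct_volume"), inherits(roi, "seg_mask"))
  mode <- match.arg(mode)
  check_same_grid(volume, roi)
  if (k <= 0) stop_mk("k must be > 0", class = "mkunet_validation_error")
  inside <- roi$voxels == 1L
  if (!any(inside))
    stop_mk("ROI is empty; cannot estimate tumor intensity statistics",
            class = "mkunet_validation_error")
  mu <- mean(volume$voxels[inside])
  sig <- stats::sd(volume$voxels[inside])
  if (is.na(sig)) sig <- 0
  thr <- if (mode == "lower") mu - k * sig else mu + k * sig
  vox <- volume$voxels
  vox[vox < thr] <- sentinel
  out <- ct_volume(vox, volume$spacing, volume$time_days, volume$patient_id)
  attr(out, "windowing") <- list(mu_tumor = mu, sigma_tumor = sig, k = k,
                                 mode = mode, threshold = thr, sentinel = sentinel)
  out
}

#' Augmentation configuration
#'
#' @param rotation Max absolute in-plane rotation in degrees (default 10).
#' @param scale_range Isotropic scale factor range (default `c(0.9, 1.1)`).
#' @param translation Max absolute translation per axis in voxels (default 5).
#' @param noise_sd Additive Gaussian noise sd in HU, applied to intensity
#'   channels only (default 10).
#' @param seed Integer seed fixing the full augmentation stream.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation = 10, scale_range = c(0.9, 1.1),
                                translation = 5, noise_sd = 10, seed = 1L) {
  if (rotation < 0 || translation < 0 || noise_sd < 0 ||
      any(scale_range <= 0) || scale_range[2] < scale_range[1])
    stop_mk("augmentation ranges must be non-negative and ordered",
            class = "mkunet_validation_error")
  structure(list(rotation = rotation, scale_range = as.numeric(scale_range),
                 translation = translation, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Random geometric + noise augmentation
#'
#' Samples one in-plane rotation, isotropic scale and 3-D translation and
#' applies the identical transform to every channel (trilinear interpolation)
#' and to the mask (nearest neighbor); Gaussian noise is then added to the
#' intensity channels (HU and denoised) only. The whole stream is a
#' deterministic function of `cfg$seed`.
#'
#' @param mcv A `multichannel_volume`.
#' @param mask The paired [seg_mask()].
#' @param cfg An [augmentation_config()].
#' @return List with elements `mcv` and `mask`.
#' @export
augment <- function(mcv, mask, cfg = augmentation_config()) {
  stopifnot(inherits(mcv, "multichannel_volume"), inherits(mask, "seg_mask"),
            inherits(cfg, "augmentation_config"))
  d <- dim(mcv$channels)[1:3]
  if (!identical(dim(mask$voxels), d))
    stop_mk("mask grid does not match channels", class = "mkunet_grid_error")
  set.seed(cfg$seed)
  theta <- runif(1, -cfg$rotation, cfg$rotation) * pi / 180
  s <- runif(1, cfg$scale_range[1], cfg$scale_range[2])
  tr <- runif(3, -cfg$translation, cfg$translation)
  # forward map: y = s * Rz(theta) (x - c) + c + tr ; resampling needs inverse
  ct <- (d - 1) / 2
  Rz <- matrix(c(cos(theta), sin(theta), 0,
                 -sin(theta), cos(theta), 0,
                 0, 0, 1), 3, 3)
  A <- t(Rz) / s # inverse: (1/s) Rz(-theta)
  shift <- as.numeric(ct - A %*% (ct + tr))
  identity_tf <- cfg$rotation == 0 && cfg$translation == 0 &&
    cfg$scale_range[1] == cfg$scale_range[2] && cfg$scale_range[1] == 1
  ch <- mcv$channels
  if (!identity_tf) {
    bg <- c(-1024, 0, -1024, 0) # HU floor for intensity channels, 0 otherwise
    for (ci in 1:4)
      ch[, , , ci] <- array(resample3(as.numeric(ch[, , , ci]), d, A, shift,
                                      FALSE, bg[ci]), d)
    mvox <- array(resample3(as.numeric(mask$voxels), d, A, shift, TRUE, 0), d)
  } else {
    mvox <- mask$voxels
  }
  if (cfg$noise_sd > 0) {
    nvox <- prod(d)
    ch[, , , 1] <- ch[, , , 1] + array(rnorm(nvox, 0, cfg$noise_sd), d)
    ch[, , , 3] <- ch[, , , 3] + array(rnorm(nvox, 0, cfg$noise_sd), d)
  }
  out <- mcv
  out$channels <- ch
  list(mcv = out, mask = seg_mask(mvox > 0.5, mask$spacing))
}
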