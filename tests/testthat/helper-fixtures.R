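# Shared fixtures: geometric masks and independent brute-force oracles.
# Oracles here deliberately use different code paths (R shifts, outer
# distance tables, explicit co-occurrence counting) from the implementation.

ball_mask <- function(r_mm, n = 2 * r_mm + 9, spacing = c(1, 1, 1)) {
  ctr <- (n - 1) / 2
  idx <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  inside <- (idx$x - ctr)^2 * spacing[1]^2 + (idx$y - ctr)^2 * spacing[2]^2 +
    (idx$z - ctr)^2 * spacing[3]^2 <= r_mm^2
  seg_mask(array(inside, c(n, n, n)), spacing)
}

cube_mask <- function(side, margin = 4L, spacing = c(1, 1, 1)) {
  n <- side + 2L * margin
  sel <- seq_len(n) %in% (margin + seq_len(side))
  seg_mask(array(outer(outer(sel, sel), sel), c(n, n, n)), spacing)
}

# random non-empty blobby mask (thresholded smoothed noise)
random_mask <- function(n = 10L, spacing = c(1, 1, 1)) {
  repeat {
    raw <- array(rnorm(n^3), c(n, n, n))
    v <- ct_volume(raw, spacing)
    sm <- denoise_channel(v, kernel = 3, sigma = 1)
    m <- sm > quantile(sm, 0.7)
    if (sum(m) > 0) return(seg_mask(m, spacing))
  }
}

# brute-force overlap oracles by explicit voxel counting
oracle_dice <- function(a, b) {
  av <- a$voxels == 1L; bv <- b$voxels == 1L
  2 * sum(av & bv) / (sum(av) + sum(bv))
}
oracle_iou <- function(a, b) {
  av <- a$voxels == 1L; bv <- b$voxels == 1L
  sum(av & bv) / sum(av | bv)
}

# brute-force HD95: surfaces by 6-neighbor shifts, all-pairs distance table
oracle_surface <- function(m) {
  v <- m$voxels == 1L
  d <- dim(v)
  pad <- array(FALSE, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- v
  has_bg_nbr <- array(FALSE, d)
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    nb <- pad[seq_len(d[1]) + 1 + off[1], seq_len(d[2]) + 1 + off[2],
              seq_len(d[3]) + 1 + off[3]]
    has_bg_nbr <- has_bg_nbr | !nb
  }
  which(v & has_bg_nbr, arr.ind = TRUE)
}

oracle_hd <- function(a, b, spacing, prob = 0.95) {
  sa <- oracle_surface(a); sb <- oracle_surface(b)
  pa <- sweep(sa - 1, 2, spacing, `*`); pb <- sweep(sb - 1, 2, spacing, `*`)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  dd <- sqrt(d2)
  dab <- apply(dd, 1, min); dba <- apply(dd, 2, min)
  unname(quantile(c(dab, dba), prob, type = 7))
}

# 6-neighborhood morphological erosion / dilation (test-side implementation)
morph6 <- function(v, dilate = TRUE) {
  d <- dim(v)
  pad <- array(!dilate, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- v
  out <- v
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    nb <- pad[seq_len(d[1]) + 1 + off[1], seq_len(d[2]) + 1 + off[2],
              seq_len(d[3]) + 1 + off[3]]
    out <- if (dilate) out | nb else out & nb
  }
  out
}

# small training fixture shared by the training tests
fixture_phantom_sample <- function(seed, radius = 8, growth = 0, spic = 0L) {
  ph <- generate_phantom(phantom_spec(shape = c(48L, 48L, 32L), base_radius = radius,
                                      growth_rate = growth, scan_times = c(0, 5, 10),
                                      n_spiculations = spic, spiculation_length = 4,
                                      seed = seed),
                         patient_id = sprintf("fix%03d", seed))
  phantom_training_sample(ph, 1L, crop = 32L)
}
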