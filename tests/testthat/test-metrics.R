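test_that("Dice and IoU closed-form cases", {
  a <- array(0L, c(8, 8, 8)); b <- a
  a[2:5, 2, 2] <- 1L                     # |A| = 4
  b[4:7, 2, 2] <- 1L                     # |B| = 4, overlap 2
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(iou(a, a), 1)
  disj <- array(0L, c(8, 8, 8)); disj[8, 8, 8] <- 1L
  expect_equal(dice_coefficient(a, disj), 0)
  expect_equal(iou(a, disj), 0)
  empty <- array(0L, c(8, 8, 8))
  de <- dice_coefficient(empty, empty)
  expect_equal(as.numeric(de), 1)
  expect_true(isTRUE(attr(de, "degenerate")))
  expect_error(dice_coefficient(a, array(0L, c(4, 4, 4))), class = "mkunet_grid_error")
})

test_that("losses match closed forms", {
  t <- array(0L, c(8, 8, 8)); t[1:4, , ] <- 1L     # half the volume
  perfect <- array(as.numeric(t), dim(t))
  expect_lt(dice_loss(perfect, t), 1e-6)
  expect_lt(bce_loss(perfect, t), 1e-6)
  expect_lt(hybrid_loss(perfect, t), 1e-6)
  miss <- array(0, dim(t))
  expect_gt(dice_loss(miss, t), 0.99)
  half <- array(0.5, dim(t))
  expect_equal(bce_loss(half, t), log(2), tolerance = 1e-9)
  # soft-Dice algebraic oracle for p = 0.5 everywhere, |T| = N/2
  N <- length(t); Tn <- sum(t)
  expect_equal(dice_loss(half, t, eps = 1),
               1 - (2 * 0.5 * Tn + 1) / (0.5 * N + Tn + 1), tolerance = 1e-12)
  one_vox <- array(0.25, c(1, 1, 1))
  expect_equal(bce_loss(one_vox, array(1L, c(1, 1, 1))), -log(0.25), tolerance = 1e-9)
})

test_that("hybrid loss recovers its printed weights from component isolation", {
  # components: dice_loss = 1 (total miss, large mask so eps is negligible),
  # bce ~ 0  =>  hybrid ~ lambda1
  t <- array(1L, c(20, 20, 20))
  p_miss <- array(1e-12, dim(t))
  expect_equal(dice_loss(p_miss, t), 1, tolerance = 1e-3)
  l1 <- hybrid_loss(p_miss, t) - loss_weights()$lambda2 * bce_loss(p_miss, t)
  expect_equal(l1, 0.6, tolerance = 1e-3)
  # dice_loss ~ 0, bce = 1 via y=1, p = exp(-1)
  p_e <- array(exp(-1), dim(t))
  expect_equal(bce_loss(p_e, t), 1, tolerance = 1e-9)
  l2 <- hybrid_loss(p_e, t) - loss_weights()$lambda1 * dice_loss(p_e, t)
  expect_equal(l2, 0.4, tolerance = 1e-9)
})

test_that("HD95 closed-form cases in physical units", {
  a <- ball_mask(4, 16)
  expect_equal(hd95(a, a), 0)
  m1 <- seg_mask(array(0L, c(9, 9, 9)), c(1, 1, 1)); m2 <- m1
  m1$voxels[3, 3, 3] <- 1L; m2$voxels[6, 3, 3] <- 1L
  expect_equal(hd95(m1, m2), 3)
  m3 <- seg_mask(array(0L, c(6, 6, 6)), c(0.6, 0.6, 3.0)); m4 <- m3
  m3$voxels[3, 3, 3] <- 1L; m4$voxels[3, 3, 4] <- 1L
  expect_equal(hd95(m3, m4), 3.0)
  # empty mask -> undefined with flag
  h <- hd95(m1, seg_mask(array(0L, c(9, 9, 9)), c(1, 1, 1)))
  expect_true(is.na(h) && isTRUE(attr(h, "undefined")))
})

test_that("metrics agree with brute-force oracles on random masks", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(6:12, 1)
    sp <- sample(list(c(1, 1, 1), c(0.6, 0.6, 3.0), c(2, 1, 1)), 1)[[1]]
    a <- random_mask(n, sp); b <- random_mask(n, sp)
    expect_equal(as.numeric(dice_coefficient(a, b)), oracle_dice(a, b), tolerance = 1e-9)
    expect_equal(as.numeric(iou(a, b)), oracle_iou(a, b), tolerance = 1e-9)
    expect_equal(hd95(a, b), oracle_hd(a, b, sp), tolerance = 1e-9)
    # per-case Dice/IoU identity and hd95 symmetry + bound by exact Hausdorff
    io <- as.numeric(iou(a, b))
    expect_equal(as.numeric(dice_coefficient(a, b)), 2 * io / (1 + io), tolerance = 1e-12)
    expect_equal(hd95(a, b), hd95(b, a), tolerance = 1e-12)
    expect_lte(hd95(a, b), hd95(a, b, prob = 1) + 1e-12)
    # dice_loss + dice_coefficient = 1 on binary inputs (eps = 0)
    expect_equal(dice_loss(array(as.numeric(a$voxels), dim(a$voxels)), b, eps = 0) +
                   as.numeric(dice_coefficient(a, b)), 1, tolerance = 1e-12)
  }
})

test_that("case evaluation aggregates overall and by LVCR stratum", {
  a <- ball_mask(4, 14)
  b <- seg_mask(morph6(a$voxels == 1L, dilate = TRUE), a$spacing)
  pairs <- list(
    list(pred = a, truth = a, lvcr = 0.2, id = "hi1"),
    list(pred = b, truth = a, lvcr = 0.3, id = "hi2"),
    list(pred = a, truth = a, lvcr = 0.05, id = "lo1"),
    list(pred = b, truth = a, lvcr = 0.01, id = "lo2"))
  rep_ <- evaluate_cases(pairs)
  expect_s3_class(rep_, "metric_report")
  expect_identical(rep_$cases$stratum, c("high", "high", "low", "low"))
  agg <- rep_$aggregate
  hi <- agg[agg$stratum == "high", ]
  d_hi <- rep_$cases$dice[1:2]
  expect_equal(hi$dice_mean, mean(d_hi), tolerance = 1e-12)
  expect_equal(hi$dice_sd, sd(d_hi), tolerance = 1e-12)
  # perfect predictions -> dice 1, hd95 0, sd 0
  perf <- evaluate_cases(list(list(pred = a, truth = a)))
  expect_equal(perf$aggregate$dice_mean, 1)
  expect_equal(perf$aggregate$hd95_mean, 0)
  expect_equal(perf$aggregate$dice_sd, 0)
  expect_error(evaluate_cases(list()), class = "mkunet_validation_error")
})
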