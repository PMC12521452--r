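test_that("clinical encoding normalizes every slot into [0, 1]", {
  r <- clinical_record(50, "male", "former", 2, "I", 0.1)
  v <- encode_clinical(r)
  expect_length(v, 6)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(unname(v["age"]), 0.5)
  expect_equal(unname(v["stage"]), 0.25)
  expect_equal(unname(encode_clinical(clinical_record(50, "male", "former", 2, "IV", 0.1))["stage"]), 1.0)
  expect_equal(unname(v["lvcr"]), (0.1 + 0.05) / 0.35)
  expect_error(clinical_record(50, "unknown", "never", 1, "I", 0),
               class = "mkunet_vocabulary_error")
  expect_error(clinical_record(150, "male", "never", 1, "I", 0),
               class = "mkunet_validation_error")
})

test_that("attention gate closed forms: zero weights, saturation, determinism", {
  set.seed(60)
  d <- c(4L, 4L, 2L, 3L)
  fe <- array(rnorm(prod(d)), d)
  fd <- array(rnorm(prod(d)), d)
  p0 <- attention_gate_params(rep(0, 3), rep(0, 3), b = 0)
  g0 <- attention_gate(fe, fd, p0)
  expect_equal(attr(g0, "alpha"), array(0.5, d[1:3]), tolerance = 1e-12)
  expect_equal(as.numeric(g0), as.numeric(fe) / 2, tolerance = 1e-12)
  psat <- attention_gate_params(rep(0, 3), rep(0, 3), b = 40)
  gsat <- attention_gate(fe, fd, psat)
  expect_equal(as.numeric(gsat), as.numeric(fe), tolerance = 1e-12)
  pr <- attention_gate_params(rnorm(3), rnorm(3), rnorm(1))
  expect_identical(attention_gate(fe, fd, pr), attention_gate(fe, fd, pr))
  expect_true(all(attr(attention_gate(fe, fd, pr), "alpha") > 0 &
                    attr(attention_gate(fe, fd, pr), "alpha") < 1))
  expect_error(attention_gate(fe, array(0, c(2, 2, 2, 3)), pr),
               class = "mkunet_dim_error")
})

test_that("IAAG reduces to the plain gate at zero LVCR weight and is monotone", {
  set.seed(61)
  d <- c(4L, 4L, 4L, 5L)
  fe <- array(rnorm(prod(d)), d)
  fd <- array(rnorm(prod(d)), d)
  w_e <- rnorm(5); w_d <- rnorm(5); b <- rnorm(1)
  plain <- attention_gate(fe, fd, attention_gate_params(w_e, w_d, b))
  zero_w <- iaag(fe, fd, 0.7, attention_gate_params(w_e, w_d, b, w_lvcr = 0))
  expect_equal(attr(zero_w, "alpha"), attr(plain, "alpha"), tolerance = 1e-12)
  # zero LVCR value with any weight also matches the plain gate
  zero_v <- iaag(fe, fd, 0, attention_gate_params(w_e, w_d, b, w_lvcr = 2.3))
  expect_equal(attr(zero_v, "alpha"), attr(plain, "alpha"), tolerance = 1e-12)
  # alpha is non-decreasing in the LVCR value everywhere under positive weight
  pp <- attention_gate_params(w_e, w_d, b, w_lvcr = 1.4)
  lv <- seq(0, 1, by = 0.25)
  alphas <- vapply(lv, function(l) attr(iaag(fe, fd, l, pp), "alpha"),
                   array(0, d[1:3]))
  diffs <- apply(alphas, c(1, 2, 3), diff)
  expect_true(all(diffs > 0))
  expect_error(iaag(fe, fd, 0.5, attention_gate_params(w_e, w_d, b)),
               class = "mkunet_validation_error")
})

test_that("forward pass honors shape, range and seeded determinism", {
  cfg <- model_config(in_channels = 4, base_channels = 4, seed = 3)
  m <- build_model(cfg)
  set.seed(62)
  x <- array(runif(32 * 32 * 16 * 4), c(32, 32, 16, 4))
  cl <- runif(6)
  p <- model_forward(m, x, cl)$prob
  expect_identical(dim(p), c(32L, 32L, 16L))
  expect_true(all(p > 0 & p < 1))
  m2 <- build_model(cfg)
  expect_identical(m$params, m2$params)
  expect_identical(p, model_forward(m2, x, cl)$prob)
  m3 <- build_model(model_config(in_channels = 4, base_channels = 4, seed = 4))
  expect_false(identical(m$params, m3$params))
  # dims not divisible by 2^depth are rejected
  expect_error(model_forward(m, array(0.5, c(30, 32, 16, 4)), cl),
               class = "mkunet_validation_error")
})

test_that("default configuration lands in the expected parameter band", {
  m <- build_model(model_config())
  expect_equal(m$cfg$bottleneck_channels, 256L)
  n <- count_params(m)
  expect_gte(n, 20e6)
  expect_lte(n, 40e6)
})

test_that("ablation toggles add exactly their own parameter groups", {
  base <- build_model(model_config(base_channels = 4, attention = FALSE,
                                   knowledge_fusion = FALSE, iaag = FALSE))
  att <- build_model(model_config(base_channels = 4, attention = TRUE,
                                  knowledge_fusion = FALSE, iaag = FALSE))
  fus <- build_model(model_config(base_channels = 4, attention = TRUE,
                                  knowledge_fusion = TRUE, iaag = FALSE))
  full <- build_model(model_config(base_channels = 4))
  flat_names <- function(m) {
    out <- character(0)
    rec <- function(x, pre) {
      if (is.list(x)) for (nm in names(x)) rec(x[[nm]], paste0(pre, "$", nm))
      else out <<- c(out, pre)
    }
    rec(m$params, "")
    sort(out)
  }
  nb <- flat_names(base); na <- flat_names(att); nf <- flat_names(fus); nfu <- flat_names(full)
  expect_true(all(grepl("gate", setdiff(na, nb))))      # +attention adds only gates
  expect_identical(setdiff(nf, na), c("$fusion$W", "$fusion$b"))
  expect_true(all(grepl("w_lvcr", setdiff(nfu, nf))))   # +iaag adds only LVCR weights
  # with fusion and iaag off the encoder/decoder conv parameters are identical
  # in shape to the attention-gated baseline
  expect_identical(lapply(att$params$enc, lapply, dim),
                   lapply(full$params$enc, lapply, dim))
  expect_error(model_config(attention = FALSE, iaag = TRUE),
               class = "mkunet_validation_error")
})

test_that("prediction crops, thresholds and re-embeds on the input grid", {
  ph <- generate_phantom(phantom_spec(shape = c(48L, 48L, 32L), base_radius = 8,
                                      scan_times = 0, seed = 5))
  mc <- build_multichannel(ph$scans[[1]]$volume)
  cl <- encode_clinical(ph$clinical)
  m <- build_model(model_config(base_channels = 2, seed = 1))
  pm <- predict_mask(m, mc, cl, roi_box = c(9, 40, 9, 40, 5, 28))
  expect_identical(dim(pm$voxels), c(48L, 48L, 32L))
  expect_equal(sum(pm$voxels[1:8, , ]), 0)   # nothing outside the box
  # threshold 0 fills the whole processed crop; the 24-deep box grows to the
  # next multiple of 2^depth (32) inside the grid before inference
  p0 <- predict_mask(m, mc, cl, roi_box = c(9, 40, 9, 40, 5, 28), threshold = 0)
  expect_equal(sum(p0$voxels), 32 * 32 * 32)
  p1 <- predict_mask(m, mc, cl, threshold = 1)
  expect_equal(sum(p1$voxels), 0)
  # a strongly negative output bias drives the mask empty
  mneg <- m
  mneg$params$final$b <- -50
  expect_equal(sum(predict_mask(mneg, mc, cl)$voxels), 0)
  expect_error(predict_mask(m, mc, cl, roi_box = c(0, 49, 1, 48, 1, 32)),
               class = "mkunet_validation_error")
})
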