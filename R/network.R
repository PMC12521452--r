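# The segmentation network: a 4-level 3-D encoder-decoder with
# attention-gated skip connections, clinical-vector fusion at the 256-channel
# bottleneck, and LVCR-conditioned immune-aware attention gates (IAAG).
#
# No deep-learning framework is used: convolutions are im2col (C++) plus
# BLAS matrix multiplies, with hand-written backward passes. Feature maps are
# held as (n_voxels x channels) matrices in column-major voxel order, so
# as.numeric(m) is exactly the (x, y, z, channel) array layout the C++
# kernels expect.

# ---- clinical encoding ------------------------------------------------------

.genders <- c("female", "male")
.smoking <- c("never", "former", "current")
.stages <- c("I", "II", "III", "IV")
.max_grade <- 3L

#' Construct a clinical record
#'
#' The six clinical/biomarker fields fused into the network: age, gender,
#' smoking history, pathological grade, tumor stage and LVCR (log volume
#' change rate, 1/day).
#'
#' @param age Age in years, in \[0, 120\].
#' @param gender `"female"` or `"male"`.
#' @param smoking_history `"never"`, `"former"` or `"current"`.
#' @param pathological_grade Ordinal grade 1..3.
#' @param tumor_stage `"I"`, `"II"`, `"III"` or `"IV"` (or 1..4).
#' @param lvcr LVCR in 1/day (finite).
#' @return An object of class `clinical_record`.
#' @export
clinical_record <- function(age, gender, smoking_history, pathological_grade,
                            tumor_stage, lvcr) {
  if (!is.numeric(age) || age < 0 || age > 120)
    stop_mk("age must be in [0, 120]", class = "mkunet_validation_error")
  if (!gender %in% .genders)
    stop_mk("unknown gender '", gender, "' (expected ",
            paste(.genders, collapse = "/"), ")", class = "mkunet_vocabulary_error")
  if (!smoking_history %in% .smoking)
    stop_mk("unknown smoking_history '", smoking_history, "'",
            class = "mkunet_vocabulary_error")
  pathological_grade <- as.integer(pathological_grade)
  if (!pathological_grade %in% seq_len(.max_grade))
    stop_mk("pathological_grade must be 1..", .max_grade,
            class = "mkunet_vocabulary_error")
  if (is.numeric(tumor_stage)) tumor_stage <- .stages[tumor_stage]
  if (!tumor_stage %in% .stages)
    stop_mk("unknown tumor_stage (expected I..IV)", class = "mkunet_vocabulary_error")
  if (!is.finite(lvcr))
    stop_mk("lvcr must be finite", class = "mkunet_validation_error")
  structure(list(age = age, gender = gender, smoking_history = smoking_history,
                 pathological_grade = pathological_grade, tumor_stage = tumor_stage,
                 lvcr = lvcr),
            class = "clinical_record")
}

#' Encode a clinical record as a 6-D vector in \[0, 1\]
#'
#' Slots, in order: age/100 (clipped), gender (male = 1), smoking history
#' (ever-smoker = 1), pathological grade rank/3, tumor stage rank/4 (stage I
#' = 0.25, IV = 1), and LVCR min-max normalized over \[-0.05, 0.30\] 1/day
#' (see [normalize_lvcr()]). The LVCR slot is last (slot 6) and is the value
#' consumed by the immune-aware attention gates.
#'
#' @param record A [clinical_record()].
#' @return Named numeric vector of length 6, all entries in \[0, 1\].
#' @export
encode_clinical <- function(record) {
  stopifnot(inherits(record, "clinical_record"))
  c(age = min(max(record$age / 100, 0), 1),
    gender = as.numeric(record$gender == "male"),
    smoking = as.numeric(record$smoking_history != "never"),
    grade = record$pathological_grade / .max_grade,
    stage = match(record$tumor_stage, .stages) / length(.stages),
    lvcr = normalize_lvcr(record$lvcr))
}

# ---- standalone attention gates --------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Attention-gate parameters
#'
#' A single learnable linear map over the concatenated encoder features,
#' decoder gating features and (for IAAG) a broadcast LVCR channel, followed
#' by a sigmoid: \eqn{\alpha = \sigma(W_\theta [f_{enc}, f_{dec}, LVCR] + b_\theta)},
#' one attention value per spatial location.
#'
#' @param w_enc Weights over encoder channels.
#' @param w_dec Weights over decoder gating channels.
#' @param b Scalar bias.
#' @param w_lvcr Optional scalar weight of the LVCR channel (IAAG).
#' @return An object of class `attention_gate_params`.
#' @export
attention_gate_params <- function(w_enc, w_dec, b = 0, w_lvcr = NULL) {
  structure(list(w_enc = as.numeric(w_enc), w_dec = as.numeric(w_dec),
                 b = as.numeric(b),
                 w_lvcr = if (is.null(w_lvcr)) NULL else as.numeric(w_lvcr)),
            class = "attention_gate_params")
}

gate_alpha <- function(fe, fd, params, lvcr_value = NULL) {
  z <- fe %*% params$w_enc + fd %*% params$w_dec + params$b
  if (!is.null(params$w_lvcr) && !is.null(lvcr_value))
    z <- z + params$w_lvcr * lvcr_value
  sigmoid(as.numeric(z))
}

#' Apply an attention gate to encoder features
#'
#' Computes \eqn{\alpha \in (0,1)} per spatial location from the encoder
#' features and the (already upsampled/projected) decoder gating features,
#' and returns \eqn{\alpha \odot f_{enc}}.
#'
#' @param f_enc 4-D array (x, y, z, channels) of encoder features.
#' @param f_dec 4-D array on the same spatial grid (gating features).
#' @param params An [attention_gate_params()].
#' @return Gated feature array, same shape as `f_enc`, with the attention map
#'   attached as attribute `alpha` (3-D array).
#' @export
attention_gate <- function(f_enc, f_dec, params) {
  stopifnot(inherits(params, "attention_gate_params"))
  de <- dim(f_enc); dd <- dim(f_dec)
  if (length(de) != 4L || length(dd) != 4L || !identical(de[1:3], dd[1:3]))
    stop_mk("f_enc and f_dec must be 4-D arrays on one spatial grid",
            class = "mkunet_dim_error")
  if (de[4] != length(params$w_enc) || dd[4] != length(params$w_dec))
    stop_mk("gate weight lengths do not match channel counts",
            class = "mkunet_dim_error")
  nvox <- prod(de[1:3])
  fe <- matrix(f_enc, nvox, de[4]); fd <- matrix(f_dec, nvox, dd[4])
  alpha <- gate_alpha(fe, fd, params)
  out <- array(fe * alpha, de)
  attr(out, "alpha") <- array(alpha, de[1:3])
  out
}

#' Immune-aware attention gate (IAAG)
#'
#' Identical to [attention_gate()] except that the normalized LVCR value is
#' broadcast as one constant extra channel concatenated to
#' \eqn{[f_{enc}, f_{dec}]} before the gate's linear map, so the attention
#' weights depend on both imaging patterns and growth kinetics. With a zero
#' LVCR-channel weight the gate reduces exactly to the plain attention gate.
#'
#' @inheritParams attention_gate
#' @param lvcr_value Normalized LVCR scalar (the clinical vector's slot 6).
#' @return Gated feature array with attribute `alpha`.
#' @export
iaag <- function(f_enc, f_dec, lvcr_value, params) {
  stopifnot(inherits(params, "attention_gate_params"))
  if (is.null(params$w_lvcr))
    stop_mk("IAAG parameters need w_lvcr", class = "mkunet_validation_error")
  de <- dim(f_enc); dd <- dim(f_dec)
  if (length(de) != 4L || length(dd) != 4L || !identical(de[1:3], dd[1:3]))
    stop_mk("f_enc and f_dec must be 4-D arrays on one spatial grid",
            class = "mkunet_dim_error")
  nvox <- prod(de[1:3])
  fe <- matrix(f_enc, nvox, de[4]); fd <- matrix(f_dec, nvox, dd[4])
  alpha <- gate_alpha(fe, fd, params, lvcr_value)
  out <- array(fe * alpha, de)
  attr(out, "alpha") <- array(alpha, de[1:3])
  out
}

# ---- model configuration and construction ----------------------------------

#' Network configuration
#'
#' Default schedule: 4 encoder levels with channels doubling
#' (32, 64, 128, 256), four 2x downsamplings, a bottleneck that widens to 512
#' internally and projects back to a 256-channel map where the spatially
#' expanded 6-D clinical vector is concatenated and fused by a 1x1x1
#' convolution. Input patch dimensions must be divisible by `2^depth`.
#'
#' @param in_channels Input channels (4 for the multi-channel stack, 1 for
#'   raw-HU ablation).
#' @param base_channels First-level channel count (default 32).
#' @param depth Number of downsampling blocks (default 4).
#' @param clinical_dim Clinical vector length (default 6).
#' @param attention Enable attention-gated skips (default `TRUE`).
#' @param knowledge_fusion Enable clinical-vector fusion at the bottleneck.
#' @param iaag Enable the LVCR channel inside every attention gate.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(in_channels = 4L, base_channels = 32L, depth = 4L,
                         clinical_dim = 6L, attention = TRUE,
                         knowledge_fusion = TRUE, iaag = TRUE, seed = 1L) {
  if (iaag && !attention)
    stop_mk("iaag requires attention gates", class = "mkunet_validation_error")
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 clinical_dim = as.integer(clinical_dim),
                 attention = isTRUE(attention),
                 knowledge_fusion = isTRUE(knowledge_fusion),
                 iaag = isTRUE(iaag),
                 bottleneck_channels = as.integer(base_channels * 2^(depth - 1L)),
                 seed = as.integer(seed)),
            class = "model_config")
}

he_init <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

#' Build the segmentation model
#'
#' Allocates and seeds all learnable parameters for the configured
#' architecture. The model maps a (x, y, z, channels) input patch plus a 6-D
#' clinical vector to a voxel-wise tumor probability map via a sigmoid
#' output layer.
#'
#' @param cfg A [model_config()].
#' @return An object of class `mk_model`.
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(cfg$seed)
  C <- cfg$base_channels
  chan <- C * 2^(seq_len(cfg$depth) - 1L) # encoder channels per level
  cb <- chan[cfg$depth]                   # bottleneck (fusion) channels
  p <- list(enc = vector("list", cfg$depth), dec = vector("list", cfg$depth))
  cin <- cfg$in_channels
  for (l in seq_len(cfg$depth)) {
    co <- chan[l]
    p$enc[[l]] <- list(W1 = he_init(27L * cin, co), b1 = numeric(co),
                       W2 = he_init(27L * co, co), b2 = numeric(co))
    cin <- co
  }
  p$bott <- list(W1 = he_init(27L * cb, 2L * cb), b1 = numeric(2L * cb),
                 W2 = he_init(27L * 2L * cb, cb), b2 = numeric(cb))
  if (cfg$knowledge_fusion)
    p$fusion <- list(W = he_init(cb + cfg$clinical_dim, cb), b = numeric(cb))
  cup <- cb # channels entering each decoder stage from below
  for (l in rev(seq_len(cfg$depth))) {
    cl <- chan[l]
    st <- list(Wu = he_init(27L * cup, cl), bu = numeric(cl),
               W1 = he_init(27L * 2L * cl, cl), b1 = numeric(cl),
               W2 = he_init(27L * cl, cl), b2 = numeric(cl))
    if (cfg$attention) {
      st$gate <- list(w_enc = rnorm(cl, 0, sqrt(1 / cl)),
                      w_dec = rnorm(cl, 0, sqrt(1 / cl)),
                      b = 0)
      if (cfg$iaag) st$gate$w_lvcr <- 0
    }
    p$dec[[l]] <- st
    cup <- cl
  }
  p$final <- list(W = he_init(chan[1], 1L), b = numeric(1))
  structure(list(cfg = cfg, params = p), class = "mk_model")
}

#' Count trainable parameters
#'
#' @param model An `mk_model`.
#' @return Total number of scalar parameters.
#' @export
count_params <- function(model) {
  n <- 0L
  rec <- function(x) {
    if (is.list(x)) for (e in x) rec(e) else n <<- n + length(x)
  }
  rec(model$params)
  n
}

#' @export
print.mk_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("<mk_model> depth %d, channels %s, bottleneck %d",
                     ", attention=%s, fusion=%s, iaag=%s, %.1fM parameters\n"),
              cfg$depth,
              paste(cfg$base_channels * 2^(seq_len(cfg$depth) - 1), collapse = "-"),
              cfg$bottleneck_channels, cfg$attention, cfg$knowledge_fusion,
              cfg$iaag, count_params(x) / 1e6))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# 3x3x3 conv, stride 1, zero pad 1. m: (nvox x cin) matrix; d: spatial dims.
conv3_fwd <- function(m, d, W, b, act = TRUE, keep_cols = TRUE) {
  cols <- im2col3(as.numeric(m), c(d, ncol(m)), 3L, 1L)
  y <- cols %*% W
  y <- y + rep(b, each = nrow(y))
  if (act) y <- relu(y)
  if (keep_cols) list(y = y, cols = cols) else list(y = y)
}

conv3_bwd <- function(dy, cache_cols, y, d, cin, W, act = TRUE) {
  if (act) dy <- dy * (y > 0)
  dW <- crossprod(cache_cols, dy)
  db <- colSums(dy)
  dx <- col2im3(dy %*% t(W), c(d, cin), 3L, 1L)
  list(dx = matrix(dx, prod(d), cin), dW = dW, db = db)
}

#' Forward pass of the segmentation model
#'
#' @param model An `mk_model` from [build_model()].
#' @param x Input patch: 4-D array (x, y, z, channels) with channel count
#'   matching the config and spatial dims divisible by `2^depth`. Inputs are
#'   expected on the normalized scale produced by [as_network_input()].
#' @param clinical Clinical vector of length `clinical_dim` (values in
#'   \[0, 1\]; slot 6 is the normalized LVCR consumed by IAAG). May be `NULL`
#'   when knowledge fusion and IAAG are disabled.
#' @param cache Keep intermediates for the backward pass (training only).
#' @return List with `prob` (3-D probability array, values in (0, 1)) and,
#'   if requested, `cache`.
#' @export
model_forward <- function(model, x, clinical = NULL, cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  d <- dim(x)
  if (length(d) != 4L || d[4] != cfg$in_channels)
    stop_mk("input must be (x, y, z, ", cfg$in_channels, ") array",
            class = "mkunet_dim_error")
  if (any(d[1:3] %% 2^cfg$depth != 0))
    stop_mk("patch dims (", paste(d[1:3], collapse = "x"),
            ") must be divisible by 2^depth = ", 2^cfg$depth,
            class = "mkunet_validation_error")
  if (cfg$knowledge_fusion || cfg$iaag) {
    if (is.null(clinical) || length(clinical) != cfg$clinical_dim)
      stop_mk("clinical vector of length ", cfg$clinical_dim, " required",
              class = "mkunet_validation_error")
  }
  lv <- if (cfg$iaag) as.numeric(clinical[cfg$clinical_dim]) else NULL
  dims <- d[1:3]
  cur <- matrix(x, prod(dims), d[4])
  K <- list(dims = vector("list", cfg$depth))
  enc_out <- vector("list", cfg$depth)
  enc_cache <- vector("list", cfg$depth)
  pool_cache <- vector("list", cfg$depth)
  dl <- dims
  for (l in seq_len(cfg$depth)) {
    e <- p$enc[[l]]
    c1 <- conv3_fwd(cur, dl, e$W1, e$b1, keep_cols = cache)
    c2 <- conv3_fwd(c1$y, dl, e$W2, e$b2, keep_cols = cache)
    enc_out[[l]] <- c2$y
    if (cache) enc_cache[[l]] <- list(c1 = c1, c2 = c2, d = dl, cin = ncol(cur))
    mp <- maxpool3(as.numeric(c2$y), c(dl, ncol(c2$y)))
    if (cache) pool_cache[[l]] <- list(idx = mp$idx, n_in = prod(dl) * ncol(c2$y),
                                       d_in = dl)
    K$dims[[l]] <- dl
    dl <- dl %/% 2L
    cur <- matrix(mp$out, prod(dl), ncol(c2$y))
  }
  bA <- conv3_fwd(cur, dl, p$bott$W1, p$bott$b1, keep_cols = cache)
  bB <- conv3_fwd(bA$y, dl, p$bott$W2, p$bott$b2, keep_cols = cache)
  bott_in <- cur
  cur <- bB$y
  fus <- NULL
  if (cfg$knowledge_fusion) {
    nb <- nrow(cur)
    Fin <- cbind(cur, matrix(rep(as.numeric(clinical), each = nb), nb))
    y <- Fin %*% p$fusion$W
    y <- relu(y + rep(p$fusion$b, each = nb))
    fus <- list(Fin = Fin, y = y)
    cur <- y
  }
  dec_cache <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    st <- p$dec[[l]]
    dl_up <- K$dims[[l]]
    uz <- upsample2_zero(as.numeric(cur), c(dl_up %/% 2L, ncol(cur)))
    cu <- conv3_fwd(matrix(uz, prod(dl_up), ncol(cur)), dl_up, st$Wu, st$bu, keep_cols = cache)
    u <- cu$y
    fe <- enc_out[[l]]
    if (cfg$attention) {
      z <- as.numeric(fe %*% st$gate$w_enc + u %*% st$gate$w_dec + st$gate$b)
      if (cfg$iaag) z <- z + st$gate$w_lvcr * lv
      alpha <- sigmoid(z)
      gated <- fe * alpha
    } else {
      alpha <- NULL
      gated <- fe
    }
    cat_ <- cbind(gated, u)
    c1 <- conv3_fwd(cat_, dl_up, st$W1, st$b1, keep_cols = cache)
    c2 <- conv3_fwd(c1$y, dl_up, st$W2, st$b2, keep_cols = cache)
    if (cache)
      dec_cache[[l]] <- list(cu = cu, c1 = c1, c2 = c2, fe = fe, u = u,
                             alpha = alpha, d = dl_up, c_below = if (l == cfg$depth)
                               ncol(bB$y) else ncol(p$dec[[l + 1L]]$W2))
    cur <- c2$y
  }
  z_out <- cur %*% p$final$W
  z_out <- z_out + p$final$b
  prob <- sigmoid(z_out)
  res <- list(prob = array(prob, dims))
  if (cache)
    res$cache <- list(dims = dims, enc = enc_cache, pool = pool_cache,
                      bott = list(bA = bA, bB = bB, bott_in = bott_in, d = dl),
                      fus = fus, dec = dec_cache, enc_out = enc_out,
                      last = cur, prob = as.numeric(prob), lv = lv,
                      clinical = clinical)
  res
}

# Backward pass; dprob: gradient of the loss w.r.t. the probability map
# (numeric vector, voxel column-major order). Returns gradients in the same
# nested structure as model$params.
model_backward <- function(model, cache, dprob) {
  cfg <- model$cfg
  p <- model$params
  g <- list(enc = vector("list", cfg$depth), dec = vector("list", cfg$depth))
  pr <- cache$prob
  dz <- dprob * pr * (1 - pr)
  dz <- matrix(dz, ncol = 1L)
  g$final <- list(W = crossprod(cache$last, dz), b = sum(dz))
  dcur <- dz %*% t(p$final$W)
  for (l in seq_len(cfg$depth)) {
    dc <- cache$dec[[l]]
    st <- p$dec[[l]]
    cl <- ncol(dc$c2$y)
    b2 <- conv3_bwd(dcur, dc$c2$cols, dc$c2$y, dc$d, cl, st$W2)
    b1 <- conv3_bwd(b2$dx, dc$c1$cols, dc$c1$y, dc$d, 2L * cl, st$W1)
    dcat <- b1$dx
    dgated <- dcat[, seq_len(cl), drop = FALSE]
    du <- dcat[, cl + seq_len(cl), drop = FALSE]
    gst <- list(W2 = b2$dW, b2 = b2$db, W1 = b1$dW, b1 = b1$db)
    if (cfg$attention) {
      alpha <- dc$alpha
      dfe <- dgated * alpha
      dalpha <- rowSums(dgated * dc$fe)
      dzg <- dalpha * alpha * (1 - alpha)
      gst$gate <- list(w_enc = as.numeric(crossprod(dc$fe, dzg)),
                       w_dec = as.numeric(crossprod(dc$u, dzg)),
                       b = sum(dzg))
      if (cfg$iaag) gst$gate$w_lvcr <- sum(dzg) * cache$lv
      dfe <- dfe + outer(dzg, st$gate$w_enc)
      du <- du + outer(dzg, st$gate$w_dec)
    } else {
      dfe <- dgated
    }
    bu <- conv3_bwd(du, dc$cu$cols, dc$cu$y, dc$d, dc$c_below, st$Wu)
    gst$Wu <- bu$dW; gst$bu <- bu$db
    dbelow <- matrix(downsample2_even(as.numeric(bu$dx), c(dc$d, dc$c_below)),
                     prod(dc$d %/% 2L), dc$c_below)
    g$dec[[l]] <- gst
    # propagate skip gradient to the encoder level, and the below gradient
    # onward; the decoder loop runs shallow -> deep, so stash per level
    cache$dec[[l]]$dfe <- dfe
    dcur <- dbelow
  }
  if (cfg$knowledge_fusion) {
    fus <- cache$fus
    dy <- dcur * (fus$y > 0)
    g$fusion <- list(W = crossprod(fus$Fin, dy), b = colSums(dy))
    dFin <- dy %*% t(p$fusion$W)
    dcur <- dFin[, seq_len(ncol(cache$bott$bB$y)), drop = FALSE]
  }
  bt <- cache$bott
  cb2 <- conv3_bwd(dcur, bt$bB$cols, bt$bB$y, bt$d, ncol(bt$bA$y), p$bott$W2)
  cb1 <- conv3_bwd(cb2$dx, bt$bA$cols, bt$bA$y, bt$d, ncol(bt$bott_in), p$bott$W1)
  g$bott <- list(W1 = cb1$dW, b1 = cb1$db, W2 = cb2$dW, b2 = cb2$db)
  dcur <- cb1$dx
  for (l in rev(seq_len(cfg$depth))) {
    pc <- cache$pool[[l]]
    dpool <- maxpool3_bwd(as.numeric(dcur), pc$idx, pc$n_in)
    dh <- matrix(dpool, prod(pc$d_in), ncol(cache$enc[[l]]$c2$y))
    dh <- dh + cache$dec[[l]]$dfe # skip-connection gradient
    ec <- cache$enc[[l]]
    e <- p$enc[[l]]
    e2 <- conv3_bwd(dh, ec$c2$cols, ec$c2$y, ec$d, ncol(ec$c1$y), e$W2)
    e1 <- conv3_bwd(e2$dx, ec$c1$cols, ec$c1$y, ec$d, ec$cin, e$W1)
    g$enc[[l]] <- list(W1 = e1$dW, b1 = e1$db, W2 = e2$dW, b2 = e2$db)
    dcur <- e1$dx
  }
  g
}

# ---- input normalization and prediction ------------------------------------

#' Normalize a volume or multi-channel stack for the network
#'
#' Fixed deterministic scalings bring all channels to roughly \[0, 1\]:
#' HU-valued channels (raw and denoised) map through `(x + 1024) / 2048`
#' (clipped), the edge channel is already binary, and the GLCM contrast
#' channel is divided by its theoretical maximum `(levels - 1)^2`.
#'
#' @param x A `multichannel_volume` or a [ct_volume()] (single channel).
#' @param glcm_levels Gray-level count used for the contrast channel scaling.
#' @return 4-D array (x, y, z, channels) on the normalized scale.
#' @export
as_network_input <- function(x, glcm_levels = 32L) {
  hu <- function(v) pmin(pmax((v + 1024) / 2048, 0), 1)
  if (inherits(x, "ct_volume")) {
    d <- dim(x$voxels)
    return(array(hu(x$voxels), c(d, 1L)))
  }
  stopifnot(inherits(x, "multichannel_volume"))
  ch <- x$channels
  ch[, , , 1] <- hu(ch[, , , 1])
  ch[, , , 3] <- hu(ch[, , , 3])
  ch[, , , 4] <- pmin(ch[, , , 4] / (glcm_levels - 1L)^2, 1)
  ch
}

# internal: pad (with value) or crop a 4-D array to target spatial dims
pad_to <- function(arr, target, value = 0) {
  d <- dim(arr)
  out <- array(value, c(target, d[4]))
  nx <- min(d[1], target[1]); ny <- min(d[2], target[2]); nz <- min(d[3], target[3])
  out[seq_len(nx), seq_len(ny), seq_len(nz), ] <- arr[seq_len(nx), seq_len(ny), seq_len(nz), , drop = FALSE]
  out
}

#' Segment a volume with a model
#'
#' Crops the input to the ROI box (padded to dimensions divisible by
#' `2^depth`), runs the network, thresholds the probability map and re-embeds
#' the binary mask into the full voxel grid.
#'
#' @param model An `mk_model`.
#' @param x A `multichannel_volume` (or [ct_volume()] for 1-channel models).
#' @param clinical Clinical vector (see [model_forward()]).
#' @param roi_box Optional integer vector
#'   `c(xmin, xmax, ymin, ymax, zmin, zmax)` (1-based, inclusive) delimiting
#'   the tumor region; default is the whole volume.
#' @param threshold Probability threshold (default 0.5); foreground is
#'   `prob > threshold`.
#' @return A [seg_mask()] on the full input grid.
#' @export
predict_mask <- function(model, x, clinical = NULL, roi_box = NULL, threshold = 0.5) {
  inp <- as_network_input(x)
  d <- dim(inp)[1:3]
  spacing <- x$spacing
  if (is.null(roi_box)) roi_box <- c(1L, d[1], 1L, d[2], 1L, d[3])
  rb <- as.integer(roi_box)
  if (length(rb) != 6L || any(rb[c(1, 3, 5)] < 1L) ||
      rb[2] > d[1] || rb[4] > d[2] || rb[6] > d[3] ||
      any(rb[c(2, 4, 6)] < rb[c(1, 3, 5)]))
    stop_mk("roi_box outside the volume or malformed", class = "mkunet_validation_error")
  mult <- 2^model$cfg$depth
  sz <- rb[c(2, 4, 6)] - rb[c(1, 3, 5)] + 1L
  target <- as.integer(ceiling(sz / mult) * mult)
  # grow the box (preferring to stay inside the grid) up to the target size
  lo <- rb[c(1, 3, 5)]; hi <- rb[c(2, 4, 6)]
  for (ax in 1:3) {
    need <- target[ax] - (hi[ax] - lo[ax] + 1L)
    grow_lo <- min(need %/% 2L, lo[ax] - 1L)
    lo[ax] <- lo[ax] - grow_lo
    hi[ax] <- min(d[ax], hi[ax] + (need - grow_lo))
  }
  crop <- inp[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], , drop = FALSE]
  csz <- dim(crop)[1:3]
  padded <- !identical(as.integer(csz), target)
  if (padded) crop <- pad_to(crop, target)
  pr <- model_forward(model, crop, clinical)$prob
  mask_crop <- (pr > threshold)[seq_len(csz[1]), seq_len(csz[2]), seq_len(csz[3]), drop = FALSE]
  full <- array(0L, d)
  full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- as.integer(mask_crop)
  seg_mask(full, spacing)
}
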