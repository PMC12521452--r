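# Segmentation losses (soft Dice, BCE, hybrid) and evaluation metrics
# (Dice, IoU, HD95) with LVCR-stratified aggregation.

as_binary_array <- function(x) {
  if (inherits(x, "seg_mask")) return(x$voxels)
  if (is.logical(x)) { storage.mode(x) <- "integer"; return(x) }
  x
}

#' Dice coefficient of two binary masks
#'
#' \eqn{\mathrm{Dice}(A,B) = 2|A \cap B| / (|A| + |B|)}, symmetric in its
#' arguments. If both masks are empty the conventional value 1 is returned
#' with a `degenerate` attribute.
#'
#' @param a,b [seg_mask()]s or binary arrays on one grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  av <- as_binary_array(a); bv <- as_binary_array(b)
  if (!identical(dim(av), dim(bv)))
    stop_mk("masks are on different grids", class = "mkunet_grid_error")
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  2 * sum(av * bv) / (na + nb)
}

#' Intersection over union (Jaccard) of two binary masks
#'
#' \eqn{|A \cap B| / |A \cup B|}; both-empty returns 1 with a `degenerate`
#' attribute. Related to Dice by \eqn{\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})}.
#'
#' @inheritParams dice_coefficient
#' @return IoU in \[0, 1\].
#' @export
iou <- function(a, b) {
  av <- as_binary_array(a); bv <- as_binary_array(b)
  if (!identical(dim(av), dim(bv)))
    stop_mk("masks are on different grids", class = "mkunet_grid_error")
  inter <- sum(av * bv)
  uni <- sum(av) + sum(bv) - inter
  if (uni == 0) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  inter / uni
}

#' Loss weights of the hybrid objective
#'
#' @param lambda1 Soft-Dice loss weight (default 0.6).
#' @param lambda2 Binary cross-entropy weight (default 0.4).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 0.6, lambda2 = 0.4) {
  if (lambda1 < 0 || lambda2 < 0)
    stop_mk("loss weights must be >= 0", class = "mkunet_validation_error")
  structure(list(lambda1 = lambda1, lambda2 = lambda2), class = "loss_weights")
}

#' Soft Dice loss
#'
#' \eqn{1 - (2\sum p t + \epsilon) / (\sum p + \sum t + \epsilon)}, the soft
#' formulation replacing voxel counts with sums of predicted probabilities;
#' 0 for a perfect prediction, differentiable in `pred`.
#'
#' @param pred Probability map (array, values in \[0, 1\]).
#' @param target Binary target mask (array or [seg_mask()]).
#' @param eps Smoothing constant added to numerator and denominator (default 1).
#' @return Loss value in \[0, 1\].
#' @export
dice_loss <- function(pred, target, eps = 1) {
  tv <- as_binary_array(target)
  if (!identical(dim(pred), dim(tv)))
    stop_mk("prediction and target are on different grids", class = "mkunet_grid_error")
  1 - (2 * sum(pred * tv) + eps) / (sum(pred) + sum(tv) + eps)
}

#' Binary cross-entropy loss
#'
#' Mean over all voxels of \eqn{-[y \ln p + (1-y)\ln(1-p)]}, with predictions
#' clipped to \[`eps`, 1-`eps`\].
#'
#' @inheritParams dice_loss
#' @param eps Clipping constant (default 1e-7).
#' @return Non-negative mean loss.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  tv <- as_binary_array(target)
  if (!identical(dim(pred), dim(tv)))
    stop_mk("prediction and target are on different grids", class = "mkunet_grid_error")
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(tv * log(p) + (1 - tv) * log(1 - p))
}

#' Hybrid segmentation loss
#'
#' \eqn{\lambda_1 \cdot \mathrm{DiceLoss} + \lambda_2 \cdot \mathrm{BCE}}
#' with default weights 0.6 and 0.4.
#'
#' @inheritParams dice_loss
#' @param w A [loss_weights()].
#' @return Loss value.
#' @export
hybrid_loss <- function(pred, target, w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"))
  w$lambda1 * dice_loss(pred, target) + w$lambda2 * bce_loss(pred, target)
}

#' 95th-percentile Hausdorff distance (HD95)
#'
#' Surface voxels (foreground voxels with at least one background 6-neighbor;
#' the outside of the array counts as background) of both masks are extracted,
#' directed nearest-surface distances are computed both ways in physical mm,
#' and HD95 is the 95th percentile (linear interpolation) of the pooled
#' bidirectional distances. The pooled convention makes `hd95(a, b)`
#' symmetric; HD95 is bounded above by the exact Hausdorff distance.
#'
#' @param a,b Non-empty [seg_mask()]s (or binary arrays) on one grid.
#' @param spacing Voxel spacing in mm; defaults to the masks' spacing.
#' @param prob Percentile in (0, 1\] (default 0.95).
#' @return Distance in mm, or `NA` with an `undefined` attribute when either
#'   mask is empty (such cases are excluded from aggregates).
#' @export
hd95 <- function(a, b, spacing = NULL, prob = 0.95) {
  if (is.null(spacing)) {
    if (inherits(a, "seg_mask")) spacing <- a$spacing
    else if (inherits(b, "seg_mask")) spacing <- b$spacing
    else spacing <- c(1, 1, 1)
  }
  av <- as_binary_array(a); bv <- as_binary_array(b)
  if (!identical(dim(av), dim(bv)))
    stop_mk("masks are on different grids", class = "mkunet_grid_error")
  if (sum(av) == 0L || sum(bv) == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  sd_ <- surf_dists(as.integer(av), as.integer(bv), dim(av), as.numeric(spacing))
  unname(stats::quantile(c(sd_$dab, sd_$dba), prob, type = 7))
}

#' Evaluate predicted masks against ground truth
#'
#' Per-case Dice, IoU and HD95 plus mean +/- sd aggregates, overall and per
#' LVCR stratum (`"high"` iff LVCR > `threshold`, strict). Cases with an
#' undefined HD95 (an empty mask) are excluded from the HD95 aggregate and
#' counted in `n_hd95_undefined`.
#'
#' @param pairs List of cases; each case is a list with elements `pred` and
#'   `truth` ([seg_mask()]s on one grid) and optionally `lvcr` (1/day) and `id`.
#' @param threshold LVCR stratification threshold in 1/day (default 0.15).
#' @return An object of class `metric_report`: list with `cases` (data.frame)
#'   and `aggregate` (data.frame of mean/sd by stratum and overall).
#' @export
evaluate_cases <- function(pairs, threshold = 0.15) {
  if (!length(pairs))
    stop_mk("no cases to evaluate", class = "mkunet_validation_error")
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    check_same_grid(p$pred, p$truth)
    data.frame(
      id = if (!is.null(p$id)) as.character(p$id) else as.character(i),
      dice = as.numeric(dice_coefficient(p$pred, p$truth)),
      iou = as.numeric(iou(p$pred, p$truth)),
      hd95_mm = as.numeric(hd95(p$pred, p$truth)),
      lvcr = if (!is.null(p$lvcr)) p$lvcr else NA_real_,
      stringsAsFactors = FALSE)
  })
  cases <- do.call(rbind, rows)
  cases$stratum <- ifelse(is.na(cases$lvcr), NA_character_,
                          as.character(stratify_lvcr(cases$lvcr, threshold)))
  agg_one <- function(df, label) {
    hd <- df$hd95_mm[!is.na(df$hd95_mm)]
    data.frame(stratum = label, n = nrow(df),
               dice_mean = mean(df$dice), dice_sd = if (nrow(df) > 1) sd(df$dice) else 0,
               iou_mean = mean(df$iou), iou_sd = if (nrow(df) > 1) sd(df$iou) else 0,
               hd95_mean = if (length(hd)) mean(hd) else NA_real_,
               hd95_sd = if (length(hd) > 1) sd(hd) else 0,
               n_hd95_undefined = sum(is.na(df$hd95_mm)),
               stringsAsFactors = FALSE)
  }
  agg <- agg_one(cases, "overall")
  for (s in c("low", "high"))
    if (any(cases$stratum %in% s)) agg <- rbind(agg, agg_one(cases[cases$stratum %in% s, ], s))
  structure(list(cases = cases, aggregate = agg, lvcr_threshold = threshold,
                 hd95_convention = "pooled bidirectional surface distances, linear percentile"),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> ", nrow(x$cases), " case(s)\n", sep = "")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Paired two-sided t-test on per-case Dice
#'
#' Convenience wrapper comparing two models' per-case Dice scores.
#'
#' @param dice_a,dice_b Per-case Dice vectors of equal length.
#' @return An `htest` object from [stats::t.test()].
#' @export
paired_dice_test <- function(dice_a, dice_b) {
  stats::t.test(dice_a, dice_b, paired = TRUE)
}
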