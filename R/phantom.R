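# Synthetic longitudinal lung-CT phantoms: volumes, exact masks and clinical
# metadata with known growth rate, shape and noise, so every module is
# testable without external data.

#' Phantom specification
#'
#' The tumor is a ball of `base_radius` mm at baseline, optionally decorated
#' with conical spiculations and a low-HU necrotic core, growing (or
#' shrinking) exponentially in volume at the true log-volume slope
#' `growth_rate` so that the mask volume at scan time t is
#' \eqn{V_0 e^{g t}}. Masks are the exact generating shapes. Default HU
#' palette: aerated lung background -800 +/- 50 HU, tumor 40 +/- 15 HU,
#' necrotic core -20 +/- 10 HU.
#'
#' @param shape Grid dimensions in voxels (default `c(96, 96, 48)`, desk scale).
#' @param spacing Voxel spacing (x, y, z) in mm (default 1 mm isotropic).
#' @param base_radius Baseline tumor radius in mm (default 10).
#' @param growth_rate True log-volume slope in 1/day (default 0.01).
#' @param scan_times Scan times in days, strictly increasing from 0.
#' @param n_spiculations Number of conical spiculations (default 0).
#' @param spiculation_length Spike length beyond the ball surface in mm.
#' @param spiculation_width Spike base radius in mm.
#' @param necrosis_fraction Volume fraction of the necrotic core in \[0, 1).
#' @param tumor_hu,tumor_sd,background_hu,background_sd,necrosis_hu,necrosis_sd
#'   Intensity palette (mean and Gaussian noise sd, HU).
#' @param seed Integer seed; fixes spiculation directions and noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 48L), spacing = c(1, 1, 1),
                         base_radius = 10, growth_rate = 0.01,
                         scan_times = c(0, 30, 60),
                         n_spiculations = 0L, spiculation_length = 6,
                         spiculation_width = 2.5,
                         necrosis_fraction = 0,
                         tumor_hu = 40, tumor_sd = 15,
                         background_hu = -800, background_sd = 50,
                         necrosis_hu = -20, necrosis_sd = 10,
                         seed = 1L) {
  if (base_radius <= 0)
    stop_mk("base_radius must be > 0", class = "mkunet_validation_error")
  if (length(scan_times) < 1L || scan_times[1] != 0 || any(diff(scan_times) <= 0))
    stop_mk("scan_times must be strictly increasing from 0",
            class = "mkunet_validation_error")
  if (necrosis_fraction < 0 || necrosis_fraction >= 1)
    stop_mk("necrosis_fraction must be in [0, 1)", class = "mkunet_validation_error")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 base_radius = base_radius, growth_rate = growth_rate,
                 scan_times = as.numeric(scan_times),
                 n_spiculations = as.integer(n_spiculations),
                 spiculation_length = spiculation_length,
                 spiculation_width = spiculation_width,
                 necrosis_fraction = necrosis_fraction,
                 tumor_hu = tumor_hu, tumor_sd = tumor_sd,
                 background_hu = background_hu, background_sd = background_sd,
                 necrosis_hu = necrosis_hu, necrosis_sd = necrosis_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# internal: physical (mm) coordinates of every voxel relative to grid center
phantom_coords <- function(shape, spacing) {
  ctr <- (shape - 1) / 2
  gx <- (seq_len(shape[1]) - 1 - ctr[1]) * spacing[1]
  gy <- (seq_len(shape[2]) - 1 - ctr[2]) * spacing[2]
  gz <- (seq_len(shape[3]) - 1 - ctr[3]) * spacing[3]
  list(x = array(gx, shape),
       y = array(rep(gy, each = shape[1]), shape),
       z = array(rep(gz, each = shape[1] * shape[2]), shape))
}

# internal: tumor shape (ball + conical spiculations) at radius r_mm.
# Spikes keep their full base width out to the ball surface and taper to a
# point over spic_len beyond it, so they stay resolvable after voxelization.
phantom_shape_mask <- function(co, r_mm, dirs, spic_len, spic_w) {
  dist <- sqrt(co$x^2 + co$y^2 + co$z^2)
  m <- dist <= r_mm
  if (!is.null(dirs) && nrow(dirs) > 0) {
    tip <- r_mm + spic_len
    for (i in seq_len(nrow(dirs))) {
      u <- dirs[i, ]
      s <- co$x * u[1] + co$y * u[2] + co$z * u[3]
      perp2 <- pmax(dist^2 - s^2, 0)
      w <- spic_w * (1 - pmax(s - r_mm, 0) / spic_len)
      m <- m | (s >= 0 & s <= tip & perp2 <= w^2)
    }
  }
  m
}

#' Generate a longitudinal phantom
#'
#' Produces one scan per `scan_times` entry: a noisy CT volume and the exact
#' generating mask, plus a sampled clinical record whose LVCR field is the
#' true growth rate. The tumor radius at time t is scaled so the ball volume
#' follows \eqn{V_0 e^{g t}} exactly; spiculation directions are fixed per
#' phantom.
#'
#' @param spec A [phantom_spec()].
#' @param patient_id Identifier stamped on the scans.
#' @return List of class `phantom_series` with `scans` (list of
#'   `list(volume, mask)`), `clinical` (a [clinical_record()]) and
#'   `true_growth_rate`.
#' @export
generate_phantom <- function(spec = phantom_spec(), patient_id = "phantom-01") {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  co <- phantom_coords(spec$shape, spec$spacing)
  dirs <- NULL
  if (spec$n_spiculations > 0) {
    v <- matrix(rnorm(3 * spec$n_spiculations), ncol = 3)
    dirs <- v / sqrt(rowSums(v^2))
  }
  half_extent <- (spec$shape - 1) / 2 * spec$spacing
  scans <- vector("list", length(spec$scan_times))
  for (i in seq_along(spec$scan_times)) {
    t <- spec$scan_times[i]
    r_t <- spec$base_radius * exp(spec$growth_rate * t / 3)
    if (r_t + spec$spiculation_length * (spec$n_spiculations > 0) >= min(half_extent))
      stop_mk("tumor (radius ", signif(r_t, 4), " mm) exceeds the grid",
              class = "mkunet_validation_error")
    m <- phantom_shape_mask(co, r_t, dirs, spec$spiculation_length,
                            spec$spiculation_width)
    vox <- spec$background_hu + rnorm(prod(spec$shape), 0, spec$background_sd)
    vox <- array(vox, spec$shape)
    ntum <- sum(m)
    vox[m] <- spec$tumor_hu + rnorm(ntum, 0, spec$tumor_sd)
    if (spec$necrosis_fraction > 0) {
      r_core <- r_t * spec$necrosis_fraction^(1 / 3)
      core <- sqrt(co$x^2 + co$y^2 + co$z^2) <= r_core
      vox[core] <- spec$necrosis_hu + rnorm(sum(core), 0, spec$necrosis_sd)
    }
    scans[[i]] <- list(
      volume = ct_volume(vox, spec$spacing, time_days = t, patient_id = patient_id),
      mask = seg_mask(m, spec$spacing))
  }
  clinical <- clinical_record(
    age = round(runif(1, 40, 85)),
    gender = sample(.genders, 1),
    smoking_history = sample(.smoking, 1),
    pathological_grade = sample(1:3, 1),
    tumor_stage = sample(.stages, 1),
    lvcr = spec$growth_rate)
  structure(list(scans = scans, clinical = clinical,
                 true_growth_rate = spec$growth_rate, spec = spec,
                 patient_id = patient_id),
            class = "phantom_series")
}

#' Longitudinal volume series of a phantom (from its masks)
#'
#' @param ph A `phantom_series`.
#' @return A [longitudinal_series()] of segmented volumes.
#' @export
phantom_series_volumes <- function(ph) {
  stopifnot(inherits(ph, "phantom_series"))
  longitudinal_series(
    ph$patient_id,
    times = vapply(ph$scans, function(s) s$volume$time_days, numeric(1)),
    volumes = vapply(ph$scans, function(s) as.numeric(mask_volume(s$mask)), numeric(1)))
}

#' Write a synthetic cohort to disk
#'
#' Generates `n_patients` phantoms (growth rates either supplied or sampled
#' uniformly from `growth_range`), writes per-scan NIfTI volumes and masks,
#' a cohort CSV readable by [read_cohort()], and a ground-truth sidecar CSV
#' (`patient_id, true_growth_rate, true_stratum`).
#'
#' @param n_patients Number of patients (>= 1).
#' @param dir Output directory (created if needed).
#' @param growth_rates Optional vector of true growth rates (1/day), recycled.
#' @param growth_range Sampling range when `growth_rates` is `NULL`.
#' @param base_spec A [phantom_spec()] supplying all non-growth parameters;
#'   the default uses short inter-scan intervals (0, 5, 10 days) so that even
#'   fast-growing tumors (up to 0.25/day) stay inside the desk-scale grid.
#' @param seed Cohort-level seed (per-patient seeds derive from it).
#' @return Invisibly, a list with `cohort_csv`, `truth_csv` and the cohort
#'   data.frame.
#' @export
make_cohort <- function(n_patients, dir, growth_rates = NULL,
                        growth_range = c(-0.01, 0.25),
                        base_spec = phantom_spec(shape = c(48L, 48L, 32L), base_radius = 5,
                                                 scan_times = c(0, 5, 10)),
                        seed = 1L) {
  if (n_patients < 1L) stop_mk("n_patients must be >= 1", class = "mkunet_validation_error")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_mk("cannot create directory ", dir, class = "mkunet_io_error")
  set.seed(seed)
  g <- if (is.null(growth_rates))
    runif(n_patients, growth_range[1], growth_range[2])
  else rep_len(growth_rates, n_patients)
  rows <- list()
  truth <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%03d", i)
    spec <- base_spec
    spec$growth_rate <- g[i]
    spec$seed <- seed + 1000L * i
    ph <- generate_phantom(spec, patient_id = pid)
    cl <- ph$clinical
    for (s in ph$scans) {
      t <- s$volume$time_days
      vf <- sprintf("%s_t%03d_ct.nii.gz", pid, as.integer(t))
      mf <- sprintf("%s_t%03d_mask.nii.gz", pid, as.integer(t))
      write_volume(s$volume, file.path(dir, vf))
      write_volume(s$mask, file.path(dir, mf))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, age = cl$age, gender = cl$gender,
        smoking_history = cl$smoking_history,
        pathological_grade = cl$pathological_grade,
        tumor_stage = cl$tumor_stage, time_days = t,
        volume_path = vf, mask_path = mf, stringsAsFactors = FALSE)
    }
    truth[[i]] <- data.frame(patient_id = pid, true_growth_rate = g[i],
                             true_stratum = as.character(stratify_lvcr(g[i])),
                             stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, rows)
  cohort_csv <- file.path(dir, "cohort.csv")
  truth_csv <- file.path(dir, "ground_truth.csv")
  write.csv(cohort, cohort_csv, row.names = FALSE)
  write.csv(do.call(rbind, truth), truth_csv, row.names = FALSE)
  invisible(list(cohort_csv = cohort_csv, truth_csv = truth_csv, cohort = cohort))
}

#' Build training samples from a phantom
#'
#' Crops a cube around the tumor centroid, builds the 4-channel stack,
#' normalizes it and pairs it with the exact mask — the desk-scale analogue
#' of patch-based training around the ROI.
#'
#' @param ph A `phantom_series`.
#' @param scan Index of the scan to use (default 1).
#' @param crop Cubic crop size in voxels (default 32; must be divisible by
#'   `2^depth` of the target model).
#' @param channels 4 for the multi-channel stack, 1 for raw HU only.
#' @return A [training_sample()].
#' @export
phantom_training_sample <- function(ph, scan = 1L, crop = 32L, channels = 4L) {
  stopifnot(inherits(ph, "phantom_series"))
  s <- ph$scans[[scan]]
  d <- dim(s$volume$voxels)
  idx <- which(s$mask$voxels == 1L, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  lo <- pmax(1L, pmin(as.integer(ctr - crop %/% 2L + 1L), d - crop + 1L))
  hi <- lo + crop - 1L
  vox <- s$volume$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  msk <- s$mask$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  vol <- ct_volume(vox, s$volume$spacing, s$volume$time_days, ph$patient_id)
  x <- if (channels == 4L) as_network_input(build_multichannel(vol))
       else as_network_input(vol)
  cl <- ph$clinical
  training_sample(x, msk, encode_clinical(cl))
}
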