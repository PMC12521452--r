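# Imaging and cohort I/O: CT volumes, segmentation masks, cohort tables and
# deterministic train/validation/test partitioning.

#' Construct a CT volume
#'
#' A `ct_volume` is the atomic imaging object: a dense 3-D array of
#' intensities in Hounsfield Units (HU) together with voxel spacing in mm and
#' an acquisition time relative to the patient's baseline scan.
#'
#' @param voxels 3-D numeric array of intensities in HU.
#' @param spacing Numeric length-3 vector of voxel edge lengths (x, y, z) in mm.
#' @param time_days Scan time in days relative to baseline (baseline = 0).
#' @param patient_id Opaque patient identifier.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), time_days = 0, patient_id = NA_character_) {
  if (length(dim(voxels)) != 3L)
    stop_mk("voxels must be a 3-D array, got ", length(dim(voxels)), " dimensions",
            class = "mkunet_dim_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_mk("spacing must be three positive finite values (mm)")
  if (!is.numeric(time_days) || length(time_days) != 1L || time_days < 0)
    stop_mk("time_days must be a single non-negative number")
  structure(list(voxels = voxels, spacing = spacing,
                 time_days = as.numeric(time_days),
                 patient_id = as.character(patient_id)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s  grid %s  spacing %s mm  t=%g d\n",
              x$patient_id, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$time_days))
  invisible(x)
}

#' Construct a binary segmentation mask
#'
#' A `seg_mask` shares the exact voxel grid of its paired [ct_volume()]; no
#' implicit resampling is ever performed (grid mismatches raise errors).
#'
#' @param voxels 3-D array with values in \{0, 1\} (logical or numeric).
#' @param spacing Voxel spacing (x, y, z) in mm.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(voxels, spacing = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L)
    stop_mk("mask voxels must be a 3-D array", class = "mkunet_dim_error")
  v <- voxels
  if (is.logical(v)) storage.mode(v) <- "integer"
  u <- unique(as.vector(v))
  if (!all(u %in% c(0, 1)))
    stop_mk("mask values must be binary (0/1)")
  storage.mode(v) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_mk("spacing must be three positive values (mm)")
  structure(list(voxels = v, spacing = spacing), class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> grid %s  spacing %s mm  foreground %d voxels\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

# internal: check two objects share one voxel grid
check_same_grid <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop_mk("objects are on different voxel grids (",
            paste(dim(a$voxels), collapse = "x"), " vs ",
            paste(dim(b$voxels), collapse = "x"),
            "); no implicit resampling is performed", class = "mkunet_grid_error")
  invisible(TRUE)
}

#' Read a CT volume or mask from NIfTI
#'
#' Reads a 3-D NIfTI file, applying the header's slope/intercept so in-memory
#' intensities are true HU, and taking voxel spacing from the header. DICOM
#' series directories are not supported; convert to NIfTI first.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param time_days,patient_id Metadata attached to the returned volume.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, time_days = 0, patient_id = NA_character_) {
  if (dir.exists(path))
    stop_mk("'", path, "' is a directory; DICOM series reading is not supported, ",
            "convert the series to NIfTI", class = "mkunet_io_error")
  if (!file.exists(path))
    stop_mk("cannot read volume: file not found: ", path, class = "mkunet_io_error")
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr)) # drop NIfTI header attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop_mk("'", path, "' is not a 3-D volume (", length(dim(arr)), "-D)",
            class = "mkunet_dim_error")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop_mk("'", path, "' has no usable voxel spacing in its header",
            class = "mkunet_format_error")
  ct_volume(arr, spacing = sp, time_days = time_days, patient_id = patient_id)
}

#' Read a binary mask from NIfTI
#'
#' @param path Path to a `.nii` or `.nii.gz` file; voxels above 0.5 are foreground.
#' @return A [seg_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  seg_mask(v$voxels > 0.5, spacing = v$spacing)
}

#' Write a CT volume or mask to NIfTI
#'
#' @param x A [ct_volume()] or [seg_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "ct_volume") || inherits(x, "seg_mask"))
  arr <- x$voxels
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and validate a cohort table
#'
#' The cohort CSV has one row per scan with columns `patient_id`, `age`,
#' `gender`, `smoking_history`, `pathological_grade`, `tumor_stage`,
#' `time_days`, `volume_path`, `mask_path`. Paths are resolved relative to the
#' CSV's directory. Every referenced file must exist, every patient needs at
#' least one scan, and a baseline (`time_days == 0`) scan per patient.
#'
#' @param path Path to the cohort CSV.
#' @param check_files Verify referenced image files exist (default `TRUE`).
#' @return A `data.frame` of class `cohort_table`.
#' @export
read_cohort <- function(path, check_files = TRUE) {
  if (!file.exists(path))
    stop_mk("cohort table not found: ", path, class = "mkunet_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "gender", "smoking_history", "pathological_grade",
            "tumor_stage", "time_days", "volume_path", "mask_path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_mk("cohort table missing columns: ", paste(miss, collapse = ", "))
  root <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  df$volume_path <- resolve(df$volume_path)
  df$mask_path <- resolve(df$mask_path)
  if (check_files) {
    bad <- c(df$volume_path[!file.exists(df$volume_path)],
             df$mask_path[!file.exists(df$mask_path)])
    if (length(bad))
      stop_mk("cohort references missing files: ", paste(bad, collapse = ", "),
              class = "mkunet_io_error")
  }
  by_pat <- split(df$time_days, df$patient_id)
  no_base <- names(by_pat)[!vapply(by_pat, function(t) any(t == 0), logical(1))]
  if (length(no_base))
    stop_mk("patients without a baseline (time_days = 0) scan: ",
            paste(no_base, collapse = ", "))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Specify a cohort partition
#'
#' @param train,validation,test Partition fractions; must sum to 1.
#' @param seed Integer seed making the partition reproducible.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train = 0.714, validation = 0.143, test = 0.143, seed = 1L) {
  f <- c(train = train, validation = validation, test = test)
  if (any(f < 0))
    stop_mk("split fractions must be non-negative", class = "mkunet_validation_error")
  if (abs(sum(f) - 1) > 1e-9)
    stop_mk("split fractions must sum to 1 (got ", sum(f), ")",
            class = "mkunet_validation_error")
  structure(list(fractions = f, seed = as.integer(seed)), class = "split_spec")
}

#' Deterministic train/validation/test partition
#'
#' Validation and test sizes are `round(n * fraction)`; the remainder goes to
#' the training set, so 420 cases at fractions (0.714, 0.143, 0.143) yield
#' exactly 300/60/60. The same seed always reproduces the same partition.
#'
#' @param n_cases Number of cases to partition (>= 3).
#' @param spec A [split_spec()].
#' @return Named list of disjoint integer index vectors
#'   (`train`, `validation`, `test`) covering `1:n_cases`.
#' @export
split_cohort <- function(n_cases, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n_cases <- as.integer(n_cases)
  if (n_cases < 3L)
    stop_mk("need at least 3 cases to partition", class = "mkunet_validation_error")
  f <- spec$fractions
  n_val <- round(n_cases * f[["validation"]])
  n_test <- round(n_cases * f[["test"]])
  n_train <- n_cases - n_val - n_test
  if (n_train < 0)
    stop_mk("rounded validation/test sizes exceed n_cases",
            class = "mkunet_validation_error")
  perm <- local({
    set.seed(spec$seed)
    sample.int(n_cases)
  })
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[seq_len(n_val) + n_train]),
       test = sort(perm[seq_len(n_test) + n_train + n_val]))
}

#' Write a partition as a two-column CSV
#'
#' @param split Result of [split_cohort()].
#' @param ids Character vector of patient ids (indexable by the split).
#' @param path Output CSV path (`patient_id,partition`).
#' @return `path`, invisibly.
#' @export
write_split <- function(split, ids, path) {
  df <- do.call(rbind, lapply(names(split), function(p)
    if (length(split[[p]])) data.frame(patient_id = ids[split[[p]]], partition = p)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
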