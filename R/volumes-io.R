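# Imaging volume containers and NIfTI / table I/O.
#
# Conventions: times are minutes post-injection, activity is kBq/mL, decay
# correction is assumed already applied upstream. Voxel coordinates are
# array indices; PET and label volumes must share one grid (no resampling).

#' Segmentation label volume
#'
#' @param labels 3D array of non-negative integer label IDs (FreeSurfer
#'   aseg/aparc convention; 0 = background).
#' @param voxel_size Numeric length-3, mm per axis, all > 0.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (any(!is.finite(labels)) || any(labels != round(labels)) ||
      any(labels < 0))
    stop("non-integer labels: label volumes must hold non-negative integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three positive numbers (mm)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_size = voxel_size),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  ids <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf("Label volume %s, voxel %s mm, %d labels\n",
              paste(dim(x$labels), collapse = "x"),
              paste(format(x$voxel_size, digits = 3), collapse = "x"),
              length(ids)))
  invisible(x)
}

#' Dynamic (or windowed-static) PET volume
#'
#' @param voxels 4D array of activity concentration (kBq/mL), axes
#'   x, y, z, frame. A 3D array is promoted to a single frame.
#' @param voxel_size Numeric length-3, mm per axis.
#' @param schedule A [frame_schedule()] whose length matches the frame axis.
#' @return An object of class `dynamic_volume`.
#' @export
dynamic_volume <- function(voxels, voxel_size, schedule) {
  if (length(dim(voxels)) == 3L)
    dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a 3D or 4D array")
  if (!inherits(schedule, "frame_schedule"))
    stop("schedule must be a frame_schedule")
  if (dim(voxels)[4L] != n_frames(schedule))
    stop("frame axis length must equal schedule length")
  if (any(!is.finite(voxels)))
    stop("voxel values must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three positive numbers (mm)")
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 schedule = schedule), class = "dynamic_volume")
}

#' @export
print.dynamic_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Dynamic volume %s, %d frame(s), %.4g-%.4g min\n",
              paste(d[1:3], collapse = "x"), d[4L],
              x$schedule$start[1L], x$schedule$end[nrow(x$schedule)]))
  invisible(x)
}

.check_grid_match <- function(pet, labels) {
  if (!identical(dim(pet$voxels)[1:3], dim(labels$labels)))
    stop("grid mismatch: PET and label volumes have different shapes")
  if (max(abs(pet$voxel_size - labels$voxel_size)) > 1e-6)
    stop("grid mismatch: PET and label volumes have different voxel sizes")
  invisible(TRUE)
}

#' Read a segmentation label volume from NIfTI
#'
#' @param path Path to a 3D integer-valued NIfTI file (.nii/.nii.gz).
#' @return A [label_volume()]; label values are preserved exactly.
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("label volume must be 3D, got ", length(dim(img)), "D")
  vx <- RNifti::pixdim(img)[1:3]
  label_volume(array(as.vector(img), dim = dim(img)), vx)
}

#' Write a label volume to NIfTI
#' @param labels A [label_volume()].
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(labels, path) {
  img <- RNifti::asNifti(labels$labels)
  RNifti::pixdim(img) <- labels$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read frame timing from CSV
#'
#' The timing table has a header `start_min,end_min`, one row per frame.
#'
#' @param path CSV path.
#' @return A [frame_schedule()].
#' @export
read_frame_timing <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  tab <- utils::read.csv(path)
  if (!all(c("start_min", "end_min") %in% names(tab)))
    stop("timing table must have columns start_min,end_min")
  frame_schedule(tab$start_min, tab$end_min)
}

#' Write frame timing to CSV
#' @param schedule A [frame_schedule()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_timing <- function(schedule, path) {
  utils::write.csv(
    data.frame(start_min = schedule$start, end_min = schedule$end),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a dynamic PET series with its frame timing
#'
#' A 3D file (windowed static scan) becomes a single-frame volume; a 4D
#' file must match the timing table row count. Frames are ordered by start
#' time.
#'
#' @param path NIfTI path (3D or 4D).
#' @param timing A [frame_schedule()] or a path to a timing CSV
#'   (columns `start_min,end_min`).
#' @return A [dynamic_volume()].
#' @export
read_dynamic_series <- function(path, timing) {
  if (!file.exists(path))
    stop("file not found: ", path)
  if (!inherits(timing, "frame_schedule"))
    timing <- read_frame_timing(timing)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (!nd %in% c(3L, 4L))
    stop("PET series must be 3D or 4D")
  vx <- RNifti::pixdim(img)[1:3]
  arr <- array(as.vector(img), dim = dim(img))
  if (nd == 3L)
    dim(arr) <- c(dim(arr), 1L)
  if (dim(arr)[4L] != n_frames(timing))
    stop(sprintf("frame-count mismatch: %d frames, %d timing rows",
                 dim(arr)[4L], n_frames(timing)))
  dynamic_volume(arr, vx, timing)
}

#' Write a dynamic volume to NIfTI (+ timing CSV alongside if requested)
#' @param pet A [dynamic_volume()].
#' @param path Output NIfTI path.
#' @param timing_path Optional CSV path for the frame schedule.
#' @return `path`, invisibly.
#' @export
write_dynamic_series <- function(pet, path, timing_path = NULL) {
  arr <- pet$voxels
  if (dim(arr)[4L] == 1L)
    dim(arr) <- dim(arr)[1:3]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- if (length(dim(arr)) == 4L)
    c(pet$voxel_size, 1) else pet$voxel_size
  RNifti::writeNifti(img, path)
  if (!is.null(timing_path))
    write_frame_timing(pet$schedule, timing_path)
  invisible(path)
}

#' A single regional quantification result
#'
#' @param subject Subject identifier.
#' @param region Region or composite name.
#' @param metric One of `"SUV"`, `"SUVR"`, `"BPND"`, `"VT"`.
#' @param value Numeric value (unitless).
#' @param reference Reference-region name for SUVR/BPND; `NA` for SUV/VT.
#' @param pvc Logical: was partial volume correction applied?
#' @return A one-row data frame of class `regional_measure`.
#' @export
regional_measure <- function(subject, region, metric, value,
                             reference = NA_character_, pvc = FALSE) {
  metric <- match.arg(metric, c("SUV", "SUVR", "BPND", "VT"))
  if (metric %in% c("SUVR", "BPND") && (is.na(reference) || !nzchar(reference)))
    stop(metric, " requires a reference region name")
  if (metric %in% c("SUV", "VT") && !is.na(reference))
    stop(metric, " must not carry a reference region")
  if (!is.finite(value))
    stop("value must be finite")
  structure(data.frame(subject = as.character(subject),
                       region = as.character(region), metric = metric,
                       reference = as.character(reference),
                       pvc = as.logical(pvc), value = as.numeric(value)),
            class = c("regional_measure", "data.frame"))
}

#' Write regional measures to a delimited table
#'
#' Columns: subject, region, metric, reference, pvc, value. Values
#' round-trip through [read_regional_table()] to better than 1e-12
#' relative.
#'
#' @param measures A data frame of regional measures (rows from
#'   [regional_measure()] or an rbind of them).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_regional_table <- function(measures, path) {
  if (is.null(measures) || nrow(measures) == 0L)
    stop("nothing to write: empty measure list")
  cols <- c("subject", "region", "metric", "reference", "pvc", "value")
  if (!all(cols %in% names(measures)))
    stop("measures must have columns ", paste(cols, collapse = ", "))
  df <- as.data.frame(measures)[, cols]
  df$value <- sprintf("%.17g", df$value)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regional_table
#' @export
read_regional_table <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = c(
    subject = "character", region = "character", metric = "character",
    reference = "character", pvc = "logical", value = "character"))
  df$value <- as.numeric(df$value)  # %.17g strings survive quoting exactly
  structure(df, class = c("regional_measure", "data.frame"))
}
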