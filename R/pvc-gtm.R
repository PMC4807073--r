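# Partial volume correction via regional spread functions (RSF), also
# known as the geometric transfer matrix (GTM) technique: blur each
# region's binary indicator with the scanner point spread function, form
# the mixing matrix omega (observed region j <- source region i), and
# solve omega %*% T = t for the true regional means T.
#
# The blur used to build omega is the identical discrete operator used by
# the digital phantom generator, so for a noise-free phantom blurred with
# the matched PSF the correction is exact up to solver precision.

#' Scanner point spread function model
#'
#' @param fwhm Full width at half maximum in mm; a scalar (isotropic) or
#'   one value per axis. `0` denotes an exact delta PSF (no blur).
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(fwhm = 6) {
  fwhm <- as.numeric(fwhm)
  if (!length(fwhm) %in% c(1L, 3L) || any(!is.finite(fwhm)) || any(fwhm < 0))
    stop("fwhm must be 1 or 3 non-negative numbers (mm)")
  if (length(fwhm) == 1L)
    fwhm <- rep(fwhm, 3L)
  structure(list(fwhm = fwhm), class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("Gaussian PSF, FWHM %s mm\n",
              paste(format(x$fwhm, digits = 4), collapse = " x ")))
  invisible(x)
}

# Box-discretized 1D Gaussian kernel for a given sigma in voxel units:
# weight_k = Phi((k+1/2)/sigma) - Phi((k-1/2)/sigma), renormalized to 1.
.gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0)
    return(1)
  radius <- max(1L, ceiling(4 * sigma_vox))
  k <- -radius:radius
  w <- stats::pnorm((k + 0.5) / sigma_vox) - stats::pnorm((k - 0.5) / sigma_vox)
  w / sum(w)
}

# Dense convolution matrix (n x n) for one axis, zero-padded outside the
# field of view; row sums are <= 1, = 1 in the interior.
.conv_matrix <- function(n, sigma_vox) {
  kern <- .gauss_kernel_1d(sigma_vox)
  radius <- (length(kern) - 1L) %/% 2L
  C <- matrix(0, n, n)
  for (off in -radius:radius) {
    idx <- seq_len(n)
    j <- idx + off
    ok <- j >= 1L & j <= n
    C[cbind(idx[ok], j[ok])] <- kern[off + radius + 1L]
  }
  C
}

.fwhm_to_sigma_vox <- function(fwhm, voxel_size) {
  fwhm / (2 * sqrt(2 * log(2))) / voxel_size
}

#' Separable 3D Gaussian blur on the voxel grid
#'
#' Applies the same box-discretized, zero-padded kernel per axis that
#' [build_gtm()] uses to form regional spread functions, so that blurring
#' a phantom and correcting it are matched operations.
#'
#' @param arr 3D numeric array.
#' @param psf A [psf_model()].
#' @param voxel_size mm per axis (length 3).
#' @return Blurred array of the same shape.
#' @export
gaussian_blur <- function(arr, psf, voxel_size) {
  d <- dim(arr)
  if (length(d) != 3L)
    stop("arr must be 3D")
  sig <- .fwhm_to_sigma_vox(psf$fwhm, voxel_size)
  if (any(6 * sig > d))
    warning("PSF is wide relative to the volume extent")
  for (ax in 1:3) {
    if (sig[ax] <= 0) next
    C <- .conv_matrix(d[ax], sig[ax])
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    m <- C %*% matrix(a, nrow = d[ax])
    a <- array(m, dim = d[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Build the geometric transfer matrix for a label volume
#'
#' For each source region i, the regional spread function RSF_i is the
#' 3D Gaussian blur (sigma = FWHM / 2.3548 per axis, voxel units) of the
#' region's binary indicator; omega\[j, i\] is the mean of RSF_i over the
#' voxels of observed region j. With `include_background`, all label-0
#' voxels form one additional region (reported, but its corrected value is
#' conventionally discarded from outputs).
#'
#' @param labels A [label_volume()].
#' @param scheme An [roi_scheme()]; every scheme region must be non-empty
#'   in `labels`.
#' @param psf A [psf_model()].
#' @param include_background Model label-0 voxels as a region
#'   (default TRUE).
#' @return An object of class `gtm_system` with fields `omega`,
#'   `region_order` and `condition_number`.
#' @export
build_gtm <- function(labels, scheme, psf = psf_model(),
                      include_background = TRUE) {
  region_names <- names(scheme$regions)
  masks <- lapply(region_names, function(nm) {
    m <- labels$labels %in% scheme$regions[[nm]]
    if (!any(m))
      stop("empty region in label volume: ", nm)
    m
  })
  names(masks) <- region_names
  if (include_background) {
    bg <- labels$labels == 0L
    if (any(bg)) {
      masks <- c(masks, list(.background = bg))
      region_names <- c(region_names, ".background")
    }
  }
  K <- length(masks)
  d <- dim(labels$labels)
  omega <- matrix(0, K, K, dimnames = list(region_names, region_names))
  for (i in seq_len(K)) {
    rsf <- gaussian_blur(array(as.numeric(masks[[i]]), dim = d), psf,
                         labels$voxel_size)
    for (j in seq_len(K))
      omega[j, i] <- mean(rsf[masks[[j]]])
  }
  sv <- svd(omega, nu = 0, nv = 0)$d
  cond <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  structure(list(omega = omega, region_order = region_names,
                 condition_number = cond), class = "gtm_system")
}

#' @export
print.gtm_system <- function(x, ...) {
  cat(sprintf("GTM system: %d regions (%s), condition number %.4g\n",
              length(x$region_order),
              paste(x$region_order, collapse = ", "), x$condition_number))
  invisible(x)
}

#' Correct observed regional means with a GTM system
#'
#' Solves `omega %*% T = t` for the true means `T` by least squares
#' (QR, never an explicit inverse). Corrections are refused when the
#' system is ill-conditioned.
#'
#' @param system A [gtm_system()][build_gtm()].
#' @param observed_means Numeric vector of observed regional means, in
#'   `system$region_order`.
#' @param cond_limit Refuse the solve above this condition number
#'   (default 1e4).
#' @return Corrected means, named by `region_order`.
#' @export
apply_gtm <- function(system, observed_means, cond_limit = 1e4) {
  if (length(observed_means) != length(system$region_order))
    stop(sprintf("length mismatch: %d observed means for %d regions",
                 length(observed_means), length(system$region_order)))
  if (!is.finite(system$condition_number) ||
      system$condition_number > cond_limit)
    stop(sprintf(
      "ill-conditioned GTM (condition number %.4g > limit %.4g)",
      system$condition_number, cond_limit))
  corrected <- qr.solve(system$omega, as.numeric(observed_means))
  stats::setNames(corrected, system$region_order)
}

#' Frame-wise RSF partial volume correction of a dynamic volume
#'
#' Builds one GTM from the label volume, then corrects the vector of
#' observed regional means frame by frame, yielding corrected TACs that
#' feed PVC SUVR and PVC Logan analysis.
#'
#' @inheritParams build_gtm
#' @param pet A [dynamic_volume()] on the same grid as `labels`.
#' @param cond_limit Passed to [apply_gtm()].
#' @return Named list of corrected [tac()] objects, one per scheme region
#'   (background is used in the solve but dropped from the output).
#' @export
correct_dynamic <- function(pet, labels, scheme, psf = psf_model(),
                            include_background = TRUE, cond_limit = 1e4) {
  .check_grid_match(pet, labels)
  system <- build_gtm(labels, scheme, psf, include_background)
  observed <- vapply(system$region_order, function(nm) {
    ids <- if (nm == ".background") 0L else scheme$regions[[nm]]
    extract_tac(pet, labels, ids)$values
  }, numeric(n_frames(pet$schedule)))
  observed <- matrix(observed, nrow = n_frames(pet$schedule))
  corrected <- apply(observed, 1L, function(v)
    apply_gtm(system, v, cond_limit))
  corrected <- matrix(corrected, ncol = n_frames(pet$schedule))
  out_regions <- setdiff(system$region_order, ".background")
  out <- lapply(match(out_regions, system$region_order), function(i)
    tac_on_schedule(pet$schedule, corrected[i, ]))
  stats::setNames(out, out_regions)
}
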