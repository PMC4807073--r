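# Regional quantification: TAC extraction, windowed means, SUV, SUVR,
# composites and cross-sectional group comparison.

#' Extract a regional time-activity curve
#'
#' Per-frame unweighted mean over all voxels whose label is in
#' `label_ids`; TAC mid-times are frame (start + end) / 2.
#'
#' @param pet A [dynamic_volume()].
#' @param labels A [label_volume()] on the same grid.
#' @param label_ids Integer vector of label IDs defining the ROI.
#' @return A [tac()].
#' @export
extract_tac <- function(pet, labels, label_ids) {
  .check_grid_match(pet, labels)
  mask <- labels$labels %in% as.integer(label_ids)
  if (!any(mask))
    stop("empty ROI: no voxel carries label(s) ",
         paste(label_ids, collapse = ", "))
  nf <- dim(pet$voxels)[4L]
  vox <- matrix(pet$voxels, ncol = nf)
  values <- colMeans(vox[mask, , drop = FALSE])
  tac_on_schedule(pet$schedule, values)
}

#' Duration-weighted mean activity within a time window
#'
#' Uses only frames fully contained in `[t0, t1]` (frame start >= t0 and
#' end <= t1, reconstructed as mid-time +/- duration / 2); partially
#' overlapping frames are excluded rather than fractionally weighted.
#'
#' @param tac A [tac()].
#' @param t0,t1 Window bounds, minutes post-injection (default 40-70 min,
#'   the standard amyloid PET uptake window).
#' @return Mean activity, kBq/mL.
#' @export
windowed_mean <- function(tac, t0 = 40, t1 = 70) {
  starts <- tac$mid_times - tac$durations / 2
  ends <- tac$mid_times + tac$durations / 2
  keep <- starts >= t0 - 1e-9 & ends <= t1 + 1e-9
  if (!any(keep))
    stop(sprintf("no frame fully contained in [%g, %g] min", t0, t1))
  sum(tac$values[keep] * tac$durations[keep]) / sum(tac$durations[keep])
}

#' Standardized uptake value
#'
#' SUV = activity / (injected dose / body weight), with dose converted to
#' kBq and body weight to mL at an assumed tissue density of 1 g/mL, so
#' the result is unitless.
#'
#' @param mean_activity Regional mean activity, kBq/mL.
#' @param dose A [dose_record()].
#' @return SUV (unitless).
#' @export
compute_suv <- function(mean_activity, dose) {
  if (!inherits(dose, "dose_record"))
    dose <- do.call(dose_record, as.list(dose))
  dose_kbq <- dose$injected_dose * 1000      # MBq -> kBq
  weight_ml <- dose$body_weight * 1000       # kg -> g -> mL at 1 g/mL
  mean_activity / (dose_kbq / weight_ml)
}

#' Standardized uptake value ratio
#'
#' @param target_mean Target-region mean activity.
#' @param reference_mean Reference-region mean activity, > 0.
#' @return SUVR = target / reference; invariant to common rescaling.
#' @export
compute_suvr <- function(target_mean, reference_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0)
    stop("reference mean must be positive")
  target_mean / reference_mean
}

#' Volume-weighted composite of per-region values
#'
#' Aggregates member-region values of a composite with ROI-volume weights
#' (approximating voxel-level pooling of the member regions); set
#' `weighted = FALSE` for an unweighted mean.
#'
#' @param per_region Named numeric vector or list, region -> value.
#' @param scheme An [roi_scheme()].
#' @param composite Composite name in `scheme`.
#' @param weights Named numeric vector, region -> ROI volume (mL), all
#'   positive. Ignored when `weighted = FALSE`.
#' @param weighted Use volume weighting (default TRUE).
#' @return The composite value, guaranteed inside the member value range.
#' @export
composite_value <- function(per_region, scheme, composite, weights = NULL,
                            weighted = TRUE) {
  if (!composite %in% names(scheme$composites))
    stop("unknown composite: ", composite)
  members <- scheme$composites[[composite]]
  per_region <- unlist(per_region)
  missing <- setdiff(members, names(per_region))
  if (length(missing))
    stop("missing member value(s): ", paste(missing, collapse = ", "))
  vals <- as.numeric(per_region[members])
  if (!weighted)
    return(mean(vals))
  if (is.null(weights))
    stop("weights required for volume-weighted composite")
  weights <- unlist(weights)
  missing_w <- setdiff(members, names(weights))
  if (length(missing_w))
    stop("missing member weight(s): ", paste(missing_w, collapse = ", "))
  w <- as.numeric(weights[members])
  if (any(!is.finite(w)) || any(w <= 0) || sum(w) <= 0)
    stop("member weights must be positive")
  sum(w * vals) / sum(w)
}

#' Two-sample group comparison
#'
#' Student (pooled-variance, the cross-sectional default) or Welch
#' two-sample t-test. Two identical degenerate groups (zero pooled
#' variance, equal means) are reported as t = 0, p = 1.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @return List with elements `t` and `p` (two-sided).
#' @export
group_compare <- function(group_a, group_b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs n >= 2")
  pooled_var <- (sum((group_a - mean(group_a))^2) +
                 sum((group_b - mean(group_b))^2)) /
    (length(group_a) + length(group_b) - 2L)
  if (pooled_var == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, p = 1))
    stop("zero variance with unequal means: t is unbounded")
  }
  fit <- stats::t.test(group_a, group_b,
                       var.equal = (variant == "student"))
  list(t = unname(fit$statistic), p = fit$p.value)
}
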