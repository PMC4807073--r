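# High-level regional quantification pipeline: one call from a dynamic
# volume + segmentation to a table of SUVR (or SUV) measures under a
# chosen reference composite, with or without RSF/GTM partial volume
# correction.

#' Regional SUVR (or SUV) table for one scan
#'
#' Extracts per-region windowed means, optionally corrects them with the
#' RSF/GTM technique, and reports each region's SUVR against the chosen
#' reference composite plus the reserved composites themselves. Composite
#' values are ROI-volume-weighted means of member-region values.
#'
#' @param pet A [dynamic_volume()].
#' @param labels A [label_volume()] on the same grid.
#' @param scheme An [roi_scheme()] (default: [load_roi_scheme()]).
#' @param ref Reference composite name (`"cer"`, `"bs"`, `"cw"`, `"tw"`).
#' @param window Evaluation window `c(t0, t1)` in minutes (default
#'   40-70).
#' @param pvc `"none"` or `"rsf"`.
#' @param psf A [psf_model()] for `pvc = "rsf"`.
#' @param dose Optional [dose_record()]; when given, SUV rows are
#'   appended for every region and composite.
#' @param subject Subject identifier for the output table.
#' @param cond_limit Condition-number limit for the GTM solve.
#' @return A `regional_measure` data frame (one row per region/composite
#'   and metric).
#' @export
regional_suvr_table <- function(pet, labels, scheme = load_roi_scheme(),
                                ref = "cer", window = c(40, 70),
                                pvc = c("none", "rsf"), psf = psf_model(),
                                dose = NULL, subject = "subject",
                                cond_limit = 1e4) {
  pvc <- match.arg(pvc)
  if (!ref %in% names(scheme$composites))
    stop("unknown reference composite: ", ref)
  # quantify only the scheme regions the segmentation actually contains
  # (partial user configs keep default regions that a given study may lack)
  present <- vapply(scheme$regions, function(ids)
    any(labels$labels %in% ids), logical(1))
  if (!any(present))
    stop("no scheme region is present in the label volume")
  if (!all(present)) {
    dropped <- names(scheme$regions)[!present]
    keep <- names(scheme$regions)[present]
    scheme <- roi_scheme(
      scheme$regions[present],
      Filter(length, lapply(scheme$composites, intersect, keep)))
    if (!ref %in% names(scheme$composites))
      stop("reference composite '", ref, "' has no region in the ",
           "label volume")
    message("dropping scheme region(s) absent from segmentation: ",
            paste(dropped, collapse = ", "))
  }
  region_names <- names(scheme$regions)
  if (pvc == "rsf") {
    tacs <- correct_dynamic(pet, labels, scheme, psf,
                            cond_limit = cond_limit)
  } else {
    tacs <- lapply(region_names, function(nm)
      extract_tac(pet, labels, scheme$regions[[nm]]))
    names(tacs) <- region_names
  }
  means <- vapply(tacs, windowed_mean, numeric(1),
                  t0 = window[1L], t1 = window[2L])
  vols <- region_volumes(labels, scheme)
  comp_means <- vapply(names(scheme$composites), function(cmp)
    composite_value(means, scheme, cmp, weights = vols), numeric(1))
  all_means <- c(means, comp_means)
  ref_mean <- comp_means[[ref]]
  rows <- lapply(names(all_means), function(nm)
    regional_measure(subject, nm, "SUVR",
                     compute_suvr(all_means[[nm]], ref_mean),
                     reference = ref, pvc = pvc == "rsf"))
  if (!is.null(dose)) {
    rows <- c(rows, lapply(names(all_means), function(nm)
      regional_measure(subject, nm, "SUV",
                       compute_suv(all_means[[nm]], dose),
                       pvc = pvc == "rsf")))
  }
  do.call(rbind, rows)
}

#' Mean cortical SUVR for one scan
#'
#' Convenience wrapper returning just the `mc` composite SUVR against the
#' chosen reference.
#'
#' @inheritParams regional_suvr_table
#' @return A single numeric SUVR value.
#' @export
mc_suvr <- function(pet, labels, scheme = load_roi_scheme(), ref = "cer",
                    window = c(40, 70), pvc = c("none", "rsf"),
                    psf = psf_model(), cond_limit = 1e4) {
  tab <- regional_suvr_table(pet, labels, scheme, ref, window, match.arg(pvc),
                             psf, cond_limit = cond_limit)
  tab$value[tab$region == "mc" & tab$metric == "SUVR"]
}
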