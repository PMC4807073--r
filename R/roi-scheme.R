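# ROI schemes: named regions (sets of FreeSurfer label IDs) plus named
# composites over those regions. The reserved composites are:
#   cer - cerebellar cortex reference
#   bs  - brainstem (approximates the pontine reference)
#   cw  - core white matter (corpus callosum + unsegmented white matter)
#   tw  - total cerebral white matter
#   mc  - mean cortical target composite
.RESERVED_COMPOSITES <- c("mc", "cer", "bs", "cw", "tw")

#' Construct an ROI scheme
#'
#' @param regions Named list: region name -> integer vector of label IDs
#'   (non-empty, no duplicates across calls enforced by the label volume).
#' @param composites Named list: composite name -> character vector of
#'   member region names, all of which must exist in `regions`.
#' @return An object of class `roi_scheme`.
#' @seealso [load_roi_scheme()] for the default FreeSurfer-based scheme.
#' @export
roi_scheme <- function(regions, composites = list()) {
  if (length(regions) < 1L || is.null(names(regions)) ||
      any(!nzchar(names(regions))))
    stop("regions must be a non-empty named list")
  if (anyDuplicated(names(regions)))
    stop("duplicate region names")
  regions <- lapply(regions, function(x) {
    x <- as.integer(x)
    if (length(x) < 1L || any(is.na(x)) || any(x < 0))
      stop("empty or invalid label list in ROI scheme")
    sort(unique(x))
  })
  if (length(composites)) {
    if (is.null(names(composites)) || any(!nzchar(names(composites))))
      stop("composites must be named")
    if (anyDuplicated(names(composites)))
      stop("duplicate composite names")
    for (nm in names(composites)) {
      members <- as.character(composites[[nm]])
      missing <- setdiff(members, names(regions))
      if (length(missing))
        stop(sprintf("composite '%s' references unknown region(s): %s",
                     nm, paste(missing, collapse = ", ")))
      if (length(members) < 1L)
        stop(sprintf("composite '%s' has no members", nm))
      composites[[nm]] <- members
    }
  }
  structure(list(regions = regions, composites = composites),
            class = "roi_scheme")
}

#' @export
print.roi_scheme <- function(x, ...) {
  cat(sprintf("ROI scheme: %d regions, %d composites (%s)\n",
              length(x$regions), length(x$composites),
              paste(names(x$composites), collapse = ", ")))
  invisible(x)
}

#' All label IDs belonging to a region or composite
#' @param scheme An [roi_scheme()].
#' @param name A region or composite name.
#' @return Integer vector of label IDs.
#' @export
scheme_label_ids <- function(scheme, name) {
  if (name %in% names(scheme$composites)) {
    sort(unique(unlist(scheme$regions[scheme$composites[[name]]],
                       use.names = FALSE)))
  } else if (name %in% names(scheme$regions)) {
    scheme$regions[[name]]
  } else {
    stop("unknown region or composite: ", name)
  }
}

# Bilateral aparc cortical label pair (ctx-lh = 1000 + i, ctx-rh = 2000 + i).
.aparc_pair <- function(idx) c(1000L + idx, 2000L + idx)

.default_regions <- function() {
  list(
    # reference building blocks (aseg labels)
    `Left-Cerebellum-Cortex`      = 8L,
    `Right-Cerebellum-Cortex`     = 47L,
    `Brain-Stem`                  = 16L,
    `Corpus-Callosum`             = 251:255,
    `Unsegmented-White-Matter`    = c(5001L, 5002L),
    `Cerebral-White-Matter`       = c(2L, 41L),
    # mean cortical members (bilateral aparc pairs); the exact membership
    # is configurable -- this default is a documented stand-in
    precuneus                     = .aparc_pair(25L),
    superiorfrontal               = .aparc_pair(28L),
    rostralmiddlefrontal          = .aparc_pair(27L),
    lateralorbitofrontal          = .aparc_pair(12L),
    medialorbitofrontal           = .aparc_pair(14L),
    superiortemporal              = .aparc_pair(30L),
    middletemporal                = .aparc_pair(15L)
  )
}

.default_composites <- function() {
  list(
    cer = c("Left-Cerebellum-Cortex", "Right-Cerebellum-Cortex"),
    bs  = "Brain-Stem",
    cw  = c("Corpus-Callosum", "Unsegmented-White-Matter"),
    tw  = c("Cerebral-White-Matter", "Corpus-Callosum",
            "Unsegmented-White-Matter"),
    mc  = c("precuneus", "superiorfrontal", "rostralmiddlefrontal",
            "lateralorbitofrontal", "medialorbitofrontal",
            "superiortemporal", "middletemporal")
  )
}

#' Load an ROI scheme (default or from a YAML/JSON config)
#'
#' The default scheme uses the FreeSurfer aseg/aparc label convention:
#' `cer` = bilateral cerebellar cortex \{8, 47\}; `bs` = brainstem \{16\}
#' (approximating a pontine reference); `cw` = corpus callosum
#' \{251..255\} plus unsegmented white matter \{5001, 5002\};
#' `tw` = cerebral white matter \{2, 41\} plus the `cw` labels; `mc` = a
#' configurable bilateral cortical composite (precuneus, superior frontal,
#' rostral middle frontal, lateral and medial orbitofrontal, superior and
#' middle temporal).
#'
#' A config file holds top-level maps `regions` (name -> list of label
#' IDs) and `composites` (name -> list of region names); entries override
#' the defaults per region/composite. All five reserved composites
#' (`mc`, `cer`, `bs`, `cw`, `tw`) must be present after merging.
#'
#' @param path `"default"` or a path to a YAML/JSON scheme config.
#' @return An [roi_scheme()].
#' @export
load_roi_scheme <- function(path = "default") {
  regions <- .default_regions()
  composites <- .default_composites()
  if (!identical(path, "default")) {
    if (!file.exists(path))
      stop("file not found: ", path)
    cfg <- yaml::read_yaml(path)
    for (nm in names(cfg$regions))
      regions[[nm]] <- as.integer(unlist(cfg$regions[[nm]]))
    for (nm in names(cfg$composites))
      composites[[nm]] <- as.character(unlist(cfg$composites[[nm]]))
  }
  scheme <- roi_scheme(regions, composites)
  missing <- setdiff(.RESERVED_COMPOSITES, names(scheme$composites))
  if (length(missing))
    stop("scheme is missing reserved composite(s): ",
         paste(missing, collapse = ", "))
  scheme
}

#' Region volumes in a label volume
#'
#' @param labels A [label_volume()].
#' @param scheme An [roi_scheme()].
#' @param names Region or composite names (default: all regions).
#' @return Named numeric vector of volumes in mL (voxel count times voxel
#'   volume; 1 mm^3 = 1e-3 mL).
#' @export
region_volumes <- function(labels, scheme, names = base::names(scheme$regions)) {
  voxel_ml <- prod(labels$voxel_size) / 1000
  counts <- vapply(names, function(nm) {
    sum(labels$labels %in% scheme_label_ids(scheme, nm))
  }, numeric(1))
  counts * voxel_ml
}
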