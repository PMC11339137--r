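# Per-subject, per-zone aggregation of parameter maps and the
# inner-zone-normalized gradient representation.

ZONE_NAMES <- c("IZ", "MZ", "OZ")
METRICS <- c("FA", "MD", "Dax_intra", "Dax_extra", "V_intra", "V_CSF")

#' Summarize parameter maps over the zone parcellation
#'
#' For each metric map and each zone, the chosen statistic of the valid
#' (non-`NA`) voxels. Edema volume is reported both for the included
#' (post-exclusion) voxels and for the full edema mask when supplied.
#'
#' @param maps Named list of 3D arrays, conventionally `FA`, `MD`,
#'   `Dax_intra`, `Dax_extra`, `V_intra`, `V_CSF` (any subset allowed).
#' @param parcellation A `zone_parcellation` from [zonate()].
#' @param spacing Voxel spacing in mm (length 3), for the volume tally.
#' @param statistic `"mean"` (default) or `"median"` voxel aggregator.
#' @param subject,group Identifier strings carried into the output.
#' @param full_edema_vox Optional voxel count of the edema mask before
#'   exclusions.
#' @return An object of class `subject_zone_summary`: data.frame with one
#'   row per metric, columns `subject`, `group`, `metric`, `IZ`, `MZ`,
#'   `OZ`, plus attributes `edema_volume_ml` (included voxels),
#'   `edema_volume_full_ml`, `counts`, `incomplete`.
#' @export
summarize_zones <- function(maps, parcellation, spacing,
                            statistic = c("mean", "median"),
                            subject = "s1", group = NA_character_,
                            full_edema_vox = NULL) {
  statistic <- match.arg(statistic)
  agg <- if (statistic == "mean") mean else stats::median
  zone <- parcellation$zone
  rows <- list()
  incomplete <- FALSE
  for (mname in names(maps)) {
    map <- maps[[mname]]
    stopifnot(identical(dim(map), dim(zone)))
    vals <- vapply(1:3, function(k) {
      v <- map[zone == k]
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        incomplete <<- TRUE
        return(NA_real_)
      }
      agg(v)
    }, numeric(1))
    rows[[mname]] <- data.frame(subject = subject, group = group,
                                metric = mname, IZ = vals[1], MZ = vals[2],
                                OZ = vals[3], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  vox_ml <- prod(spacing) / 1000
  attr(out, "edema_volume_ml") <- sum(parcellation$counts) * vox_ml
  if (!is.null(full_edema_vox)) {
    attr(out, "edema_volume_full_ml") <- full_edema_vox * vox_ml
  }
  attr(out, "counts") <- parcellation$counts
  attr(out, "incomplete") <- incomplete
  class(out) <- c("subject_zone_summary", class(out))
  out
}

#' Zone gradients normalized to the inner zone
#'
#' Differences MZ - IZ and OZ - IZ per metric (the IZ - IZ difference is
#' identically zero and is not carried).
#'
#' @param summary A `subject_zone_summary` from [summarize_zones()].
#' @return Data.frame with columns `subject`, `group`, `metric`,
#'   `MZ_IZ`, `OZ_IZ`.
#' @export
zone_gradients <- function(summary) {
  if (isTRUE(attr(summary, "incomplete"))) {
    stop("incomplete subject: a zone has no valid voxels for some metric")
  }
  data.frame(subject = summary$subject, group = summary$group,
             metric = summary$metric,
             MZ_IZ = summary$MZ - summary$IZ,
             OZ_IZ = summary$OZ - summary$IZ,
             stringsAsFactors = FALSE)
}

#' Stack per-subject summaries into a tidy long table
#'
#' @param summaries List of `subject_zone_summary` objects.
#' @return Data.frame with columns `subject`, `group`, `metric`, `zone`,
#'   `value`, `edema_volume_ml`.
#' @export
tidy_zone_summaries <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    vol <- attr(s, "edema_volume_ml")
    do.call(rbind, lapply(ZONE_NAMES, function(z) {
      data.frame(subject = s$subject, group = s$group, metric = s$metric,
                 zone = z, value = s[[z]], edema_volume_ml = vol,
                 stringsAsFactors = FALSE)
    }))
  }))
}
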