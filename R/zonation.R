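# Equal-volume parcellation of the edema shell by Euclidean expansion
# from the enhancing-core outline.

# Shift a logical 3D array by one voxel along axis k (direction +/-1),
# filling with FALSE. Used for 6-connectivity neighborhood operations.
shift_mask <- function(m, k, dir) {
  out <- array(FALSE, dim = dim(m))
  n <- dim(m)[k]
  idx_src <- if (dir > 0) 1:(n - 1) else 2:n
  idx_dst <- if (dir > 0) 2:n else 1:(n - 1)
  if (k == 1) out[idx_dst, , ] <- m[idx_src, , ]
  if (k == 2) out[, idx_dst, ] <- m[, idx_src, ]
  if (k == 3) out[, , idx_dst] <- m[, , idx_src]
  out
}

# One step of 6-connectivity dilation.
dilate6 <- function(m) {
  out <- m
  for (k in 1:3) for (dir in c(-1, 1)) out <- out | shift_mask(m, k, dir)
  out
}

#' Exclude tumor margins and adjacent gray matter from the edema
#'
#' Removes edema voxels within `margin_vox` voxels (6-connectivity
#' dilation) of the enhancing core — partial-volume contamination at the
#' enhancing margin — and any edema voxel 6-adjacent to a gray-matter
#' voxel.
#'
#' @param labels Label volume from [make_labels()] (or any integer array
#'   using the same codes with a `spacing` attribute).
#' @param margin_vox Width of the core margin exclusion in voxels
#'   (default 1).
#' @return A logical 3D array of included edema voxels, with attribute
#'   `exclusions` = counts per reason (`margin`, `gray_matter`).
#' @export
exclude_margins <- function(labels, margin_vox = 1) {
  core <- labels == LABELS[["core"]]
  edema <- labels == LABELS[["edema"]]
  if (!any(core) || !any(edema)) stop("labels must contain core and edema")

  dil <- core
  for (i in seq_len(margin_vox)) dil <- dilate6(dil)
  margin_excl <- edema & dil

  gm_adj <- dilate6(labels == LABELS[["gray_matter"]])
  gm_excl <- edema & gm_adj & !margin_excl

  included <- edema & !margin_excl & !gm_excl
  if (!any(included)) {
    stop("degenerate parcellation: all edema voxels excluded")
  }
  attr(included, "exclusions") <- c(margin = sum(margin_excl),
                                    gray_matter = sum(gm_excl))
  included
}

#' Euclidean distance from the core outline
#'
#' For each included edema voxel, the anisotropy-aware Euclidean distance
#' (mm) from its center to the nearest core voxel center. This is the
#' sampled exact distance transform of the core, restricted to the
#' included voxels.
#'
#' @param core Logical 3D array: enhancing-core voxels.
#' @param included Logical 3D array: edema voxels to measure.
#' @param spacing Voxel spacing in mm (length 3).
#' @return Numeric vector of distances, one per `which(included)` voxel
#'   in array order.
#' @export
distance_from_core <- function(core, included, spacing) {
  if (!any(core)) stop("empty core mask")
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  dims <- dim(core)
  coord <- function(mask) {
    ijk <- which(mask, arr.ind = TRUE)
    sweep(ijk, 2, spacing, "*")
  }
  cc <- coord(core)
  ec <- coord(included)
  if (nrow(ec) == 0) return(numeric(0))
  # chunked exact nearest-neighbor distances
  out <- numeric(nrow(ec))
  chunk <- max(1L, floor(2e7 / nrow(cc)))
  c2 <- rowSums(cc^2)
  for (start in seq(1, nrow(ec), by = chunk)) {
    rows <- start:min(start + chunk - 1, nrow(ec))
    e <- ec[rows, , drop = FALSE]
    d2 <- outer(rowSums(e^2), c2, "+") - 2 * e %*% t(cc)
    out[rows] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# Deterministic equal-count bands of a distance vector: stable sort by
# (distance, index), remainder assigned innermost-first. Returns integer
# band labels 1..n_zones aligned with the input order.
tertile_bands <- function(d, n_zones = 3) {
  n <- length(d)
  ord <- order(d, seq_along(d))
  base <- n %/% n_zones
  sizes <- rep(base, n_zones)
  r <- n %% n_zones
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  bands <- rep(seq_len(n_zones), times = sizes)
  out <- integer(n)
  out[ord] <- bands
  out
}

#' Partition the edema into equal-volume distance-ordered zones
#'
#' Voxels are sorted by (distance, array index) and split into `n_zones`
#' consecutive bands of equal count (remainder voxels go to the inner
#' zones first). Zone 1 is the inner zone adjacent to the enhancing core,
#' zone `n_zones` the outer zone at the edema boundary.
#'
#' @param distance Distances (mm) from [distance_from_core()].
#' @param included Logical 3D array matching the distance vector.
#' @param n_zones Number of zones (default 3; must be >= 2).
#' @return An object of class `zone_parcellation`: list with `zone`
#'   (integer 3D array, 0 = excluded/background, 1 = IZ .. `n_zones` = OZ),
#'   `distance` (vector, mm), `thresholds` (max distance per zone, mm),
#'   `counts` (voxels per zone), and `exclusions` (carried over from
#'   `included`, if present).
#' @export
partition_equal_volume <- function(distance, included, n_zones = 3) {
  if (n_zones < 2) stop("n_zones must be at least 2")
  n <- sum(included)
  if (n < n_zones) stop("fewer included voxels than zones")
  stopifnot(length(distance) == n)
  bands <- tertile_bands(distance, n_zones)
  zone <- array(0L, dim = dim(included))
  zone[which(included)] <- bands
  thresholds <- vapply(seq_len(n_zones),
                       function(k) max(distance[bands == k]), numeric(1))
  counts <- tabulate(bands, n_zones)
  structure(list(zone = zone, distance = distance,
                 thresholds = thresholds, counts = counts,
                 exclusions = attr(included, "exclusions")),
            class = "zone_parcellation")
}

#' @export
print.zone_parcellation <- function(x, ...) {
  k <- length(x$counts)
  cat("Zone parcellation:", sum(x$counts), "included voxels in", k, "zones\n")
  cat("  counts:", paste(x$counts, collapse = ", "), "\n")
  cat("  distance thresholds (mm):",
      paste(sprintf("%.2f", x$thresholds), collapse = ", "), "\n")
  if (!is.null(x$exclusions)) {
    cat("  excluded:", paste(names(x$exclusions), x$exclusions,
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full zonation of a label volume
#'
#' Convenience wrapper: margin and gray-matter exclusion, Euclidean
#' distance from the core outline, and equal-volume partition.
#'
#' @param labels Label volume (see [make_labels()]).
#' @param n_zones Number of zones (default 3).
#' @param margin_vox Core margin exclusion width in voxels (default 1).
#' @return A `zone_parcellation` (see [partition_equal_volume()]).
#' @export
zonate <- function(labels, n_zones = 3, margin_vox = 1) {
  spacing <- attr(labels, "spacing")
  if (is.null(spacing)) stop("labels must carry a 'spacing' attribute")
  included <- exclude_margins(labels, margin_vox = margin_vox)
  d <- distance_from_core(labels == LABELS[["core"]], included, spacing)
  partition_equal_volume(d, included, n_zones = n_zones)
}
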