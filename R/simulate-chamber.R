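#' Simulate a voxelized border-cell cluster inside an egg chamber
#'
#' Places an axis-aligned ellipsoidal cluster along the anterior-posterior
#' (x) axis of an egg chamber, at the fractional position
#' `anterior_pos + cluster_fraction * (oocyte_pos - anterior_pos)`, and
#' voxelizes it (a voxel is foreground when its centre lies inside the
#' ellipsoid). The returned landmarks are the ground truth for
#' [migration_index()]; the ellipsoid axes are the ground truth for
#' [principal_extents()] and [sphericity()].
#'
#' @param anterior_pos,oocyte_pos landmarks on the AP axis, um
#'   (`oocyte_pos > anterior_pos`).
#' @param cluster_fraction fractional cluster position in \[0, 1\]
#'   (0 = anterior, 1 = oocyte).
#' @param cluster_axes semi-axes (a, b, c) of the ellipsoid, um; `a` lies
#'   along the AP axis.
#' @param voxel_size voxel edge, um (scalar or length-3 for anisotropic
#'   voxels, ordered x, y, z).
#' @param margin padding around the chamber span and the ellipsoid, um.
#' @param dims optional explicit volume size in voxels (x, y, z); an
#'   ellipsoid not contained in an explicit volume is an error.
#' @param seed unused by the deterministic geometry; accepted for interface
#'   symmetry with the other generators.
#' @return list of class `egg_chamber_sim`:
#'   \describe{
#'     \item{volume}{a [cluster_volume()] (x, y, z voxel array)}
#'     \item{model}{list `anterior_pos`, `oocyte_pos`, `cluster_centroid`
#'       (planted, um), `origin` (um of the voxel grid corner)}
#'   }
#' @export
simulate_egg_chamber <- function(anterior_pos = 0, oocyte_pos = 100,
                                 cluster_fraction = 0.5,
                                 cluster_axes = c(8, 6, 5),
                                 voxel_size = 1, margin = NULL,
                                 dims = NULL, seed = NULL) {
  if (!is.numeric(oocyte_pos) || !is.numeric(anterior_pos) ||
      oocyte_pos <= anterior_pos)
    stop_param("'oocyte_pos' must exceed 'anterior_pos'")
  if (!is.numeric(cluster_fraction) || length(cluster_fraction) != 1L ||
      is.na(cluster_fraction) || cluster_fraction < 0 || cluster_fraction > 1)
    stop_param("'cluster_fraction' must lie in [0, 1]")
  if (!is.numeric(cluster_axes) || length(cluster_axes) != 3L ||
      any(cluster_axes <= 0))
    stop_param("'cluster_axes' must be three positive semi-axes (um)")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_param("'voxel_size' must be a positive scalar or length-3 vector")
  margin <- margin %||% (max(cluster_axes) + 2 * max(voxel_size))

  centroid_x <- anterior_pos + cluster_fraction * (oocyte_pos - anterior_pos)
  half_yz <- cluster_axes[2:3] + margin
  if (is.null(dims)) {
    origin <- c(anterior_pos - margin - cluster_axes[1], -half_yz)
    extent <- c(oocyte_pos + margin + cluster_axes[1] - origin[1], 2 * half_yz)
    dims <- ceiling(extent / voxel_size)
  } else {
    dims <- vapply(seq_len(3L), function(i) check_count(dims[i], "dims"), 1L)
    origin <- c(anterior_pos - margin, -(dims[2:3] * voxel_size[2:3]) / 2)
  }
  center <- c(centroid_x, 0, 0)
  if (any(center - cluster_axes < origin) ||
      any(center + cluster_axes > origin + dims * voxel_size))
    stop_param("ellipsoid not contained in the volume")

  cx <- origin[1] + (seq_len(dims[1]) - 0.5) * voxel_size[1]
  cy <- origin[2] + (seq_len(dims[2]) - 0.5) * voxel_size[2]
  cz <- origin[3] + (seq_len(dims[3]) - 0.5) * voxel_size[3]
  qx <- ((cx - center[1]) / cluster_axes[1])^2
  qy <- ((cy - center[2]) / cluster_axes[2])^2
  qz <- ((cz - center[3]) / cluster_axes[3])^2
  vol <- outer(outer(qx, qy, `+`), qz, `+`) <= 1
  if (!any(vol)) stop_param("ellipsoid too small for the voxel grid")

  volume <- cluster_volume(vol * 1L, voxel_size = voxel_size, origin = origin)
  model <- list(anterior_pos = anterior_pos, oocyte_pos = oocyte_pos,
                cluster_centroid = centroid_x, origin = origin)
  structure(list(volume = volume, model = model), class = "egg_chamber_sim")
}

#' Labelled 3D cluster volume container
#'
#' @param voxels 3D array (x, y, z); non-zero voxels are foreground.
#' @param voxel_size voxel edges, um (scalar or length 3, ordered x, y, z).
#' @param origin world coordinate (um) of the grid corner before voxel
#'   (1, 1, 1); defaults to the origin.
#' @return list of class `cluster_volume`.
#' @export
cluster_volume <- function(voxels, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_param("'voxels' must be a 3D array")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_param("'voxel_size' must be a positive scalar or length-3 vector")
  structure(list(voxels = voxels != 0, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "cluster_volume")
}

#' @export
print.cluster_volume <- function(x, ...) {
  cat(sprintf("cluster_volume: %s voxels (%s um each), %d foreground\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(signif(x$voxel_size, 3), collapse = " x "),
              sum(x$voxels)))
  invisible(x)
}
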