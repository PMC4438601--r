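#' Extract node time series from a 4-D NIfTI image
#'
#' Averages the BOLD signal over all voxels whose centers fall within
#' `radius_mm` of each node center (spherical ROIs; e.g. 10 mm diameter
#' nodes use `radius_mm = 5`). Node centers are given in world (scanner)
#' millimetre coordinates, RAS convention, and are mapped against voxel
#' centers through the image's sform/qform affine.
#'
#' @param image a 4-D NIfTI image, or a path readable by
#'   [RNifti::readNifti()].
#' @param centers numeric n_nodes x 3 matrix of world coordinates (x, y, z
#'   in mm); row names, if present, become node IDs.
#' @param radius_mm sphere radius in millimetres (> 0).
#' @param tr repetition time in seconds; defaults to the image's pixdim.
#' @return a [ts_matrix()] with one row per node.
#' @export
extract_node_timeseries <- function(image, centers, radius_mm = 5, tr = NULL) {
  check_number(radius_mm, "radius_mm", lower = 1e-9)
  img <- if (is.character(image)) RNifti::readNifti(image) else image
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stopf("a 4-D image is required")
  dm <- dim(arr)
  centers <- as.matrix(centers)
  if (ncol(centers) != 3L) stopf("`centers` must have 3 columns (x, y, z mm)")
  ids <- rownames(centers) %||% sprintf("n%03d", seq_len(nrow(centers)))
  if (is.null(tr)) {
    pd <- attr(img, "pixdim")
    tr <- if (!is.null(pd) && length(pd) >= 4L && pd[4] > 0) pd[4] else 1
  }
  A <- RNifti::xform(img)              # voxel (0-based) -> world mm
  ijk <- as.matrix(expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1),
                               k = 0:(dm[3] - 1)))
  world <- ijk %*% t(A[1:3, 1:3]) + matrix(A[1:3, 4], nrow(ijk), 3,
                                           byrow = TRUE)
  flat <- matrix(arr, nrow = prod(dm[1:3]), ncol = dm[4])
  out <- matrix(NA_real_, nrow(centers), dm[4])
  for (n in seq_len(nrow(centers))) {
    d2 <- (world[, 1] - centers[n, 1])^2 + (world[, 2] - centers[n, 2])^2 +
      (world[, 3] - centers[n, 3])^2
    vox <- which(d2 <= radius_mm^2)
    if (!length(vox))
      stopf("node '%s' (%g, %g, %g): no voxel center within %g mm", ids[n],
            centers[n, 1], centers[n, 2], centers[n, 3], radius_mm)
    out[n, ] <- if (length(vox) == 1L) flat[vox, ] else colMeans(flat[vox, ,
                                                                      drop = FALSE])
  }
  ts_matrix(out, tr = tr, node_ids = ids)
}
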