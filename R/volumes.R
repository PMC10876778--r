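#' 4D BOLD time-series volume
#'
#' Container for a resting-state 4D volume: a numeric array with dimensions
#' `(x, y, z, t)`, a 4x4 voxel-to-MNI-mm affine, and the repetition time.
#' Voxel indices are 1-based; the affine maps the zero-based index
#' `(i-1, j-1, k-1, 1)` to MNI mm, the convention used by NIfTI headers.
#'
#' @param data numeric 4D array `(x, y, z, t)`.
#' @param affine numeric 4x4 voxel-to-mm transform (must be invertible).
#' @param tr_seconds repetition time in seconds (> 0).
#' @return an object of class `ts_volume`.
#' @export
ts_volume <- function(data, affine, tr_seconds) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L)
    stop("a time-series volume needs at least 2 volumes")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("`tr_seconds` must be positive")
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds),
            class = "ts_volume")
}

#' @export
print.ts_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ts_volume> %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' 3D activity / statistic map sharing a volume's grid geometry
#'
#' @param data numeric 3D array.
#' @param affine 4x4 voxel-to-mm transform.
#' @param metric label such as `"reho"`, `"alff"`, `"falff"`, `"mreho"`, `"t"`.
#' @param mask optional logical/0-1 3D array marking where values are defined.
#' @param df optional degrees of freedom (for t/p statistic maps).
#' @return an object of class `activity_map`.
#' @export
activity_map <- function(data, affine, metric = "map", mask = NULL, df = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4")
  if (!is.null(mask) && !all(dim(mask) == dim(data)))
    stop("`mask` dimensions must match `data`")
  structure(list(data = data, affine = affine, metric = metric,
                 mask = mask, df = df),
            class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<activity_map:%s> %d x %d x %d voxels%s\n", x$metric,
              d[1], d[2], d[3],
              if (is.null(x$df)) "" else sprintf(", df = %g", x$df)))
  invisible(x)
}

#' Map 1-based voxel indices to MNI mm coordinates
#'
#' @param affine 4x4 voxel-to-mm transform.
#' @param ijk integer matrix (n x 3) or length-3 vector of 1-based indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(affine, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  xyz1 <- cbind(ijk - 1, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

#' Map MNI mm coordinates to (fractional) 1-based voxel indices
#'
#' @inheritParams voxel_to_mm
#' @param xyz matrix (n x 3) or length-3 vector of mm coordinates.
#' @return n x 3 matrix of fractional 1-based voxel indices.
#' @export
mm_to_voxel <- function(affine, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  ijk0 <- cbind(xyz, 1) %*% t(solve(affine))
  ijk0[, 1:3, drop = FALSE] + 1
}

#' mm coordinates of every voxel centre in a grid
#'
#' @param dims length-3 integer grid dimensions.
#' @param affine 4x4 voxel-to-mm transform.
#' @return (prod(dims)) x 3 matrix in array (column-major) order.
#' @export
grid_coordinates_mm <- function(dims, affine) {
  ijk <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  voxel_to_mm(affine, ijk)
}

#' Default desk-scale MNI-like affine: isotropic voxels, grid centred on 0 mm
#'
#' @param dims length-3 grid dimensions.
#' @param voxel_mm isotropic voxel size in mm.
#' @return 4x4 affine.
#' @export
centered_affine <- function(dims, voxel_mm = 3) {
  offset <- -voxel_mm * (dims - 1) / 2
  rbind(cbind(diag(voxel_mm, 3), offset), c(0, 0, 0, 1))
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] keeping
#' the affine and TR attached.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param tr_seconds repetition time for 4D data; taken from the NIfTI header
#'   `pixdim[4]` when `NULL`.
#' @return `read_volume()`: a `ts_volume` (4D) or `activity_map` (3D).
#' @export
read_volume <- function(path, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), class = NULL)
  nd <- length(dim(img))
  if (nd == 4L) {
    if (is.null(tr_seconds)) tr_seconds <- RNifti::pixdim(img)[4]
    ts_volume(array(as.numeric(img), dim = dim(img)), affine, tr_seconds)
  } else if (nd == 3L) {
    activity_map(array(as.numeric(img), dim = dim(img)), affine)
  } else stop("expected a 3D or 4D NIfTI image")
}

#' @rdname read_volume
#' @param x a `ts_volume` or `activity_map`.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$data)
  # pixdim must precede the xforms: changing it rescales an existing sform
  voxdim <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- if (inherits(x, "ts_volume"))
    c(voxdim, x$tr_seconds) else voxdim
  img <- RNifti::`sform<-`(img, structure(x$affine, code = 4L))
  img <- RNifti::`qform<-`(img, structure(x$affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
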