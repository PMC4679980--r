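#' Construct a 4D time-series image
#'
#' Container for a brain-masked BOLD series: a 4D array (x, y, z, t) with its
#' voxel-to-world affine, voxel size and repetition time (TR).
#'
#' @param data 4D numeric array, dimensions (x, y, z, t). All values must be
#'   finite and the series must have at least two volumes.
#' @param tr Repetition time in seconds (> 0).
#' @param affine 4x4 voxel-to-world transform. Defaults to a scaled identity
#'   built from \code{voxel_size}.
#' @param voxel_size Length-3 vector of voxel edge lengths in mm.
#' @return An object of class \code{ts_image}.
#' @export
ts_image <- function(data, tr, affine = NULL, voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 4L)
    stop("not a time series: expected a 4D array, got ",
         length(dim(data)), "D", call. = FALSE)
  if (dim(data)[4] < 2L)
    stop("time series must contain at least 2 volumes", call. = FALSE)
  if (!all(is.finite(data)))
    stop("time series contains non-finite values", call. = FALSE)
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("tr must be a single positive number (seconds)", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(affine))
    affine <- diag(c(voxel_size, 1))
  affine <- check_affine(affine)
  structure(list(data = data, tr = as.numeric(tr),
                 voxel_size = voxel_size, affine = affine),
            class = "ts_image")
}

#' Construct a 3D binary mask
#'
#' @param data 3D array of 0/1 values (logical arrays are accepted and
#'   converted).
#' @param affine 4x4 voxel-to-world transform (identity-scaled default).
#' @return An object of class \code{mask3d}.
#' @export
mask3d <- function(data, affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  } else {
    if (!all(data %in% c(0, 1)))
      stop("mask values must be binary (0/1)", call. = FALSE)
    storage.mode(data) <- "integer"
  }
  if (is.null(affine))
    affine <- diag(4)
  affine <- check_affine(affine)
  structure(list(data = data, affine = affine), class = "mask3d")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix", call. = FALSE)
  unname(affine)
}

#' @export
print.ts_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ts_image> %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask3d> %d x %d x %d, %d voxels set\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Read a 4D NIfTI time series
#'
#' Reads a 4D NIfTI-1 volume (optionally gzip-compressed). The repetition
#' time is taken from the header (4th pixdim); a header TR of zero or less is
#' an error unless \code{tr} is supplied explicitly, because downstream
#' filter design depends on it.
#'
#' @param path Path to a NIfTI file.
#' @param tr Optional repetition time in seconds, overriding the header.
#' @return A \code{\link{ts_image}}.
#' @export
read_timeseries <- function(path, tr = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop("not a time series: '", path, "' is ", length(dim(img)), "D",
         call. = FALSE)
  # the raw header keeps a zero/absent TR; the in-memory image sanitizes it
  hdr <- RNifti::niftiHeader(path)
  header_tr <- hdr$pixdim[5]
  pd <- RNifti::pixdim(img)
  if (is.null(tr)) {
    if (!is.finite(header_tr) || header_tr <= 0)
      stop("repetition time missing from header of '", path,
           "'; pass tr= explicitly", call. = FALSE)
    tr <- header_tr
  }
  arr <- array(as.numeric(img), dim = dim(img))
  if (!all(is.finite(arr)))
    stop("'", path, "' contains non-finite voxel values", call. = FALSE)
  ts_image(arr, tr = tr, affine = RNifti::xform(img),
           voxel_size = pd[1:3])
}

#' Read a 3D binary mask from NIfTI
#'
#' @param path Path to a 3D NIfTI file containing only 0/1 values.
#' @return A \code{\link{mask3d}}.
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("mask file '", path, "' is not 3D", call. = FALSE)
  arr <- array(as.numeric(img), dim = dim(img))
  mask3d(arr, affine = RNifti::xform(img))
}

#' Write a mask to NIfTI (unsigned 8-bit)
#'
#' @param mask A \code{\link{mask3d}}.
#' @param path Output path; the containing directory must exist.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask3d"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  img <- as_nifti_grid(mask$data, mask$affine)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write a 4D time series to NIfTI
#'
#' @param img A \code{\link{ts_image}}.
#' @param path Output path.
#' @export
write_timeseries <- function(img, path) {
  stopifnot(inherits(img, "ts_image"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  nim <- as_nifti_grid(img$data, img$affine, tr = img$tr)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

# Attach grid geometry (pixdim + sform/qform) to an array before writing.
as_nifti_grid <- function(arr, affine, tr = NULL) {
  nim <- RNifti::asNifti(arr)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(nim) <- if (is.null(tr)) vox else c(vox, tr)
  RNifti::`sform<-`(nim, structure(affine, code = 2L))
}

#' Map in-mask voxels to graph node indices
#'
#' Enumerates the true voxels of a mask in the array storage order (first
#' index fastest), giving every in-mask voxel a stable node index. Voxel
#' coordinates are 0-based.
#'
#' @param mask A \code{\link{mask3d}} with at least one voxel set.
#' @return An object of class \code{voxel_map} with elements \code{coords}
#'   (n x 3 integer matrix of 0-based (i, j, k)), \code{n_nodes}, and
#'   \code{dim} (the mask grid).
#' @export
voxel_index_map <- function(mask) {
  stopifnot(inherits(mask, "mask3d"))
  lin <- which(mask$data != 0L)
  if (length(lin) == 0L)
    stop("mask is empty", call. = FALSE)
  coords <- arrayInd(lin, dim(mask$data)) - 1L
  colnames(coords) <- c("i", "j", "k")
  structure(list(coords = coords, n_nodes = nrow(coords),
                 dim = dim(mask$data), linear = lin),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat(sprintf("<voxel_map> %d nodes on a %s grid\n", x$n_nodes,
              paste(x$dim, collapse = " x ")))
  invisible(x)
}

# Shared-grid check: masks and series must live on one voxel grid.
check_same_grid <- function(a_dim, a_affine, b_dim, b_affine,
                            tol = 1e-4, what = "inputs") {
  if (!all(a_dim == b_dim))
    stop(what, " are not on the same voxel grid: ",
         paste(a_dim, collapse = "x"), " vs ",
         paste(b_dim, collapse = "x"), call. = FALSE)
  if (max(abs(a_affine - b_affine)) > tol)
    stop(what, " have mismatched affines (max abs difference > ", tol, ")",
         call. = FALSE)
  invisible(TRUE)
}

spatial_dim <- function(x) {
  if (inherits(x, "ts_image")) dim(x$data)[1:3] else dim(x$data)
}
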