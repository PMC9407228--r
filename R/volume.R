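#' 3D image volume with world geometry
#'
#' A `volume3d` couples a 3D intensity array with its voxel spacing (mm) and
#' world origin (mm).  Voxel indices are 0-based and follow the voxel-centre
#' convention: voxel `i` sits at world coordinate `origin + i * spacing`.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, voxel spacing in mm (strictly positive).
#' @param origin numeric length-3, world coordinate (mm) of voxel (0,0,0).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("grid must be non-empty", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

# World mm -> continuous 0-based voxel coordinates (matrix n x 3).
world_to_voxel <- function(vol, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  sweep(sweep(pts, 2L, vol$origin, "-"), 2L, vol$spacing, "/")
}

voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx, 2L, vol$spacing, "*"), 2L, vol$origin, "+")
}

#' Read a NIfTI volume
#'
#' Loads a NIfTI-1 file, reorients the data to the RAS axis convention and
#' returns a [volume3d] carrying the stored spacing and world origin.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume3d].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("not a readable NIfTI file: ", path, " (",
                         conditionMessage(e), ")", call. = FALSE))
  if (!is.null(dim(img)) && length(dim(img)) > 3L)
    img <- img[, , , 1L, drop = TRUE]
  RNifti::orientation(img) <- "RAS"
  x <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- as.numeric(x[1:3, 4])
  volume3d(array(as.numeric(img), dim = dim(img)[1:3]), spacing, origin)
}

#' Write a volume as NIfTI
#'
#' Writes a standard-conformant NIfTI-1 file (sform and qform set to the
#' axis-aligned RAS transform implied by the volume's spacing and origin).
#'
#' @param vol a [volume3d].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @param datatype on-disk scalar type, `"float"` (32-bit, default) or
#'   `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = c("float", "double")) {
  datatype <- match.arg(datatype)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  a <- structure(vol$data, pixdim = vol$spacing)
  img <- RNifti::asNifti(a, datatype = datatype)
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) stop("cannot write ", path, " (",
                                    conditionMessage(e), ")", call. = FALSE))
  invisible(path)
}

#' Resample a volume to an isotropic grid
#'
#' Trilinearly resamples onto an isotropic grid (1 mm^3 by default, the grid
#' every downstream stage assumes).  The world extent is preserved to within
#' half a voxel; the new origin is shifted by `(new - old) spacing / 2` per
#' axis so voxel centres tile the same physical span.
#'
#' @param vol a [volume3d].
#' @param spacing target isotropic spacing in mm (default 1).
#' @return A [volume3d] with spacing `c(spacing, spacing, spacing)`.
#' @export
resample_isotropic <- function(vol, spacing = 1) {
  stopifnot(inherits(vol, "volume3d"))
  if (any(dim(vol$data) < 2L))
    stop("degenerate input: every axis needs >= 2 voxels to interpolate",
         call. = FALSE)
  if (spacing <= 0) stop("`spacing` must be positive", call. = FALSE)
  n_old <- dim(vol$data)
  n_new <- pmax(1L, as.integer(round(n_old * vol$spacing / spacing)))
  new_origin <- vol$origin + (spacing - vol$spacing) / 2
  if (all(vol$spacing == spacing)) return(vol)
  gx <- (seq_len(n_new[1]) - 1) * spacing + new_origin[1]
  gy <- (seq_len(n_new[2]) - 1) * spacing + new_origin[2]
  gz <- (seq_len(n_new[3]) - 1) * spacing + new_origin[3]
  pts <- cbind(rep(gx, times = n_new[2] * n_new[3]),
               rep(rep(gy, each = n_new[1]), times = n_new[3]),
               rep(gz, each = n_new[1] * n_new[2]))
  vox <- world_to_voxel(vol, pts)
  vals <- .trilinear_sample_cpp(vol$data, vox)
  volume3d(array(vals, dim = n_new), rep(spacing, 3), new_origin)
}

#' Percentile intensity normalization
#'
#' Affinely maps the `p_low` percentile to 0 and the `p_high` percentile to
#' 1, then clips to `[0, 1]`.  The defaults (1, 99) are robust to
#' hyperintense outliers such as vessels.  A constant volume normalizes to
#' all zeros with a warning.
#'
#' @param vol a [volume3d].
#' @param p_low,p_high percentiles in `[0, 100]` with `p_low < p_high`.
#' @return A [volume3d] with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(vol, p_low = 1, p_high = 99) {
  stopifnot(inherits(vol, "volume3d"))
  if (!(p_low < p_high)) stop("`p_low` must be < `p_high`", call. = FALSE)
  q <- quantile(vol$data, probs = c(p_low, p_high) / 100, names = FALSE,
                type = 7)
  if (q[2] <= q[1]) {
    warning("constant intensity volume; normalizing to all zeros")
    return(volume3d(array(0, dim(vol$data)), vol$spacing, vol$origin))
  }
  v <- (vol$data - q[1]) / (q[2] - q[1])
  v[v < 0] <- 0
  v[v > 1] <- 1
  volume3d(v, vol$spacing, vol$origin)
}
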