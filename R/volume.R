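#' 3D scalar volume on an isotropic grid
#'
#' `volume_grid` is the carrier type for every 3D field in the package:
#' binary structure masks, input channels and dose distributions. Values are
#' stored as a plain 3D array; geometry is defined by an isotropic voxel
#' spacing (mm) and the world coordinate (mm) of the *center* of voxel
#' `[1,1,1]`. Voxel indices are 0-based in world-coordinate formulas:
#' `world = origin_mm + index * spacing_mm`.
#'
#' @param values numeric 3D array of voxel values (finite).
#' @param spacing_mm positive scalar, isotropic voxel spacing in mm.
#' @param origin_mm numeric length-3, world position (mm) of the first voxel
#'   center. Default `c(0, 0, 0)`.
#' @return An object of class `volume_grid` with fields `values`,
#'   `spacing_mm`, `origin_mm`.
#' @export
volume_grid <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3D volume", call. = FALSE)
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("spacing_mm must be a positive scalar", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("origin_mm must be a finite 3-vector", call. = FALSE)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("volume values must be finite", call. = FALSE)
  structure(list(values = values, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("volume_grid %dx%dx%d @ %.3g mm, origin (%.4g, %.4g, %.4g) mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing_mm,
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

is_volume_grid <- function(x) inherits(x, "volume_grid")

#' Check that two volumes share the canonical grid
#'
#' @param a,b `volume_grid` objects.
#' @param tol float tolerance for spacing/origin comparison.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$spacing_mm - b$spacing_mm) < tol &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop(sprintf("%s do not share a grid", what), call. = FALSE)
  invisible(TRUE)
}

#' World coordinates of all voxel centers
#'
#' @param v a `volume_grid`.
#' @return n-by-3 matrix of voxel-center world coordinates (mm), in array
#'   (column-major) order.
#' @export
voxel_centers <- function(v) {
  d <- dim(v$values)
  i <- seq_len(d[1]) - 1; j <- seq_len(d[2]) - 1; k <- seq_len(d[3]) - 1
  cbind(v$origin_mm[1] + rep(i, times = d[2] * d[3]) * v$spacing_mm,
        v$origin_mm[2] + rep(rep(j, each = d[1]), times = d[3]) * v$spacing_mm,
        v$origin_mm[3] + rep(k, each = d[1] * d[2]) * v$spacing_mm)
}

## Continuous (0-based, fractional) voxel coordinates of world points.
world_to_index <- function(v, pts) {
  sweep(pts, 2, v$origin_mm) / v$spacing_mm
}

#' Sample a volume at arbitrary world points
#'
#' Trilinear or nearest-neighbor interpolation; points outside the grid
#' support return `outside`.
#'
#' @param v a `volume_grid`.
#' @param pts n-by-3 matrix of world coordinates (mm).
#' @param mode `"linear"` (trilinear) or `"nearest"`.
#' @param outside value returned for points outside the grid (default 0).
#' @param clamp if `TRUE`, points are clamped to the voxel-center hull instead
#'   of receiving `outside` (edge extension; used by resampling).
#' @return numeric vector of length n.
#' @export
interp_volume <- function(v, pts, mode = c("linear", "nearest"), outside = 0,
                          clamp = FALSE) {
  mode <- match.arg(mode)
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  d <- dim(v$values)
  g <- world_to_index(v, pts)   # fractional 0-based indices
  if (clamp) {
    g[, 1] <- pmin(pmax(g[, 1], 0), d[1] - 1)
    g[, 2] <- pmin(pmax(g[, 2], 0), d[2] - 1)
    g[, 3] <- pmin(pmax(g[, 3], 0), d[3] - 1)
  }
  out <- rep(as.numeric(outside), nrow(pts))
  if (mode == "nearest") {
    ii <- round(g[, 1]); jj <- round(g[, 2]); kk <- round(g[, 3])
    ok <- ii >= 0 & ii <= d[1] - 1 & jj >= 0 & jj <= d[2] - 1 & kk >= 0 & kk <= d[3] - 1
    if (any(ok)) {
      lin <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1
      out[ok] <- v$values[lin]
    }
    return(out)
  }
  ok <- g[, 1] >= 0 & g[, 1] <= d[1] - 1 &
        g[, 2] >= 0 & g[, 2] <= d[2] - 1 &
        g[, 3] >= 0 & g[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  gx <- g[ok, 1]; gy <- g[ok, 2]; gz <- g[ok, 3]
  x0 <- pmin(floor(gx), d[1] - 2); y0 <- pmin(floor(gy), d[2] - 2)
  z0 <- pmin(floor(gz), d[3] - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  V <- v$values
  base <- x0 + d[1] * (y0 + d[2] * z0) + 1
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  c000 <- V[base];                 c100 <- V[base + sx]
  c010 <- V[base + sy];            c110 <- V[base + sx + sy]
  c001 <- V[base + sz];            c101 <- V[base + sx + sz]
  c011 <- V[base + sy + sz];       c111 <- V[base + sx + sy + sz]
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Resample a volume to an isotropic target spacing
#'
#' The canonical analysis grid is 2 mm isotropic; all masks, channels and
#' doses are resampled onto it before any computation. Masks must use
#' `mode = "nearest"` so they remain binary; continuous fields use trilinear
#' interpolation. The physical extent (outer voxel faces) is preserved within
#' one voxel.
#'
#' @param v a `volume_grid`.
#' @param target_mm positive target spacing (mm).
#' @param mode `"linear"` or `"nearest"`.
#' @return A `volume_grid` with spacing `target_mm`.
#' @export
resample_isotropic <- function(v, target_mm, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("target_mm must be a positive scalar", call. = FALSE)
  d <- dim(v$values)
  if (abs(target_mm - v$spacing_mm) < 1e-9) return(v)
  extent <- d * v$spacing_mm                       # outer-face extent per axis
  nd <- pmax(1L, as.integer(ceiling(extent / target_mm - 1e-9)))
  corner <- v$origin_mm - v$spacing_mm / 2         # outer corner of voxel [1,1,1]
  new_origin <- corner + target_mm / 2
  out <- volume_grid(array(0, nd), target_mm, new_origin)
  vals <- interp_volume(v, voxel_centers(out), mode = mode, clamp = TRUE)
  out$values <- array(vals, nd)
  out
}

#' Read a 3D volume from a NIfTI file
#'
#' Reads masks, channels or doses stored as NIfTI (`.nii` / `.nii.gz`).
#' Spacing and origin are taken from the file header. Only 3D volumes with
#' isotropic spacing are accepted, unless `resample_mm` is given, in which
#' case anisotropic input is resampled onto an isotropic grid.
#'
#' @param path file path.
#' @param resample_mm optional isotropic target spacing (mm); enables reading
#'   of anisotropic volumes and resamples isotropic ones.
#' @param mode interpolation mode used if resampling occurs.
#' @return A `volume_grid`.
#' @export
read_volume <- function(path, resample_mm = NULL, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  dims <- dim(img)
  if (length(dims) != 3L) stop("expected 3D volume", call. = FALSE)
  xf <- RNifti::xform(img)
  # spacing from the affine column norms; origin from its translation
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  origin_mm <- as.numeric(xf[1:3, 4])
  vals <- array(as.numeric(img), dims)
  iso <- max(sp) - min(sp) < 1e-6
  if (!iso && is.null(resample_mm))
    stop("anisotropic spacing; pass resample_mm to read with resampling", call. = FALSE)
  if (iso) {
    v <- volume_grid(vals, sp[1], origin_mm)
    if (!is.null(resample_mm)) v <- resample_isotropic(v, resample_mm, mode)
    return(v)
  }
  # anisotropic: interpolate onto isotropic resample_mm grid directly
  corner <- origin_mm - sp / 2
  extent <- dims * sp
  nd <- pmax(1L, as.integer(ceiling(extent / resample_mm - 1e-9)))
  out <- volume_grid(array(0, nd), resample_mm, corner + resample_mm / 2)
  # fractional-index sampling against the anisotropic source
  pts <- voxel_centers(out)
  g <- sweep(pts, 2, origin_mm)
  g <- sweep(g, 2, sp, "/")
  tmp <- volume_grid(vals, 1, c(0, 0, 0))  # sample in index space
  out$values <- array(interp_volume(tmp, g, mode = mode, clamp = TRUE), nd)
  out
}

#' Write a volume to a NIfTI file
#'
#' Values are stored as float64 so that a write/read round trip is
#' bit-exact. The affine encodes the isotropic spacing and origin.
#'
#' @param v a `volume_grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  img <- v$values
  sp <- v$spacing_mm
  RNifti::pixdim(img) <- c(sp, sp, sp)
  xf <- diag(c(sp, sp, sp, 1))
  xf[1:3, 4] <- v$origin_mm
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
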