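#' Fluence map at the isocenter plane
#'
#' A 2D non-negative intensity grid in beam's-eye-view (BEV) coordinates.
#' Pixel `[1,1]` is centered at `(u0, v0)` mm; rows advance along `u`,
#' columns along `v`.
#'
#' @param values numeric matrix (nu x nv), all values `>= 0`.
#' @param pixel_mm pixel size (mm) at the isocenter plane.
#' @param u0,v0 BEV coordinates (mm) of the first pixel center.
#' @param beam_index which beam this fluence belongs to.
#' @return A `fluence_map` object.
#' @export
fluence_map <- function(values, pixel_mm, u0, v0, beam_index = 1L) {
  if (!is.matrix(values)) stop("fluence values must be a matrix", call. = FALSE)
  if (any(values < 0)) stop("beamlet intensities must be non-negative", call. = FALSE)
  structure(list(values = values, pixel_mm = pixel_mm, u0 = u0, v0 = v0,
                 beam_index = as.integer(beam_index)),
            class = "fluence_map")
}

#' Project world points onto a beam's isocenter plane (BEV)
#'
#' Divergent (perspective) projection through the source onto the plane
#' normal to the central axis at the isocenter. A point at depth `t` from the
#' source with lateral offset `x` projects to `x * SAD / t`.
#'
#' @param points_mm n-by-3 matrix (or length-3 vector) of world points.
#' @param beam a `beam_config`.
#' @return n-by-3 matrix with columns `u`, `v` (mm at the isocenter plane)
#'   and `t` (distance from source along the central axis, mm).
#' @export
project_to_bev <- function(points_mm, beam) {
  if (!is.matrix(points_mm)) points_mm <- matrix(points_mm, ncol = 3)
  ax <- beam_axes(beam)
  w <- sweep(points_mm, 2, ax$source)
  t <- w %*% ax$axis
  if (any(t <= 1e-9))
    stop("point at or behind the source cannot be projected", call. = FALSE)
  s <- beam$SAD_mm / t
  cbind(u = as.numeric(s * (w %*% ax$u_hat)),
        v = as.numeric(s * (w %*% ax$v_hat)),
        t = as.numeric(t))
}

## Binary dilation of a matrix by a disk of radius r pixels (shift-OR).
dilate_disk <- function(m, radius_px) {
  if (radius_px <= 0) return(m)
  r <- floor(radius_px + 1e-9)
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (dx in -r:r) for (dy in -r:r) {
    if (dx == 0 && dy == 0) next
    if (dx * dx + dy * dy > radius_px^2 + 1e-9) next
    xs <- max(1, 1 + dx):min(nr, nr + dx)
    xt <- max(1, 1 - dx):min(nr, nr - dx)
    ys <- max(1, 1 + dy):min(nc, nc + dy)
    yt <- max(1, 1 - dy):min(nc, nc - dy)
    out[xt, yt] <- pmax(out[xt, yt], m[xs, ys])
  }
  out
}

#' Conformal aperture for a target in a beam's-eye view
#'
#' Projects every target voxel center onto the BEV plane, rasterizes at
#' `pixel_mm`, and dilates the footprint by an isotropic margin (default
#' 5 mm) with a disk structuring element. The result is a binary unit-fluence
#' map. Disjoint target lobes stay disjoint (no convex fill).
#'
#' @param ptv binary target mask (`volume_grid`), nonempty.
#' @param beam a `beam_config`.
#' @param margin_mm isotropic dilation margin (mm), default 5.
#' @param pixel_mm fluence pixel size (mm), default 2.
#' @return A binary `fluence_map` centered on the central axis.
#' @export
conformal_aperture <- function(ptv, beam, margin_mm = 5, pixel_mm = 2) {
  idx <- which(ptv$values > 0)
  if (length(idx) == 0) stop("empty PTV: cannot build an aperture", call. = FALSE)
  pts <- voxel_centers(ptv)[idx, , drop = FALSE]
  uv <- project_to_bev(pts, beam)
  half <- max(abs(uv[, 1]), abs(uv[, 2])) + margin_mm + 2 * pixel_mm
  n_half <- ceiling(half / pixel_mm)
  n <- 2L * as.integer(n_half) + 1L           # symmetric grid, center pixel on axis
  u0 <- -n_half * pixel_mm; v0 <- u0
  m <- matrix(0, n, n)
  iu <- round((uv[, 1] - u0) / pixel_mm) + 1
  iv <- round((uv[, 2] - v0) / pixel_mm) + 1
  m[cbind(iu, iv)] <- 1
  m <- dilate_disk(m, margin_mm / pixel_mm)
  fluence_map(m, pixel_mm, u0, v0, 1L)
}

## 1D normalized Gaussian kernel, truncated at 4 sigma.
gauss_kernel_1d <- function(sigma_mm, pixel_mm) {
  r <- max(1L, as.integer(ceiling(4 * sigma_mm / pixel_mm)))
  x <- (-r:r) * pixel_mm
  k <- exp(-x^2 / (2 * sigma_mm^2))
  k / sum(k)
}

## Toeplitz band matrix implementing zero-padded 1D convolution of length n.
conv_matrix <- function(k, n) {
  r <- (length(k) - 1L) / 2L
  T <- matrix(0, n, n)
  for (o in -r:r) {
    val <- k[o + r + 1L]
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    T[cbind(i[ok], j[ok])] <- val
  }
  T
}

#' Convolve a fluence map with the lateral penumbra kernel
#'
#' Separable 2D Gaussian convolution (sigma in mm, truncated at 4 sigma,
#' discretely normalized, zero-padded). The total fluence is preserved within
#' 0.5% for apertures at least 3 sigma away from the array border.
#'
#' @param f a `fluence_map`.
#' @param kernel_sigma_mm Gaussian sigma (mm).
#' @return A `fluence_map` with smoothed values.
#' @export
convolve_fluence <- function(f, kernel_sigma_mm) {
  k <- gauss_kernel_1d(kernel_sigma_mm, f$pixel_mm)
  Tu <- conv_matrix(k, nrow(f$values))
  Tv <- conv_matrix(k, ncol(f$values))
  f$values <- Tu %*% f$values %*% t(Tv)
  f$values[f$values < 0] <- 0
  f
}

#' Radiological (water-equivalent) depth along source-to-point rays
#'
#' Line integral of the density along the segment from the source to each
#' point, evaluated by midpoint-rule ray marching with nearest-neighbor
#' density lookup. Density is zero outside the grid, so the integral only
#' accumulates inside the volume (0 for points upstream of body entry).
#'
#' @param density a `volume_grid` of relative densities (binary body mask by
#'   default in this package).
#' @param source_mm world position of the source (mm).
#' @param points_mm n-by-3 matrix (or length-3 vector) of world points; must
#'   lie inside the grid bounding box.
#' @param step_mm marching step (mm), default 0.5.
#' @return numeric vector of water-equivalent depths (mm).
#' @export
radiological_depth <- function(density, source_mm, points_mm, step_mm = 0.5) {
  if (!is.matrix(points_mm)) points_mm <- matrix(points_mm, ncol = 3)
  d <- dim(density$values)
  corner_lo <- density$origin_mm - density$spacing_mm / 2
  corner_hi <- corner_lo + d * density$spacing_mm
  inside <- points_mm[, 1] >= corner_lo[1] & points_mm[, 1] <= corner_hi[1] &
            points_mm[, 2] >= corner_lo[2] & points_mm[, 2] <= corner_hi[2] &
            points_mm[, 3] >= corner_lo[3] & points_mm[, 3] <= corner_hi[3]
  if (!all(inside)) stop("all points must lie inside the density grid", call. = FALSE)
  ray_march_depth(density, source_mm, points_mm, step_mm)
}

## Core marcher, shared with the dose engine (no inside-grid check).
ray_march_depth <- function(density, source_mm, points_mm, step_mm) {
  n <- nrow(points_mm)
  d <- dim(density$values)
  corner_lo <- density$origin_mm - density$spacing_mm / 2
  corner_hi <- corner_lo + d * density$spacing_mm
  dxyz <- sweep(points_mm, 2, source_mm)          # p - src
  len <- sqrt(rowSums(dxyz^2))
  # slab intersection of the ray segment t in [0,1] with the grid box
  t0 <- rep(0, n); t1 <- rep(1, n)
  for (a in 1:3) {
    da <- dxyz[, a]
    lo <- (corner_lo[a] - source_mm[a]) / da
    hi <- (corner_hi[a] - source_mm[a]) / da
    tn <- pmin(lo, hi); tx <- pmax(lo, hi)
    par <- abs(da) < 1e-12                        # ray parallel to this slab
    tn[par] <- 0; tx[par] <- 1
    t0 <- pmax(t0, tn); t1 <- pmin(t1, tx)
  }
  t1 <- pmax(t1, t0)
  seg <- (t1 - t0) * len                          # geometric length inside box
  M <- max(1L, as.integer(ceiling(max(seg) / step_mm)))
  depth <- numeric(n)
  o <- density$origin_mm; sp <- density$spacing_mm
  V <- density$values
  for (k in seq_len(M)) {
    tk <- t0 + (k - 0.5) / M * (t1 - t0)
    px <- source_mm[1] + tk * dxyz[, 1]
    py <- source_mm[2] + tk * dxyz[, 2]
    pz <- source_mm[3] + tk * dxyz[, 3]
    ii <- round((px - o[1]) / sp); jj <- round((py - o[2]) / sp)
    kk <- round((pz - o[3]) / sp)
    ok <- ii >= 0 & ii <= d[1] - 1 & jj >= 0 & jj <= d[2] - 1 &
          kk >= 0 & kk <= d[3] - 1
    if (any(ok)) {
      lin <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1
      dens <- numeric(n); dens[ok] <- V[lin]
      depth <- depth + dens * seg / M
    }
  }
  depth
}

## Bilinear sample of a fluence map at BEV coordinates (0 outside).
sample_fluence <- function(f, u, v) {
  gu <- (u - f$u0) / f$pixel_mm
  gv <- (v - f$v0) / f$pixel_mm
  nu <- nrow(f$values); nv <- ncol(f$values)
  out <- numeric(length(u))
  ok <- gu >= 0 & gu <= nu - 1 & gv >= 0 & gv <= nv - 1
  if (!any(ok)) return(out)
  x0 <- pmin(pmax(floor(gu[ok]), 0), nu - 2)
  y0 <- pmin(pmax(floor(gv[ok]), 0), nv - 2)
  fx <- gu[ok] - x0; fy <- gv[ok] - y0
  base <- x0 + nu * y0 + 1
  Fv <- f$values
  out[ok] <- Fv[base] * (1 - fx) * (1 - fy) + Fv[base + 1] * fx * (1 - fy) +
    Fv[base + nu] * (1 - fx) * fy + Fv[base + nu + 1] * fx * fy
  out
}

## Geometry of one beam against the case grid: everything about the mapping
## from fluence pixels to in-body voxels that does not depend on the fluence
## values. Used by fcbb_beam_dose and the FMO influence matrices.
beam_geometry <- function(case, beam, model, step_mm = NULL) {
  body <- case$structures$body
  if (is.null(step_mm)) step_mm <- body$spacing_mm
  idx <- which(body$values > 0)
  pts <- voxel_centers(body)[idx, , drop = FALSE]
  uv <- project_to_bev(pts, beam)
  ax <- beam_axes(beam)
  depth <- ray_march_depth(body, ax$source, pts, step_mm)
  fac <- model$pdd_fun(depth)
  if (model$inverse_square) fac <- fac * (beam$SAD_mm / uv[, 3])^2
  list(idx = idx, u = uv[, 1], v = uv[, 2], factor = fac)
}

#' Single-beam FCBB dose
#'
#' Fluence-convolution broad-beam dose: for each in-body voxel `x`,
#' `dose(x) = F(bev(x)) * PDD(radiological_depth(x)) * (SAD / t)^2`, where
#' `F` is the (already convolved) fluence sampled bilinearly at the voxel's
#' BEV projection, `t` the source distance along the central axis, and the
#' inverse-square factor applies only when enabled in the model. Dose is 0
#' outside the body and linear in the fluence.
#'
#' @param case a `case_bundle`.
#' @param beam a `beam_config`.
#' @param fluence a `fluence_map` (non-negative).
#' @param model a `beam_model`; default the case's model.
#' @param step_mm ray-marching step (mm); default the grid spacing.
#' @return A dose `volume_grid` (relative units).
#' @export
fcbb_beam_dose <- function(case, beam, fluence, model = case$model,
                           step_mm = NULL) {
  if (any(fluence$values < 0))
    stop("beamlet intensities must be non-negative", call. = FALSE)
  geo <- beam_geometry(case, beam, model, step_mm)
  body <- case$structures$body
  dose <- array(0, dim(body$values))
  dose[geo$idx] <- sample_fluence(fluence, geo$u, geo$v) * geo$factor
  volume_grid(dose, body$spacing_mm, body$origin_mm)
}

#' Total dose from one fluence map per beam
#'
#' Sum of per-beam FCBB doses; the forward operator of the fluence-map
#' optimization problem. For the matching adjoint, see [dose_operator()].
#'
#' @param case a `case_bundle`.
#' @param fluences list of `fluence_map`, one per beam (in beam order).
#' @param model a `beam_model`; default the case's model.
#' @param step_mm ray-marching step (mm).
#' @return A dose `volume_grid` (relative units).
#' @export
total_dose <- function(case, fluences, model = case$model, step_mm = NULL) {
  if (length(fluences) != length(case$beams))
    stop("need exactly one fluence map per beam", call. = FALSE)
  body <- case$structures$body
  acc <- array(0, dim(body$values))
  for (b in seq_along(case$beams)) {
    acc <- acc + fcbb_beam_dose(case, case$beams[[b]], fluences[[b]],
                                model, step_mm)$values
  }
  volume_grid(acc, body$spacing_mm, body$origin_mm)
}

#' Linear dose operator with exact adjoint
#'
#' Precomputes, per beam, the sparse influence mapping from fluence pixels to
#' in-body voxels (bilinear BEV interpolation weights times depth-dose and
#' inverse-square factors) and the penumbra convolution, exposing the forward
#' map `A: fluences -> dose vector` and its exact adjoint
#' `A^T: dose vector -> fluence gradients`. This is the workhorse of the FMO
#' module; `apply_dose_operator(op, f)` agrees with [total_dose()] up to the
#' shared discretization.
#'
#' @param case a `case_bundle`.
#' @param model a `beam_model`; default the case's model.
#' @param pixel_mm fluence pixel size for the optimization beamlets
#'   (default 5 mm; coarser than the beam-trace pixel to bound problem size).
#' @param margin_mm aperture margin (mm) defining each beam's beamlet extent.
#' @param step_mm ray-marching step (mm).
#' @param convolve logical; include the penumbra convolution inside the
#'   operator (default `TRUE`).
#' @return A `dose_operator` with fields `B` (list of sparse matrices),
#'   `K` (list of convolution factor pairs), `geoms` (fluence geometries),
#'   `idx` (in-body voxel indices), `n_vox`, `dim`, `spacing_mm`, `origin_mm`.
#' @export
dose_operator <- function(case, model = case$model, pixel_mm = 5,
                          margin_mm = 5, step_mm = NULL, convolve = TRUE) {
  body <- case$structures$body
  union_t <- target_union(case$structures)
  Bs <- list(); Ks <- list(); geoms <- list()
  k1 <- gauss_kernel_1d(model$kernel_sigma_mm, pixel_mm)
  for (b in seq_along(case$beams)) {
    beam <- case$beams[[b]]
    ap <- conformal_aperture(union_t, beam, margin_mm, pixel_mm)
    geo <- beam_geometry(case, beam, model, step_mm)
    nu <- nrow(ap$values); nv <- ncol(ap$values)
    gu <- (geo$u - ap$u0) / pixel_mm
    gv <- (geo$v - ap$v0) / pixel_mm
    ok <- gu >= 0 & gu <= nu - 1 & gv >= 0 & gv <= nv - 1
    x0 <- pmin(pmax(floor(gu[ok]), 0), nu - 2)
    y0 <- pmin(pmax(floor(gv[ok]), 0), nv - 2)
    fx <- gu[ok] - x0; fy <- gv[ok] - y0
    rows <- which(ok)
    fac <- geo$factor[ok]
    i <- rep(rows, 4)
    j <- c(x0 + nu * y0 + 1, x0 + 2 + nu * y0, x0 + 1 + nu * (y0 + 1),
           x0 + 2 + nu * (y0 + 1))
    w <- c(fac * (1 - fx) * (1 - fy), fac * fx * (1 - fy),
           fac * (1 - fx) * fy, fac * fx * fy)
    Bs[[b]] <- Matrix::sparseMatrix(i = i, j = j, x = w,
                                    dims = c(length(geo$idx), nu * nv))
    Ks[[b]] <- if (convolve) list(Tu = conv_matrix(k1, nu), Tv = conv_matrix(k1, nv)) else NULL
    geoms[[b]] <- list(nu = nu, nv = nv, pixel_mm = pixel_mm,
                       u0 = ap$u0, v0 = ap$v0,
                       aperture = ap$values)
  }
  structure(list(B = Bs, K = Ks, geoms = geoms, idx = which(body$values > 0),
                 dim = dim(body$values), spacing_mm = body$spacing_mm,
                 origin_mm = body$origin_mm, n_beams = length(case$beams)),
            class = "dose_operator")
}

#' @rdname dose_operator
#' @param op a `dose_operator`.
#' @param fluences list of fluence matrices (or `fluence_map`s) matching
#'   `op$geoms`.
#' @return `apply_dose_operator`: numeric vector of dose at `op$idx` voxels.
#' @export
apply_dose_operator <- function(op, fluences) {
  dvec <- numeric(length(op$idx))
  for (b in seq_len(op$n_beams)) {
    f <- fluences[[b]]
    if (inherits(f, "fluence_map")) f <- f$values
    if (!is.null(op$K[[b]])) f <- op$K[[b]]$Tu %*% f %*% t(op$K[[b]]$Tv)
    dvec <- dvec + as.numeric(op$B[[b]] %*% as.numeric(f))
  }
  dvec
}

#' @rdname dose_operator
#' @param dvec numeric vector over in-body voxels (length `length(op$idx)`).
#' @return `adjoint_dose_operator`: list of fluence-shaped gradient matrices.
#' @export
adjoint_dose_operator <- function(op, dvec) {
  lapply(seq_len(op$n_beams), function(b) {
    g <- matrix(as.numeric(Matrix::crossprod(op$B[[b]], dvec)),
                op$geoms[[b]]$nu, op$geoms[[b]]$nv)
    if (!is.null(op$K[[b]])) g <- t(op$K[[b]]$Tu) %*% g %*% op$K[[b]]$Tv
    g
  })
}

## Dose vector (on op$idx) -> full volume_grid.
dose_vec_to_volume <- function(op, dvec) {
  arr <- array(0, op$dim)
  arr[op$idx] <- dvec
  volume_grid(arr, op$spacing_mm, op$origin_mm)
}

## Union of all target masks (SIB apertures must cover every target).
target_union <- function(structures) {
  u <- structures$targets[[1]]$mask
  if (length(structures$targets) > 1) {
    acc <- u$values
    for (t in structures$targets[-1]) acc <- pmax(acc, t$mask$values)
    u$values <- acc
  }
  u
}
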