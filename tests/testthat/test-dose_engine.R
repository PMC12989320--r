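test_that("BEV projection satisfies the similar-triangles geometry", {
  b <- beam_config(90, c(0, 0, 0), 1000)   # source at (0, 1000, 0)
  expect_equal(as.numeric(project_to_bev(c(0, 0, 0), b)[1, 1:2]), c(0, 0))
  # in-plane point: projection preserves the offset magnitude
  uv <- project_to_bev(c(10, 0, 0), b)
  expect_equal(unname(abs(uv[1, "u"])), 10, tolerance = 1e-9)
  expect_equal(unname(uv[1, "v"]), 0, tolerance = 1e-9)
  # 100 mm upstream, 10 mm offset: |u| = 10 * 1000 / 900
  uv2 <- project_to_bev(c(10, 100, 0), b)
  expect_equal(unname(abs(uv2[1, "u"])), 10 * 1000 / 900, tolerance = 1e-9)
  expect_equal(unname(uv2[1, "t"]), 900, tolerance = 1e-9)
  # axial offset maps to v unchanged at the isocenter plane
  uv3 <- project_to_bev(c(0, 0, 7), b)
  expect_equal(unname(uv3[1, "v"]), 7, tolerance = 1e-9)
  expect_error(project_to_bev(c(0, 1000, 0), b), "source")
})

test_that("conformal apertures equal the projected silhouette plus the margin", {
  g <- centered_grid(32, 2)
  ptv <- mask_from(g, function(cc) rowSums(cc^2) <= 20^2)
  b <- beam_config(0, c(0, 0, 0), 1000)
  radius_of <- function(ap, axis = 1) {
    idx <- which(ap$values > 0, arr.ind = TRUE)
    u <- ap$u0 + (idx[, 1] - 1) * ap$pixel_mm
    v <- ap$v0 + (idx[, 2] - 1) * ap$pixel_mm
    if (axis == 1) max(abs(u)) else max(abs(v))
  }
  ap0 <- conformal_aperture(ptv, b, margin_mm = 0, pixel_mm = 1)
  ap5 <- conformal_aperture(ptv, b, margin_mm = 5, pixel_mm = 1)
  expect_true(all(ap0$values %in% c(0, 1)))
  expect_true(all(ap5$values %in% c(0, 1)))
  # margin adds 5 mm along both principal axes, within one pixel
  for (axis in 1:2) {
    expect_equal(radius_of(ap5, axis) - radius_of(ap0, axis), 5, tolerance = 1)
  }

  # margin 0 equals an independently rasterized raw projection
  pts <- voxel_centers(ptv)[ptv$values > 0, , drop = FALSE]
  ax <- list(source = c(1000, 0, 0), u = c(0, 1, 0), v = c(0, 0, 1))
  w <- sweep(pts, 2, ax$source)
  t <- -w[, 1]
  uo <- 1000 / t * (w %*% ax$u); vo <- 1000 / t * (w %*% ax$v)
  expected <- matrix(0, nrow(ap0$values), ncol(ap0$values))
  iu <- round((uo - ap0$u0) / ap0$pixel_mm) + 1
  iv <- round((vo - ap0$v0) / ap0$pixel_mm) + 1
  expected[cbind(iu, iv)] <- 1
  expect_identical(ap0$values, expected)

  expect_error(conformal_aperture(mask_from(g, function(cc) rep(FALSE, nrow(cc))), b),
               "empty PTV")
})

test_that("disjoint target lobes give disjoint aperture components", {
  g <- centered_grid(32, 2)
  two <- mask_from(g, function(cc)
    rowSums(sweep(cc, 2, c(0, 0, 20))^2) <= 64 |
    rowSums(sweep(cc, 2, c(0, 0, -20))^2) <= 64)
  b <- beam_config(0, c(0, 0, 0), 1000)
  ap <- conformal_aperture(two, b, margin_mm = 2, pixel_mm = 2)
  # count connected components by flood fill (4-neighborhood)
  m <- ap$values > 0
  lab <- matrix(0L, nrow(m), ncol(m)); comp <- 0L
  for (s in which(m)) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (lab[q] != 0L || !m[q]) next
      lab[q] <- comp
      i <- (q - 1) %% nrow(m) + 1; j <- (q - 1) %/% nrow(m) + 1
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        if (nb[1] >= 1 && nb[1] <= nrow(m) && nb[2] >= 1 && nb[2] <= ncol(m)) {
          qq <- (nb[2] - 1) * nrow(m) + nb[1]
          if (m[qq] && lab[qq] == 0L) queue <- c(queue, qq)
        }
      }
    }
  }
  expect_equal(comp, 2L)
})

test_that("penumbra convolution preserves mass and maps a delta to a Gaussian", {
  f <- fluence_map(matrix(0, 41, 41), 1, -20, -20)
  f$values[21, 21] <- 1
  cf <- convolve_fluence(f, 3)
  expect_equal(sum(cf$values), 1, tolerance = 5e-3)
  expect_equal(which.max(cf$values), which.max(f$values))
  expect_true(all(cf$values >= 0))
  # ratio test against the Gaussian profile along the central row
  prof <- cf$values[, 21]
  expect_equal(prof[22] / prof[21], exp(-1 / (2 * 9)), tolerance = 1e-6)

  # well-padded aperture: total preserved within 0.5%
  ap <- fluence_map(matrix(0, 61, 61), 1, -30, -30)
  ap$values[26:36, 26:36] <- 1
  cap <- convolve_fluence(ap, 3)
  expect_equal(sum(cap$values) / sum(ap$values), 1, tolerance = 5e-3)

  # constant fluence is unchanged away from the border
  u <- fluence_map(matrix(2, 41, 41), 1, -20, -20)
  cu <- convolve_fluence(u, 3)
  expect_equal(cu$values[15:27, 15:27], u$values[15:27, 15:27], tolerance = 1e-9)
})

test_that("radiological depth is the density line integral", {
  g <- centered_grid(16, 2)
  uniform <- g; uniform$values[] <- 1
  src <- c(0, 1000, 0)
  # constant density 1: water-equivalent depth equals geometric depth in grid
  d1 <- radiological_depth(uniform, src, c(0, 0, 0), step_mm = 0.25)
  expect_equal(d1, 16, tolerance = 0.3)  # grid face at y=16 to the center
  half <- g; half$values[] <- 0.5
  d2 <- radiological_depth(half, src, c(0, 0, 0), step_mm = 0.25)
  expect_equal(d2, 8, tolerance = 0.3)
  expect_error(radiological_depth(uniform, src, c(0, 999, 0)), "inside")
})

test_that("oblique-ray depth matches dense numerical quadrature within 0.5 mm", {
  set.seed(4)
  g <- centered_grid(8, 2)
  g$values[] <- stats::runif(8^3)          # heterogeneous density
  src <- c(40, 55, 30)
  pts <- rbind(c(1, 2, -3), c(-5, 4, 2), c(0.5, -6, 5))
  got <- radiological_depth(g, src, pts, step_mm = 0.25)
  # brute-force line integral at 0.01 mm with nearest-neighbor density
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    L <- sqrt(sum((p - src)^2))
    ts <- seq(0, 1, by = 0.01 / L)
    acc <- 0
    for (t in ts) {
      pos <- src + t * (p - src)
      ijk <- round((pos - g$origin_mm) / g$spacing_mm)
      if (all(ijk >= 0) && all(ijk <= 7))
        acc <- acc + g$values[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] * 0.01
    }
    expect_equal(got[i], acc, tolerance = 0.5)
  }
})

test_that("broad-beam central-axis dose reproduces the PDD table", {
  n <- 32
  case <- make_simple_case(n = n, n_beams = 1, inverse_square = FALSE)
  case$structures$body$values[] <- 1       # uniform cube phantom
  b <- case$beams[[1]]                     # gantry 0: source at (+x)
  wide <- fluence_map(matrix(1, 101, 101), 2, -100, -100)
  dose <- fcbb_beam_dose(case, b, wide)
  ax <- beam_axes(b)
  body <- case$structures$body
  # voxels along a ray parallel to the axis near the center
  i_mid <- n / 2
  for (ix in c(4, 10, 16, 24)) {
    p <- voxel_centers(body)[ix + 32 * (i_mid - 1) + 32^2 * (i_mid - 1), ]
    depth <- radiological_depth(body, ax$source, matrix(p, 1), 0.25)
    expect_equal(dose$values[ix, i_mid, i_mid], case$model$pdd_fun(depth),
                 tolerance = 0.015)
  }
})

test_that("the dose operator is linear, non-negative and exactly adjoint", {
  case <- make_simple_case(n = 16, n_beams = 2)
  b <- case$beams[[1]]
  ap <- conformal_aperture(case$structures$targets[[1]]$mask, b, 5, 2)
  set.seed(5)
  f1 <- ap; f1$values <- matrix(stats::runif(length(ap$values)), nrow(ap$values))
  f2 <- ap; f2$values <- matrix(stats::runif(length(ap$values)), nrow(ap$values))
  d1 <- fcbb_beam_dose(case, b, f1)
  d2 <- fcbb_beam_dose(case, b, f2)
  fs <- ap; fs$values <- f1$values + f2$values
  ds <- fcbb_beam_dose(case, b, fs)
  expect_equal(ds$values, d1$values + d2$values, tolerance = 1e-12)
  expect_true(all(d1$values >= 0))

  z <- ap; z$values[] <- 0
  expect_true(all(fcbb_beam_dose(case, b, z)$values == 0))
  expect_error(fcbb_beam_dose(case, b, {bad <- ap; bad$values[1] <- -1; bad}),
               "non-negative")

  op <- dose_operator(case)
  set.seed(6)
  fl <- lapply(op$geoms, function(g) matrix(stats::runif(g$nu * g$nv), g$nu))
  dv <- stats::runif(length(op$idx))
  lhs <- sum(apply_dose_operator(op, fl) * dv)
  adj <- adjoint_dose_operator(op, dv)
  rhs <- sum(vapply(seq_along(fl), function(b) sum(fl[[b]] * adj[[b]]), numeric(1)))
  expect_equal(lhs, rhs, tolerance = 1e-6 * abs(lhs))
})

test_that("total dose sums beams, is permutation-invariant, errors on mismatch", {
  case <- make_simple_case(n = 16, n_beams = 3)
  fl <- lapply(case$beams, function(b) {
    ap <- conformal_aperture(case$structures$targets[[1]]$mask, b, 5, 2)
    convolve_fluence(ap, 3)
  })
  tot <- total_dose(case, fl)
  single <- make_simple_case(n = 16, n_beams = 3)
  single$beams <- case$beams[1]
  expect_equal(total_dose(single, fl[1])$values,
               fcbb_beam_dose(case, case$beams[[1]], fl[[1]])$values)
  perm <- c(3, 1, 2)
  case_p <- case; case_p$beams <- case$beams[perm]
  expect_equal(total_dose(case_p, fl[perm])$values, tot$values, tolerance = 1e-12)
  expect_error(total_dose(case, fl[1:2]), "one fluence map per beam")
})

test_that("grid-aligned rotations of phantom and gantry rotate the dose", {
  case <- make_simple_case(n = 16, n_beams = 1, target_center = c(4, 2, 0),
                           target_r = 6)
  case$beams <- list(beam_config(30, c(0, 0, 0), 1000))
  ap <- convolve_fluence(conformal_aperture(case$structures$targets[[1]]$mask,
                                            case$beams[[1]], 5, 2), 3)
  d0 <- fcbb_beam_dose(case, case$beams[[1]], ap)

  rcase <- case
  rcase$structures$body$values <- rot90z(case$structures$body$values)
  rcase$structures$targets[[1]]$mask$values <-
    rot90z(case$structures$targets[[1]]$mask$values)
  rbeam <- beam_config(30 + 90, c(0, 0, 0), 1000)
  rcase$beams <- list(rbeam)
  rap <- convolve_fluence(conformal_aperture(rcase$structures$targets[[1]]$mask,
                                             rbeam, 5, 2), 3)
  d1 <- fcbb_beam_dose(rcase, rbeam, rap)
  expect_equal(d1$values, rot90z(d0$values), tolerance = 1e-8)
})
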