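# Shared fixtures and independent oracles, all built in code.

# Volume on a grid centered at the world origin.
centered_grid <- function(n, spacing = 2) {
  volume_grid(array(0, rep(n, 3)), spacing, rep(-(n - 1) / 2 * spacing, 3))
}

mask_from <- function(grid, f) {
  cc <- voxel_centers(grid)
  out <- grid
  out$values <- array(as.numeric(f(cc)), dim(grid$values))
  out
}

# Deterministic small case: ellipsoidal body, spherical target at offset,
# optional spherical OAR, equispaced coplanar beams.
make_simple_case <- function(n = 16, spacing = 2, n_beams = 3, rx = 60,
                             target_center = c(0, 0, 0), target_r = 8,
                             oar_center = NULL, oar_r = 6,
                             inverse_square = FALSE) {
  g <- centered_grid(n, spacing)
  half <- n * spacing / 2
  body <- mask_from(g, function(cc)
    (cc[, 1] / (0.95 * half))^2 + (cc[, 2] / (0.9 * half))^2 +
      (cc[, 3] / (0.92 * half))^2 <= 1)
  ptv <- mask_from(g, function(cc)
    rowSums(sweep(cc, 2, target_center)^2) <= target_r^2)
  oars <- list()
  if (!is.null(oar_center)) {
    om <- mask_from(g, function(cc)
      rowSums(sweep(cc, 2, oar_center)^2) <= oar_r^2)
    om$values <- om$values * body$values
    oars <- list(list(name = "OAR1", weight = 1, mask = om))
  }
  ss <- structure_set(body, list(list(name = "PTV", mask = ptv,
                                      prescription_Gy = rx)), oars)
  beams <- lapply((seq_len(n_beams) - 1) * 360 / n_beams,
                  function(a) beam_config(a, c(0, 0, 0), 1000))
  case_bundle(ss, beams, beam_model(inverse_square = inverse_square))
}

# Rotate an array by +90 degrees about the z (third) axis:
# world (x, y) -> (-y, x) on a centered cubic grid.
rot90z <- function(a) {
  d <- dim(a)
  stopifnot(d[1] == d[2])
  out <- array(0, d)
  for (k in seq_len(d[3])) out[, , k] <- t(a[, d[2]:1, k])
  out
}

# Independent trilinear interpolation (for the gamma brute-force oracle).
oracle_trilinear <- function(arr, gx, gy, gz) {
  d <- dim(arr)
  if (gx < 0 || gx > d[1] - 1 || gy < 0 || gy > d[2] - 1 ||
      gz < 0 || gz > d[3] - 1) return(NA_real_)
  x0 <- min(floor(gx), d[1] - 2); y0 <- min(floor(gy), d[2] - 2)
  z0 <- min(floor(gz), d[3] - 2)
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    v <- v + w * arr[x0 + dx + 1, y0 + dy + 1, z0 + dz + 1]
  }
  v
}

# Exhaustive brute-force gamma passing rate: full lattice search (step
# dta/10) out to just beyond dta, which determines pass/fail exactly.
oracle_gpr <- function(reference, evaluated, dd_pct = 3, dta = 2, ldt_pct = 10) {
  dmax <- max(reference$values)
  dd <- dd_pct / 100 * dmax
  sp <- reference$spacing_mm
  d <- dim(reference$values)
  incl <- which(reference$values >= ldt_pct / 100 * dmax)
  step <- dta / 10
  ks <- -10:10
  offs <- as.matrix(expand.grid(ks, ks, ks)) * step
  offs <- offs[sqrt(rowSums(offs^2)) <= dta + 1e-9, , drop = FALSE]
  pass <- logical(length(incl))
  for (ii in seq_along(incl)) {
    lin <- incl[ii] - 1
    i <- lin %% d[1]; j <- (lin %/% d[1]) %% d[2]; k <- lin %/% (d[1] * d[2])
    rv <- reference$values[incl[ii]]
    for (o in seq_len(nrow(offs))) {
      ev <- oracle_trilinear(evaluated$values, i + offs[o, 1] / sp,
                             j + offs[o, 2] / sp, k + offs[o, 3] / sp)
      if (is.na(ev)) next
      g2 <- ((ev - rv) / dd)^2 + sum(offs[o, ]^2) / dta^2
      if (g2 <= 1 + 1e-9) { pass[ii] <- TRUE; break }
    }
  }
  100 * mean(pass)
}

# Smooth positive dose-like random field (sum of random Gaussian blobs).
smooth3d_field <- function(n, spacing = 2) {
  g <- centered_grid(n, spacing)
  cc <- voxel_centers(g)
  f <- numeric(nrow(cc))
  for (b in 1:3) {
    ctr <- stats::runif(3, -n * spacing / 4, n * spacing / 4)
    amp <- stats::runif(1, 20, 60)
    sig <- stats::runif(1, 8, 20)
    f <- f + amp * exp(-rowSums(sweep(cc, 2, ctr)^2) / (2 * sig^2))
  }
  array(f, rep(n, 3))
}

# One labelled entry for predictor tests (phantom + FMO label + channels).
make_training_entry <- function(seed, n = 24, n_beams = 7, fmo_iters = 100) {
  sp <- phantom_spec(seed = seed, shape = rep(n, 3), spacing_mm = 2,
                     n_beams = n_beams)
  cs <- generate_phantom(sp)
  op <- dose_operator(cs)
  lb <- make_label_dose(cs, objective_config(max_iter = fmo_iters), op = op)
  list(stack = build_channel_stack(cs), label = lb, case = cs, op = op)
}
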