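#' Specification for a seeded synthetic phantom
#'
#' Describes the sampling ranges for one synthetic case: a convex ellipsoidal
#' body, one or two nested spherical/ellipsoidal targets (single prescription
#' or simultaneous integrated boost), one to three organs at risk placed near
#' or overlapping the target, and a coplanar beam arrangement. Every field
#' left `NULL` is drawn from the stated ranges using the spec's seed, so a
#' `phantom_spec` is both an explicit description and a template for cohort
#' sampling. Defaults emulate the heterogeneity of clinical IMRT plans:
#' 7-25 beams at arbitrary gantry angles and prescriptions spanning
#' 4-79.2 Gy.
#'
#' @param seed integer RNG seed; the generated case is a pure function of the
#'   spec (bit-identical masks and angles for the same seed).
#' @param shape grid shape (3 integers), default `c(64, 64, 64)`.
#' @param spacing_mm isotropic spacing, default 2 (the canonical grid).
#' @param body_semiaxes_mm ellipsoid semi-axes (mm) or `NULL` to sample.
#' @param target_radius_mm primary target radius (mm) or `NULL` to sample
#'   from `[8, 18]`.
#' @param prescription_Gy primary (or boost, for SIB) prescription or `NULL`
#'   to sample from `prescription_range_Gy`.
#' @param sib logical or `NULL`; `NULL` samples SIB cases at `sib_prob`.
#' @param sib_prob probability of a simultaneous-integrated-boost case.
#' @param n_oars number of OARs, or `NULL` to sample 1-3.
#' @param oar_overlap_rate probability that an OAR is placed overlapping the
#'   target (exercises the overlap-relabeling workflow).
#' @param n_beams beam count, or `NULL` to sample uniformly from
#'   `beam_range`.
#' @param beam_range inclusive beam-count range, default `c(7, 25)`.
#' @param angle_mode `"equispaced"` (angles `360 k / n`, k = 0..n-1) or
#'   `"random"` (sorted uniform).
#' @param prescription_range_Gy prescription sampling range, default
#'   `c(4, 79.2)` Gy.
#' @param SAD_mm source-to-axis distance, default 1000.
#' @param model a `beam_model`.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(seed = 1L, shape = c(64L, 64L, 64L), spacing_mm = 2,
                         body_semiaxes_mm = NULL, target_radius_mm = NULL,
                         prescription_Gy = NULL, sib = NULL, sib_prob = 0.25,
                         n_oars = NULL, oar_overlap_rate = 0.2,
                         n_beams = NULL, beam_range = c(7L, 25L),
                         angle_mode = c("equispaced", "random"),
                         prescription_range_Gy = c(4, 79.2), SAD_mm = 1000,
                         model = beam_model()) {
  angle_mode <- match.arg(angle_mode)
  if (!is.null(n_beams) && n_beams < 1) stop("n_beams must be >= 1", call. = FALSE)
  if (any(prescription_range_Gy <= 0)) stop("prescriptions must be positive", call. = FALSE)
  structure(as.list(environment()), class = "phantom_spec")
}

## Run expr with a private, restored RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

ellipsoid_mask <- function(grid, center, semiaxes) {
  cc <- voxel_centers(grid)
  r <- sweep(cc, 2, center)
  r <- sweep(r, 2, semiaxes, "/")
  array(as.numeric(rowSums(r^2) <= 1), dim(grid$values))
}

cylinder_mask <- function(grid, center, radius, half_h) {
  cc <- voxel_centers(grid)
  dx <- cc[, 1] - center[1]; dy <- cc[, 2] - center[2]
  dz <- abs(cc[, 3] - center[3])
  array(as.numeric(dx^2 + dy^2 <= radius^2 & dz <= half_h), dim(grid$values))
}

#' Generate a synthetic phantom case
#'
#' Constructs masks and beam geometry from a [phantom_spec()], deterministic
#' in the seed. Targets are guaranteed to lie inside the body; the isocenter
#' is the primary target center; a boost target, when present, is nested
#' strictly inside the primary one.
#'
#' @param spec a `phantom_spec`.
#' @return A `case_bundle` without a label dose.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    shape <- as.integer(spec$shape); sp <- spec$spacing_mm
    origin <- -(shape - 1) / 2 * sp
    grid <- volume_grid(array(0, shape), sp, origin)
    half_extent <- shape * sp / 2

    semi <- spec$body_semiaxes_mm
    if (is.null(semi)) semi <- half_extent * stats::runif(3, 0.80, 0.95)
    if (any(semi > half_extent))
      stop("body semi-axes exceed the grid", call. = FALSE)
    body <- volume_grid(ellipsoid_mask(grid, c(0, 0, 0), semi), sp, origin)

    rt <- spec$target_radius_mm
    if (is.null(rt)) {
      # 8-18 mm on clinical-scale grids, shrunk so the target always fits
      hi <- min(18, 0.5 * min(semi))
      lo <- min(8, 0.6 * hi)
      rt <- stats::runif(1, lo, hi)
    }
    if (rt + sp >= min(semi)) stop("target larger than body", call. = FALSE)
    # a sphere of radius rt centered inside the ellipsoid with semi-axes
    # (semi - rt) lies inside the body; sample the center in that inner
    # ellipsoid (scaled to 80%), one voxel of slack for discretization
    w <- stats::runif(3, -1, 1)
    w <- w / max(1, sqrt(sum(w^2)))
    tc <- 0.8 * w * pmax(semi - rt - sp, 0)
    rx_hi <- spec$prescription_Gy
    if (is.null(rx_hi)) rx_hi <- stats::runif(1, spec$prescription_range_Gy[1],
                                              spec$prescription_range_Gy[2])
    sib <- spec$sib
    if (is.null(sib)) sib <- stats::runif(1) < spec$sib_prob
    targets <- list()
    if (sib) {
      rx_lo <- max(rx_hi * stats::runif(1, 0.75, 0.9),
                   spec$prescription_range_Gy[1])
      boost_r <- rt * stats::runif(1, 0.4, 0.6)
      targets <- list(
        list(name = "PTV_primary", prescription_Gy = rx_lo,
             mask = volume_grid(ellipsoid_mask(grid, tc, rep(rt, 3)), sp, origin)),
        list(name = "PTV_boost", prescription_Gy = rx_hi,
             mask = volume_grid(ellipsoid_mask(grid, tc, rep(boost_r, 3)), sp, origin)))
    } else {
      targets <- list(list(name = "PTV", prescription_Gy = rx_hi,
        mask = volume_grid(ellipsoid_mask(grid, tc, rep(rt, 3)), sp, origin)))
    }
    if (sum(targets[[1]]$mask$values) == 0)
      stop("degenerate phantom: empty target", call. = FALSE)

    n_oars <- spec$n_oars
    if (is.null(n_oars)) n_oars <- sample.int(3L, 1L)
    oars <- list()
    if (n_oars > 0) {
      for (i in seq_len(n_oars)) {
        ro <- stats::runif(1, 5, 14)
        overlap <- stats::runif(1) < spec$oar_overlap_rate
        shape_kind <- sample(c("sphere", "cylinder"), 1)
        # redraw placement (shrinking the distance) until the OAR has voxels
        # inside the body; deterministic given the seed
        m <- NULL
        for (try in 1:20) {
          shrink <- 0.85^(try - 1)
          dist <- if (overlap) stats::runif(1, 0.5, 0.9) * (rt + ro)
                  else stats::runif(1, rt + ro + 2, rt + ro + 2 + 23 * shrink)
          dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
          oc <- tc + dir * dist
          mm <- if (shape_kind == "sphere") ellipsoid_mask(grid, oc, rep(ro, 3))
                else cylinder_mask(grid, oc, ro * 0.8, ro)
          mm <- mm * body$values   # OARs clipped to the body by construction
          if (sum(mm) > 0) { m <- mm; break }
        }
        if (is.null(m))
          stop("OAR placement impossible inside the body", call. = FALSE)
        oars[[i]] <- list(name = sprintf("OAR%d", i),
                          weight = 1, mask = volume_grid(m, sp, origin))
      }
    }

    nb <- spec$n_beams
    if (is.null(nb)) nb <- sample(seq(spec$beam_range[1], spec$beam_range[2]), 1)
    angles <- if (spec$angle_mode == "equispaced") (seq_len(nb) - 1) * 360 / nb
              else sort(stats::runif(nb, 0, 360))
    beams <- lapply(angles, function(g) beam_config(g, tc, spec$SAD_mm))

    ss <- structure_set(body, targets, oars)
    case_bundle(ss, beams, spec$model,
                case_id = sprintf("phantom_%010d", as.integer(spec$seed)))
  })
}

#' Label dose by objective-based fluence-map optimization
#'
#' Produces the "clinical-like" ground-truth dose for a synthetic case by
#' solving the planning fluence-map optimization problem through the FCBB
#' engine (see [optimize_planning()]). The label is non-negative and, for
#' non-conflicting phantoms, covers each target (D95% near the
#' prescription).
#'
#' @param case a `case_bundle`.
#' @param objectives an `objective_config`; default [objective_config()].
#' @param op optional precomputed [dose_operator()].
#' @param ... passed to [optimize_planning()].
#' @return A dose `volume_grid` in Gy, with the optimization status in
#'   attribute `"fmo_status"`.
#' @export
make_label_dose <- function(case, objectives = objective_config(), op = NULL, ...) {
  res <- optimize_planning(case, objectives, op = op, ...)
  if (!all(is.finite(res$dose$values)))
    stop("fluence optimization produced a non-finite dose", call. = FALSE)
  dose <- res$dose
  attr(dose, "fmo_status") <- res$status
  dose
}

#' Generate a cohort of labelled synthetic cases
#'
#' Draws `n` cases from a template spec with per-case derived seeds, computes
#' a label dose for each via fluence-map optimization, writes each case to
#' its own directory and records a train/validation/test split manifest.
#' The split rule: `floor(n * f)` cases for train and validation (train gets
#' at least one case), the remainder to test.
#'
#' @param n number of cases (>= 1).
#' @param template a `phantom_spec` used as sampling template (its seed is
#'   ignored).
#' @param seed cohort master seed; case `i` uses
#'   `(seed + 99991 * i) mod 2^31-1`.
#' @param out_dir output directory; one subdirectory per case plus
#'   `manifest.json`. `NULL` keeps everything in memory.
#' @param split fractions `c(train, val, test)`, summing to 1.
#' @param label compute label doses (default `TRUE`).
#' @param objectives,fmo_args label-FMO configuration; see
#'   [make_label_dose()].
#' @return A manifest list with `cases` (data.frame: case_id, dir, seed,
#'   split) and, when `out_dir` is `NULL`, the in-memory `bundles`.
#' @export
generate_cohort <- function(n, template = phantom_spec(), seed = 1L,
                            out_dir = NULL, split = c(0.7, 0.15, 0.15),
                            label = TRUE, objectives = objective_config(),
                            fmo_args = list()) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1", call. = FALSE)
  n_train <- max(1L, as.integer(floor(n * split[1])))
  n_val <- min(as.integer(floor(n * split[2])), n - n_train)
  n_test <- n - n_train - n_val
  groups <- c(rep("train", n_train), rep("val", n_val), rep("test", n_test))
  seeds <- (as.numeric(seed) + 99991 * seq_len(n)) %% 2147483647
  bundles <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- template; sp$seed <- as.integer(seeds[i])
    case <- generate_phantom(sp)
    if (label) {
      case$label_dose <- do.call(make_label_dose,
                                 c(list(case, objectives), fmo_args))
    }
    cdir <- NA_character_
    if (!is.null(out_dir)) {
      cdir <- file.path(out_dir, case$case_id)
      write_case(case, cdir, seed = sp$seed)
    } else {
      bundles[[i]] <- case
    }
    rows[[i]] <- data.frame(case_id = case$case_id, dir = cdir,
                            seed = seeds[i], split = groups[i],
                            stringsAsFactors = FALSE)
  }
  manifest <- list(n = n, seed = seed, split = split,
                   cases = do.call(rbind, rows))
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(n = n, seed = seed, split = split,
                              cases = manifest$cases),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    manifest$bundles <- bundles
  }
  invisible(manifest)
}
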