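#' Beam geometry configuration
#'
#' One treatment beam: gantry angle (degrees, normalized to `[0, 360)`),
#' couch angle (non-coplanar hook; the dose engine supports only 0),
#' isocenter world position (mm) and source-to-axis distance (SAD, mm;
#' standard linac value 1000 mm).
#'
#' The beam geometry convention: the source sits at
#' `isocenter + SAD * (cos g, sin g, 0)` for gantry angle `g`, so the central
#' axis lies in the axial (x-y) plane and the beam's-eye-view (BEV) axes are
#' `u = (-sin g, cos g, 0)`, `v = (0, 0, 1)`.
#'
#' @param gantry_deg gantry angle in degrees (any real; normalized).
#' @param isocenter_mm world isocenter (mm), length 3.
#' @param SAD_mm source-to-axis distance (mm), positive.
#' @param couch_deg couch angle (degrees); must be 0 for the bundled engine.
#' @return A `beam_config` object.
#' @export
beam_config <- function(gantry_deg, isocenter_mm = c(0, 0, 0), SAD_mm = 1000,
                        couch_deg = 0) {
  if (!is.finite(gantry_deg)) stop("gantry angle must be finite", call. = FALSE)
  if (SAD_mm <= 0) stop("SAD_mm must be positive", call. = FALSE)
  structure(list(gantry_deg = ((gantry_deg %% 360) + 360) %% 360,
                 couch_deg = couch_deg,
                 isocenter_mm = as.numeric(isocenter_mm),
                 SAD_mm = as.numeric(SAD_mm)),
            class = "beam_config")
}

#' Orthonormal beam axes and source position
#'
#' Geometry of one beam: world source position, unit central-axis vector
#' (source toward isocenter) and the BEV in-plane axes `u_hat`, `v_hat`.
#' Trigonometry uses `sinpi`/`cospi`, which are exact at multiples of 90
#' degrees, so grid-aligned rotational equivariance holds to float
#' precision.
#'
#' @param beam a `beam_config` (couch angle must be 0).
#' @return list with `source`, `axis`, `u_hat`, `v_hat` (mm / unit vectors).
#' @export
beam_axes <- function(beam) {
  if (abs(beam$couch_deg) > 1e-9)
    stop("non-coplanar beams (couch_deg != 0) are not supported by the dose engine",
         call. = FALSE)
  g <- beam$gantry_deg / 180
  cg <- cospi(g); sg <- sinpi(g)
  list(source = beam$isocenter_mm + beam$SAD_mm * c(cg, sg, 0),
       axis   = c(-cg, -sg, 0),        # unit vector source -> isocenter
       u_hat  = c(-sg, cg, 0),
       v_hat  = c(0, 0, 1))
}

#' Beam physics model
#'
#' Percentage-depth-dose (PDD) table and lateral penumbra kernel used by the
#' fluence-convolution broad-beam (FCBB) dose engine. The default PDD is a
#' synthetic 6 MV-like curve: linear build-up from the surface to its maximum
#' at `d_max = 15` mm, then exponential attenuation `exp(-mu (d - d_max))`
#' with `mu = 0.005` / mm, tabulated at 1 mm and linearly interpolated. It is
#' a documented stand-in for machine commissioning data.
#'
#' @param pdd data.frame with columns `depth_mm`, `rel_dose` (max 1 at the
#'   build-up depth). Default: `default_pdd()`.
#' @param kernel_sigma_mm isotropic 2D Gaussian penumbra sigma at the
#'   isocenter plane (mm); truncated at 4 sigma, discretely normalized.
#' @param fluence_pixel_mm fluence-grid pixel size (mm) for beam-trace
#'   apertures.
#' @param inverse_square include the inverse-square distance factor
#'   `(SAD / source-to-voxel distance)^2` in the dose (default `TRUE`).
#' @return A `beam_model` object.
#' @export
beam_model <- function(pdd = default_pdd(), kernel_sigma_mm = 3,
                       fluence_pixel_mm = 2, inverse_square = TRUE) {
  stopifnot(is.data.frame(pdd), all(c("depth_mm", "rel_dose") %in% names(pdd)))
  if (any(pdd$rel_dose < 0)) stop("PDD must be non-negative", call. = FALSE)
  if (kernel_sigma_mm <= 0 || fluence_pixel_mm <= 0)
    stop("kernel_sigma_mm and fluence_pixel_mm must be positive", call. = FALSE)
  m <- structure(list(pdd = pdd, kernel_sigma_mm = kernel_sigma_mm,
                      fluence_pixel_mm = fluence_pixel_mm,
                      inverse_square = isTRUE(inverse_square)),
                 class = "beam_model")
  m$pdd_fun <- stats::approxfun(pdd$depth_mm, pdd$rel_dose, rule = 2)
  m
}

#' @rdname beam_model
#' @param d_max_mm build-up depth (mm).
#' @param mu_per_mm attenuation coefficient beyond `d_max` (1/mm).
#' @param max_depth_mm table extent (mm).
#' @export
default_pdd <- function(d_max_mm = 15, mu_per_mm = 0.005, max_depth_mm = 400) {
  depth <- seq(0, max_depth_mm, by = 1)
  rel <- ifelse(depth <= d_max_mm, depth / d_max_mm,
                exp(-mu_per_mm * (depth - d_max_mm)))
  data.frame(depth_mm = depth, rel_dose = rel)
}

#' Structure set: body, targets and organs at risk
#'
#' @param body binary `volume_grid` body mask.
#' @param targets list of targets, each `list(name=, mask=, prescription_Gy=)`;
#'   masks must be binary volumes contained in the body; at least one
#'   nonempty target; prescriptions positive (Gy).
#' @param oars list of OARs, each `list(name=, mask=, weight=)`; weights in
#'   `[0, 1]`. OAR voxels outside the body are clipped with a warning.
#' @return A `structure_set` object.
#' @export
structure_set <- function(body, targets, oars = list()) {
  stopifnot(is_volume_grid(body))
  if (!all(body$values %in% c(0, 1))) stop("body mask must be binary", call. = FALSE)
  if (length(targets) == 0) stop("at least one target is required", call. = FALSE)
  any_vox <- FALSE
  for (t in targets) {
    stopifnot(is_volume_grid(t$mask))
    stopifnot_same_grid(body, t$mask, "body and target masks")
    if (is.null(t$prescription_Gy) || t$prescription_Gy <= 0)
      stop("prescription_Gy must be positive", call. = FALSE)
    if (any(t$mask$values > 0 & body$values == 0))
      stop(sprintf("target '%s' extends outside the body", t$name), call. = FALSE)
    if (any(t$mask$values > 0)) any_vox <- TRUE
  }
  if (!any_vox) stop("all target masks are empty", call. = FALSE)
  oars <- lapply(oars, function(o) {
    stopifnot(is_volume_grid(o$mask))
    stopifnot_same_grid(body, o$mask, "body and OAR masks")
    if (is.null(o$weight)) o$weight <- 1
    if (o$weight < 0 || o$weight > 1)
      stop("OAR weight must lie in [0, 1]", call. = FALSE)
    if (any(o$mask$values > 0 & body$values == 0)) {
      warning(sprintf("OAR '%s' extends outside the body; clipping", o$name))
      o$mask$values <- o$mask$values * body$values
    }
    o
  })
  structure(list(body = body, targets = targets, oars = oars),
            class = "structure_set")
}

#' Bundle of everything defining one case
#'
#' @param structures a `structure_set`.
#' @param beams list of `beam_config`; all beams must share isocenter and SAD.
#' @param model a `beam_model`.
#' @param label_dose optional dose `volume_grid` (Gy) on the same grid.
#' @param case_id character id.
#' @return A `case_bundle` object.
#' @export
case_bundle <- function(structures, beams, model = beam_model(),
                        label_dose = NULL, case_id = "case") {
  stopifnot(inherits(structures, "structure_set"), inherits(model, "beam_model"))
  if (length(beams) < 1) stop("at least one beam is required", call. = FALSE)
  iso <- beams[[1]]$isocenter_mm; sad <- beams[[1]]$SAD_mm
  for (b in beams) {
    stopifnot(inherits(b, "beam_config"))
    if (any(abs(b$isocenter_mm - iso) > 1e-6) || abs(b$SAD_mm - sad) > 1e-6)
      stop("all beams must share isocenter and SAD", call. = FALSE)
  }
  if (!is.null(label_dose)) {
    stopifnot(is_volume_grid(label_dose))
    stopifnot_same_grid(structures$body, label_dose, "body and label dose")
  }
  structure(list(case_id = case_id, structures = structures, beams = beams,
                 model = model, label_dose = label_dose),
            class = "case_bundle")
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf("case_bundle '%s': %d beam(s), %d target(s), %d OAR(s), grid %s @ %g mm\n",
              x$case_id, length(x$beams), length(x$structures$targets),
              length(x$structures$oars),
              paste(dim(x$structures$body$values), collapse = "x"),
              x$structures$body$spacing_mm))
  invisible(x)
}

#' Maximum prescribed dose of a case (Gy)
#' @param structures a `structure_set` or `case_bundle`.
#' @return scalar Gy.
#' @export
max_prescription <- function(structures) {
  if (inherits(structures, "case_bundle")) structures <- structures$structures
  max(vapply(structures$targets, function(t) t$prescription_Gy, numeric(1)))
}

#' Read a plan description file
#'
#' Plans are stored as one JSON document per case with keys `case_id`,
#' `isocenter_mm`, `SAD_mm`, `beams` (list of objects with `gantry_deg` and
#' optional `couch_deg`), `targets` (name, prescription_Gy, mask file),
#' `oars` (name, weight, mask file), `body_mask`, and optional `beam_model`
#' (kernel_sigma_mm, fluence_pixel_mm, inverse_square, inline pdd table) and
#' `label_dose`. Gantry angles are normalized to `[0, 360)`.
#'
#' `read_plan` parses and validates geometry/prescription metadata without
#' loading any mask volume; `read_case` loads the full bundle.
#'
#' @param path plan JSON file.
#' @return A list with elements `case_id`, `beams` (list of `beam_config`),
#'   `targets`, `oars` (metadata incl. mask file names), `body_mask`,
#'   `model`, `label_dose` (file name or `NULL`).
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (key in c("beams", "isocenter_mm", "SAD_mm", "targets"))
    if (is.null(p[[key]])) stop(sprintf("plan is missing required key '%s'", key), call. = FALSE)
  if (length(p$beams) == 0) stop("plan has zero beams", call. = FALSE)
  if (p$SAD_mm <= 0) stop("SAD_mm must be positive", call. = FALSE)
  beams <- lapply(p$beams, function(b) {
    if (is.null(b$gantry_deg) || !is.numeric(b$gantry_deg) || !is.finite(b$gantry_deg))
      stop("beam without a numeric gantry_deg", call. = FALSE)
    beam_config(b$gantry_deg, as.numeric(p$isocenter_mm), p$SAD_mm,
                couch_deg = if (is.null(b$couch_deg)) 0 else b$couch_deg)
  })
  for (t in p$targets)
    if (is.null(t$prescription_Gy) || t$prescription_Gy <= 0)
      stop("target prescriptions must be positive", call. = FALSE)
  model <- beam_model()
  if (!is.null(p$beam_model)) {
    bm <- p$beam_model
    pdd <- if (!is.null(bm$pdd))
      data.frame(depth_mm = as.numeric(bm$pdd$depth_mm),
                 rel_dose = as.numeric(bm$pdd$rel_dose)) else default_pdd()
    model <- beam_model(pdd,
      kernel_sigma_mm = bm$kernel_sigma_mm %||% 3,
      fluence_pixel_mm = bm$fluence_pixel_mm %||% 2,
      inverse_square = bm$inverse_square %||% TRUE)
  }
  list(case_id = p$case_id %||% "case", beams = beams, targets = p$targets,
       oars = p$oars %||% list(), body_mask = p$body_mask %||% "body.nii.gz",
       model = model, label_dose = p$label_dose, seed = p$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a case directory into a `case_bundle`
#'
#' A case directory contains `plan.json` plus the NIfTI masks it references
#' and optionally a label dose.
#'
#' @param dir case directory.
#' @return A `case_bundle`.
#' @export
read_case <- function(dir) {
  plan <- read_plan(file.path(dir, "plan.json"))
  body <- read_volume(file.path(dir, plan$body_mask))
  targets <- lapply(plan$targets, function(t)
    list(name = t$name, prescription_Gy = t$prescription_Gy,
         mask = read_volume(file.path(dir, t$mask))))
  oars <- lapply(plan$oars, function(o)
    list(name = o$name, weight = o$weight %||% 1,
         mask = read_volume(file.path(dir, o$mask))))
  label <- NULL
  if (!is.null(plan$label_dose) && file.exists(file.path(dir, plan$label_dose)))
    label <- read_volume(file.path(dir, plan$label_dose))
  ss <- structure_set(body, targets, oars)
  case_bundle(ss, plan$beams, plan$model, label, plan$case_id)
}

#' Write a case to a directory
#'
#' @param case a `case_bundle`.
#' @param dir output directory (created if needed).
#' @param seed optional integer recorded in the plan for provenance.
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ss <- case$structures
  write_volume(ss$body, file.path(dir, "body.nii.gz"))
  tmeta <- lapply(seq_along(ss$targets), function(i) {
    t <- ss$targets[[i]]
    fn <- sprintf("target_%02d.nii.gz", i)
    write_volume(t$mask, file.path(dir, fn))
    list(name = t$name, prescription_Gy = t$prescription_Gy, mask = fn)
  })
  ometa <- lapply(seq_along(ss$oars), function(i) {
    o <- ss$oars[[i]]
    fn <- sprintf("oar_%02d.nii.gz", i)
    write_volume(o$mask, file.path(dir, fn))
    list(name = o$name, weight = o$weight, mask = fn)
  })
  label <- NULL
  if (!is.null(case$label_dose)) {
    write_volume(case$label_dose, file.path(dir, "label_dose.nii.gz"))
    label <- "label_dose.nii.gz"
  }
  plan <- list(case_id = case$case_id,
               isocenter_mm = case$beams[[1]]$isocenter_mm,
               SAD_mm = case$beams[[1]]$SAD_mm,
               beams = lapply(case$beams, function(b)
                 list(gantry_deg = b$gantry_deg, couch_deg = b$couch_deg)),
               targets = tmeta, oars = ometa, body_mask = "body.nii.gz",
               beam_model = list(kernel_sigma_mm = case$model$kernel_sigma_mm,
                                 fluence_pixel_mm = case$model$fluence_pixel_mm,
                                 inverse_square = case$model$inverse_square,
                                 pdd = list(depth_mm = case$model$pdd$depth_mm,
                                            rel_dose = case$model$pdd$rel_dose)),
               label_dose = label, seed = seed)
  jsonlite::write_json(plan, file.path(dir, "plan.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
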