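#' Normalized prescription channel
#'
#' Encodes the planning goal as an ideal dose map: each voxel carries the
#' prescription of the highest-dose target covering it, divided by the
#' maximum prescribed dose `dp_max`, and 0 outside all targets. A
#' single-prescription plan yields a binary PTV mask; a simultaneous
#' integrated boost (SIB) plan yields one discrete level per prescription
#' (ratios to `dp_max`), so the channel is invariant to uniform scaling of
#' all prescriptions.
#'
#' @param structures a `structure_set`.
#' @return list with `channel` (a `volume_grid`, values in `[0, 1]`) and
#'   `dp_max_Gy` (the normalization constant).
#' @export
encode_prescription <- function(structures) {
  if (length(structures$targets) == 0) stop("no targets", call. = FALSE)
  dp_max <- max_prescription(structures)
  body <- structures$body
  acc <- array(0, dim(body$values))
  for (t in structures$targets)
    acc <- pmax(acc, t$mask$values * (t$prescription_Gy / dp_max))
  list(channel = volume_grid(acc, body$spacing_mm, body$origin_mm),
       dp_max_Gy = dp_max)
}

#' Weighted avoidance channel
#'
#' Consolidates OARs and the body outline into a single map: OAR voxels get
#' their avoidance weight (default 1), body voxels outside any OAR get
#' `body_weight` (default 0.1), voxels outside the body get 0. Where several
#' OARs overlap, the maximum weight wins.
#'
#' Voxels where a target overlaps an OAR are resolved by `overlap_policy`:
#' `"target_priority"` (default) removes them from the avoidance set so the
#' prediction prioritizes coverage — they fall back to the body value;
#' `"oar_priority"` labels them as OAR, the patient-specific adjustment used
#' to trade coverage for sparing when a target abuts a critical structure.
#'
#' @param structures a `structure_set`.
#' @param weights optional named numeric vector overriding per-OAR weights.
#' @param overlap_policy `"target_priority"` or `"oar_priority"`.
#' @param body_weight value for in-body, non-OAR voxels (default 0.1).
#' @return A `volume_grid`.
#' @export
encode_avoidance <- function(structures, weights = NULL,
                             overlap_policy = c("target_priority", "oar_priority"),
                             body_weight = 0.1) {
  overlap_policy <- match.arg(overlap_policy)
  body <- structures$body
  acc <- body$values * body_weight
  oarmax <- array(0, dim(body$values))
  for (o in structures$oars) {
    w <- o$weight
    if (!is.null(weights) && !is.null(o$name) && o$name %in% names(weights))
      w <- weights[[o$name]]
    oarmax <- pmax(oarmax, o$mask$values * w)
  }
  if (overlap_policy == "target_priority" && length(structures$oars) > 0) {
    tu <- target_union(structures)$values
    oarmax[tu > 0] <- 0
  }
  sel <- oarmax > 0
  acc[sel] <- oarmax[sel]
  volume_grid(acc, body$spacing_mm, body$origin_mm)
}

#' Beam-trace channel
#'
#' Encodes the multi-beam geometry as a non-modulated cumulative dose
#' approximation: for each beam, a unit-fluence aperture conformal to the
#' union of targets (isotropically dilated by `margin_mm`) is convolved with
#' the penumbra kernel and pushed through the FCBB engine; each per-beam dose
#' is normalized to its own maximum, and the normalized doses are summed and
#' divided by the number of beams. Where beams overlap (at the target) the
#' map approaches 1, independent of beam count; duplicating or permuting
#' beams leaves the map unchanged.
#'
#' @param case a `case_bundle`.
#' @param margin_mm aperture margin (mm), default 5.
#' @param pixel_mm fluence pixel (mm); default the model's
#'   `fluence_pixel_mm`.
#' @param step_mm ray-marching step (mm).
#' @return A `volume_grid` with values `>= 0`, maximum typically close to 1.
#' @export
encode_beam_trace <- function(case, margin_mm = 5, pixel_mm = NULL,
                              step_mm = NULL) {
  if (length(case$beams) == 0) stop("no beams", call. = FALSE)
  if (is.null(pixel_mm)) pixel_mm <- case$model$fluence_pixel_mm
  union_t <- target_union(case$structures)
  body <- case$structures$body
  acc <- array(0, dim(body$values))
  for (beam in case$beams) {
    ap <- conformal_aperture(union_t, beam, margin_mm, pixel_mm)
    ap <- convolve_fluence(ap, case$model$kernel_sigma_mm)
    db <- fcbb_beam_dose(case, beam, ap, case$model, step_mm)$values
    mx <- max(db)
    if (mx > 0) acc <- acc + db / mx
  }
  volume_grid(acc / length(case$beams), body$spacing_mm, body$origin_mm)
}

#' Build the three generalized input channels for a case
#'
#' Assembles the prescription, avoidance and beam-trace channels on the
#' shared grid, together with the dose-normalization constant `dp_max_Gy`.
#'
#' @param case a `case_bundle`.
#' @param weights,overlap_policy,body_weight passed to [encode_avoidance()].
#' @param margin_mm,pixel_mm,step_mm passed to [encode_beam_trace()].
#' @return A `channel_stack` with fields `prescription`, `avoidance`,
#'   `beam_trace` (each a `volume_grid`) and `dp_max_Gy`.
#' @export
build_channel_stack <- function(case, weights = NULL,
                                overlap_policy = c("target_priority", "oar_priority"),
                                body_weight = 0.1, margin_mm = 5,
                                pixel_mm = NULL, step_mm = NULL) {
  overlap_policy <- match.arg(overlap_policy)
  pres <- encode_prescription(case$structures)
  avoid <- encode_avoidance(case$structures, weights, overlap_policy, body_weight)
  trace <- encode_beam_trace(case, margin_mm, pixel_mm, step_mm)
  stopifnot_same_grid(pres$channel, trace, "channels")
  structure(list(prescription = pres$channel, avoidance = avoid,
                 beam_trace = trace, dp_max_Gy = pres$dp_max_Gy),
            class = "channel_stack")
}

#' Write a channel stack to a case directory
#'
#' @param stack a `channel_stack`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_channel_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(stack$prescription, file.path(dir, "prescription.nii.gz"))
  write_volume(stack$avoidance, file.path(dir, "avoidance.nii.gz"))
  write_volume(stack$beam_trace, file.path(dir, "beamtrace.nii.gz"))
  jsonlite::write_json(list(dp_max_Gy = stack$dp_max_Gy),
                       file.path(dir, "normalization.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a channel stack written by [write_channel_stack()]
#' @param dir case directory.
#' @return A `channel_stack`.
#' @export
read_channel_stack <- function(dir) {
  norm <- jsonlite::read_json(file.path(dir, "normalization.json"),
                              simplifyVector = TRUE)
  structure(list(prescription = read_volume(file.path(dir, "prescription.nii.gz")),
                 avoidance = read_volume(file.path(dir, "avoidance.nii.gz")),
                 beam_trace = read_volume(file.path(dir, "beamtrace.nii.gz")),
                 dp_max_Gy = norm$dp_max_Gy),
            class = "channel_stack")
}
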