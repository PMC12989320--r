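#' Gamma analysis criteria
#'
#' Dose-difference / distance-to-agreement criteria for 3D gamma analysis.
#' Defaults are the clinical 3%/2 mm with a 10% low-dose threshold (LDT);
#' dose difference is normalized globally by the reference maximum, and the
#' LDT is applied on the reference.
#'
#' @param dose_diff_pct dose-difference criterion, percent of the reference
#'   maximum (default 3).
#' @param dta_mm distance-to-agreement criterion in mm (default 2).
#' @param low_dose_threshold_pct exclude voxels whose reference dose is below
#'   this percent of the reference maximum (default 10).
#' @param search_radius_factor search radius in units of `dta_mm` (default 3;
#'   only affects gamma values above 1, not the passing rate).
#' @param step_factor lattice search step in units of `dta_mm` (default 0.1).
#' @return A `gamma_criteria` object.
#' @export
gamma_criteria <- function(dose_diff_pct = 3, dta_mm = 2,
                           low_dose_threshold_pct = 10,
                           search_radius_factor = 3, step_factor = 0.1) {
  if (any(c(dose_diff_pct, dta_mm, low_dose_threshold_pct) <= 0))
    stop("gamma criteria must be positive", call. = FALSE)
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 low_dose_threshold_pct = low_dose_threshold_pct,
                 search_radius_factor = search_radius_factor,
                 step_factor = step_factor),
            class = "gamma_criteria")
}

#' 3D gamma passing rate
#'
#' Per-voxel gamma index between a reference and an evaluated dose on the
#' same grid:
#' `gamma(x) = min_r sqrt( ((E(x+r) - R(x)) / (dd% * max R))^2 + (|r| / dta)^2 )`
#' minimized over displacements `r` on a lattice of step
#' `step_factor * dta` within `search_radius_factor * dta`, with the
#' evaluated dose sampled by trilinear interpolation. Voxels with reference
#' dose below the low-dose threshold are excluded. The passing rate is the
#' percentage of included voxels with `gamma <= 1`; because any displacement
#' with `|r| > dta` already has `gamma > 1`, the lattice inside `dta` fully
#' determines the passing rate.
#'
#' @param reference reference dose `volume_grid` (the comparison baseline;
#'   its maximum defines normalization and threshold).
#' @param evaluated evaluated dose `volume_grid` on the same grid.
#' @param crit a [gamma_criteria()].
#' @return A `gamma_result`: `gpr` (percent), `gamma` (`volume_grid`, `NA`
#'   outside the analyzed region, capped at the search radius), `n_included`,
#'   `criteria`.
#' @export
gamma_passing_rate <- function(reference, evaluated, crit = gamma_criteria()) {
  stopifnot_same_grid(reference, evaluated, "reference and evaluated dose")
  dmax <- max(reference$values)
  if (dmax <= 0) stop("all-zero reference dose", call. = FALSE)
  dd <- crit$dose_diff_pct / 100 * dmax
  dta <- crit$dta_mm
  incl <- which(reference$values >= crit$low_dose_threshold_pct / 100 * dmax)
  n_inc <- length(incl)
  pts <- voxel_centers(reference)[incl, , drop = FALSE]
  rv <- reference$values[incl]

  # displacement lattice, sorted by radius
  step <- crit$step_factor * dta
  rmax <- crit$search_radius_factor * dta
  kmax <- floor(rmax / step + 1e-9)
  ks <- -kmax:kmax
  off <- as.matrix(expand.grid(x = ks, y = ks, z = ks)) * step
  rad <- sqrt(rowSums(off^2))
  keep <- rad <= rmax + 1e-9
  off <- off[keep, , drop = FALSE]; rad <- rad[keep]
  ord <- order(rad)
  off <- off[ord, , drop = FALSE]; rad <- rad[ord]

  g2 <- rep(Inf, n_inc)
  active <- seq_len(n_inc)
  for (o in seq_len(nrow(off))) {
    r2 <- (rad[o] / dta)^2
    active <- active[g2[active] > r2]
    if (length(active) == 0) break
    p <- pts[active, , drop = FALSE]
    p[, 1] <- p[, 1] + off[o, 1]; p[, 2] <- p[, 2] + off[o, 2]
    p[, 3] <- p[, 3] + off[o, 3]
    ev <- interp_volume(evaluated, p, mode = "linear", outside = NA_real_)
    cand <- ((ev - rv[active]) / dd)^2 + r2
    upd <- which(!is.na(cand) & cand < g2[active])
    g2[active[upd]] <- cand[upd]
  }
  g <- sqrt(g2)
  g[!is.finite(g)] <- crit$search_radius_factor
  gpr <- 100 * sum(g <= 1 + 1e-9) / n_inc
  garr <- array(NA_real_, dim(reference$values))
  garr[incl] <- g
  gm <- reference; gm$values <- garr
  structure(list(gpr = gpr, gamma = gm, n_included = n_inc, criteria = crit),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma %g%%/%g mm (LDT %g%%): GPR = %.2f%% over %d voxels\n",
              x$criteria$dose_diff_pct, x$criteria$dta_mm,
              x$criteria$low_dose_threshold_pct, x$gpr, x$n_included))
  invisible(x)
}

#' Dose-at-volume metric Dx%
#'
#' The largest dose `d` such that at least `x`% of the ROI volume receives a
#' dose `>= d`: descending sort, value at rank `ceiling(x/100 * n)` (no
#' interpolation).
#'
#' @param dose dose `volume_grid` (Gy).
#' @param mask binary ROI `volume_grid` on the same grid, nonempty.
#' @param x_pct volume percentage in `(0, 100]` (e.g. 95 for coverage, 2 for
#'   near-maximum); may be a vector.
#' @return Dose(s) in Gy, named `D<x>%`.
#' @export
dose_at_volume <- function(dose, mask, x_pct) {
  stopifnot_same_grid(dose, mask, "dose and mask")
  vals <- dose$values[mask$values > 0]
  n <- length(vals)
  if (n == 0) stop("empty ROI mask", call. = FALSE)
  if (any(x_pct <= 0 | x_pct > 100)) stop("x_pct must lie in (0, 100]", call. = FALSE)
  s <- sort(vals, decreasing = TRUE)
  out <- s[ceiling(x_pct / 100 * n)]
  names(out) <- sprintf("D%g%%", x_pct)
  out
}

#' Cumulative dose-volume histogram
#'
#' @param dose dose `volume_grid` (Gy).
#' @param mask binary ROI mask, nonempty.
#' @param bin_Gy dose-axis bin width (Gy), default 0.1.
#' @param roi ROI name carried in the result.
#' @return A `dvh_curve`: data.frame with `dose_Gy` and `volume_fraction`
#'   (monotone non-increasing, starting at 1 at 0 Gy), plus attribute `roi`.
#' @export
dvh_curve <- function(dose, mask, bin_Gy = 0.1, roi = "ROI") {
  stopifnot_same_grid(dose, mask, "dose and mask")
  vals <- dose$values[mask$values > 0]
  if (length(vals) == 0) stop("empty ROI mask", call. = FALSE)
  axis <- seq(0, max(vals) + bin_Gy, by = bin_Gy)
  frac <- vapply(axis, function(d) mean(vals >= d), numeric(1))
  structure(data.frame(dose_Gy = axis, volume_fraction = frac),
            roi = roi, class = c("dvh_curve", "data.frame"))
}

#' Mean absolute percentage error of DVH metrics
#'
#' `MAPE = 100/n * sum_i |Dx%_i(pred) - Dx%_i(ref)| / Dp_i`, with `Dp_i` the
#' per-case prescribed dose.
#'
#' @param pred,ref numeric vectors of a DVH metric across cases (Gy).
#' @param Dp prescribed dose(s), Gy; scalar or per-case vector, positive.
#' @return MAPE in percent.
#' @export
mape <- function(pred, ref, Dp) {
  if (length(pred) != length(ref)) stop("length mismatch", call. = FALSE)
  if (length(pred) < 1) stop("need at least one case", call. = FALSE)
  Dp <- rep_len(Dp, length(pred))
  if (any(Dp <= 0)) stop("prescribed dose must be positive", call. = FALSE)
  100 * mean(abs(pred - ref) / Dp)
}

#' Per-case and cohort metric report
#'
#' Compares dose distributions per case — typically predicted vs optimized,
#' predicted vs label ("clinical"), optimized vs label — with gamma passing
#' rates and Dx% metrics per ROI. For each comparison the second-named dose
#' acts as the gamma reference. Cases with a missing dose are skipped with a
#' warning.
#'
#' @param entries list; each element is `list(case = case_bundle, doses =
#'   named list of volume_grid)`, e.g. `doses = list(pred = ..., opt = ...,
#'   label = ...)`.
#' @param comparisons character matrix-like list of `c(evaluated, reference)`
#'   pairs; defaults to the pred/opt/label triangle.
#' @param crit a [gamma_criteria()].
#' @param x_levels Dx% levels reported per ROI (default `c(2, 5, 50, 95)`).
#' @param out_csv optional path: write the per-case table as CSV.
#' @return list with `per_case` (one row per case x comparison, GPR plus
#'   Dx% columns per ROI for both doses), `summary` (mean and sd of GPR per
#'   comparison) and `mape` (per metric and comparison, normalized by each
#'   case's maximum prescription).
#' @export
report_cohort <- function(entries,
                          comparisons = list(c("pred", "opt"),
                                             c("pred", "label"),
                                             c("opt", "label")),
                          crit = gamma_criteria(), x_levels = c(2, 5, 50, 95),
                          out_csv = NULL) {
  rows <- list()
  for (e in entries) {
    case <- e$case
    rois <- c(lapply(case$structures$targets, function(t) list(name = t$name, mask = t$mask)),
              lapply(case$structures$oars, function(o) list(name = o$name, mask = o$mask)))
    for (cmp in comparisons) {
      ev <- e$doses[[cmp[1]]]; ref <- e$doses[[cmp[2]]]
      if (is.null(ev) || is.null(ref)) {
        warning(sprintf("case %s: missing dose for %s vs %s; skipped",
                        case$case_id, cmp[1], cmp[2]))
        next
      }
      gr <- gamma_passing_rate(ref, ev, crit)
      row <- data.frame(case_id = case$case_id,
                        comparison = paste(cmp[1], "vs", cmp[2]),
                        gpr = gr$gpr, dp_max_Gy = max_prescription(case),
                        stringsAsFactors = FALSE)
      for (roi in rois) {
        if (sum(roi$mask$values) == 0) next
        for (x in x_levels) {
          row[[sprintf("%s_D%g_eval", roi$name, x)]] <-
            unname(dose_at_volume(ev, roi$mask, x))
          row[[sprintf("%s_D%g_ref", roi$name, x)]] <-
            unname(dose_at_volume(ref, roi$mask, x))
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) stop("no comparable dose pairs", call. = FALSE)
  all_cols <- unique(unlist(lapply(rows, names)))
  per_case <- do.call(rbind, lapply(rows, function(r) {
    for (m in setdiff(all_cols, names(r))) r[[m]] <- NA_real_
    r[all_cols]
  }))
  summary <- do.call(rbind, lapply(split(per_case, per_case$comparison),
    function(d) data.frame(comparison = d$comparison[1], n = nrow(d),
                           gpr_mean = mean(d$gpr), gpr_sd = stats::sd(d$gpr))))
  rownames(summary) <- NULL
  metric_cols <- grep("_D[0-9.]+_eval$", names(per_case), value = TRUE)
  mape_rows <- list()
  for (mc in metric_cols) {
    rc <- sub("_eval$", "_ref", mc)
    for (cmpn in unique(per_case$comparison)) {
      d <- per_case[per_case$comparison == cmpn, ]
      ok <- !is.na(d[[mc]]) & !is.na(d[[rc]])
      if (!any(ok)) next
      mape_rows[[length(mape_rows) + 1]] <- data.frame(
        metric = sub("_eval$", "", mc), comparison = cmpn,
        mape_pct = mape(d[[mc]][ok], d[[rc]][ok], d$dp_max_Gy[ok]))
    }
  }
  out <- list(per_case = per_case, summary = summary,
              mape = if (length(mape_rows)) do.call(rbind, mape_rows) else NULL)
  if (!is.null(out_csv)) utils::write.csv(per_case, out_csv, row.names = FALSE)
  out
}
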