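#' Objective configuration for fluence-map optimization
#'
#' One-sided quadratic penalties, normalized per structure and by the square
#' of the maximum prescription (planning mode) or the reference maximum
#' (reference mode), so the objective is invariant under joint scaling of
#' dose and prescriptions/reference.
#'
#' Planning mode (no `reference`): each target voxel is pulled toward its
#' per-voxel ideal dose (the prescription of the highest-dose target covering
#' it) with `target_under_w` on underdose and `target_over_w` on overdose;
#' OAR voxels (outside targets) are penalized quadratically above zero with
#' `oar_over_w` times the OAR's avoidance weight; body voxels are penalized
#' above the maximum prescription with `body_over_w` (hot-spot control).
#'
#' Reference mode: underdose below the reference is penalized in targets
#' (`target_under_w`), overdose above the reference everywhere
#' (`body_over_w`), plus a small symmetric fidelity term (`fidelity_w`)
#' everywhere in the body; the objective is zero iff the dose equals the
#' reference on the body, so references generated by feasible fluences are
#' exactly recoverable.
#'
#' @param target_under_w,target_over_w,oar_over_w,body_over_w,fidelity_w
#'   non-negative weights.
#' @param reference optional reference dose `volume_grid` (Gy); switches to
#'   reference mode.
#' @param max_iter maximum iterations (>= 1), default 500.
#' @param tol relative objective-change stopping tolerance, default 1e-6.
#' @return An `objective_config`.
#' @export
objective_config <- function(target_under_w = 100, target_over_w = 30,
                             oar_over_w = 5, body_over_w = 10,
                             fidelity_w = 1, reference = NULL,
                             max_iter = 500, tol = 1e-6) {
  ws <- c(target_under_w, target_over_w, oar_over_w, body_over_w, fidelity_w)
  if (any(ws < 0)) stop("weights must be non-negative", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  structure(list(target_under_w = target_under_w, target_over_w = target_over_w,
                 oar_over_w = oar_over_w, body_over_w = body_over_w,
                 fidelity_w = fidelity_w, reference = reference,
                 max_iter = max_iter, tol = tol),
            class = "objective_config")
}

## Structure bookkeeping on the in-body voxel vector (op$idx order).
fmo_context <- function(case, op, obj) {
  ss <- case$structures
  idx <- op$idx
  ideal <- encode_prescription(ss)
  dp_max <- ideal$dp_max_Gy
  ideal_v <- ideal$channel$values[idx] * dp_max
  tmask <- target_union(ss)$values[idx] > 0
  oar_v <- numeric(length(idx))   # per-voxel OAR penalty weight, targets win
  for (o in ss$oars) {
    sel <- o$mask$values[idx] > 0 & !tmask
    oar_v[sel] <- pmax(oar_v[sel], o$weight)
  }
  ref_v <- NULL
  if (!is.null(obj$reference)) {
    stopifnot_same_grid(ss$body, obj$reference, "body and reference dose")
    if (any(obj$reference$values < 0))
      stop("reference dose must be non-negative", call. = FALSE)
    ref_v <- obj$reference$values[idx]
  }
  list(ideal = ideal_v, tmask = tmask, oar_w = oar_v, dp_max = dp_max,
       ref = ref_v, n_t = max(1, sum(tmask)), n_o = max(1, sum(oar_v > 0)),
       n_b = length(idx))
}

fmo_objective_terms <- function(d, ctx, obj, gradient = FALSE) {
  if (is.null(ctx$ref)) {
    s <- ctx$dp_max^2
    under <- pmax(ctx$ideal - d, 0) * ctx$tmask
    over <- pmax(d - ctx$ideal, 0) * ctx$tmask
    oar <- pmax(d, 0) * (ctx$oar_w > 0)
    hot <- pmax(d - ctx$dp_max, 0)
    J <- obj$target_under_w * sum(under^2) / (ctx$n_t * s) +
         obj$target_over_w * sum(over^2) / (ctx$n_t * s) +
         obj$oar_over_w * sum(ctx$oar_w * oar^2) / (ctx$n_o * s) +
         obj$body_over_w * sum(hot^2) / (ctx$n_b * s)
    if (!gradient) return(J)
    g <- 2 * (-obj$target_under_w * under / (ctx$n_t * s) +
              obj$target_over_w * over / (ctx$n_t * s) +
              obj$oar_over_w * ctx$oar_w * oar / (ctx$n_o * s) +
              obj$body_over_w * hot / (ctx$n_b * s))
    return(list(J = J, g = g))
  }
  s <- max(max(ctx$ref)^2, .Machine$double.eps)
  under <- pmax(ctx$ref - d, 0) * ctx$tmask
  over <- pmax(d - ctx$ref, 0)
  res <- d - ctx$ref
  J <- obj$target_under_w * sum(under^2) / (ctx$n_t * s) +
       obj$body_over_w * sum(over^2) / (ctx$n_b * s) +
       obj$fidelity_w * sum(res^2) / (ctx$n_b * s)
  if (!gradient) return(J)
  g <- 2 * (-obj$target_under_w * under / (ctx$n_t * s) +
            obj$body_over_w * over / (ctx$n_b * s) +
            obj$fidelity_w * res / (ctx$n_b * s))
  list(J = J, g = g)
}

#' Penalty objective value of a dose distribution
#'
#' Pure function evaluating the one-sided penalty objective (see
#' [objective_config()]) for a dose on the case grid. Non-negative; zero iff
#' every one-sided constraint is satisfied (and, in reference mode, the dose
#' matches the reference on the body).
#'
#' @param dose a dose `volume_grid` (Gy).
#' @param case a `case_bundle`.
#' @param obj an `objective_config`.
#' @return scalar objective value.
#' @export
objective_value <- function(dose, case, obj = objective_config()) {
  stopifnot_same_grid(case$structures$body, dose, "body and dose")
  op_like <- list(idx = which(case$structures$body$values > 0))
  ctx <- fmo_context(case, op_like, obj)
  fmo_objective_terms(dose$values[op_like$idx], ctx, obj)
}

## Spectral projected gradient with Barzilai-Borwein step and monotone
## backtracking. Deterministic from the zero-fluence initialization.
solve_fmo <- function(op, ctx, obj) {
  sizes <- vapply(op$geoms, function(g) g$nu * g$nv, numeric(1))
  offs <- c(0, cumsum(sizes))
  split_f <- function(fv) lapply(seq_len(op$n_beams), function(b)
    matrix(fv[(offs[b] + 1):offs[b + 1]], op$geoms[[b]]$nu, op$geoms[[b]]$nv))
  fv <- numeric(sum(sizes))
  dv <- numeric(length(op$idx))
  tg <- fmo_objective_terms(dv, ctx, obj, gradient = TRUE)
  J <- tg$J
  trace <- J
  gf <- unlist(adjoint_dose_operator(op, tg$g))
  status <- "max_iter"
  # first step: exact line search along the projected steepest descent
  # direction from zero fluence (dose is linear in the step there)
  p <- pmax(-gf, 0)
  if (sum(p) > 0) {
    dp <- apply_dose_operator(op, split_f(p))
    alphas <- 10^seq(-8, 8, length.out = 81)
    Js <- vapply(alphas, function(a) fmo_objective_terms(a * dp, ctx, obj),
                 numeric(1))
    best <- which.min(Js)
    if (Js[best] < J) {
      fv <- alphas[best] * p
      dv <- alphas[best] * dp
      J <- Js[best]
      trace <- c(trace, J)
    }
  }
  gprev <- NULL; fprev <- NULL
  alpha <- 1
  stall <- 0L
  alpha_ok <- if (max(abs(gf)) > 0) max(fv) / max(abs(gf)) + 1e-12 else 1
  for (it in seq_len(obj$max_iter)) {
    tg <- fmo_objective_terms(dv, ctx, obj, gradient = TRUE)
    gf <- unlist(adjoint_dose_operator(op, tg$g))
    if (!all(is.finite(gf)))
      stop("non-finite FMO gradient; aborting (check objective weights)", call. = FALSE)
    if (!is.null(fprev)) {
      sdiff <- fv - fprev; ydiff <- gf - gprev
      sy <- sum(sdiff * ydiff)
      alpha <- if (is.finite(sy) && sy > 1e-300) sum(sdiff^2) / sy else alpha
      if (!is.finite(alpha) || alpha <= 0) alpha <- 1
    } else if (max(abs(gf)) > 0) {
      alpha <- max(fv) / max(abs(gf)) + 1e-12
    }
    fprev <- fv; gprev <- gf
    backtrack <- function(a0) {
      a <- a0
      for (bt in 1:30) {
        ftry <- pmax(fv - a * gf, 0)
        dtry <- apply_dose_operator(op, split_f(ftry))
        Jtry <- fmo_objective_terms(dtry, ctx, obj)
        if (!is.finite(Jtry)) stop("non-finite FMO objective; aborting", call. = FALSE)
        if (Jtry < J) return(list(f = ftry, d = dtry, J = Jtry, a = a))
        a <- a / 2
      }
      NULL
    }
    # Barzilai-Borwein step with monotone backtracking; if the BB step is so
    # far off-scale that halving cannot rescue it, retry from the last
    # accepted step before declaring convergence (the problem is convex)
    res_bt <- backtrack(alpha)
    if (is.null(res_bt) && alpha_ok < alpha / 2^30) res_bt <- backtrack(alpha_ok)
    if (is.null(res_bt)) { status <- "converged"; break }
    alpha_ok <- res_bt$a
    ftry <- res_bt$f; dtry <- res_bt$d; Jtry <- res_bt$J
    rel <- (J - Jtry) / max(J, .Machine$double.eps)
    fv <- ftry; dv <- dtry; J <- Jtry
    trace <- c(trace, J)
    # BB progress is oscillatory: stop only when the relative decrease stays
    # below tol for several consecutive iterations
    stall <- if (rel < obj$tol) stall + 1L else 0L
    if (stall >= 5L) { status <- "converged"; break }
  }
  fmaps <- lapply(seq_len(op$n_beams), function(b) {
    g <- op$geoms[[b]]
    fluence_map(split_f(fv)[[b]], g$pixel_mm, g$u0, g$v0, b)
  })
  list(fluences = fmaps, dose_vec = dv, objective_trace = trace,
       status = status, iterations = length(trace) - 1)
}

#' Objective-based planning optimization
#'
#' Solves the planning fluence-map optimization problem: minimize the
#' one-sided penalty objective of [objective_config()] over non-negative
#' beamlet intensities, through the linear FCBB dose operator, by spectral
#' projected gradient with Barzilai-Borwein steps and monotone backtracking.
#' The objective trace is non-increasing; fluences are non-negative at every
#' iterate; the solver is deterministic (zero-fluence initialization).
#'
#' @param case a `case_bundle`.
#' @param obj an `objective_config` with `reference = NULL`.
#' @param op optional precomputed [dose_operator()] (built at
#'   `beamlet_mm` otherwise).
#' @param beamlet_mm beamlet pixel size for optimization, default 5 mm.
#' @param step_mm ray-marching step for operator construction.
#' @return An `fmo_result`: `fluences` (list of `fluence_map`), `dose`
#'   (`volume_grid`, Gy), `objective_trace`, `status`
#'   (`"converged"`/`"max_iter"`), `iterations`.
#' @export
optimize_planning <- function(case, obj = objective_config(), op = NULL,
                              beamlet_mm = 5, step_mm = NULL) {
  if (!is.null(obj$reference))
    stop("planning mode expects no reference; use optimize_reference()", call. = FALSE)
  if (is.null(op)) op <- dose_operator(case, case$model, pixel_mm = beamlet_mm,
                                       step_mm = step_mm)
  ctx <- fmo_context(case, op, obj)
  res <- solve_fmo(op, ctx, obj)
  res$dose <- dose_vec_to_volume(op, res$dose_vec)
  res$dose_vec <- NULL
  class(res) <- "fmo_result"
  res
}

#' Reference-guided optimization (feasibility probe)
#'
#' Turns a reference dose — typically a network prediction — into a
#' physically achievable one: the returned dose is produced by non-negative
#' beamlet intensities through the FCBB engine, optimized so underdose below
#' the reference (in targets), overdose above it (everywhere) and a small
#' symmetric misfit (everywhere in the body) are minimized. If the reference
#' was itself generated by feasible fluences, it is recovered (objective 0);
#' a physically impossible reference yields a deviating dose, visible as a
#' reduced gamma passing rate against the reference.
#'
#' @param case a `case_bundle`.
#' @param reference_dose reference `volume_grid` (Gy) on the case grid.
#' @param obj an `objective_config` (its `reference` field is overwritten).
#' @param op,beamlet_mm,step_mm as in [optimize_planning()].
#' @return An `fmo_result` (see [optimize_planning()]).
#' @export
optimize_reference <- function(case, reference_dose, obj = objective_config(),
                               op = NULL, beamlet_mm = 5, step_mm = NULL) {
  obj$reference <- reference_dose
  if (is.null(op)) op <- dose_operator(case, case$model, pixel_mm = beamlet_mm,
                                       step_mm = step_mm)
  ctx <- fmo_context(case, op, obj)
  res <- solve_fmo(op, ctx, obj)
  res$dose <- dose_vec_to_volume(op, res$dose_vec)
  res$dose_vec <- NULL
  class(res) <- "fmo_result"
  res
}

#' @export
print.fmo_result <- function(x, ...) {
  cat(sprintf("fmo_result: %d beams, %d iterations, status '%s', objective %.4g -> %.4g\n",
              length(x$fluences), x$iterations, x$status,
              x$objective_trace[1], utils::tail(x$objective_trace, 1)))
  invisible(x)
}
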