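#' Rigid pre-registration and target nipple displacement
#'
#' Least-squares rigid alignment (rotation + translation, no scaling) of the
#' chest-wall landmark sets; the target nipple displacement Vmax is the
#' distance between the prone nipple and the rigidly mapped supine nipple.
#' Any whole-body rigid motion between the two acquisitions is thereby
#' absorbed, leaving Vmax to measure the gravity-induced deformation alone.
#'
#' @param nipple_supine,nipple_prone nipple landmarks, world mm
#' @param chest_supine,chest_prone at least 3 paired non-collinear chest-wall
#'   landmarks (N x 3 mm)
#' @return list with `transform` (rigid `breastfem_affine`, supine -> prone
#'   frame) and `Vmax` (mm)
#' @export
rigid_preregister <- function(nipple_supine, nipple_prone,
                              chest_supine, chest_prone) {
  Tr <- affine_from_landmarks(chest_supine, chest_prone, kind = "rigid")
  mapped <- drop(apply_affine(Tr, rbind(as.numeric(nipple_supine))))
  list(transform = Tr,
       Vmax = sqrt(sum((as.numeric(nipple_prone) - mapped)^2)))
}

#' Grid-search settings for the material optimization
#' @param coarse_n log-spaced points of the coarse pass
#' @param refine_n points per refinement round
#' @param refine_rounds refinement rounds around the incumbent
#' @export
grid_config <- function(coarse_n = 12, refine_n = 5, refine_rounds = 2) {
  list(coarse_n = coarse_n, refine_n = refine_n, refine_rounds = refine_rounds)
}

#' Patient-specific stiffness estimation by grid search
#'
#' Multi-resolution grid search over the adipose Young's modulus E in
#' (lb, ub): a log-spaced coarse pass followed by refinement rounds around
#' the incumbent. The fibro-glandular modulus is slaved to
#' `stiffness_ratio * E` at every trial; each trial runs the full
#' supine-to-prone simulation and evaluates `|Vmax - Vn|`, the mismatch
#' between the target and the simulated nipple displacement. The search
#' stops as soon as a trial reaches `tol` (default 1 mm) or the grid
#' resolution is exhausted. Trials whose solve fails are recorded and
#' skipped; grid points tying within 0.01 mm resolve to the smallest E.
#'
#' @param mesh supine `breastfem_mesh` with skin layer and nipple node
#' @param Vmax target nipple displacement from [rigid_preregister()], mm
#' @param lb,ub open search bounds on E, kPa (0.5 and 500)
#' @param stiffness_ratio fibro-glandular / adipose ratio held fixed
#' @param tol stopping tolerance on `|Vmax - Vn|`, mm
#' @param config a [fem_config()]
#' @param grid a [grid_config()]
#' @param materials_template [material_params()] supplying densities, skin
#'   modulus and Poisson's ratio for the trials
#' @return list with `materials` (best-fit [material_params()]), and `state`:
#'   `E`, `Vn`, `Vmax`, `objective`, `converged` (objective <= tol),
#'   `history` (one row per trial: E, Vn, objective, solver success),
#'   `trials`, `wall_time_s`
#' @export
grid_search_optimize <- function(mesh, Vmax, lb = 0.5, ub = 500,
                                 stiffness_ratio = 7.5, tol = 1.0,
                                 config = fem_config(), grid = grid_config(),
                                 materials_template = material_params()) {
  stopifnot(Vmax >= 0, lb > 0, ub > lb)
  mesh <- fem_prepare(mesh)
  t0 <- proc.time()[["elapsed"]]
  hist_E <- hist_Vn <- hist_obj <- numeric(0)
  hist_ok <- logical(0)

  warm <- new.env(parent = emptyenv())
  trial <- function(E) {
    mat <- material_params(
      E_adipose = E, nu = materials_template$adipose$nu,
      E_skin = materials_template$skin$E,
      rho_adipose = materials_template$adipose$rho,
      rho_gland = materials_template$gland$rho,
      rho_skin = materials_template$skin$rho,
      stiffness_ratio = stiffness_ratio)
    Vn <- tryCatch(nipple_displacement(
      simulate_supine_to_prone(mesh, mat, config, warm = warm)),
      error = function(e) NA_real_)
    hist_E <<- c(hist_E, E)
    hist_Vn <<- c(hist_Vn, Vn)
    hist_obj <<- c(hist_obj, abs(Vmax - Vn))
    hist_ok <<- c(hist_ok, !is.na(Vn))
    if (is.na(Vn)) Inf else abs(Vmax - Vn)
  }

  run_pass <- function(Es) {
    for (E in Es) {
      obj <- trial(E)
      if (obj <= tol) return(TRUE)
    }
    FALSE
  }

  # the search starts from the initial (default-table) model, mirroring the
  # optimization loop that simulates the initial properties first and only
  # then updates them; the coarse grid sweeps the admissible range upward
  lgl <- log(lb); lgu <- log(ub)
  step <- (lgu - lgl) / grid$coarse_n
  coarse <- exp(lgl + (seq_len(grid$coarse_n) - 0.5) * step)
  E_init <- materials_template$adipose$E
  first <- if (E_init > lb && E_init < ub) E_init else numeric(0)
  done <- run_pass(c(first, coarse))
  if (!done) {
    for (r in seq_len(grid$refine_rounds)) {
      if (!any(hist_ok)) break
      best <- hist_E[hist_ok][which.min(hist_obj[hist_ok])]
      newE <- exp(seq(log(best) - step, log(best) + step,
                      length.out = grid$refine_n + 2))
      newE <- newE[newE > lb & newE < ub]
      newE <- setdiff(round(newE, 10), round(hist_E, 10))
      step <- 2 * step / (grid$refine_n + 1)
      if (run_pass(sort(newE))) break
    }
  }
  if (!any(hist_ok))
    stop("no grid trial converged; failed E values (kPa): ",
         paste(signif(hist_E, 4), collapse = ", "))

  ok <- which(hist_ok)
  omin <- min(hist_obj[ok])
  tied <- ok[hist_obj[ok] <= omin + 0.01]   # solver-noise ties -> smallest E
  ibest <- tied[which.min(hist_E[tied])]
  # quasi-convexity diagnostic on the sampled objective
  oE <- order(hist_E[ok])
  ob <- hist_obj[ok][oE]
  sgn <- sign(diff(ob))
  sgn <- sgn[sgn != 0]
  if (length(sgn) && any(diff(sgn) < 0))
    warning("objective is not quasi-convex in E on the sampled grid")

  best_mat <- material_params(
    E_adipose = hist_E[ibest], nu = materials_template$adipose$nu,
    E_skin = materials_template$skin$E,
    rho_adipose = materials_template$adipose$rho,
    rho_gland = materials_template$gland$rho,
    rho_skin = materials_template$skin$rho,
    stiffness_ratio = stiffness_ratio)
  list(materials = best_mat,
       state = list(E = hist_E[ibest], Vn = hist_Vn[ibest], Vmax = Vmax,
                    objective = hist_obj[ibest],
                    converged = hist_obj[ibest] <= tol,
                    lb = lb, ub = ub, tol = tol,
                    history = data.frame(E = hist_E, Vn = hist_Vn,
                                         objective = hist_obj, ok = hist_ok),
                    trials = length(hist_E),
                    wall_time_s = proc.time()[["elapsed"]] - t0))
}
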