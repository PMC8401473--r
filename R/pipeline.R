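#' Default pipeline configuration
#'
#' One reproducible end-to-end run on a phantom case: generation, fuzzy
#' c-means segmentation, meshing, forward simulation, material optimization,
#' registration and TRE evaluation. A single global `seed` fans out to
#' per-stage seeds by fixed offsets. The configuration round-trips
#' losslessly through YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param seed global integer seed
#' @param outdir output directory
#' @param stages character subset of
#'   `c("phantom", "segment", "mesh", "solve", "optimize", "register",
#'   "evaluate")`
#' @param phantom named list of [phantom_spec()] overrides
#' @param element_size FE element size, mm
#' @param lb,ub,stiffness_ratio,tol material-search settings (kPa, kPa, -, mm)
#' @param fem named list of [fem_config()] overrides
#' @return list of class `breastfem_run_config`
#' @export
run_config <- function(seed = 1L, outdir = tempfile("breastfem_run_"),
                       stages = c("phantom", "segment", "mesh", "solve",
                                  "optimize", "register", "evaluate"),
                       phantom = list(), element_size = 4,
                       lb = 0.5, ub = 500, stiffness_ratio = 7.5, tol = 1.0,
                       fem = list()) {
  structure(list(seed = as.integer(seed), outdir = outdir, stages = stages,
                 phantom = phantom, element_size = element_size, lb = lb,
                 ub = ub, stiffness_ratio = stiffness_ratio, tol = tol,
                 fem = fem),
            class = "breastfem_run_config")
}

#' @rdname run_config
#' @param config a `breastfem_run_config`
#' @param path YAML file path
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cf <- yaml::read_yaml(path)
  do.call(run_config, cf)
}

#' Run the registration pipeline end to end
#'
#' Executes the enabled stages in order on a synthetic phantom case and
#' writes a JSON manifest (parameters, seeds, per-file MD5 checksums,
#' per-stage timings, package version) sufficient to re-run bit-identically.
#'
#' @param config a [run_config()]
#' @return the manifest (invisibly also written to
#'   `file.path(config$outdir, "manifest.json")`)
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "breastfem_run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  fem_cf <- do.call(fem_config, config$fem)
  manifest <- list(package_version = as.character(utils::packageVersion("breastfem")),
                   seed = config$seed, parameters = unclass(config),
                   stages = list())
  t_all <- proc.time()[["elapsed"]]
  case <- NULL; fcm <- NULL; mesh <- NULL; sol <- NULL; opt <- NULL
  report <- NULL

  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    fun()
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }

  for (st in config$stages) {
    switch(st,
      phantom = stage("phantom", function() {
        spec <- do.call(phantom_spec,
                        utils::modifyList(list(seed = config$seed + 101L),
                                          config$phantom))
        case <<- make_supine_phantom(spec)
        case <<- make_prone_ground_truth(case, config = fem_cf,
                                         element_size = config$element_size)
        write_phantom(case, file.path(config$outdir, "phantom"))
      }),
      segment = stage("segment", function() {
        fcm <<- fcm_segment(case$ct_supine, case$labels_supine)
        write_volume(fcm$labels, file.path(config$outdir, "fcm_labels.nii.gz"))
        jsonlite::write_json(
          list(centroids = fcm$centroids, iterations = fcm$iterations,
               final_shift = fcm$final_shift, converged = fcm$converged),
          file.path(config$outdir, "fcm_summary.json"),
          auto_unbox = TRUE, digits = NA)
      }),
      mesh = stage("mesh", function() {
        mesh <<- voxel_to_hex_mesh(case$labels_supine, config$element_size,
                                   nipple = case$nipple_supine)
        mesh <<- add_skin_layer(mesh, fem_cf$skin_thickness)
        write_mesh_vtk(mesh, file.path(config$outdir, "mesh.vtk"))
      }),
      solve = stage("solve", function() {
        sol <<- simulate_supine_to_prone(mesh, case$materials_truth, fem_cf)
        write_mesh_vtk(mesh, file.path(config$outdir, "solution.vtk"),
                       point_data = list(displacement = sol$u))
      }),
      optimize = stage("optimize", function() {
        pre <- rigid_preregister(case$nipple_supine, case$nipple_prone,
                                 case$chest_wall_landmarks,
                                 case$chest_wall_landmarks_prone)
        opt <<- grid_search_optimize(mesh, pre$Vmax, lb = config$lb,
                                     ub = config$ub,
                                     stiffness_ratio = config$stiffness_ratio,
                                     tol = config$tol, config = fem_cf)
        jsonlite::write_json(
          opt$state[c("E", "Vn", "Vmax", "objective", "converged", "trials",
                      "wall_time_s")],
          file.path(config$outdir, "optimization.json"),
          auto_unbox = TRUE, digits = NA)
        utils::write.csv(opt$state$history,
                         file.path(config$outdir, "optimization_history.csv"),
                         row.names = FALSE)
      }),
      register = stage("register", function() {
        mats <- if (!is.null(opt)) opt$materials else case$materials_truth
        report <<- evaluate_case(case, element_size = config$element_size,
                                 config = fem_cf, materials = mats)
        jsonlite::write_json(
          list(tre = report$tre, tre_similarity = report$tre_similarity,
               C_MR = report$C_MR, C_PET = report$C_PET,
               Vmax = report$Vmax, Vn = report$Vn,
               E_adipose = report$E_adipose),
          file.path(config$outdir, "registration.json"),
          auto_unbox = TRUE, digits = NA)
      }),
      evaluate = stage("evaluate", function() {
        if (is.null(report)) stop("evaluate stage needs the register stage")
        feats <- report$features
        utils::write.csv(
          data.frame(case = "phantom", tre = report$tre,
                     tre_similarity = report$tre_similarity,
                     as.data.frame(feats)),
          file.path(config$outdir, "report.csv"), row.names = FALSE)
      }),
      stop("unknown stage: ", st))
  }

  files <- setdiff(list.files(config$outdir, recursive = TRUE,
                              full.names = TRUE),
                   file.path(config$outdir, "manifest.json"))
  sums <- tools::md5sum(files)
  manifest$checksums <- as.list(stats::setNames(unname(sums),
                                                basename(names(sums))))
  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
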