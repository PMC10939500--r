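#' Default end-to-end run configuration
#'
#' Stage parameters follow the study design where that design states them:
#' PC variance threshold 0.96 and 10,000 permutations.  The remaining knobs
#' (registration schedule, GPA tolerance) are the package defaults.
#'
#' @param ... named overrides of the defaults.
#' @return a named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    manifest = NULL,            # path to a cohort manifest CSV, or NULL
    template = NULL,            # template OBJ path (with manifest input)
    template_landmarks = NULL,  # template landmark CSV (with manifest input)
    genotype_levels = NULL,     # c(reference, variant)
    simulate = NULL,            # list of cohort_spec() arguments (+ resolution)
    register = NULL,            # force/skip registration; NULL = auto
    registration = list(iterations = 30L, sigma_init = 8, sigma_final = 0.8,
                        step = 0.5),
    gpa_tol = 1e-10,
    variance_threshold = 0.96,
    n_permutations = 10000L
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      cm_stop("yaml package required for YAML configs", "invalid_parameter")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

validate_config <- function(cfg) {
  cfg$seed <- check_count(cfg$seed, "seed")
  cfg$n_permutations <- check_count(cfg$n_permutations, "n_permutations",
                                    min = 1L)
  cfg$variance_threshold <- check_number(cfg$variance_threshold,
                                         "variance_threshold")
  if (cfg$variance_threshold <= 0 || cfg$variance_threshold > 1) {
    cm_stop("variance_threshold must be in (0, 1]", "invalid_parameter")
  }
  if (is.null(cfg$simulate) && is.null(cfg$manifest)) {
    cm_stop("config needs either a 'simulate' block or a 'manifest' path",
            "invalid_parameter")
  }
  cfg
}

file_hashes <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) return(list())
  h <- tools::md5sum(paths)
  as.list(stats::setNames(unname(h), basename(names(h))))
}

#' Run the full genotype-to-shape pipeline
#'
#' Orchestrates synthesize/ingest, registration (skipped when the input is a
#' synthetic cohort that is already corresponded), generalized Procrustes
#' alignment, PCA + permutation effect testing, and report writing.  All
#' stochastic stages draw from named substreams of `config$seed`, so
#' rerunning with an identical config reproduces every numeric output.
#'
#' @param config a list (see [default_config()]) or path to a JSON/YAML file.
#' @return object of class `cm_report`: the `cm_effect`, the aligned cohort,
#'   diagnostics, and (when `out_dir` is set) paths of the written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- validate_config(utils::modifyList(default_config(), config))

  stage <- "input"
  result <- tryCatch({
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      resolution <- sim$resolution %||% 16L
      sim$resolution <- NULL
      template <- make_template(resolution)
      if (!is.null(sim$effect_patch_seed_vertex)) {
        sim$effect_patch <- vertex_patch(template, sim$effect_patch_seed_vertex,
                                         sim$effect_patch_rings %||% 2L)
        sim$effect_patch_seed_vertex <- NULL
        sim$effect_patch_rings <- NULL
      }
      sim$seed <- sim$seed %||% cfg$seed
      cohort <- generate_cohort(template, do.call(cohort_spec, sim))
      input_hashes <- list()
      must_register <- cfg$register %||% cohort$spec$decorrespond
      stage <- "registration"
      corresponded <- if (must_register) {
        do.call(build_cohort, c(list(cohort), cfg$registration))
      } else {
        as_corresponded(cohort)
      }
    } else {
      manifest <- read_manifest(cfg$manifest,
                                genotype_levels = cfg$genotype_levels)
      template <- read_obj(cfg$template)
      tlm <- read_landmarks_csv(cfg$template_landmarks)
      input_hashes <- file_hashes(c(cfg$manifest, cfg$template,
                                    cfg$template_landmarks, manifest$mesh_path))
      stage <- "registration"
      corresponded <- do.call(build_cohort,
                              c(list(manifest, template = template,
                                     template_landmarks = tlm),
                                cfg$registration))
    }

    stage <- "gpa"
    aligned <- gpa(corresponded, tol = cfg$gpa_tol)

    stage <- "effect"
    effect <- fit_genotype_effect(aligned,
                                  genotype_levels = cfg$genotype_levels,
                                  threshold = cfg$variance_threshold,
                                  n_permutations = cfg$n_permutations,
                                  seed = cfg$seed)

    stage <- "report"
    report <- list(
      package_version = as.character(utils::packageVersion("craniomorph")),
      seed = cfg$seed,
      n_specimens = dim(aligned$shapes)[1L],
      n_vertices = dim(aligned$shapes)[2L],
      retained_m = effect$retained_m,
      variance_threshold = cfg$variance_threshold,
      n_permutations = effect$n_permutations,
      global_partial_R2 = effect$global_partial_R2,
      global_p = effect$global_p,
      gpa_iterations = aligned$iterations,
      input_hashes = input_hashes,
      config = cfg[c("variance_threshold", "n_permutations", "gpa_tol",
                     "registration")]
    )
    paths <- NULL
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      mean_mesh <- cm_mesh(aligned$mean_shape, template$faces)
      paths <- c(report = file.path(cfg$out_dir, "report.json"),
                 write_vertex_field(mean_mesh, effect$per_vertex_R2,
                                    file.path(cfg$out_dir, "per_vertex_R2")),
                 write_vertex_field(mean_mesh, effect$normal_displacement,
                                    file.path(cfg$out_dir,
                                              "normal_displacement")))
    }
    structure(list(report = report, effect = effect, aligned = aligned,
                   diagnostics = corresponded$diagnostics, paths = paths),
              class = "cm_report")
  }, craniomorph_error = function(e) {
    cm_stop(sprintf("pipeline failed at stage '%s': %s", stage,
                    conditionMessage(e)), "pipeline_error")
  })
  result
}

#' @export
print.cm_report <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<cm_report> N = %d, V = %d | global partial R2 = %.4f,",
                     " p = %.4g (%d perms, %d PCs)\n"),
              r$n_specimens, r$n_vertices, r$global_partial_R2, r$global_p,
              r$n_permutations, r$retained_m))
  invisible(x)
}
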