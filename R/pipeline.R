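#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()].  Exactly one input source
#' must be given: a `population_spec` (synthetic data), a list of
#' `landmark_config` objects, or a landmark file path.
#'
#' @param population a `population_spec`, or NULL.
#' @param configs list of `landmark_config` objects, or NULL.
#' @param input_path landmark file (with `input_dialect`), or NULL.
#' @param input_dialect dialect for `input_path` (see [read_landmarks()]).
#' @param template `template_definition`; required for sliding, fragment
#'   extraction, and synthetic generation (defaults to
#'   [build_ideal_femur()] when a population is generated).
#' @param mirror mirror right-side configurations to left form before
#'   analysis (default TRUE).
#' @param relax_template_iters,relax_consensus_iters sliding iteration
#'   counts (defaults 5 and 2; 0 disables a stage).
#' @param axes PC axes scanned for dimorphism.
#' @param G_max mixture component search limit.
#' @param alpha allometry significance threshold.
#' @param fragments fragment portions to analyse alongside the complete
#'   bones (default `c("proximal", "distal")`; NULL disables).
#' @param seed seed recorded in the report (the synthetic generator uses
#'   its own `population_spec` seed).
#' @param out_dir optional output directory for the JSON/CSV report bundle.
#' @return object of class `run_config`.
#' @export
run_config <- function(population = NULL, configs = NULL, input_path = NULL,
                       input_dialect = "table", template = NULL,
                       mirror = TRUE,
                       relax_template_iters = 5L,
                       relax_consensus_iters = 2L,
                       axes = 1:5, G_max = 9L, alpha = 0.05,
                       fragments = c("proximal", "distal"),
                       seed = 0L, out_dir = NULL) {
  n_src <- (!is.null(population)) + (!is.null(configs)) +
    (!is.null(input_path))
  if (n_src != 1L)
    stop("exactly one of population, configs, input_path must be given")
  if (relax_template_iters < 0 || relax_consensus_iters < 0)
    stop("relaxation iteration counts must be non-negative")
  if (!is.null(population)) stopifnot(inherits(population, "population_spec"))
  structure(list(population = population, configs = configs,
                 input_path = input_path, input_dialect = input_dialect,
                 template = template, mirror = isTRUE(mirror),
                 relax_template_iters = as.integer(relax_template_iters),
                 relax_consensus_iters = as.integer(relax_consensus_iters),
                 axes = as.integer(axes), G_max = as.integer(G_max),
                 alpha = alpha, fragments = fragments,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

pipeline_log <- function(...) message("[osteomorph] ", sprintf(...))

## Stage: load or generate the input configurations.
stage_load <- function(config) {
  if (!is.null(config$population)) {
    template <- config$template
    if (is.null(template)) template <- build_ideal_femur(with_mesh = FALSE)
    pop <- generate_population(config$population, template)
    list(configs = pop$specimens, meshes = pop$meshes,
         template = template, truth = pop$truth)
  } else if (!is.null(config$configs)) {
    list(configs = config$configs, meshes = NULL,
         template = config$template, truth = NULL)
  } else {
    list(configs = read_landmarks(config$input_path, config$input_dialect,
                                  template = config$template),
         meshes = NULL, template = config$template, truth = NULL)
  }
}

## Stage: mirror right-side configurations to left form.
stage_mirror <- function(configs) {
  lapply(configs, function(cc)
    if (cc$side == "right") mirror_config(cc) else cc)
}

## Stage: relaxation protocol (project if meshes, 5x template, 2x consensus).
stage_relax <- function(configs, template, meshes, n_template, n_consensus) {
  trace <- list()
  if (!is.null(meshes) && length(meshes) && !is.null(template$template_mesh)) {
    pipeline_log("projecting template surface patch onto %d meshes",
                 length(configs))
    fixed_idx <- which(template$template_config$classes != "surface_semi")
    configs <- lapply(seq_along(configs), function(i) {
      fx <- configs[[i]]
      fx$points <- fx$points[fixed_idx, , drop = FALSE]
      fx$classes <- fx$classes[fixed_idx]; fx$group <- fx$group[fixed_idx]
      project_patch(template, meshes[[i]], fx)
    })
  }
  if (n_template > 0) {
    pipeline_log("relaxing to template (%d iterations)", n_template)
    sl <- relax_to_template(configs, template, n_iter = n_template,
                            meshes = meshes)
    configs <- sl$configs
    trace$template <- sl$bending_energy_trace
  }
  if (n_consensus > 0) {
    pipeline_log("relaxing to consensus (%d iterations)", n_consensus)
    sl <- relax_to_consensus(configs, template, n_iter = n_consensus,
                             meshes = meshes)
    configs <- sl$configs
    trace$consensus <- sl$bending_energy_trace
  }
  list(configs = configs, trace = trace)
}

## Stage: superimposition + ordination + dimorphism scan.
stage_analyse <- function(configs, axes, G_max, alpha) {
  g <- gpa(configs)
  p <- shape_pca(g)
  scan <- dimorphism_scan(p, g, axes = axes, G_max = G_max, alpha = alpha)
  list(gpa = g, pca = p, scan = scan)
}

#' Run the full dimorphism-detection pipeline
#'
#' Ordered stages: load or generate configurations; mirror right-side
#' elements (optional); project the template surface patch onto specimen
#' meshes (when meshes are present); relax semilandmarks to the template
#' (default 5 iterations) and to the Procrustes consensus (default 2);
#' generalized Procrustes analysis; PCA; per-axis Gaussian mixture /
#' allometry scan; cluster mean shapes along any dimorphic axis; fragment
#' analyses (proximal/distal subsets re-analysed end-to-end) with
#' cluster-consistency counts against the complete-bone clustering.  Each
#' stage is an exported function, so any prefix of the chain can be run by
#' hand; `run_pipeline` only orders them.
#'
#' @param config a `run_config`.
#' @return object of class `pipeline_report`; see Details.  When
#'   `config$out_dir` is set, a JSON summary and CSV tables are written
#'   there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- stage_load(config)
  configs <- inp$configs
  pipeline_log("loaded %d configurations", length(configs))
  if (config$mirror) configs <- stage_mirror(configs)
  template <- inp$template
  if (!is.null(template) &&
      (config$relax_template_iters > 0 || config$relax_consensus_iters > 0)) {
    rx <- stage_relax(configs, template, inp$meshes,
                      config$relax_template_iters,
                      config$relax_consensus_iters)
    configs <- rx$configs
    relax_trace <- rx$trace
  } else relax_trace <- NULL

  main <- stage_analyse(configs, config$axes, config$G_max, config$alpha)
  flagged <- main$scan$summary$axis[main$scan$summary$dimorphic]
  pipeline_log("complete-bone scan: %s",
               if (length(flagged))
                 paste0("dimorphic axis PC", paste(flagged, collapse = ", PC"))
               else "no dimorphic axis")

  shapes <- NULL
  if (length(flagged)) {
    ax <- flagged[1]
    shapes <- cluster_mean_shapes(main$pca,
                                  main$scan$axes[[paste0("PC", ax)]]$gmm,
                                  axis = ax, template = template)
  }

  fragments <- list()
  if (!is.null(template) && length(config$fragments) &&
      length(template$fragments)) {
    for (portion in intersect(config$fragments, names(template$fragments))) {
      fragged <- lapply(configs, extract_fragment, portion = portion,
                        template = template)
      fr <- stage_analyse(fragged, config$axes, config$G_max, config$alpha)
      fr_flag <- fr$scan$summary$axis[fr$scan$summary$dimorphic]
      consistency <- NULL
      if (length(flagged) && length(fr_flag)) {
        a_main <- main$scan$axes[[paste0("PC", flagged[1])]]$gmm$assignments
        names(a_main) <- main$pca$specimen_ids
        a_frag <- fr$scan$axes[[paste0("PC", fr_flag[1])]]$gmm$assignments
        names(a_frag) <- fr$pca$specimen_ids
        consistency <- cluster_consistency(a_main, a_frag)
      }
      fragments[[portion]] <- list(gpa = fr$gpa, pca = fr$pca,
                                   scan = fr$scan,
                                   consistency = consistency)
      pipeline_log("%s fragment scan: %s", portion,
                   if (length(fr_flag))
                     paste0("dimorphic axis PC",
                            paste(fr_flag, collapse = ", PC"))
                   else "no dimorphic axis")
    }
  }

  report <- structure(list(config = config, truth = inp$truth,
                           relax_trace = relax_trace,
                           gpa = main$gpa, pca = main$pca,
                           scan = main$scan,
                           dimorphic_axes = flagged,
                           cluster_shapes = shapes,
                           fragments = fragments),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$scan)
  for (portion in names(x$fragments)) {
    cons <- x$fragments[[portion]]$consistency
    if (!is.null(cons))
      cat(sprintf("  %s fragment: %d/%d specimens consistently clustered\n",
                  portion, cons$n_consistent, cons$n_shared))
  }
  invisible(x)
}

#' Write a pipeline report bundle (JSON summary + CSV tables)
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return the JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(specimen_id = report$pca$specimen_ids,
                              log_cs = report$gpa$log_centroid_sizes,
                              report$pca$scores[, seq_len(
                                min(10, ncol(report$pca$scores))),
                                drop = FALSE]),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(report$scan$summary, file.path(dir, "scan_summary.csv"),
                   row.names = TRUE)
  for (nm in names(report$scan$axes)) {
    g <- report$scan$axes[[nm]]$gmm
    utils::write.csv(as.data.frame(g$bic_table),
                     file.path(dir, paste0("bic_", nm, ".csv")))
  }
  cfg <- report$config
  summary <- list(
    config = list(mirror = cfg$mirror,
                  relax_template_iters = cfg$relax_template_iters,
                  relax_consensus_iters = cfg$relax_consensus_iters,
                  axes = cfg$axes, G_max = cfg$G_max, alpha = cfg$alpha,
                  seed = cfg$seed,
                  population = if (!is.null(cfg$population))
                    unclass(cfg$population)),
    n_specimens = length(report$gpa$aligned),
    variance_fraction = report$pca$variance_fraction[
      seq_len(min(10, length(report$pca$variance_fraction)))],
    scan = report$scan$summary,
    dimorphic_axes = report$dimorphic_axes,
    fragments = lapply(report$fragments, function(fr)
      list(scan = fr$scan$summary,
           consistency = if (!is.null(fr$consistency))
             fr$consistency[c("n_shared", "n_consistent", "agreement")])))
  path <- file.path(dir, "report.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
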