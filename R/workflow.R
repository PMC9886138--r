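#' Workflow configuration
#'
#' A single serializable document describing a full run: which stages to
#' execute, the global seed, the output directory, and per-stage settings.
#' Unknown keys are rejected so that config typos fail before any work is
#' done.
#'
#' @param stages character vector among `"generate"`, `"extract"`,
#'   `"align"`, `"optimize"`, `"analyze"` (order fixed by the pipeline).
#' @param seed global seed; stage seeds derive from it.
#' @param out_dir output directory.
#' @param generate list of [peanut_params()] overrides.
#' @param extract list of [extraction_config()] overrides.
#' @param align list with `reference_domain` (default `"A_r"`).
#' @param optimize list of [optimizer_config()] overrides.
#' @param analyze list with optional `n_modes` and
#'   [imbalance_experiment()] overrides under `imbalance` (or
#'   `imbalance = FALSE` to skip it).
#' @param log_level `"info"` or `"quiet"`.
#' @return a list of class `run_config`.
#' @export
run_config <- function(stages = c("generate", "extract", "align", "optimize",
                                  "analyze"),
                       seed = 1L, out_dir = "shapeshared_out",
                       generate = list(), extract = list(), align = list(),
                       optimize = list(), analyze = list(),
                       log_level = "info") {
  known <- c("generate", "extract", "align", "optimize", "analyze")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0L)
      stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
  }
  check_keys(generate, names(formals(peanut_params)), "generate")
  check_keys(extract, names(formals(extraction_config)), "extract")
  check_keys(align, "reference_domain", "align")
  check_keys(optimize, names(formals(optimizer_config)), "optimize")
  check_keys(analyze, c("n_modes", "imbalance"), "analyze")
  structure(list(stages = stages, seed = as.integer(seed), out_dir = out_dir,
                 generate = generate, extract = extract, align = align,
                 optimize = optimize, analyze = analyze,
                 log_level = log_level),
            class = "run_config")
}

#' Read a workflow configuration from JSON
#'
#' @param path JSON file with the fields of [run_config()]; unknown
#'   top-level keys are rejected.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(run_config))
  bad <- setdiff(names(doc), allowed)
  if (length(bad) > 0L)
    stop("unknown key(s) in config: ", paste(bad, collapse = ", "))
  do.call(run_config, doc)
}

wf_log <- function(cfg, stage, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full shape-modeling workflow
#'
#' Executes the requested stages in pipeline order (generate the synthetic
#' peanut cohort, extract shared boundaries, align, optimize particles,
#' analyze), writing geometry as PLY, contours and particles as plain text,
#' numerics as CSV, and a manifest (config echo, seed, stage list, output
#' files with content hashes) that makes a run reproducible bit-for-bit
#' under a fixed seed.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly; also written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages_done <- character(0)
  files <- character(0)
  emit <- function(path) files <<- c(files, path)

  run_stage <- function(stage, fn) {
    wf_log(config, stage, "starting")
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    stages_done <<- c(stages_done, stage)
    wf_log(config, stage, "done")
  }

  cohort <- NULL
  extracted <- NULL
  system <- NULL

  if ("generate" %in% config$stages) {
    run_stage("generate", function() {
      gp <- do.call(peanut_params,
                    utils::modifyList(list(seed = config$seed),
                                      config$generate))
      cohort <<- generate_peanut_cohort(gp)
      gdir <- file.path(out, "meshes")
      dir.create(gdir, showWarnings = FALSE)
      for (s in cohort$samples) {
        for (dn in names(s$domains)) {
          p <- file.path(gdir, sprintf("%s_%s.ply", s$subject_id, dn))
          write_mesh(s$domains[[dn]], p)
          emit(p)
        }
      }
      lp <- file.path(out, "labels.csv")
      utils::write.csv(cohort$metadata[, c("subject_id", "group")], lp,
                       row.names = FALSE)
      emit(lp)
      mp <- file.path(out, "metadata.csv")
      utils::write.csv(cohort$metadata, mp, row.names = FALSE)
      emit(mp)
    })
  }

  if ("extract" %in% config$stages) {
    run_stage("extract", function() {
      if (is.null(cohort)) stop("extract requires the generate stage")
      ec <- do.call(extraction_config, config$extract)
      extracted <<- extract_cohort(cohort, ec)
      edir <- file.path(out, "extracted")
      dir.create(edir, showWarnings = FALSE)
      for (s in extracted) {
        for (dn in names(s$domains)) {
          d <- s$domains[[dn]]
          if (is_contour3d(d)) {
            p <- file.path(edir, sprintf("%s_%s.txt", s$subject_id, dn))
            write_contour(d, p)
          } else {
            p <- file.path(edir, sprintf("%s_%s.ply", s$subject_id, dn))
            write_mesh(d, p)
          }
          emit(p)
        }
      }
    })
  }

  if ("align" %in% config$stages) {
    run_stage("align", function() {
      if (is.null(extracted)) stop("align requires the extract stage")
      ref <- config$align$reference_domain
      if (is.null(ref)) ref <- "A_r"
      al <- align_cohort(extracted, ref)
      extracted <<- al$samples
      tf <- lapply(al$transforms, function(t)
        list(rotation = t$rotation, translation = t$translation))
      tp <- file.path(out, "transforms.json")
      jsonlite::write_json(tf, tp, auto_unbox = TRUE, digits = NA)
      emit(tp)
    })
  }

  if ("optimize" %in% config$stages) {
    run_stage("optimize", function() {
      if (is.null(extracted)) stop("optimize requires the extract stage")
      oc <- do.call(optimizer_config,
                    utils::modifyList(list(seed = config$seed),
                                      config$optimize))
      system <<- optimize_particles(extracted, oc)
      pdir <- file.path(out, "particles")
      dir.create(pdir, showWarnings = FALSE)
      for (n in seq_along(system$subjects)) {
        for (ki in seq_along(system$domains)) {
          P <- system$positions[[n]][[ki]]
          p <- file.path(pdir, sprintf("%s_%s.particles",
                                       system$subjects[n],
                                       system$domains[ki]))
          writeLines(paste(fmt_num(P[, 1]), fmt_num(P[, 2]),
                           fmt_num(P[, 3])), p)
          emit(p)
        }
      }
      el <- attr(system, "energy_log")
      ep <- file.path(out, "energy.csv")
      utils::write.csv(el, ep, row.names = FALSE)
      emit(ep)
    })
  }

  if ("analyze" %in% config$stages) {
    run_stage("analyze", function() {
      if (is.null(system)) stop("analyze requires the optimize stage")
      sm <- build_shape_matrix(system)
      pca <- pca_modes(sm, config$analyze$n_modes)
      evp <- file.path(out, "eigenvalues.csv")
      utils::write.csv(data.frame(mode = seq_along(pca$eigenvalues),
                                  eigenvalue = pca$eigenvalues,
                                  ratio = pca$ratios), evp,
                       row.names = FALSE)
      emit(evp)
      if (length(sm$domains) >= 2L) {
        ml <- mlca(sm)
        for (comp in c("between", "within")) {
          pc <- ml[[paste0("pca_", comp)]]
          p <- file.path(out, sprintf("mlca_%s.csv", comp))
          utils::write.csv(data.frame(mode = seq_along(pc$eigenvalues),
                                      eigenvalue = pc$eigenvalues,
                                      ratio = pc$ratios), p,
                           row.names = FALSE)
          emit(p)
        }
      }
      if (!is.null(sm$labels) && length(unique(sm$labels)) == 2L) {
        gd <- group_difference(sm)
        sp <- file.path(out, "scores.csv")
        utils::write.csv(data.frame(subject_id = rownames(sm$data),
                                    group = sm$labels, raw = gd$raw,
                                    score = gd$scores), sp,
                         row.names = FALSE)
        emit(sp)
        imb_cfg <- config$analyze$imbalance
        if (!isFALSE(imb_cfg) && !is.null(imb_cfg)) {
          oc <- do.call(optimizer_config,
                        utils::modifyList(list(seed = config$seed),
                                          config$optimize))
          imb <- do.call(imbalance_experiment,
                         c(list(samples = extracted, config = oc,
                                full_system = system,
                                seed = config$seed), imb_cfg))
          ip <- file.path(out, "imbalance_report.csv")
          utils::write.csv(data.frame(subject_id = names(imb$full_scores),
                                      imb$trial_scores,
                                      full = imb$full_scores, t = imb$t,
                                      p = imb$p), ip, row.names = FALSE)
          emit(ip)
        }
      }
    })
  }

  manifest <- list(
    stages = stages_done,
    seed = config$seed,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("shapeshared")),
    outputs = lapply(stats::setNames(files, basename(files)), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  wf_log(config, "workflow", sprintf("%d stage(s) complete, manifest at %s",
                                     length(stages_done), mp))
  invisible(manifest)
}
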