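#' Orchestrate the full sampling-scheme analysis
#'
#' Runs the pipeline stages in order, writing every artifact under
#' `out_dir` and recording a JSON manifest (config, seeds, file list).
#' Stages:
#' \describe{
#'   \item{simulate}{generate a synthetic study (genotypes, rasters, nodes,
#'     ground truth) — skipped when real input paths are supplied}
#'   \item{summarize}{population-genetic summary table}
#'   \item{distances}{individual and population distance matrices plus
#'     index correlations}
#'   \item{resistance}{predictor effective-resistance matrices and the VIF
#'     screen log}
#'   \item{fit}{deterministic PSS and PASS model selection under ML and
#'     REML}
#'   \item{schemes}{bootstrap ISS replicates and convergence analysis}
#'   \item{report}{collate the convergence curves and manifest}
#' }
#' Each stage reads its upstream artifacts from `out_dir`; running a stage
#' before its prerequisite fails with an error naming the missing stage.
#'
#' @param config configuration list, or path to a YAML file. Recognized
#'   keys: `synthetic` (arguments to [synthetic_config()]), `inputs`
#'   (`genotypes`, `format`, `nodes`, `rasters`: named list of
#'   `path`/`mode`/`class_value` entries), `min_pop_size`, `n_values`, `R`,
#'   `methods`, `delta_threshold`, `weight_threshold`, `count_threshold`,
#'   `agreement_threshold`, `models` (named list of predictor-name vectors;
#'   default all singles plus the uniform `distance` layer), `vif_threshold`,
#'   `connectivity`, `n_perm`.
#' @param out_dir output directory (created).
#' @param stages character vector of stages to run, in order.
#' @param seed master seed for every stochastic step.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = "ibrsamp_run",
                         stages = c("simulate", "summarize", "distances",
                                    "resistance", "fit", "schemes",
                                    "report"),
                         seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_defaults(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, config = cfg, files = character(0),
                   log = character(0))
  mpath <- file.path(out_dir, "manifest.json")

  note <- function(msg) {
    manifest$log <<- c(manifest$log, msg)
    message("[ibrsamp] ", msg)
  }
  emit <- function(relpath) {
    manifest$files <<- unique(c(manifest$files, relpath))
  }
  need <- function(relpath, stage) {
    p <- file.path(out_dir, relpath)
    if (!file.exists(p)) {
      stop(sprintf("missing artifact '%s': run the '%s' stage first",
                   relpath, stage), call. = FALSE)
    }
    p
  }

  for (stage in stages) {
    switch(stage,
      simulate = {
        if (!is.null(cfg$inputs)) {
          note("real inputs supplied; simulate stage skipped")
          next
        }
        scfg <- do.call(synthetic_config, cfg$synthetic)
        study <- simulate_ibr_study(scfg, seed = seed,
                                    connectivity = cfg$connectivity)
        write_genotypes(study$table, file.path(out_dir, "genotypes.csv"),
                        "csv")
        write_genotypes(study$table, file.path(out_dir, "genotypes.gen"),
                        "genepop")
        write_nodes(study$nodes, file.path(out_dir, "nodes.csv"))
        write_ascii_grid(study$landscape$cover,
                         file.path(out_dir, "cover.asc"))
        write_ascii_grid(study$landscape$slope,
                         file.path(out_dir, "slope.asc"))
        write_ascii_grid(study$landscape$solar,
                         file.path(out_dir, "solar.asc"))
        for (nm in names(study$predictors)) {
          write_dist_matrix(study$predictors[[nm]],
                            file.path(out_dir,
                                      sprintf("predictor_%s.csv", nm)))
          emit(sprintf("predictor_%s.csv", nm))
        }
        jsonlite::write_json(
          list(causal_class = study$truth$causal_class,
               R_true = unclass(study$truth$R_true),
               class_codes = as.list(study$landscape$class_codes)),
          file.path(out_dir, "ground_truth.json"),
          auto_unbox = TRUE, digits = NA
        )
        emit("genotypes.csv"); emit("genotypes.gen"); emit("nodes.csv")
        emit("cover.asc"); emit("slope.asc"); emit("solar.asc")
        emit("ground_truth.json")
        note(sprintf("simulated %d individuals at %d sites",
                     n_individuals(study$table), scfg$n_sites))
      },
      summarize = {
        tab <- pipeline_genotypes(cfg, out_dir, need)
        ps <- pop_summary(tab, min_pop_size = cfg$min_pop_size,
                          n_perm = cfg$n_perm, seed = seed)
        utils::write.csv(ps, file.path(out_dir, "pop_summary.csv"),
                         row.names = FALSE)
        emit("pop_summary.csv")
        note(sprintf("summarized %d population-level sites", nrow(ps)))
      },
      distances = {
        tab <- pipeline_genotypes(cfg, out_dir, need)
        cls <- classify_sites(tab, cfg$min_pop_size)
        pop_tab <- subset_genotypes(tab, sites = cls$population)
        dps <- population_dps(pop_tab)
        da <- population_distances(pop_tab, "nei_da",
                                   sites = rownames(dps))
        fst <- population_distances(pop_tab, "fst", sites = rownames(dps))
        write_dist_matrix(dps, file.path(out_dir, "dps_population.csv"))
        write_dist_matrix(da, file.path(out_dir, "nei_da_population.csv"))
        write_dist_matrix(fst, file.path(out_dir, "fst_population.csv"))
        dps_all <- population_dps(tab)
        write_dist_matrix(dps_all, file.path(out_dir, "dps_all_sites.csv"))
        cors <- list(
          dps_vs_nei_da_r2 = index_correlation(dps, da, "r2"),
          dps_vs_fst_r2 = index_correlation(dps, fst, "r2")
        )
        jsonlite::write_json(cors,
                             file.path(out_dir, "index_correlations.json"),
                             auto_unbox = TRUE, digits = NA)
        emit("dps_population.csv"); emit("nei_da_population.csv")
        emit("fst_population.csv"); emit("dps_all_sites.csv")
        emit("index_correlations.json")
        note(sprintf("index correlations R2: Da %.3f, Fst %.3f",
                     cors$dps_vs_nei_da_r2, cors$dps_vs_fst_r2))
      },
      resistance = {
        preds <- pipeline_predictors(cfg, out_dir, need)
        for (nm in names(preds)) {
          write_dist_matrix(preds[[nm]],
                            file.path(out_dir,
                                      sprintf("predictor_%s.csv", nm)))
          emit(sprintf("predictor_%s.csv", nm))
        }
        scr <- vif_screen(preds[setdiff(names(preds), "distance")],
                          threshold = cfg$vif_threshold)
        jsonlite::write_json(
          list(removed = scr$removed, vif = as.list(scr$vif)),
          file.path(out_dir, "vif_screen.json"),
          auto_unbox = TRUE, digits = NA
        )
        emit("vif_screen.json")
        note(sprintf("VIF screen removed: %s",
                     if (length(scr$removed)) {
                       paste(scr$removed, collapse = ", ")
                     } else "none"))
      },
      fit = {
        tab <- pipeline_genotypes(cfg, out_dir, need)
        preds <- pipeline_read_predictors(cfg, out_dir, need)
        models <- pipeline_models(cfg, preds)
        cls <- classify_sites(tab, cfg$min_pop_size)
        runs <- list(PSS = cls$population, PASS = unique(tab$site))
        for (rn in names(runs)) {
          y <- population_dps(subset_genotypes(tab, sites = runs[[rn]]))
          for (method in cfg$methods) {
            sel <- fit_model_set(y, preds, models, method)
            f <- sprintf("selection_%s_%s.csv", rn, method)
            merged <- merge(sel$aicc, sel$bic, by = c("model", "k"),
                            suffixes = c("_aicc", "_bic"))
            utils::write.csv(merged[order(merged$delta_aicc), ],
                             file.path(out_dir, f), row.names = FALSE)
            emit(f)
          }
        }
        note("deterministic PSS/PASS selection tables written")
      },
      schemes = {
        tab <- pipeline_genotypes(cfg, out_dir, need)
        preds <- pipeline_read_predictors(cfg, out_dir, need)
        models <- pipeline_models(cfg, preds)
        cls <- classify_sites(tab, cfg$min_pop_size)
        densities <- list(`18` = cls$population, `40` = unique(tab$site))
        for (dn in names(densities)) {
          sites <- densities[[dn]]
          if (length(sites) < 4) next
          rs <- run_replicates(tab, sites, preds, models,
                               n_values = cfg$n_values, R = cfg$R,
                               methods = cfg$methods, base_seed = seed,
                               delta_threshold = cfg$delta_threshold)
          f <- sprintf("replicates_density%s.csv", dn)
          utils::write.csv(rs$summary, file.path(out_dir, f),
                           row.names = FALSE)
          emit(f)
          # convergence against the deterministic full-data reference
          y_full <- population_dps(subset_genotypes(tab, sites = sites))
          for (method in cfg$methods) {
            sel <- fit_model_set(y_full, preds, models, method)
            ref <- sel$aicc$model[sel$aicc$delta < cfg$delta_threshold]
            cv <- convergence_analysis(
              rs, ref, method = method,
              agreement_threshold = cfg$agreement_threshold
            )
            fc <- sprintf("convergence_density%s_%s.csv", dn, method)
            utils::write.csv(
              data.frame(n_per_site = rs$n_values,
                         agreement = cv$fractions,
                         converged_n = cv$converged_n),
              file.path(out_dir, fc), row.names = FALSE
            )
            emit(fc)
            note(sprintf(
              "density %s, %s: convergence at n = %s", dn, method,
              ifelse(is.na(cv$converged_n), "none", cv$converged_n)
            ))
          }
        }
      },
      report = {
        need("manifest.json", "any prior")
        note("report: see manifest.json for the artifact list")
      },
      stop("unknown stage: ", stage)
    )
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

pipeline_defaults <- function(config) {
  defaults <- list(
    synthetic = list(), inputs = NULL,
    min_pop_size = 11, n_values = 1:11, R = 100,
    methods = c("ML", "REML"), delta_threshold = 2,
    weight_threshold = 0.1, count_threshold = 30,
    agreement_threshold = 0.9, vif_threshold = 4,
    connectivity = 8, n_perm = 1000, models = NULL
  )
  for (nm in names(config)) defaults[[nm]] <- config[[nm]]
  defaults
}

pipeline_genotypes <- function(cfg, out_dir, need) {
  if (!is.null(cfg$inputs)) {
    return(read_genotypes(cfg$inputs$genotypes,
                          format = cfg$inputs$format %||% "csv"))
  }
  read_genotypes(need("genotypes.csv", "simulate"), "csv")
}

pipeline_read_predictors <- function(cfg, out_dir, need) {
  files <- list.files(out_dir, pattern = "^predictor_.*\\.csv$")
  if (!length(files)) {
    stop("missing artifact 'predictor_*.csv': run the 'resistance' stage",
         " first", call. = FALSE)
  }
  preds <- lapply(files, function(f) {
    read_dist_matrix(file.path(out_dir, f),
                     metric = "effective_resistance")
  })
  names(preds) <- sub("^predictor_(.*)\\.csv$", "\\1", files)
  preds
}

pipeline_predictors <- function(cfg, out_dir, need) {
  if (is.null(cfg$inputs)) {
    # synthetic runs already wrote predictors during simulate
    return(pipeline_read_predictors(cfg, out_dir, need))
  }
  nodes <- read_nodes(cfg$inputs$nodes)
  preds <- list()
  base_raster <- NULL
  for (nm in names(cfg$inputs$rasters)) {
    spec <- cfg$inputs$rasters[[nm]]
    ras <- read_ascii_grid(spec$path)
    if (is.null(base_raster)) base_raster <- ras
    surf <- parameterize(ras, spec$mode %||% "raw",
                         class_value = spec$class_value)
    preds[[nm]] <- effective_resistance(
      build_graph(surf, cfg$connectivity), nodes
    )
  }
  preds$distance <- uniform_ibd_predictor(base_raster, nodes,
                                          cfg$connectivity)
  preds
}

pipeline_models <- function(cfg, preds) {
  if (!is.null(cfg$models)) {
    multis <- cfg$models[vapply(cfg$models, length, 1L) > 1]
    singles <- unlist(cfg$models[vapply(cfg$models, length, 1L) == 1])
    return(candidate_models(singles, multis))
  }
  candidate_models(names(preds))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
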