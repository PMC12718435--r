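#' Configure the end-to-end calibration workflow
#'
#' Collects every knob of the full pipeline: preprocessing thresholds,
#' screening and selection settings, the calibration model grid, the RNE
#' radii, manual site exclusions and the master seed from which all stage
#' seeds are derived.
#'
#' @param dataset A `diatom_dataset` (see [load_dataset()], [new_dataset()]),
#'   or `NULL` if file paths are given.
#' @param count_path,env_path,coords_path,taxon_meta_path CSV paths used when
#'   `dataset` is `NULL`.
#' @param out_dir Output directory for the report bundle.
#' @param benthic_only Restrict to benthic taxa before preprocessing.
#' @param min_pct,min_occurrences Rare-taxon thresholds (percent, sites).
#' @param skew_threshold Skewness threshold for log-transforming variables.
#' @param cor_r,cor_p Correlation-grouping thresholds.
#' @param alpha,n_perm Permutation-test settings.
#' @param target Calibration variable; `NULL` picks the usable (eigenvalue
#'   ratio > 0.5) selected variable explaining the most variance.
#' @param forced_covariates Variables to condition on even if not selected.
#' @param exclude_sites Sites removed before analysis (manual outlier
#'   decisions; the pipeline itself never deletes sites silently).
#' @param specs Model grid (default [default_model_grid()]).
#' @param transforms Data transforms evaluated in the grid.
#' @param radii RNE deletion radii (km).
#' @param n_random_reps Random-deletion repetitions in the RNE stage.
#' @param k_env,k_taxa Cluster counts for the environment/assemblage trees.
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(dataset = NULL, count_path = NULL, env_path = NULL,
                            coords_path = NULL, taxon_meta_path = NULL,
                            out_dir = tempfile("diatomtf-run-"),
                            benthic_only = TRUE, min_pct = 1,
                            min_occurrences = 2, skew_threshold = 1,
                            cor_r = 0.8, cor_p = 0.001, alpha = 0.01,
                            n_perm = 999, target = NULL,
                            forced_covariates = character(),
                            exclude_sites = character(),
                            specs = default_model_grid(),
                            transforms = c("hellinger", "none"),
                            radii = c(0, 1, 2, 5, 10, 20, 40),
                            n_random_reps = 10, k_env = 3, k_taxa = 6,
                            seed = 1) {
  if (1 / (n_perm + 1) > alpha) {
    warn(sprintf(
      "n_perm = %d cannot reach alpha = %g (p floor %.4f); selection will be empty",
      n_perm, alpha, 1 / (n_perm + 1)))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

ws_write <- function(tbl, path, config, stage) {
  con <- file(path, "w")
  writeLines(sprintf("# diatomtf %s | stage=%s | seed=%s",
                     as.character(utils::packageVersion("diatomtf")),
                     stage, config$seed), con)
  close(con)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
}

#' Run the full calibration workflow
#'
#' Executes, in order: data loading, optional habit filtering and manual site
#' exclusion, relative abundance, rare-taxon filtering, Hellinger transform,
#' environment transformation, correlation grouping, per-group forward
#' selection with independence testing, the final partial-RDA variance
#' partition with eigenvalue-ratio screening, the usable-variable gate, the
#' model-selection grid with leave-one-out validation, a report-only outlier
#' screen, taxon optima/tolerances, indicator species over gradient classes,
#' environment and assemblage clustering, and (when coordinates exist) the
#' RNE autocorrelation analysis. Every table is written as TSV with a
#' provenance header, and a JSON manifest records the configuration, seed and
#' stage-wise site/taxon bookkeeping. A stage failure aborts with the stage
#' name; tables already written are left in place.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_full_workflow <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("diatomtf")),
                   stages = list())
  res <- list()
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  ds <- run_stage("load", {
    d <- config$dataset %||%
      load_dataset(config$count_path, config$env_path, config$coords_path,
                   config$taxon_meta_path)
    if (length(config$exclude_sites)) {
      keep <- !(d$counts$site %in% config$exclude_sites)
      d <- new_dataset(d$counts[keep, ], d$env[keep, ],
                       if (!is.null(d$coords)) d$coords[keep, ], d$habit)
    }
    d
  })
  note("load", n_sites = nrow(ds$counts), n_taxa = length(ds$habit),
       excluded = config$exclude_sites)

  counts <- run_stage("habit_filter", {
    if (config$benthic_only && any(ds$habit == "benthic")) {
      habit_filter(ds$counts, ds$habit, "benthic")
    } else ds$counts
  })
  note("habit_filter", n_taxa = ncol(counts) - 1L)

  rel <- run_stage("relative_abundance", relative_abundance(counts))
  filt <- run_stage("rare_filter",
                    rare_taxon_filter(rel, config$min_pct, config$min_occurrences))
  rep_f <- attr(filt, "filter_report")
  note("rare_filter", n_taxa = length(rep_f$retained),
       dropped = length(rep_f$dropped), valve_fraction = rep_f$valve_fraction)

  hel <- run_stage("hellinger", hellinger(filt))
  envs <- run_stage("transform_env", transform_env(ds$env, config$skew_threshold))

  dca <- run_stage("gradient_length", dca_gradient_length(hel))
  note("gradient_length", length = dca$gradient_length,
       recommendation = dca$recommendation)

  grp <- run_stage("correlation_groups",
                   correlation_groups(envs, config$cor_r, config$cor_p))
  note("correlation_groups", n_groups = length(grp$groups))

  sel <- run_stage("forward_selection", {
    picks <- character(); rejected <- list()
    for (g in grp$groups) {
      fs <- forward_select(hel, envs, candidates = g,
                           covariates = intersect(config$forced_covariates,
                                                  setdiff(names(envs), g)),
                           alpha = config$alpha, n_perm = config$n_perm,
                           seed = stage_seed(config$seed, paste(g, collapse = "")))
      gp <- fs$variable
      # within-group independence check: drop variables whose variance is
      # absorbed by a stronger group member
      if (length(gp) > 1) {
        keep <- gp
        for (i in seq_along(gp)) for (j in seq_along(gp)) {
          if (i < j && all(c(gp[i], gp[j]) %in% keep)) {
            it <- independence_test(hel, envs, gp[i], gp[j],
                                    alpha = config$alpha, n_perm = config$n_perm,
                                    seed = stage_seed(config$seed,
                                                      paste0(gp[i], gp[j])))
            if (it$verdict == "dependent") {
              lose <- setdiff(c(gp[i], gp[j]), it$retain)
              keep <- setdiff(keep, lose)
              rejected[[lose]] <- sprintf("dependent on %s", it$retain)
            }
          }
        }
        gp <- keep
      }
      picks <- c(picks, gp)
    }
    list(selected = picks, rejected = rejected, report = NULL)
  })
  note("forward_selection", selected = sel$selected,
       dependent_dropped = names(sel$rejected))
  if (length(sel$selected) == 0) {
    abort("stage 'forward_selection' failed: no variable passed selection")
  }

  part <- run_stage("variance_partition", {
    covs <- setdiff(config$forced_covariates, sel$selected)
    variance_partition(hel, envs, sel$selected,
                       covariates = if (length(covs)) covs,
                       n_perm = config$n_perm,
                       seed = stage_seed(config$seed, "vp"))
  })
  ws_write(part, file.path(config$out_dir, "variance_partition.tsv"),
           config, "variance_partition")

  target <- run_stage("target_gate", {
    tg <- config$target
    if (is.null(tg)) {
      usable <- part$variable[part$lambda_ratio > 0.5]
      if (length(usable) == 0) {
        warn("no variable passes the eigenvalue-ratio gate; taking the best ratio")
        usable <- part$variable[which.max(part$lambda_ratio)]
      }
      tg <- part$variable[part$variable %in% usable][
        which.max(part$variance_pct[part$variable %in% usable])]
    }
    tg
  })
  note("target_gate", target = target,
       usable = part$variable[part$lambda_ratio > 0.5])

  x <- ds$env[[target]]
  grid <- run_stage("model_selection",
                    model_selection_table(filt, x, config$specs,
                                          config$transforms))
  ws_write(grid, file.path(config$out_dir, "model_selection.tsv"),
           config, "model_selection")
  best_row <- grid[grid$selected, ][1, ]
  best_spec <- Filter(function(s) spec_label(s) == best_row$model,
                      config$specs)[[1]]
  best_tbl <- if (best_row$transform == "hellinger") hel else filt
  note("model_selection", model = best_row$model,
       transform = best_row$transform, rmsep = best_row$rmsep,
       r2_jack = best_row$r2_jack)

  outl <- run_stage("outlier_screen",
                    outlier_screen(best_tbl, x, best_spec))
  if (nrow(outl$flagged)) {
    ws_write(outl$flagged, file.path(config$out_dir, "outliers.tsv"),
             config, "outlier_screen")
  }
  note("outlier_screen", flagged = outl$flagged$site)

  loo <- run_stage("loo", loo_predictions(best_tbl, x, best_spec))
  ws_write(loo, file.path(config$out_dir, "loo_residuals.tsv"), config, "loo")

  resp <- run_stage("responses", estimate_responses(best_tbl, x))
  ws_write(resp, file.path(config$out_dir, "optima_tolerances.tsv"),
           config, "responses")

  ind <- run_stage("indicators", {
    indval(filt, gradient_classes(x),
           n_perm = config$n_perm,
           seed = stage_seed(config$seed, "indval"))
  })
  ws_write(ind, file.path(config$out_dir, "indicators.tsv"), config, "indicators")

  clu_env <- run_stage("cluster_env",
                       cluster_sites(envs, k = min(config$k_env, nrow(envs))))
  clu_tax <- run_stage("cluster_taxa",
                       cluster_sites(hel, k = min(config$k_taxa, nrow(hel))))
  ws_write(clu_env$assignment, file.path(config$out_dir, "clusters_env.tsv"),
           config, "cluster_env")
  ws_write(clu_tax$assignment, file.path(config$out_dir, "clusters_taxa.tsv"),
           config, "cluster_taxa")

  rne <- NULL
  if (!is.null(ds$coords)) {
    rne <- run_stage("rne", rne_analysis(best_tbl, x, ds$coords, best_spec,
                                         radii = config$radii,
                                         n_random_reps = config$n_random_reps,
                                         seed = stage_seed(config$seed, "rne")))
    ws_write(rne, file.path(config$out_dir, "rne_curves.tsv"), config, "rne")
    note("rne", radii = config$radii)
  } else {
    inform("no coordinates supplied; RNE stage skipped")
    note("rne", skipped = TRUE)
  }

  manifest$config <- lapply(unclass(config), function(v)
    if (is.list(v) && !is.data.frame(v)) NULL else v)
  manifest$target <- target
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  res <- list(dataset = ds, abundance = filt, hellinger = hel, env = envs,
              gradient_length = dca, groups = grp, selected = sel$selected,
              partition = part, target = target, grid = grid,
              best_spec = best_spec, outliers = outl, loo = loo,
              responses = resp, indicators = ind,
              clusters_env = clu_env, clusters_taxa = clu_tax, rne = rne,
              manifest = manifest, out_dir = config$out_dir)
  invisible(res)
}
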