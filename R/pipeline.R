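# End-to-end pipeline -----------------------------------------------------

#' Run the full risk-mapping pipeline on a synthetic landscape
#'
#' Orchestrates every stage: simulate the landscape, build the
#' boater-traffic network and pick the centrality measure most correlated
#' with invasion status, assign streams and compute per-species
#' connectivity for both censuses, assemble the two covariate tables,
#' screen covariates by Pearson correlation, select the secondary-variable
#' pair per species by temporal-validation AUC, optionally predict the
#' water-masked probability surface from current (second-census) statuses,
#' rank waterbodies into five quantile risk classes, and summarise
#' per-rank counts and the cross-species rank-5 union. Identical config
#' and parameters reproduce identical results.
#'
#' @param config A [landscape_config()].
#' @param params A [kriging_params()].
#' @param screen_threshold Pearson screening threshold (default 0.1).
#' @param do_surface Predict gridded surfaces and rankings (default TRUE;
#'   turn off for validation-only replicate runs).
#' @param grid_cell Grid cell size in km (default `params$lag_size`).
#' @param out_dir If non-NULL, stage outputs are written there (CSV,
#'   GeoJSON, ESRI ASCII, JSON) together with `provenance.json`.
#' @return List of class `pipeline_result` with elements `landscape`,
#'   `centrality_choice`, `covariates` (t1, t2), `screen`, `selection`
#'   (per species), `validation` (per species `validation_report`),
#'   `surface`, `ranking`, `summary`, `config`, `params`.
#' @export
run_pipeline <- function(config = landscape_config(),
                         params = kriging_params(),
                         screen_threshold = 0.1,
                         do_surface = TRUE,
                         grid_cell = params$lag_size,
                         out_dir = NULL) {
  validate_landscape_config(config)
  ls <- simulate_landscape(config)
  wb <- ls$waterbodies

  cents <- list(
    eigenvector = eigenvector_centrality(ls$network),
    betweenness = betweenness_centrality(ls$network),
    degree = degree_centrality(ls$network)
  )
  status_now <- list(zm = ls$reported$zm_t2, ewm = ls$reported$ewm_t2)
  choice <- select_centrality(cents, status_now)
  v5 <- cents[[choice$measure]]$score[wb$id]

  conn <- list()
  for (sp in c("zm", "ewm")) {
    for (yr in c("t1", "t2")) {
      invaded <- wb$id[ls$reported[[paste0(sp, "_", yr)]] == 1]
      asg <- assign_streams(wb, ls$streams, invaded_ids = invaded)
      conn[[paste0(sp, "_", yr)]] <- connectivity_to_invaded(asg, invaded)
    }
  }

  cov <- list()
  for (yr in c("t1", "t2")) {
    cov[[yr]] <- assemble_covariates(
      wb,
      status_zm = ls$reported[[paste0("zm_", yr)]],
      status_ewm = ls$reported[[paste0("ewm_", yr)]],
      conn_zm = unname(conn[[paste0("zm_", yr)]]),
      conn_ewm = unname(conn[[paste0("ewm_", yr)]]),
      centrality = unname(v5),
      road_scores = unname(ls$road_access),
      year = yr
    )
  }

  screen <- pearson_screen(cov$t1, threshold = screen_threshold)
  selection <- list()
  validation <- list()
  for (sp in c("zm", "ewm")) {
    cand <- screen$candidates[[sp]]
    if (length(cand) < 2) {
      stop("model selection aborted for ", sp,
           ": fewer than two screened candidate secondaries", call. = FALSE)
    }
    selection[[sp]] <- select_model(cov$t1, cov$t2, sp, cand, params)
    validation[[sp]] <- selection[[sp]]$report
  }

  surface <- NULL
  ranking <- NULL
  summary <- list(
    n_waterbodies = nrow(wb),
    centrality = choice$measure,
    counts_by_variable = lapply(cov, function(tb) {
      c(v1_zm = sum(tb$v1_zm), v2_ewm = sum(tb$v2_ewm),
        v3_conn_zm = sum(tb$v3_conn_zm), v4_conn_ewm = sum(tb$v4_conn_ewm),
        v5_eig = sum(tb$v5_eig > 0), v6_invroad = nrow(tb))
    }),
    selected = lapply(selection, function(s) {
      list(secondaries = s$secondaries, auc = s$auc)
    })
  )

  if (do_surface) {
    grid <- grid_spec(config$extent, grid_cell)
    mask <- water_mask(grid, wb)
    surface <- list()
    ranking <- list()
    for (sp in c("zm", "ewm")) {
      model <- fit_species_model(cov$t2, sp, selection[[sp]]$secondaries,
                                 params)
      data <- cokrige_data(cov$t2, sp, selection[[sp]]$secondaries, params)
      surface[[sp]] <- predict_surface(model, data, grid, mask)
      probs <- extract_at_waterbodies(surface[[sp]], wb)
      ranking[[sp]] <- rank_by_quantiles(probs)
    }
    summary$at_or_above_3 <- lapply(ranking, count_at_or_above, rank = 3)
    summary$rank5_union <- union_at_rank(ranking$zm, ranking$ewm, rank = 5)
  }

  result <- structure(
    list(landscape = ls, centrality_choice = choice, covariates = cov,
         screen = screen, selection = selection, validation = validation,
         surface = surface, ranking = ranking, summary = summary,
         config = config, params = params),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write all pipeline stage outputs to a directory
#'
#' Plain standard formats so any stage can be inspected or re-run
#' standalone: waterbodies and lines as GeoJSON, surveys and covariate
#' tables as CSV, the correlation matrix as CSV, model selection and
#' validation as JSON, rankings as CSV, surfaces as ESRI ASCII grids, and
#' `provenance.json` holding the full config and kriging parameters.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ls <- result$landscape
  fp <- function(...) file.path(out_dir, ...)
  wb_out <- cbind(ls$waterbodies, ls$reported[match(ls$waterbodies$id,
                                                    ls$reported$id), -1])
  write_geojson_points(wb_out, fp("waterbodies.geojson"))
  write_geojson_lines(ls$streams, fp("streams.geojson"))
  write_geojson_lines(ls$roads, fp("roads.geojson"))
  utils::write.csv(ls$surveys, fp("surveys.csv"), row.names = FALSE)
  utils::write.csv(result$covariates$t1, fp("covariates_t1.csv"),
                   row.names = FALSE)
  utils::write.csv(result$covariates$t2, fp("covariates_t2.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$screen$matrix),
                   fp("correlations.csv"))
  jsonlite::write_json(
    lapply(result$selection, function(s) {
      list(table = s$table, secondaries = s$secondaries, auc = s$auc)
    }),
    fp("model_selection.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    lapply(result$validation, function(v) {
      v[c("scheme", "species", "secondaries", "auc", "sensitivity",
          "specificity", "threshold_rank")]
    }),
    fp("validation.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(result$ranking)) {
    ranked <- data.frame(
      id = result$ranking$zm$id,
      prob_zm = result$ranking$zm$prob, rank_zm = result$ranking$zm$rank,
      prob_ewm = result$ranking$ewm$prob, rank_ewm = result$ranking$ewm$rank
    )
    utils::write.csv(ranked, fp("ranked.csv"), row.names = FALSE)
    write_ascii_grid(result$surface$zm, fp("surface_zm.asc"))
    write_ascii_grid(result$surface$ewm, fp("surface_ewm.asc"))
  }
  jsonlite::write_json(result$summary, fp("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config = unclass(result$config), params = unclass(result$params)),
    fp("provenance.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
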