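#' Default pipeline configuration
#'
#' All tunable parameters of the sociospatial pipeline in one list, suitable
#' for serialisation next to the outputs. `input` selects the source: either
#' `list(mode = "simulate", ...)` with arguments forwarded to
#' [simulate_study()], or `list(mode = "telemetry", path = <csv>)`.
#'
#' @param ... Overrides for any top-level field.
#' @return A named list with class `pbsn_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input = list(mode = "simulate"),
    seed = 1,
    assoc_dist = 50,
    round_tolerance = 300,
    max_speed = 15000,
    max_step = 10000,
    isopleth_level = 0.95,
    min_fixes = 5,
    udoi_restrict = TRUE,
    outlier_km2 = 4000,
    n_iter = 1000,
    out_dir = "pbsn-results"
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "pbsn_config"
  cfg
}

write_stage <- function(df, path, manifest, stage, params = list()) {
  utils::write.csv(df, path, row.names = FALSE)
  manifest[[length(manifest) + 1]] <- list(
    stage = stage,
    file = basename(path),
    rows = nrow(df),
    md5 = unname(tools::md5sum(path)),
    params = params
  )
  manifest
}

#' Run the full sociospatial pipeline
#'
#' Orchestrates simulate/read -> screen -> season-partition -> rounds ->
#' social networks -> home ranges, overlap and fidelity -> permutation
#' ensemble -> model suite, writing every stage's output as CSV into
#' `config$out_dir` together with a JSON manifest (stage, file, row count,
#' md5, parameters) and the serialized configuration. Stage failures abort
#' with a stage-named error; outputs written before the failure are kept.
#'
#' @param config A list from [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results (`fixes`,
#'   `social`, `areas`, `spatial`, `fidelity`, `ensemble`, `coefnull`,
#'   `records`, `models`) and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(glue::glue("pipeline stage '{name}' failed: {conditionMessage(e)}"),
                   parent = e)
    })
  }

  raw <- stage("input", {
    if (identical(config$input$mode, "simulate")) {
      args <- config$input[setdiff(names(config$input), "mode")]
      if (is.null(args$seed)) args$seed <- config$seed
      do.call(simulate_study, args)
    } else if (identical(config$input$mode, "telemetry")) {
      read_telemetry(config$input$path)
    } else {
      rlang::abort("config$input$mode must be 'simulate' or 'telemetry'")
    }
  })

  fixes <- stage("preprocess", {
    f <- screen_fixes(raw, max_speed = config$max_speed, max_step = config$max_step)
    rej <- attr(f, "rejected")
    if (!"season" %in% names(f)) f <- assign_season(f)
    f <- build_rounds(f, tolerance = config$round_tolerance)
    manifest <- write_stage(rej, file.path(config$out_dir, "rejected_fixes.csv"),
                             manifest, "preprocess",
                             list(max_speed = config$max_speed, max_step = config$max_step))
    manifest <- write_stage(
      dplyr::mutate(f, timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
                    round_time = format(.data$round_time, "%Y-%m-%dT%H:%M:%SZ")),
      file.path(config$out_dir, "fixes.csv"), manifest, "preprocess",
      list(round_tolerance = config$round_tolerance))
    f
  })

  social <- stage("social_network", {
    net <- build_pbsn(fixes, assoc_dist = config$assoc_dist)
    manifest <- write_stage(net$edges, file.path(config$out_dir, "social_edges.csv"),
                             manifest, "social_network",
                             list(assoc_dist = config$assoc_dist))
    manifest <- write_stage(net$strength, file.path(config$out_dir, "social_strength.csv"),
                             manifest, "social_network",
                             list(assoc_dist = config$assoc_dist))
    manifest <- write_stage(net$groups, file.path(config$out_dir, "group_counts.csv"),
                             manifest, "social_network",
                             list(assoc_dist = config$assoc_dist))
    net
  })
  grp <- social$groups
  rlang::inform(glue::glue(
    "groups of >= 2 collared animals: {sum(grp$n_groups)} total across {nrow(grp)} herd-season-years"
  ))

  areas <- stage("home_range", {
    a <- home_range_areas(fixes, level = config$isopleth_level,
                          min_fixes = config$min_fixes)
    manifest <- write_stage(a, file.path(config$out_dir, "home_range_areas.csv"),
                             manifest, "home_range",
                             list(level = config$isopleth_level))
    a
  })
  spatial <- stage("spatial_network", {
    s <- build_spatial_network(fixes, level = config$isopleth_level,
                               min_fixes = config$min_fixes,
                               restrict = config$udoi_restrict)
    manifest <- write_stage(s$edges, file.path(config$out_dir, "spatial_edges.csv"),
                             manifest, "spatial_network",
                             list(level = config$isopleth_level, restrict = config$udoi_restrict))
    manifest <- write_stage(s$strength, file.path(config$out_dir, "spatial_strength.csv"),
                             manifest, "spatial_network", list())
    s
  })
  fidelity <- stage("site_fidelity", {
    fd <- site_fidelity(fixes, level = config$isopleth_level,
                        min_fixes = config$min_fixes,
                        restrict = config$udoi_restrict)
    manifest <- write_stage(fd, file.path(config$out_dir, "site_fidelity.csv"),
                             manifest, "site_fidelity", list())
    fd
  })

  ensemble <- stage("permutation", {
    en <- run_ensemble(fixes, n_iter = config$n_iter, seed = config$seed,
                       assoc_dist = config$assoc_dist,
                       tolerance = config$round_tolerance)
    manifest <- write_stage(tidy(en), file.path(config$out_dir, "ensemble_summary.csv"),
                             manifest, "permutation",
                             list(n_iter = config$n_iter, seed = config$seed))
    en
  })
  coefnull <- stage("coefficient_null", {
    cn <- coefficient_null(ensemble)
    manifest <- write_stage(cn$summary, file.path(config$out_dir, "coefficient_null.csv"),
                             manifest, "coefficient_null", list(band = cn$band))
    cn
  })

  models <- stage("inference", {
    records <- assemble_records(social = social, spatial = spatial,
                                fidelity = fidelity, areas = areas,
                                ensemble = ensemble)
    records <- filter_outliers(records, threshold = config$outlier_km2)
    suite <- run_model_suite(records)
    manifest <- write_stage(tidy(suite), file.path(config$out_dir, "model_summary.csv"),
                             manifest, "inference",
                             list(outlier_km2 = config$outlier_km2))
    list(records = records, suite = suite)
  })

  jsonlite::write_json(unclass(config), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    fixes = fixes, social = social, areas = areas, spatial = spatial,
    fidelity = fidelity, ensemble = ensemble, coefnull = coefnull,
    records = models$records, models = models$suite, manifest = manifest,
    config = config
  ))
}
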