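#' Run the full analysis pipeline on a scenario
#'
#' Executes generate -> quality -> access -> equity -> plan -> evaluate on
#' a synthetic scenario (or a city read from files), writing every stage's
#' artifact plus a checksummed manifest to `out_dir`. Re-running with the
#' same configuration reproduces byte-identical files.
#'
#' Artifacts: `parks.geojson`, `entrances.geojson`, `residences.geojson`,
#' `parcels.geojson`, `roads.graphml`, `blocks.csv`, `config.yml`,
#' `landcover/*.asc`, `park_quality.csv`, `supply_ratios.csv`,
#' `accessibility.csv`, `lisa.csv`, `moran_summary.json`,
#' `blind_zones.csv`, `targets.csv`, `kcurve.csv`, `siting_plan.geojson`,
#' `evaluation.json`, `manifest.json`.
#'
#' @param config a [scenario_config()] (default: the reference scenario).
#' @param out_dir output directory.
#' @param k_new `"auto"` (K-curve knee) or a fixed integer number of new
#'   parks.
#' @param equity list with `k`, `n_perm`, `alpha`.
#' @param write_city_files write the synthetic-city input files too?
#' @return invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config = reference_scenario(), out_dir,
                         k_new = "auto",
                         equity = list(k = 8, n_perm = 999, alpha = 0.05),
                         write_city_files = TRUE) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "\n  (check the scenario config and stage inputs)",
           call. = FALSE)
    })
  }
  seed <- config$seed

  city <- stage("generate", {
    cty <- generate_city(config)
    if (write_city_files) write_city(cty, out_dir)
    cty
  })
  quality <- stage("quality", {
    q <- park_quality(city)
    write.csv(q, file.path(out_dir, "park_quality.csv"), row.names = FALSE)
    q
  })
  accres <- stage("access", {
    dist <- residence_park_distances(city)
    acc <- access_table(city, quality, dist = dist)
    ratios <- supply_demand_ratios(city, quality,
                                   catchment_config("type_specific"), dist)
    write.csv(ratios, file.path(out_dir, "supply_ratios.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(acc), file.path(out_dir, "accessibility.csv"),
              row.names = FALSE)
    list(dist = dist, access = acc, ratios = ratios)
  })
  lisa <- stage("equity", {
    w <- build_weights(city$residences, k = equity$k)
    l <- bivariate_moran(accres$access$A_comprehensive,
                         city$residences$price, w, n_perm = equity$n_perm,
                         alpha = equity$alpha, seed = seed)
    write.csv(as.data.frame(l), file.path(out_dir, "lisa.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(global_I = l$global_I, counts = as.list(l$counts),
           alpha = l$alpha, n_perm = l$n_perm),
      file.path(out_dir, "moran_summary.json"), auto_unbox = TRUE,
      digits = NA)
    l
  })
  planres <- stage("plan", {
    blind <- identify_blind_zones(accres$access, accres$dist)
    write.csv(blind, file.path(out_dir, "blind_zones.csv"),
              row.names = FALSE)
    targets <- suppressWarnings(select_targets(accres$access, lisa))
    write.csv(targets, file.path(out_dir, "targets.csv"), row.names = FALSE)
    if (nrow(targets) < 3) {
      plan <- data.frame()
      kc <- NULL; pso <- NULL
    } else {
      feats <- planning_features(accres$access, lisa, targets)
      kmax <- min(12L, nrow(targets) - 1L)
      kc <- kmeans_curve(feats, k_range = seq_len(kmax), seed = seed,
                         k_override = if (identical(k_new, "auto")) NULL
                                      else as.integer(k_new))
      write.csv(kc$curve, file.path(out_dir, "kcurve.csv"),
                row.names = FALSE)
      tpts <- city$residences[match(targets$residence_id,
                                    city$residences$id), ]
      pso <- pso_site_selection(
        tpts, k = min(kc$chosen_k, nrow(city$parcels)),
        bounds = c(0, city$extent[1], 0, city$extent[2]), seed = seed)
      plan <- assign_park_classes(pso, city$parcels)
      write_geojson(siting_features(plan),
                    file.path(out_dir, "siting_plan.geojson"))
    }
    list(blind = blind, targets = targets, kcurve = kc, pso = pso,
         plan = plan)
  })
  evaluation <- stage("evaluate", {
    ev <- evaluate_plan(city, planres$plan, quality, equity = equity,
                        seed = seed,
                        before = list(access = accres$access, lisa = lisa,
                                      blind = planres$blind))
    jsonlite::write_json(evaluation_summary(ev),
                         file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    ev
  })
  manifest <- write_manifest(out_dir, config, equity)
  invisible(list(city = city, quality = quality, access = accres$access,
                 ratios = accres$ratios, lisa = lisa, blind = planres$blind,
                 targets = planres$targets, kcurve = planres$kcurve,
                 plan = planres$plan, evaluation = evaluation,
                 manifest = manifest))
}

siting_features <- function(plan) {
  lapply(seq_len(nrow(plan)), function(i) {
    p <- plan[i, ]
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = list(p$cx, p$cy)),
         properties = list(parcel_id = p$parcel_id, class = p$class,
                           radius_m = p$radius_m, area_hm2 = p$area_hm2,
                           site_x = p$site_x, site_y = p$site_y,
                           w = p$w, h = p$h))
  })
}

evaluation_summary <- function(ev) {
  d <- ev$deltas
  list(
    n_new_parks = nrow(ev$plan),
    mean_accessibility_before = vapply(
      grep("^A_", names(ev$before$access), value = TRUE),
      function(cn) mean(ev$before$access[[cn]]), numeric(1)),
    mean_accessibility_after = vapply(
      grep("^A_", names(ev$after$access), value = TRUE),
      function(cn) mean(ev$after$access[[cn]]), numeric(1)),
    delta_mean_accessibility = as.list(d$mean_accessibility),
    delta_zero_count = as.list(d$zero_count),
    blind_before = as.list(d$blind_counts_before),
    blind_after = as.list(d$blind_counts_after),
    lisa_before = as.list(d$lisa_counts_before),
    lisa_after = as.list(d$lisa_counts_after))
}

write_manifest <- function(out_dir, config, equity) {
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package = "parkequity",
    version = as.character(utils::packageVersion("parkequity")),
    stages = c("generate", "quality", "access", "equity", "plan",
               "evaluate"),
    seed = config$seed,
    equity = equity,
    checksums = as.list(setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
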