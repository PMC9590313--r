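# End-to-end orchestration: configuration, per-mode analysis chain,
# output writing and a plain-text report.

.config_fields <- c("city_dir", "scenario", "scenario_seed", "modes",
                    "huff_variant", "weights", "supply_scale",
                    "weight_scheme", "permutations", "alpha", "seed",
                    "lisa_on", "lorenz_resource", "thresholds", "out_dir")

#' Run configuration
#'
#' Validated bag of every tunable the pipeline accepts. Defaults reproduce
#' the standard study parameters: speeds 5/15/40 km/h with thresholds
#' 30/25/30 min, service radii 300/500 m, equal attractiveness weights,
#' Gaussian Huff variant, queen contiguity, 999 permutations at
#' alpha = 0.05.
#'
#' @param city_dir directory with a saved city bundle (exclusive with
#'   \code{scenario}).
#' @param scenario synthetic scenario name (see \code{\link{make_scenario}}).
#' @param scenario_seed seed for the synthetic city.
#' @param modes travel modes to run.
#' @param huff_variant Huff weight variant.
#' @param weights attractiveness weights \code{c(area, green, diversity)}.
#' @param supply_scale \code{"dimensionless"} or \code{"area"}
#'   (m2/person ratios).
#' @param weight_scheme LISA contiguity scheme.
#' @param permutations LISA conditional permutations.
#' @param alpha LISA significance level.
#' @param seed seed for all pipeline randomness (LISA permutations).
#' @param lisa_on run LISA on the equality index (\code{"Ei"}) or raw
#'   accessibility (\code{"Ai"}).
#' @param lorenz_resource \code{"PA"} (population-weighted accessibility,
#'   default) or \code{"A"}.
#' @param thresholds named t0 overrides in minutes, e.g.
#'   \code{c(walking = 30)}.
#' @param out_dir optional output directory; when set, every table is
#'   written as CSV/GeoJSON plus a report and run manifest.
#' @return a \code{run_config}.
#' @export
run_config <- function(city_dir = NULL, scenario = "baseline",
                       scenario_seed = 1L,
                       modes = c("walking", "cycling", "driving"),
                       huff_variant = "gaussian",
                       weights = rep(1, 3) / 3,
                       supply_scale = "dimensionless",
                       weight_scheme = "queen", permutations = 999,
                       alpha = 0.05, seed = 1L, lisa_on = "Ei",
                       lorenz_resource = "PA", thresholds = NULL,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  extra <- setdiff(names(cfg), .config_fields)
  if (length(extra)) stop("unknown config field(s): ", paste(extra, collapse = ", "))
  stopifnot(
    all(cfg$modes %in% c("walking", "cycling", "driving")),
    cfg$huff_variant %in% c("gaussian", "gaussian_over_time",
                            "gaussian_times_time"),
    length(cfg$weights) == 3, abs(sum(cfg$weights) - 1) < 1e-9,
    cfg$supply_scale %in% c("dimensionless", "area"),
    cfg$weight_scheme %in% c("queen", "rook", "distance_band"),
    cfg$permutations >= 1, cfg$alpha > 0, cfg$alpha < 1,
    cfg$lisa_on %in% c("Ei", "Ai"),
    cfg$lorenz_resource %in% c("PA", "A")
  )
  if (!is.null(cfg$thresholds) && any(cfg$thresholds <= 0))
    stop("thresholds must be positive minutes")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$thresholds)) raw$thresholds <- unlist(raw$thresholds)
  if (!is.null(raw$weights)) {
    w <- as.numeric(raw$weights)
    if (abs(sum(w) - 1) > 1e-4) stop("config weights must sum to 1")
    raw$weights <- w / sum(w)      # absorb YAML rounding
  }
  do.call(run_config, raw)
}

#' @rdname read_config
#' @param config a \code{run_config}.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  if (!is.null(out$thresholds)) out$thresholds <- as.list(out$thresholds)
  yaml::write_yaml(out, path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full accessibility-equity pipeline
#'
#' For each requested travel mode: origin-destination travel times,
#' composite attractiveness, Huff probabilities, supply-demand ratios,
#' the accessibility surface, equality index with six-class labels, LISA
#' clusters, Lorenz/Gini, and the zonal summary. A manifest records the
#' configuration, seed, package version, stage counts and the
#' supply-conservation error per mode. Identical config and seed give
#' identical outputs.
#'
#' @param config a \code{run_config} (or path to a YAML config).
#' @param city optional pre-built \code{city_model} (overrides
#'   \code{city_dir}/\code{scenario}).
#' @return object of class \code{greenreach_run}: \code{city},
#'   \code{config}, \code{supply}, per-mode \code{results}, and
#'   \code{manifest}.
#' @export
run_pipeline <- function(config = run_config(), city = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)

  if (is.null(city)) {
    city <- if (!is.null(config$city_dir))
      stage("load_city", load_city(config$city_dir))
    else
      stage("generate_city",
            make_scenario(config$scenario, seed = config$scenario_seed))
  }

  supply <- stage("attractiveness", park_supply(city, config$weights))
  W <- stage("weights", build_weights(city$grid, config$weight_scheme))

  results <- list()
  for (m in config$modes) {
    mode <- travel_mode(m, t0_min = if (!is.null(config$thresholds) &&
                                        m %in% names(config$thresholds))
      config$thresholds[[m]] else NULL)
    fit <- stage(paste0("access_", m),
                 park_access(city, mode, weights = config$weights,
                             huff_variant = config$huff_variant,
                             supply_scale = config$supply_scale,
                             supply = supply))
    Ei <- stage(paste0("equality_", m),
                equality_index(fit$A, fit$ratios$Rj))
    eq <- classify_equality(Ei)
    eq <- cbind(cell_id = city$grid$cell_id, eq)

    lisa_x <- if (config$lisa_on == "Ei") Ei else fit$A
    lisa <- stage(paste0("lisa_", m),
                  local_moran(lisa_x, W, permutations = config$permutations,
                              alpha = config$alpha, seed = config$seed))
    lisa <- cbind(cell_id = city$grid$cell_id, lisa)

    resource <- if (config$lorenz_resource == "PA")
      city$grid$population * fit$A else fit$A
    lg <- stage(paste0("lorenz_", m),
                lorenz_gini(city$grid$population, resource))

    results[[m]] <- list(fit = fit, equality = eq, lisa = lisa,
                         lorenz = lg, summary = fit$summary)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("greenreach")),
    config = unclass(config)[setdiff(.config_fields, "out_dir")],
    counts = list(cells = nrow(city$grid),
                  populated_cells = sum(city$grid$population > 0),
                  parks = nrow(city$parks),
                  network_nodes = nrow(city$network$nodes),
                  network_edges = nrow(city$network$edges)),
    modes = lapply(results, function(r) list(
      reachable_pairs = sum(is.finite(unclass(r$fit$od)) &
                              unclass(r$fit$od) <= r$fit$spec$t0_min),
      conservation_rel_error = conservation_error(r$fit),
      gini = r$lorenz$gini, gini_band = r$lorenz$band,
      underserved_pct = r$summary$underserved_pct[r$summary$zone == "ALL"]
    ))
  )

  run <- structure(list(city = city, config = config, supply = supply,
                        results = results, manifest = manifest),
                   class = "greenreach_run")
  if (!is.null(config$out_dir)) save_outputs(run, config$out_dir)
  run
}

#' @export
print.greenreach_run <- function(x, ...) {
  cat("<greenreach_run>", length(x$results), "mode(s):",
      paste(names(x$results), collapse = ", "), "\n")
  for (m in names(x$results)) {
    r <- x$results[[m]]
    cat(sprintf("  %-8s Gini %.3f (%s), underserved %.2f%%, conservation %.1e\n",
                m, r$lorenz$gini, r$lorenz$band,
                r$summary$underserved_pct[r$summary$zone == "ALL"],
                conservation_error(r$fit)))
  }
  invisible(x)
}

#' Write every pipeline result to disk
#'
#' Per mode: \code{access_<mode>.csv}, \code{ratios_<mode>.csv},
#' \code{summary_<mode>.csv}, \code{equality_<mode>.csv},
#' \code{lisa_<mode>.csv}, \code{lorenz_<mode>.csv},
#' \code{gini_<mode>.txt} and \code{od_<mode>.csv} (wide travel-time
#' matrix, blank = unreachable); plus \code{results.geojson} (grid cells
#' with result attributes), \code{report.md} and \code{manifest.yaml}.
#'
#' @param run a \code{greenreach_run}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
save_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- run$city$grid
  for (m in names(run$results)) {
    r <- run$results[[m]]
    utils::write.csv(data.frame(cell_id = grid$cell_id, Ai = r$fit$A),
                     file.path(dir, paste0("access_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$fit$ratios,
                     file.path(dir, paste0("ratios_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$summary,
                     file.path(dir, paste0("summary_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$equality,
                     file.path(dir, paste0("equality_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$lisa, file.path(dir, paste0("lisa_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$lorenz$points,
                     file.path(dir, paste0("lorenz_", m, ".csv")),
                     row.names = FALSE)
    writeLines(sprintf("%.6f  # %s", r$lorenz$gini, r$lorenz$band),
               file.path(dir, paste0("gini_", m, ".txt")))
    od <- unclass(r$fit$od)
    odf <- as.data.frame(round(od, 4))
    names(odf) <- paste0("park_", attr(r$fit$od, "park_id"))
    odf[!is.finite(od)] <- NA   # blank = unreachable
    utils::write.csv(cbind(cell_id = grid$cell_id, odf),
                     file.path(dir, paste0("od_", m, ".csv")),
                     row.names = FALSE, na = "")
  }
  write_geojson(results_geojson(run), file.path(dir, "results.geojson"))
  writeLines(render_report(run), file.path(dir, "report.md"))
  yaml::write_yaml(run$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

results_geojson <- function(run) {
  grid <- run$city$grid
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    props <- list(cell_id = grid$cell_id[i], zone = grid$zone[i],
                  population = grid$population[i])
    for (m in names(run$results)) {
      r <- run$results[[m]]
      props[[paste0("A_", m)]] <- r$fit$A[i]
      props[[paste0("Ei_", m)]] <- r$equality$Ei[i]
      props[[paste0("class_", m)]] <- r$equality$class[i]
      props[[paste0("lisa_", m)]] <- r$lisa$label[i]
    }
    feature(
      geometry = list(type = "Polygon", coordinates = list(list(
        c(grid$x0[i], grid$y0[i]), c(grid$x1[i], grid$y0[i]),
        c(grid$x1[i], grid$y1[i]), c(grid$x0[i], grid$y1[i]),
        c(grid$x0[i], grid$y0[i])))),
      properties = props
    )
  })
  fc(feats)
}

render_report <- function(run) {
  out <- c("# Park accessibility and equity report", "")
  for (m in names(run$results)) {
    r <- run$results[[m]]
    out <- c(out, sprintf("## Mode: %s", m), "",
             "Zonal accessibility summary (populated cells):", "```",
             utils::capture.output(print(r$summary, row.names = FALSE,
                                         digits = 4)),
             "```", "",
             sprintf("Gini coefficient: %.4f (%s)", r$lorenz$gini,
                     r$lorenz$band),
             sprintf("Equality classes: %s",
                     paste(sprintf("%s=%d", names(table(r$equality$class)),
                                   as.integer(table(r$equality$class))),
                           collapse = ", ")),
             sprintf("LISA labels: %s",
                     paste(sprintf("%s=%d", names(table(r$lisa$label)),
                                   as.integer(table(r$lisa$label))),
                           collapse = ", ")),
             "")
  }
  out
}
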