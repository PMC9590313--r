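# Readers and writers for the city bundle. Geometries travel as GeoJSON
# FeatureCollections on a single planar frame (coordinates are metres, not
# lon/lat); tabular layers as CSV; run parameters as YAML.

feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry, properties = properties)
}

fc <- function(features) list(type = "FeatureCollection", features = features)

write_geojson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
}

read_geojson <- function(path) {
  out <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(out$type, "FeatureCollection"))
    stop(basename(path), ": not a GeoJSON FeatureCollection")
  out
}

square_ring <- function(cx, cy, area_m2) {
  h <- sqrt(area_m2) / 2
  list(list(
    c(cx - h, cy - h), c(cx + h, cy - h), c(cx + h, cy + h),
    c(cx - h, cy + h), c(cx - h, cy - h)
  ))
}

parks_to_geojson <- function(parks, entrances) {
  feats <- lapply(seq_len(nrow(parks)), function(i) {
    p <- parks[i, ]
    ent <- entrances[entrances$park_id == p$park_id, c("x", "y"), drop = FALSE]
    feature(
      geometry = list(type = "Polygon",
                      coordinates = square_ring(p$cx, p$cy, p$area_m2)),
      properties = list(
        park_id = p$park_id, category = p$category, area_m2 = p$area_m2,
        service_radius_m = p$service_radius_m,
        entrances = lapply(seq_len(nrow(ent)), function(k) c(ent$x[k], ent$y[k]))
      )
    )
  })
  fc(feats)
}

parks_from_geojson <- function(gj, file = "parks.geojson") {
  n <- length(gj$features)
  if (!n) stop(file, ": no park features")
  rows <- vector("list", n); ents <- vector("list", n)
  for (i in seq_len(n)) {
    f <- gj$features[[i]]; pr <- f$properties
    for (fld in c("park_id", "category", "area_m2"))
      if (is.null(pr[[fld]])) stop(file, ": feature ", i, " missing property '", fld, "'")
    if (!(pr$category %in% PARK_CATEGORIES))
      stop(file, ": feature ", i, " has unknown category '", pr$category, "'")
    if (is.null(pr$entrances) || !length(pr$entrances))
      stop(file, ": park ", pr$park_id, " has zero entrances")
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(c) c[[1]], 0); ys <- vapply(ring, function(c) c[[2]], 0)
    rows[[i]] <- data.frame(
      park_id = pr$park_id, category = pr$category, area_m2 = pr$area_m2,
      cx = mean(xs[-length(xs)]), cy = mean(ys[-length(ys)]),
      service_radius_m = if (is.null(pr$service_radius_m))
        assign_service_radius(pr$category, pr$area_m2) else pr$service_radius_m,
      stringsAsFactors = FALSE
    )
    ents[[i]] <- data.frame(
      park_id = pr$park_id,
      x = vapply(pr$entrances, function(e) e[[1]], 0),
      y = vapply(pr$entrances, function(e) e[[2]], 0)
    )
  }
  list(parks = do.call(rbind, rows), entrances = do.call(rbind, ents))
}

pois_to_geojson <- function(pois) {
  feats <- lapply(seq_len(nrow(pois)), function(i) {
    feature(
      geometry = list(type = "Point", coordinates = c(pois$x[i], pois$y[i])),
      properties = list(poi_id = pois$poi_id[i], category = pois$category[i],
                        residential = isTRUE_vec(pois$residential[i]))
    )
  })
  fc(feats)
}

pois_from_geojson <- function(gj, file = "pois.geojson") {
  n <- length(gj$features)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- gj$features[[i]]; pr <- f$properties
    if (is.null(pr$category) || !(pr$category %in% POI_CATEGORIES))
      stop(file, ": feature ", i, " category '",
           if (is.null(pr$category)) "<missing>" else pr$category,
           "' not in the 13-label set")
    rows[[i]] <- data.frame(
      poi_id = pr$poi_id, x = f$geometry$coordinates[[1]],
      y = f$geometry$coordinates[[2]], category = pr$category,
      residential = isTRUE(pr$residential), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Save a city model to a directory
#'
#' Writes the bundle consumed by \code{\link{load_city}}:
#' \code{parks.geojson}, \code{pois.geojson}, \code{grid.csv},
#' \code{network_nodes.csv}, \code{network_edges.csv},
#' \code{greenview.csv} and \code{config.yaml} (grid geometry + frame note).
#'
#' @param city a \code{city_model}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_city <- function(city, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_geojson(parks_to_geojson(city$parks, city$entrances),
                file.path(dir, "parks.geojson"))
  write_geojson(pois_to_geojson(city$pois), file.path(dir, "pois.geojson"))
  utils::write.csv(city$grid, file.path(dir, "grid.csv"), row.names = FALSE)
  utils::write.csv(city$network$nodes, file.path(dir, "network_nodes.csv"),
                   row.names = FALSE)
  utils::write.csv(city$network$edges, file.path(dir, "network_edges.csv"),
                   row.names = FALSE)
  utils::write.csv(city$greenview, file.path(dir, "greenview.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(
    extent = as.numeric(attr(city$grid, "extent")),
    cell_size_m = attr(city$grid, "cell_size_m"),
    crs_note = city$crs_note
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Load a city model from a directory
#'
#' Reads the bundle written by \code{\link{save_city}} and re-validates
#' every invariant. Parse errors name the offending file and field.
#'
#' @param dir directory containing the city bundle.
#' @param validate run \code{\link{validate_city}} (default TRUE).
#' @return a \code{city_model}.
#' @export
load_city <- function(dir, validate = TRUE) {
  need <- c("parks.geojson", "pois.geojson", "grid.csv",
            "network_nodes.csv", "network_edges.csv", "greenview.csv",
            "config.yaml")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("city bundle at ", dir, " is missing: ", paste(missing, collapse = ", "))

  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  grid <- utils::read.csv(file.path(dir, "grid.csv"), stringsAsFactors = FALSE)
  grid$zone <- as.character(grid$zone)
  attr(grid, "extent") <- as.numeric(cfg$extent)
  attr(grid, "cell_size_m") <- cfg$cell_size_m
  attr(grid, "dims") <- c(
    nx = ceiling((cfg$extent[3] - cfg$extent[1]) / cfg$cell_size_m),
    ny = ceiling((cfg$extent[4] - cfg$extent[2]) / cfg$cell_size_m)
  )

  pk <- parks_from_geojson(read_geojson(file.path(dir, "parks.geojson")))
  pois <- pois_from_geojson(read_geojson(file.path(dir, "pois.geojson")))
  nodes <- utils::read.csv(file.path(dir, "network_nodes.csv"))
  edges <- utils::read.csv(file.path(dir, "network_edges.csv"),
                           stringsAsFactors = FALSE)
  gv <- utils::read.csv(file.path(dir, "greenview.csv"))

  city <- structure(
    list(grid = grid, parks = pk$parks, entrances = pk$entrances,
         network = list(nodes = nodes, edges = edges), pois = pois,
         greenview = gv,
         crs_note = if (is.null(cfg$crs_note)) "local planar metres" else cfg$crs_note),
    class = "city_model"
  )
  if (validate) validate_city(city)
  city
}
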