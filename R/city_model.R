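# Domain containers for the analysis: demand grid, parks, road network,
# points of interest (POIs), and street green-view samples, all on one
# planar metric coordinate frame.

#' Park categories
#'
#' The four park categories recognised by the analysis, following the
#' Chinese Urban Green Space Classification Standard vocabulary used in
#' park-planning practice.
#' @export
PARK_CATEGORIES <- c("comprehensive", "special", "community", "street")

#' Service-function POI categories
#'
#' The closed set of 13 service-function categories used for the Shannon
#' diversity of a park's surroundings.
#' @export
POI_CATEGORIES <- c(
  "scenic_spot", "catering", "public_facility", "transport", "company",
  "shopping", "accommodation", "education_culture", "government",
  "healthcare", "sports_leisure", "life_service", "financial"
)

#' Build a demand grid over a rectangular extent
#'
#' Tiles the extent with square cells of side \code{cell_size_m}, row-major
#' from the south-west corner. Cells on the east/north edge that do not fit
#' entirely inside the extent are clipped, included, and flagged as partial
#' with their true area recorded. Cell ids are 0-based, row-major.
#'
#' @param extent numeric vector \code{c(xmin, ymin, xmax, ymax)} in metres.
#' @param cell_size_m cell side length in metres (default 100, the
#'   resolution used for grid-based community management).
#' @return data.frame with one row per cell: \code{cell_id}, \code{row},
#'   \code{col} (0-based), centroid \code{x}, \code{y}, bounds
#'   \code{x0,y0,x1,y1}, \code{area_m2}, \code{partial}, plus empty
#'   \code{zone} and zero \code{population} columns. Grid geometry is also
#'   attached as attributes \code{extent} and \code{cell_size_m}.
#' @export
build_grid <- function(extent, cell_size_m = 100) {
  if (!is.numeric(extent) || length(extent) != 4)
    stop("extent must be numeric c(xmin, ymin, xmax, ymax)")
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1 || cell_size_m <= 0)
    stop("cell_size_m must be a single positive number")
  xmin <- extent[1]; ymin <- extent[2]; xmax <- extent[3]; ymax <- extent[4]
  if (xmax <= xmin || ymax <= ymin) stop("extent is degenerate")

  nx <- ceiling((xmax - xmin) / cell_size_m)
  ny <- ceiling((ymax - ymin) / cell_size_m)
  col <- rep(seq_len(nx) - 1L, times = ny)
  row <- rep(seq_len(ny) - 1L, each = nx)
  x0 <- xmin + col * cell_size_m
  y0 <- ymin + row * cell_size_m
  x1 <- pmin(x0 + cell_size_m, xmax)
  y1 <- pmin(y0 + cell_size_m, ymax)
  grid <- data.frame(
    cell_id = row * nx + col,
    row = row, col = col,
    x = (x0 + x1) / 2, y = (y0 + y1) / 2,
    x0 = x0, y0 = y0, x1 = x1, y1 = y1,
    area_m2 = (x1 - x0) * (y1 - y0),
    partial = (x1 - x0) < cell_size_m - 1e-9 | (y1 - y0) < cell_size_m - 1e-9,
    zone = NA_character_,
    population = 0,
    stringsAsFactors = FALSE
  )
  attr(grid, "extent") <- c(xmin, ymin, xmax, ymax)
  attr(grid, "cell_size_m") <- cell_size_m
  attr(grid, "dims") <- c(nx = nx, ny = ny)
  grid
}

#' Assign ring-zone labels to grid cells by centroid distance from a centre
#'
#' @param grid demand grid from \code{\link{build_grid}}.
#' @param center numeric \code{c(x, y)}; defaults to the extent centre.
#' @param radii increasing vector of ring radii in metres; cells beyond the
#'   last radius fall in the outermost ring.
#' @return the grid with \code{zone} filled as \code{"ring-1"}, ...
#' @export
assign_ring_zones <- function(grid, center = NULL, radii = c(800, 1700)) {
  ext <- attr(grid, "extent")
  if (is.null(center)) center <- c((ext[1] + ext[3]) / 2, (ext[2] + ext[4]) / 2)
  if (is.unsorted(radii, strictly = TRUE)) stop("radii must be strictly increasing")
  d <- sqrt((grid$x - center[1])^2 + (grid$y - center[2])^2)
  grid$zone <- paste0("ring-", findInterval(d, radii) + 1L)
  grid
}

#' Redistribute zone population totals onto grid cells by residential POIs
#'
#' Implements the secondary spatial distribution of census populations:
#' within each zone, a cell receives population proportional to its count
#' of residential POIs; zones without any residential POI fall back to a
#' uniform allocation across their cells. Zone totals are conserved exactly
#' (largest-remainder rounding when integer output is requested).
#'
#' @param zone_totals named numeric vector of persons per zone label.
#' @param grid demand grid whose cells carry zone labels in \code{zone}.
#' @param pois POI data.frame with \code{x}, \code{y} and logical
#'   \code{residential}; only residential POIs are used.
#' @param integer logical; round to whole persons by largest remainder.
#' @return the grid with \code{population} filled.
#' @export
redistribute_population <- function(zone_totals, grid, pois, integer = TRUE) {
  if (is.null(names(zone_totals)) || any(!nzchar(names(zone_totals))))
    stop("zone_totals must be a named vector")
  if (any(!is.finite(zone_totals)) || any(zone_totals < 0))
    stop("zone totals must be finite and non-negative")
  if (any(is.na(grid$zone))) stop("every grid cell needs a zone label")
  missing_zone <- setdiff(unique(grid$zone), names(zone_totals))
  if (length(missing_zone))
    stop("no zone total for zone(s): ", paste(missing_zone, collapse = ", "))

  res <- pois[isTRUE_vec(pois$residential), , drop = FALSE]
  counts <- count_points_in_cells(grid, res$x, res$y)

  pop <- numeric(nrow(grid))
  for (z in names(zone_totals)) {
    idx <- which(grid$zone == z)
    if (!length(idx)) next
    w <- counts[idx]
    if (sum(w) == 0) w <- rep(1, length(idx))      # uniform fallback
    share <- zone_totals[[z]] * w / sum(w)
    pop[idx] <- if (integer) largest_remainder(share, round(zone_totals[[z]])) else share
  }
  grid$population <- pop
  grid
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

# Count points falling in each grid cell (half-open cells [x0, x1)).
count_points_in_cells <- function(grid, px, py) {
  counts <- numeric(nrow(grid))
  if (!length(px)) return(counts)
  ext <- attr(grid, "extent"); cs <- attr(grid, "cell_size_m")
  dims <- attr(grid, "dims")
  if (!is.null(ext) && !is.null(cs) && !is.null(dims)) {
    col <- floor((px - ext[1]) / cs); row <- floor((py - ext[2]) / cs)
    ok <- col >= 0 & col < dims["nx"] & row >= 0 & row < dims["ny"]
    id <- row[ok] * dims[["nx"]] + col[ok]
    tab <- table(match(id, grid$cell_id))
    counts[as.integer(names(tab))] <- as.numeric(tab)
  } else {
    for (k in seq_along(px)) {
      hit <- which(px[k] >= grid$x0 & px[k] < grid$x1 &
                   py[k] >= grid$y0 & py[k] < grid$y1)
      counts[hit] <- counts[hit] + 1
    }
  }
  counts
}

# Apportion a real-valued share vector to integers summing to `total`
# (largest-remainder / Hamilton method).
largest_remainder <- function(share, total) {
  fl <- floor(share)
  rem <- share - fl
  need <- as.integer(round(total - sum(fl)))
  if (need > 0) {
    up <- order(rem, decreasing = TRUE)[seq_len(need)]
    fl[up] <- fl[up] + 1
  }
  fl
}

#' Service radius of a park
#'
#' Comprehensive parks and special parks larger than 5000 m2 serve 500 m;
#' smaller special parks, community parks and street parks serve 300 m
#' (the "300 m to see green, 500 m to see a park" planning rule). A special
#' park of exactly 5000 m2 is assigned 500 m.
#'
#' @param category park category, one of \code{\link{PARK_CATEGORIES}};
#'   vectorised.
#' @param area_m2 park area in square metres.
#' @param tie_up logical; assign the 5000 m2 boundary upward to 500 m
#'   (default TRUE).
#' @return service radius in metres (300 or 500).
#' @export
assign_service_radius <- function(category, area_m2, tie_up = TRUE) {
  bad <- !(category %in% PARK_CATEGORIES)
  if (any(bad)) stop("unknown park category: ", paste(unique(category[bad]), collapse = ", "))
  if (any(!is.finite(area_m2)) || any(area_m2 <= 0)) stop("area_m2 must be positive")
  big_special <- category == "special" &
    (area_m2 > 5000 | (tie_up & area_m2 == 5000))
  ifelse(category == "comprehensive" | big_special, 500, 300)
}

#' Assemble and validate a city model
#'
#' Bundles the demand grid, parks (with entrances), road network, POIs and
#' green-view samples into a validated \code{city_model} object. All
#' geometries must share one planar metric coordinate frame.
#'
#' @param grid demand grid (see \code{\link{build_grid}}).
#' @param parks data.frame: \code{park_id}, \code{category},
#'   \code{area_m2}, centroid \code{cx}, \code{cy} and optionally
#'   \code{service_radius_m} (filled from
#'   \code{\link{assign_service_radius}} if absent).
#' @param entrances data.frame: \code{park_id}, \code{x}, \code{y}; every
#'   park needs at least one entrance.
#' @param network list with \code{nodes} (\code{node_id,x,y}) and
#'   \code{edges} (\code{u,v,length_m,road_class}).
#' @param pois data.frame: \code{poi_id,x,y,category,residential}.
#' @param greenview data.frame:
#'   \code{sample_id,x,y,f0,f90,f180,f270}, fractions in [0,1] for the four
#'   compass headings.
#' @param crs_note free-text note on the coordinate frame.
#' @return object of class \code{city_model}.
#' @export
city_model <- function(grid, parks, entrances, network, pois, greenview,
                       crs_note = "local planar metres") {
  if (!is.data.frame(parks) || !nrow(parks)) stop("parks must be a non-empty data.frame")
  if (is.null(parks$service_radius_m))
    parks$service_radius_m <- assign_service_radius(parks$category, parks$area_m2)
  city <- structure(
    list(grid = grid, parks = parks, entrances = entrances,
         network = network, pois = pois, greenview = greenview,
         crs_note = crs_note),
    class = "city_model"
  )
  validate_city(city)
  city
}

#' Validate a city model
#'
#' Checks every container invariant: unique ids, closed category sets,
#' positive areas (>= 1000 m2, the 0.1 ha floor for listed parks), at
#' least one entrance per park, positive finite edge lengths with no
#' self-loops, green-view fractions in [0,1], and non-negative finite
#' populations.
#'
#' @param city a \code{city_model}.
#' @return the city, invisibly; errors describe the offending field.
#' @export
validate_city <- function(city) {
  g <- city$grid
  if (anyDuplicated(g$cell_id)) stop("grid: duplicate cell_id")
  if (any(!is.finite(g$population)) || any(g$population < 0))
    stop("grid: population must be finite and non-negative")

  p <- city$parks
  if (anyDuplicated(p$park_id)) stop("parks: duplicate park_id")
  if (any(!(p$category %in% PARK_CATEGORIES)))
    stop("parks: category outside {", paste(PARK_CATEGORIES, collapse = ", "), "}")
  if (any(p$area_m2 < 1000))
    stop("parks: area_m2 below the 1000 m2 (0.1 ha) floor")
  if (any(!(p$service_radius_m %in% c(300, 500))))
    stop("parks: service_radius_m must be 300 or 500")
  n_ent <- table(factor(city$entrances$park_id, levels = p$park_id))
  if (any(n_ent == 0))
    stop("parks: park(s) without entrances: ",
         paste(p$park_id[n_ent == 0], collapse = ", "))

  net <- city$network
  if (any(net$edges$u == net$edges$v)) stop("network: self-loop edge")
  if (any(!is.finite(net$edges$length_m)) || any(net$edges$length_m <= 0))
    stop("network: edge lengths must be positive and finite")
  if (!all(c(net$edges$u, net$edges$v) %in% net$nodes$node_id))
    stop("network: edge endpoint not in node table")

  if (nrow(city$pois) && any(!(city$pois$category %in% POI_CATEGORIES)))
    stop("pois: category outside the 13-label set")

  gv <- city$greenview
  fr <- as.matrix(gv[, c("f0", "f90", "f180", "f270")])
  if (nrow(gv) && (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)))
    stop("greenview: vegetation fractions must lie in [0, 1]")
  invisible(city)
}

#' @export
print.city_model <- function(x, ...) {
  dims <- attr(x$grid, "dims")
  cat("<city_model>\n")
  cat(sprintf("  grid      : %d cells (%s x %s of %g m), population %s\n",
              nrow(x$grid), dims[["nx"]], dims[["ny"]],
              attr(x$grid, "cell_size_m"),
              format(sum(x$grid$population), big.mark = ",")))
  cat(sprintf("  parks     : %d (%s)\n", nrow(x$parks),
              paste(sprintf("%s %d", names(table(x$parks$category)),
                            as.integer(table(x$parks$category))), collapse = ", ")))
  cat(sprintf("  network   : %d nodes, %d edges\n",
              nrow(x$network$nodes), nrow(x$network$edges)))
  cat(sprintf("  pois      : %d (%d residential-flagged)\n",
              nrow(x$pois), sum(isTRUE_vec(x$pois$residential))))
  cat(sprintf("  greenview : %d samples\n", nrow(x$greenview)))
  cat(sprintf("  frame     : %s\n", x$crs_note))
  invisible(x)
}
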