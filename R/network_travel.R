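# Road-network travel: mode definitions, origin-destination travel times
# from demand cells to park entrances, network service areas around parks,
# and the survey arithmetic behind the psychological time thresholds.

#' Travel mode definition
#'
#' A mode couples an average speed with a psychological time threshold t0
#' (the maximum time people are willing to spend reaching a park; beyond
#' it the decay weight is zero). Defaults are walking 5 km/h / 30 min,
#' cycling 15 km/h / 25 min, driving 40 km/h / 30 min.
#'
#' @param name one of \code{"walking"}, \code{"cycling"}, \code{"driving"}.
#' @param speed_kmh average speed in km/h; default by mode.
#' @param t0_min psychological threshold in minutes; default by mode.
#' @param road_classes optional character allow-list of edge
#'   \code{road_class} values usable by this mode; NULL (default) means
#'   every edge is usable by every mode.
#' @return a \code{travel_mode} list.
#' @export
travel_mode <- function(name = c("walking", "cycling", "driving"),
                        speed_kmh = NULL, t0_min = NULL,
                        road_classes = NULL) {
  name <- match.arg(name)
  defaults <- list(walking = c(5, 30), cycling = c(15, 25), driving = c(40, 30))
  if (is.null(speed_kmh)) speed_kmh <- defaults[[name]][1]
  if (is.null(t0_min)) t0_min <- defaults[[name]][2]
  if (speed_kmh <= 0 || t0_min <= 0) stop("speed and t0 must be positive")
  structure(list(name = name, speed_kmh = speed_kmh, t0_min = t0_min,
                 road_classes = road_classes), class = "travel_mode")
}

#' Default psychological time thresholds (minutes) per mode
#' @export
DEFAULT_THRESHOLDS <- c(walking = 30, cycling = 25, driving = 30)

network_graph <- function(network, road_classes = NULL) {
  edges <- network$edges
  if (!nrow(edges)) stop("network has no edges")
  if (!is.null(road_classes))
    edges <- edges[edges$road_class %in% road_classes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$u), to = as.character(edges$v)),
    directed = FALSE,
    vertices = data.frame(name = as.character(network$nodes$node_id))
  )
  igraph::E(g)$weight <- edges$length_m
  g
}

# Nearest network node for each query point; chunked to bound memory.
snap_points <- function(nodes, px, py, chunk = 1024L) {
  n <- length(px)
  idx <- integer(n); d <- numeric(n)
  nx <- nodes$x; ny <- nodes$y
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(px[s:e], nx, "-")^2 + outer(py[s:e], ny, "-")^2
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    d[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1L), j)])
  }
  list(node = idx, dist = d)
}

#' Origin-destination travel times from demand cells to parks
#'
#' Snaps each origin (cell centroid) and each park entrance to its nearest
#' network node — the snap distance is traversed on-network at mode speed —
#' and takes, per (cell, park) pair, the minimum over the park's entrances
#' of the shortest-path travel time in minutes. Pairs in different network
#' components are unreachable (\code{Inf}).
#'
#' @param network road network list (\code{nodes}, \code{edges}).
#' @param origins data.frame of origin points with \code{x}, \code{y}
#'   (typically the demand grid).
#' @param parks park table with \code{park_id}.
#' @param entrances entrance table with \code{park_id}, \code{x}, \code{y}.
#' @param mode a \code{\link{travel_mode}}.
#' @return an \code{od_matrix}: numeric matrix (origins x parks) of minutes
#'   with \code{Inf} marking unreachable pairs; attributes \code{mode},
#'   \code{park_id}, \code{cell_id}.
#' @export
od_travel_times <- function(network, origins, parks, entrances, mode) {
  stopifnot(inherits(mode, "travel_mode"))
  if (!nrow(network$edges)) stop("empty network")
  g <- network_graph(network, mode$road_classes)
  m_per_min <- mode$speed_kmh * 1000 / 60

  so <- snap_points(network$nodes, origins$x, origins$y)
  se <- snap_points(network$nodes, entrances$x, entrances$y)

  uo <- sort(unique(so$node))
  d_nodes <- igraph::distances(
    g, v = se$node, to = uo, weights = igraph::E(g)$weight,
    algorithm = "dijkstra"
  ) # entrances x unique-origin-nodes, metres
  ocol <- match(so$node, uo)

  n_o <- nrow(origins); n_p <- nrow(parks)
  tt <- matrix(Inf, n_o, n_p)
  for (j in seq_len(n_p)) {
    rows <- which(entrances$park_id == parks$park_id[j])
    # per entrance: snap(origin) + path + snap(entrance), then min
    best <- rep(Inf, n_o)
    for (r in rows) {
      len <- d_nodes[r, ocol] + so$dist + se$dist[r]
      best <- pmin(best, len)
    }
    tt[, j] <- best / m_per_min
  }
  structure(tt, class = c("od_matrix", "matrix"),
            mode = mode$name,
            park_id = parks$park_id,
            cell_id = if (!is.null(origins$cell_id)) origins$cell_id
                      else seq_len(n_o) - 1L)
}

#' @export
print.od_matrix <- function(x, ...) {
  fin <- is.finite(x)
  cat(sprintf("<od_matrix> %d origins x %d parks, mode %s\n",
              nrow(x), ncol(x), attr(x, "mode")))
  cat(sprintf("  reachable pairs: %d/%d; minutes range %.2f-%.2f\n",
              sum(fin), length(x),
              if (any(fin)) min(x[fin]) else NA, if (any(fin)) max(x[fin]) else NA))
  invisible(x)
}

#' Network service area around a park's entrances
#'
#' The set of network locations within network distance
#' \code{radius_m} of any entrance, dilated by an off-road buffer so that
#' POIs and green-view sample points standing beside a covered street are
#' counted as inside. Returns a membership predicate.
#'
#' @param network road network list.
#' @param entrances data.frame with \code{x}, \code{y} for one park.
#' @param radius_m service radius in metres (300 or 500 in the standard
#'   configuration).
#' @param offroad_buffer_m dilation in metres (default 20).
#' @return object of class \code{service_area}; call
#'   \code{sa$contains(x, y)} for a logical vector, or use
#'   \code{predict(sa, points)}.
#' @export
network_service_area <- function(network, entrances, radius_m,
                                 offroad_buffer_m = 20) {
  if (radius_m <= 0) stop("radius_m must be positive")
  g <- network_graph(network)
  se <- snap_points(network$nodes, entrances$x, entrances$y)
  d_mat <- igraph::distances(g, v = se$node, weights = igraph::E(g)$weight)
  d_node <- apply(d_mat + se$dist, 2, min)   # network metres from nearest entrance
  names(d_node) <- igraph::V(g)$name

  nd <- network$nodes
  du <- d_node[as.character(network$edges$u)]
  dv <- d_node[as.character(network$edges$v)]
  len <- network$edges$length_m
  keep <- which(du <= radius_m | dv <= radius_m)

  # covered portion of each kept edge, as fractions of the segment
  segs <- do.call(rbind, lapply(keep, function(k) {
    fu <- max(0, min(1, (radius_m - du[k]) / len[k]))   # from u end
    fv <- max(0, min(1, (radius_m - dv[k]) / len[k]))   # from v end
    iu <- nd[match(network$edges$u[k], nd$node_id), ]
    iv <- nd[match(network$edges$v[k], nd$node_id), ]
    out <- NULL
    if (fu + fv >= 1) {            # whole edge covered
      out <- cbind(a = 0, b = 1)
    } else {
      if (fu > 0) out <- rbind(out, cbind(a = 0, b = fu))
      if (fv > 0) out <- rbind(out, cbind(a = 1 - fv, b = 1))
    }
    if (is.null(out)) return(NULL)
    cbind(x1 = iu$x, y1 = iu$y, x2 = iv$x, y2 = iv$y, out)
  }))

  ent <- entrances[se$dist <= radius_m, c("x", "y"), drop = FALSE]
  contains <- function(x, y) {
    inside <- rep(FALSE, length(x))
    for (k in seq_len(nrow(ent)))
      inside <- inside |
        (sqrt((x - ent$x[k])^2 + (y - ent$y[k])^2) <= offroad_buffer_m)
    if (!is.null(segs)) for (k in seq_len(nrow(segs))) {
      s <- segs[k, ]
      dx <- s["x2"] - s["x1"]; dy <- s["y2"] - s["y1"]
      L2 <- dx * dx + dy * dy
      t <- if (L2 > 0) ((x - s["x1"]) * dx + (y - s["y1"]) * dy) / L2 else 0
      t <- pmin(pmax(t, s["a"]), s["b"])
      d <- sqrt((x - (s["x1"] + t * dx))^2 + (y - (s["y1"] + t * dy))^2)
      inside <- inside | (d <= offroad_buffer_m)
    }
    inside
  }
  structure(list(contains = contains, radius_m = radius_m,
                 offroad_buffer_m = offroad_buffer_m),
            class = "service_area")
}

#' @export
predict.service_area <- function(object, points, ...) {
  object$contains(points$x, points$y)
}

round_half_up <- function(x) floor(x + 0.5)

#' Psychological time thresholds from travel-survey bins
#'
#' For each (park category, mode), the mean stated visit time is the sum of
#' bin midpoint times response share (the open top bin is represented by
#' its fixed 60-minute midpoint). Per mode, the threshold t0 is the maximum
#' of the four category means, rounded to the nearest whole minute
#' (half up).
#'
#' @param survey data.frame with columns \code{mode}, \code{category},
#'   \code{midpoint_min}, \code{share}; shares per (category, mode) must
#'   sum to 1.
#' @return named numeric vector of t0 minutes per mode.
#' @export
threshold_from_survey <- function(survey) {
  need <- c("mode", "category", "midpoint_min", "share")
  if (!all(need %in% names(survey)))
    stop("survey needs columns: ", paste(need, collapse = ", "))
  tot <- stats::aggregate(share ~ mode + category, survey, sum)
  if (any(abs(tot$share - 1) > 1e-9))
    stop("survey shares must sum to 1 within each (category, mode)")
  survey$wt <- survey$midpoint_min * survey$share
  means <- stats::aggregate(wt ~ mode + category, survey, sum)
  t0 <- tapply(means$wt, means$mode, max)
  out <- round_half_up(as.numeric(t0))
  names(out) <- names(t0)
  out
}
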