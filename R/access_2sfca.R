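# The supply-demand adjusted two-step floating catchment area core:
# Gaussian time decay, Huff selection probabilities, park supply-demand
# ratios, the per-cell accessibility surface, and zonal summaries.

#' Gaussian travel-time decay
#'
#' g(t) = (exp(-(t/t0)^2 / 2) - exp(-1/2)) / (1 - exp(-1/2)) for t <= t0,
#' and 0 beyond the threshold; strictly decreasing from 1 at t = 0 to 0 at
#' t = t0, and continuous at the threshold.
#'
#' @param t travel time in minutes (vectorised; \code{Inf} allowed for
#'   unreachable pairs and maps to 0).
#' @param t0 psychological time threshold in minutes.
#' @return decay weight in [0, 1].
#' @export
gaussian_decay <- function(t, t0) {
  if (t0 <= 0) stop("t0 must be positive")
  if (any(t < 0, na.rm = TRUE)) stop("travel times must be non-negative")
  eh <- exp(-0.5)
  g <- (exp(-0.5 * (t / t0)^2) - eh) / (1 - eh)
  g[t > t0] <- 0
  g
}

#' Decay specification
#'
#' Couples the time threshold with the Huff weight variant. The default
#' variant weights each park by attractiveness times Gaussian decay,
#' S_j * g(t_ij); \code{gaussian_times_time} takes the literal
#' S_j * t_ij * g(t_ij) reading and \code{gaussian_over_time} the inverse
#' S_j / max(t_ij, 0.1) * g(t_ij), both kept for sensitivity analysis.
#'
#' @param t0_min threshold in minutes.
#' @param huff_variant weight variant.
#' @return a \code{decay_spec} list.
#' @export
decay_spec <- function(t0_min,
                       huff_variant = c("gaussian", "gaussian_over_time",
                                        "gaussian_times_time")) {
  if (t0_min <= 0) stop("t0_min must be positive")
  structure(list(t0_min = t0_min, huff_variant = match.arg(huff_variant)),
            class = "decay_spec")
}

huff_weights <- function(Sj, tt, spec) {
  G <- gaussian_decay(tt, spec$t0_min)
  w <- switch(spec$huff_variant,
    gaussian            = sweep(G, 2, Sj, "*"),
    gaussian_over_time  = sweep(G / pmax(tt, 0.1), 2, Sj, "*"),
    gaussian_times_time = sweep(G * tt, 2, Sj, "*")
  )
  w[tt > spec$t0_min | !is.finite(tt)] <- 0
  w
}

#' Huff selection-probability matrix
#'
#' For each demand cell, the probability of choosing each reachable park
#' (travel time within the threshold) is its Huff weight divided by the
#' sum of weights over all reachable parks. Rows with no reachable park —
#' or whose reachable parks all have zero weight — are all-zero (the
#' latter with a warning).
#'
#' @param supply park supply table with composite \code{Sj} (see
#'   \code{\link{park_supply}}).
#' @param od an \code{od_matrix} of minutes (cells x parks).
#' @param spec a \code{\link{decay_spec}}.
#' @return matrix of probabilities (cells x parks), rows summing to 1 or 0.
#' @export
huff_matrix <- function(supply, od, spec) {
  if (ncol(od) != nrow(supply)) stop("supply and OD matrix are not aligned")
  w <- huff_weights(supply$Sj, unclass(od), spec)
  rs <- rowSums(w)
  reachable <- rowSums(unclass(od) <= spec$t0_min) > 0
  if (any(reachable & rs == 0))
    warning("cells with reachable parks but all-zero Huff weights; ",
            "their rows are left at zero")
  prob <- w / ifelse(rs > 0, rs, 1)
  dimnames(prob) <- NULL
  prob
}

#' Park supply-demand ratios (first 2SFCA stage)
#'
#' Each park's weighted demand is D_j = sum over cells within the
#' threshold of Prob_ij * P_i * g(t_ij); the ratio is R_j = S_j / D_j,
#' with R_j = 0 for parks drawing no weighted demand (this convention
#' makes the supply-conservation identity exact).
#'
#' @param supply park supply table with \code{Sj} (and \code{area_m2} via
#'   \code{supply_scale}).
#' @param population per-cell population vector P_i.
#' @param prob Huff probability matrix.
#' @param od travel-time matrix (minutes).
#' @param spec a \code{\link{decay_spec}}.
#' @param supply_scale \code{"dimensionless"} uses S_j as is;
#'   \code{"area"} multiplies S_j by park area so R_j is in m2/person.
#' @param area_m2 park areas, required when \code{supply_scale = "area"}.
#' @return data.frame with \code{park_id}, effective supply \code{Sj},
#'   demand \code{Dj}, ratio \code{Rj}.
#' @export
supply_demand_ratios <- function(supply, population, prob, od, spec,
                                 supply_scale = c("dimensionless", "area"),
                                 area_m2 = NULL) {
  supply_scale <- match.arg(supply_scale)
  if (any(!is.finite(population)) || any(population < 0))
    stop("population must be finite and non-negative")
  Sj <- supply$Sj
  if (supply_scale == "area") {
    if (is.null(area_m2)) stop("area_m2 required for supply_scale = 'area'")
    Sj <- Sj * area_m2
  }
  G <- gaussian_decay(unclass(od), spec$t0_min)
  G[unclass(od) > spec$t0_min | !is.finite(unclass(od))] <- 0
  Dj <- colSums(prob * population * G)
  Rj <- ifelse(Dj > 0, Sj / Dj, 0)
  data.frame(park_id = supply$park_id, Sj = Sj, Dj = Dj, Rj = Rj)
}

#' Cell accessibility scores (second 2SFCA stage)
#'
#' A_i = sum over parks within the threshold of Prob_ij * R_j * g(t_ij).
#' A cell with no reachable park scores exactly 0.
#'
#' @param prob Huff probability matrix (cells x parks).
#' @param ratios ratio table from \code{\link{supply_demand_ratios}}.
#' @param od travel-time matrix (minutes).
#' @param spec a \code{\link{decay_spec}}.
#' @return numeric vector A_i per cell.
#' @export
accessibility_scores <- function(prob, ratios, od, spec) {
  G <- gaussian_decay(unclass(od), spec$t0_min)
  G[unclass(od) > spec$t0_min | !is.finite(unclass(od))] <- 0
  as.numeric((prob * G) %*% ratios$Rj)
}

#' Zonal summary of an accessibility surface
#'
#' Min, max, mean, standard deviation and underserved share of A_i over
#' populated cells (P_i > 0), per zone and overall ("ALL"). The
#' underserved share is the percentage of populated cells with A_i = 0;
#' the SD is population-unweighted.
#'
#' @param A accessibility vector.
#' @param grid demand grid with \code{zone} and \code{population}.
#' @return data.frame with one row per zone plus an ALL row.
#' @export
zone_summary <- function(A, grid) {
  stopifnot(length(A) == nrow(grid))
  pop_ok <- grid$population > 0
  zones <- c("ALL", sort(unique(grid$zone)))
  rows <- lapply(zones, function(z) {
    sel <- pop_ok & (z == "ALL" | grid$zone == z)
    if (!any(sel)) {
      warning("zone ", z, " has no populated cells; returning NA row")
      return(data.frame(zone = z, n_cells = 0L, min = NA_real_,
                        max = NA_real_, mean = NA_real_, sd = NA_real_,
                        underserved_pct = NA_real_))
    }
    a <- A[sel]
    data.frame(zone = z, n_cells = sum(sel), min = min(a), max = max(a),
               mean = mean(a), sd = stats::sd(a),
               underserved_pct = 100 * mean(a == 0))
  })
  do.call(rbind, rows)
}

#' Fit the park-accessibility surface for one travel mode
#'
#' The central estimator: runs the full supply-demand adjusted 2SFCA chain
#' for one mode — origin-destination travel times, composite park
#' attractiveness, Huff selection probabilities, supply-demand ratios and
#' the per-cell accessibility surface — and returns a classed object with
#' print, summary and plot methods.
#'
#' @param city a \code{city_model}.
#' @param mode a \code{\link{travel_mode}} or mode name.
#' @param weights attractiveness weights \code{c(area, green, diversity)}.
#' @param huff_variant Huff weight variant (see \code{\link{decay_spec}}).
#' @param supply_scale \code{"dimensionless"} (default) or \code{"area"}
#'   for ratios in m2/person, the units used in zonal reporting practice.
#' @param t0_min optional threshold override in minutes.
#' @param supply optional precomputed \code{\link{park_supply}} table
#'   (reused across modes by the pipeline).
#' @param od optional precomputed \code{od_matrix}.
#' @return object of class \code{park_access} with elements \code{A}
#'   (cell accessibility), \code{ratios}, \code{prob}, \code{od},
#'   \code{supply}, \code{spec}, \code{mode}, \code{grid}, and the zonal
#'   \code{summary} table.
#' @export
park_access <- function(city, mode = "walking", weights = rep(1, 3) / 3,
                        huff_variant = "gaussian",
                        supply_scale = "dimensionless",
                        t0_min = NULL, supply = NULL, od = NULL) {
  if (is.character(mode)) mode <- travel_mode(mode)
  spec <- decay_spec(if (is.null(t0_min)) mode$t0_min else t0_min,
                     huff_variant)
  if (is.null(supply)) supply <- park_supply(city, weights)
  if (is.null(od))
    od <- od_travel_times(city$network, city$grid, city$parks,
                          city$entrances, mode)
  prob <- huff_matrix(supply, od, spec)
  ratios <- supply_demand_ratios(supply, city$grid$population, prob, od,
                                 spec, supply_scale,
                                 area_m2 = city$parks$area_m2)
  A <- accessibility_scores(prob, ratios, od, spec)
  structure(list(
    A = A, ratios = ratios, prob = prob, od = od, supply = supply,
    spec = spec, mode = mode, supply_scale = supply_scale,
    grid = city$grid, summary = zone_summary(A, city$grid)
  ), class = "park_access")
}

#' Supply-conservation check for a fitted accessibility surface
#'
#' The 2SFCA construction redistributes exactly the supply that attracts
#' demand: sum_i P_i A_i equals sum of effective S_j over parks with
#' positive weighted demand. Returns the relative error of that identity.
#'
#' @param fit a \code{park_access} object.
#' @return relative error (0 up to floating-point noise).
#' @export
conservation_error <- function(fit) {
  lhs <- sum(fit$grid$population * fit$A)
  rhs <- sum(fit$ratios$Sj[fit$ratios$Dj > 0])
  if (rhs == 0) return(abs(lhs))
  abs(lhs - rhs) / rhs
}

#' @export
print.park_access <- function(x, ...) {
  cat(sprintf("<park_access> mode %s (t0 = %g min, variant %s, supply %s)\n",
              x$mode$name, x$spec$t0_min, x$spec$huff_variant,
              x$supply_scale))
  pop <- x$grid$population > 0
  cat(sprintf("  %d cells (%d populated), %d parks\n",
              length(x$A), sum(pop), nrow(x$ratios)))
  cat(sprintf("  A_i: mean %.4g, max %.4g, underserved %.2f%%\n",
              mean(x$A[pop]), max(x$A), 100 * mean(x$A[pop] == 0)))
  invisible(x)
}

#' @export
summary.park_access <- function(object, ...) {
  structure(list(zonal = object$summary, mode = object$mode$name,
                 conservation = conservation_error(object)),
            class = "summary.park_access")
}

#' @export
print.summary.park_access <- function(x, ...) {
  cat(sprintf("Park accessibility, %s mode\n", x$mode))
  print(x$zonal, row.names = FALSE, digits = 4)
  cat(sprintf("Supply conservation relative error: %.2e\n", x$conservation))
  invisible(x)
}

#' Plot an accessibility surface
#'
#' Draws the A_i raster on the demand grid (base graphics).
#'
#' @param x a \code{park_access} object.
#' @param ... passed to \code{image}.
#' @export
plot.park_access <- function(x, ...) {
  dims <- attr(x$grid, "dims")
  z <- matrix(NA_real_, dims[["nx"]], dims[["ny"]])
  z[cbind(x$grid$col + 1L, x$grid$row + 1L)] <- x$A
  graphics::image(
    x = sort(unique(x$grid$x)), y = sort(unique(x$grid$y)), z = z,
    xlab = "x (m)", ylab = "y (m)",
    main = sprintf("Park accessibility (%s)", x$mode$name),
    col = grDevices::hcl.colors(64, "viridis"), useRaster = TRUE, ...
  )
  invisible(x)
}
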