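# Composite park attractiveness: park area, mean street green-view index
# in the park's network service area, and Shannon diversity of surrounding
# service functions, max-normalised and combined by weights summing to 1.

#' Shannon diversity of service-function counts
#'
#' H = -sum p_c log(p_c) over categories with positive count, where p_c is
#' the category's share of the total. A zero total gives H = 0. Natural
#' logarithm (nats) by default, so the maximum over the 13 service
#' categories is log(13).
#'
#' @param counts non-negative integer vector of per-category counts.
#' @param base logarithm base (default \code{exp(1)}).
#' @return diversity in nats (or the chosen base's units).
#' @export
shannon_diversity <- function(counts, base = exp(1)) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  tot <- sum(counts)
  if (tot == 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Service-function diversity around one park
#'
#' Counts POIs of each of the 13 categories inside the park's network
#' service area and returns their Shannon diversity.
#'
#' @param pois POI data.frame (\code{x}, \code{y}, \code{category}).
#' @param service_area a \code{\link{network_service_area}} predicate.
#' @param base logarithm base.
#' @return diversity in nats.
#' @export
park_service_diversity <- function(pois, service_area, base = exp(1)) {
  if (!nrow(pois)) return(0)
  inside <- service_area$contains(pois$x, pois$y)
  counts <- table(factor(pois$category[inside], levels = POI_CATEGORIES))
  shannon_diversity(as.numeric(counts), base = base)
}

#' Mean green-view index around one park
#'
#' Each sample's green-view index is the mean of its four heading
#' fractions; the park score is the mean over samples inside the service
#' area. With no samples inside, returns 0 with a warning.
#'
#' @param greenview sample data.frame
#'   (\code{x,y,f0,f90,f180,f270}).
#' @param service_area a \code{\link{network_service_area}} predicate.
#' @return mean green-view index in [0, 1].
#' @export
park_green_view <- function(greenview, service_area) {
  fr <- as.matrix(greenview[, c("f0", "f90", "f180", "f270")])
  if (nrow(greenview) && (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)))
    stop("green-view fractions must lie in [0, 1]")
  inside <- if (nrow(greenview))
    service_area$contains(greenview$x, greenview$y) else logical(0)
  if (!any(inside)) {
    warning("no green-view samples inside the service area; returning 0")
    return(0)
  }
  mean(rowMeans(fr[inside, , drop = FALSE]))
}

#' Composite attractiveness from raw component scores
#'
#' Each component (area Sja, green view Sjg, diversity Sjd) is divided by
#' its maximum over all parks, then the weighted sum is taken. A component
#' whose maximum is 0 contributes 0 for every park. Weights default to
#' equal thirds and must sum to 1.
#'
#' @param supply data.frame with \code{park_id}, \code{Sja}, \code{Sjg},
#'   \code{Sjd} (raw components; Sja is area in m2).
#' @param weights numeric length-3 \code{c(area, green, diversity)}.
#' @return \code{supply} with normalised columns \code{Sja_norm},
#'   \code{Sjg_norm}, \code{Sjd_norm} and composite \code{Sj} in [0, 1].
#' @export
composite_attractiveness <- function(supply, weights = rep(1, 3) / 3) {
  if (length(weights) != 3 || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be three values summing to 1")
  if (!nrow(supply)) stop("need at least one park")
  norm0 <- function(v) {
    m <- max(v)
    if (m <= 0) rep(0, length(v)) else v / m
  }
  supply$Sja_norm <- norm0(supply$Sja)
  supply$Sjg_norm <- norm0(supply$Sjg)
  supply$Sjd_norm <- norm0(supply$Sjd)
  supply$Sj <- weights[1] * supply$Sja_norm + weights[2] * supply$Sjg_norm +
    weights[3] * supply$Sjd_norm
  supply
}

#' Park supply table for a whole city
#'
#' Builds each park's network service area (at its assigned service
#' radius), computes the three attractiveness components and the weighted
#' composite.
#'
#' @param city a \code{city_model}.
#' @param weights attractiveness weights \code{c(area, green, diversity)}.
#' @param offroad_buffer_m dilation for service-area membership (metres).
#' @param quiet suppress the no-samples warnings from
#'   \code{\link{park_green_view}} (default TRUE; parks in sparsely
#'   sampled corners simply score 0).
#' @return data.frame: one row per park with raw and normalised components
#'   and \code{Sj}.
#' @export
park_supply <- function(city, weights = rep(1, 3) / 3,
                        offroad_buffer_m = 20, quiet = TRUE) {
  parks <- city$parks
  Sjg <- Sjd <- numeric(nrow(parks))
  for (j in seq_len(nrow(parks))) {
    ent <- city$entrances[city$entrances$park_id == parks$park_id[j], ]
    sa <- network_service_area(city$network, ent, parks$service_radius_m[j],
                               offroad_buffer_m)
    Sjd[j] <- park_service_diversity(city$pois, sa)
    Sjg[j] <- if (quiet)
      withCallingHandlers(park_green_view(city$greenview, sa),
                          warning = function(w) invokeRestart("muffleWarning"))
    else park_green_view(city$greenview, sa)
  }
  supply <- data.frame(park_id = parks$park_id, Sja = parks$area_m2,
                       Sjg = Sjg, Sjd = Sjd)
  supply <- composite_attractiveness(supply, weights)
  attr(supply, "weights") <- weights
  supply
}
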