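# Small deterministic fixtures built in code.

# A straight-line road: nodes every `step` metres along the x axis.
line_network <- function(length_m = 2500, step = 500) {
  xs <- seq(0, length_m, by = step)
  nodes <- data.frame(node_id = seq_along(xs) - 1L, x = xs, y = 0)
  edges <- data.frame(u = head(nodes$node_id, -1), v = tail(nodes$node_id, -1),
                      length_m = diff(xs), road_class = "street")
  list(nodes = nodes, edges = edges)
}

# Detour network: A(0,0)-B(0,100)-C(250,100)-D(250,0); walking from A to D
# is 450 m on-network but 250 m straight-line.
detour_network <- function() {
  nodes <- data.frame(node_id = 0:3,
                      x = c(0, 0, 250, 250), y = c(0, 100, 100, 0))
  edges <- data.frame(u = c(0, 1, 2), v = c(1, 2, 3),
                      length_m = c(100, 250, 100), road_class = "street")
  list(nodes = nodes, edges = edges)
}

# Hand-built 4 x 4 toy city (400 x 400 m): lattice network, two parks,
# a few POIs and green-view samples. Deterministic, no RNG.
toy_city <- function() {
  grid <- build_grid(c(0, 0, 400, 400), 100)
  grid$zone <- ifelse(grid$x < 200, "west", "east")
  grid$population <- rep(c(10, 20), length.out = nrow(grid))

  nx <- 5L
  rc <- expand.grid(c = 0:4, r = 0:4)
  nodes <- data.frame(node_id = rc$r * nx + rc$c, x = rc$c * 100, y = rc$r * 100)
  h <- expand.grid(c = 0:3, r = 0:4); v <- expand.grid(c = 0:4, r = 0:3)
  edges <- rbind(
    data.frame(u = h$r * nx + h$c, v = h$r * nx + h$c + 1L,
               length_m = 100, road_class = "street"),
    data.frame(u = v$r * nx + v$c, v = (v$r + 1L) * nx + v$c,
               length_m = 100, road_class = "street"))
  network <- list(nodes = nodes, edges = edges)

  parks <- data.frame(park_id = 1:2, category = c("comprehensive", "street"),
                      area_m2 = c(60000, 2000), cx = c(100, 300),
                      cy = c(100, 300), stringsAsFactors = FALSE)
  parks$service_radius_m <- assign_service_radius(parks$category, parks$area_m2)
  entrances <- data.frame(park_id = c(1, 1, 2),
                          x = c(0, 200, 300), y = c(100, 100, 300))

  pois <- data.frame(
    poi_id = 1:6,
    x = c(10, 110, 90, 310, 290, 390),
    y = c(100, 100, 90, 300, 310, 10),
    category = c("catering", "shopping", "catering", "healthcare",
                 "catering", "financial"),
    residential = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)

  greenview <- data.frame(
    sample_id = 1:4,
    x = c(50, 150, 250, 350), y = c(100, 100, 300, 300),
    f0 = c(0.2, 0.4, 0.1, 0.3), f90 = c(0.4, 0.4, 0.1, 0.3),
    f180 = c(0.6, 0.4, 0.1, 0.3), f270 = c(0.8, 0.4, 0.1, 0.3))

  city_model(grid, parks, entrances, network, pois, greenview,
             crs_note = "toy planar metres")
}

# Small synthetic scenario spec for fast multi-city property tests.
small_spec <- function(seed, ...) {
  scenario_spec(
    dims = c(15, 15), total_population = 8000,
    n_parks = c(comprehensive = 1, special = 1, community = 2, street = 2),
    n_shortcuts = 20, n_pois = 200, n_residential_pois = 300,
    ring_radii = c(400, 900), seed = seed, ...)
}

# O(n^2) pairwise mean-absolute-difference Gini for equal-population units.
gini_pairwise <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# Brute-force local Moran's I, double loop over the weights lists.
local_moran_bruteforce <- function(x, W) {
  n <- length(x); xb <- mean(x)
  m2 <- sum((x - xb)^2) / n
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    nb <- W$nb[[i]]
    for (k in seq_along(nb)) s <- s + W$w[[i]][k] * (x[nb[k]] - xb)
    out[i] <- (x[i] - xb) / m2 * s
  }
  out
}

# Frozen fingerprint of the baseline scenario at seed 7 (regression fixture).
GREENREACH_BASELINE7_FINGERPRINT <- c(606882, 1583.6741, 3000, 5219)
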