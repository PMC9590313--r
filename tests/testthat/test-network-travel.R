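test_that("travel time is path length over mode speed, min over entrances", {
  net <- line_network(2500, 500)
  origins <- data.frame(x = 0, y = 0)
  parks <- data.frame(park_id = 1)
  entr <- data.frame(park_id = 1, x = 2500, y = 0)
  od <- od_travel_times(net, origins, parks, entr, travel_mode("walking"))
  expect_equal(as.numeric(od), 30)                         # 2.5 km at 5 km/h
  od_c <- od_travel_times(net, origins, parks, entr, travel_mode("cycling"))
  expect_equal(as.numeric(od_c), 10)                       # 15 km/h

  # two entrances: the closer one wins
  entr2 <- data.frame(park_id = 1, x = c(2500, 1000), y = 0)
  od2 <- od_travel_times(net, origins, parks, entr2, travel_mode("walking"))
  expect_equal(as.numeric(od2), 12)                        # 1 km, not 2.5 km
})

test_that("snap distance is traversed on-network at mode speed", {
  net <- line_network(1000, 500)
  origins <- data.frame(x = 0, y = 120)   # 120 m off the nearest node
  parks <- data.frame(park_id = 1)
  entr <- data.frame(park_id = 1, x = 1000, y = 0)
  od <- od_travel_times(net, origins, parks, entr, travel_mode("walking"))
  expect_equal(as.numeric(od), (1000 + 120) / (5000 / 60))
})

test_that("disconnected origins are unreachable and symmetry holds", {
  net <- line_network(1000, 500)
  net$nodes <- rbind(net$nodes, data.frame(node_id = 99, x = 5000, y = 5000))
  net$edges <- rbind(net$edges,
                     data.frame(u = 99, v = 99 + 1L, length_m = 1,
                                road_class = "street")[0, ])
  # island node has no edges: graph needs it present but unconnected
  net$edges <- rbind(net$edges,
                     data.frame(u = 0, v = 1, length_m = 500,
                                road_class = "street"))
  origins <- data.frame(x = c(0, 5000), y = c(0, 5000))
  parks <- data.frame(park_id = 1)
  entr <- data.frame(park_id = 1, x = 1000, y = 0)
  od <- od_travel_times(net, origins, parks, entr, travel_mode("walking"))
  expect_true(is.finite(od[1, 1]))
  expect_identical(od[2, 1], Inf)

  # swapping origin and entrance leaves the time unchanged
  od_fwd <- od_travel_times(net, data.frame(x = 0, y = 0),
                            data.frame(park_id = 1),
                            data.frame(park_id = 1, x = 1000, y = 0),
                            travel_mode("walking"))
  od_rev <- od_travel_times(net, data.frame(x = 1000, y = 0),
                            data.frame(park_id = 1),
                            data.frame(park_id = 1, x = 0, y = 0),
                            travel_mode("walking"))
  expect_equal(as.numeric(od_fwd), as.numeric(od_rev))
})

test_that("adding an edge never increases travel times", {
  city <- make_scenario("baseline", seed = 11,
                        dims = c(12, 12), total_population = 5000,
                        n_parks = c(comprehensive = 1, community = 2),
                        n_pois = 100, n_residential_pois = 100,
                        n_shortcuts = 0, ring_radii = c(300, 700))
  mode <- travel_mode("walking")
  od1 <- od_travel_times(city$network, city$grid, city$parks,
                         city$entrances, mode)
  net2 <- city$network
  # add a long-range chord
  net2$edges <- rbind(net2$edges,
                      data.frame(u = 0, v = max(net2$nodes$node_id),
                                 length_m = 10, road_class = "street"))
  od2 <- od_travel_times(net2, city$grid, city$parks, city$entrances, mode)
  expect_true(all(od2 <= od1 + 1e-9))
})

test_that("shortest paths match exhaustive enumeration on a small graph", {
  # weighted 6-node graph; enumerate all simple paths by brute force
  nodes <- data.frame(node_id = 0:5,
                      x = c(0, 100, 200, 0, 100, 200),
                      y = c(0, 0, 0, 100, 100, 100))
  edges <- data.frame(
    u = c(0, 1, 3, 4, 0, 1, 2, 1),
    v = c(1, 2, 4, 5, 3, 4, 5, 3),
    length_m = c(90, 80, 120, 60, 70, 150, 110, 40),
    road_class = "street")
  adj <- lapply(0:5, function(n) {
    k <- which(edges$u == n | edges$v == n)
    data.frame(to = ifelse(edges$u[k] == n, edges$v[k], edges$u[k]),
               w = edges$length_m[k])
  })
  brute <- function(from, to) {
    best <- Inf
    rec <- function(node, dist, seen) {
      if (dist >= best) return()
      if (node == to) { best <<- dist; return() }
      a <- adj[[node + 1]]
      for (k in seq_len(nrow(a)))
        if (!(a$to[k] %in% seen)) rec(a$to[k], dist + a$w[k], c(seen, a$to[k]))
    }
    rec(from, 0, from)
    best
  }
  net <- list(nodes = nodes, edges = edges)
  mode <- travel_mode("walking")
  m_per_min <- 5000 / 60
  for (target in 0:5) {
    od <- od_travel_times(net, nodes, data.frame(park_id = 1),
                          data.frame(park_id = 1, x = nodes$x[target + 1],
                                     y = nodes$y[target + 1]), mode)
    expected <- vapply(0:5, brute, 0, to = target) / m_per_min
    expect_equal(as.numeric(od), expected, tolerance = 1e-12)
  }
})

test_that("service-area membership uses network distance, not straight line", {
  net <- detour_network()
  entr <- data.frame(x = 0, y = 0)
  sa <- network_service_area(net, entr, radius_m = 300)
  # 100 m along the street: inside
  expect_true(sa$contains(0, 100))
  # on-network point 250 m along (mid B-C edge): inside
  expect_true(sa$contains(150, 100))
  # D is 250 m straight-line but 450 m by network: outside
  expect_false(sa$contains(250, 0))
  # just off a covered street, within the 20 m dilation
  expect_true(sa$contains(15, 50))
  expect_false(sa$contains(80, 50))

  # beyond-radius along a straight street
  line <- line_network(1000, 100)
  sa2 <- network_service_area(line, data.frame(x = 0, y = 0), 500)
  expect_true(sa2$contains(400, 0))
  expect_false(sa2$contains(600, 0))
})

test_that("survey thresholds follow midpoint-share arithmetic with half-up rounding", {
  # all mass in the 25-35 bin for every category: t0 = 30
  svy <- expand.grid(mode = "walking",
                     category = c("comprehensive", "special", "community",
                                  "street"))
  svy$midpoint_min <- 30; svy$share <- 1
  expect_equal(unname(threshold_from_survey(svy)), 30)

  # category means (22.5, 18, 20, 24.4): max is 24.4, rounds to 24
  svy2 <- data.frame(
    mode = "cycling",
    category = rep(c("a", "b", "c", "d"), each = 2),
    midpoint_min = c(20, 30, 10, 30, 10, 30, 18, 34),
    share = c(0.75, 0.25, 0.6, 0.4, 0.5, 0.5, 0.6, 0.4))
  means <- c(20 * .75 + 30 * .25, 10 * .6 + 30 * .4, 20, 18 * .6 + 34 * .4)
  expect_equal(max(means), 24.4)
  expect_equal(unname(threshold_from_survey(svy2)), 24)

  # half-up rounding at .5
  svy3 <- data.frame(mode = "m", category = "c", midpoint_min = 24.5,
                     share = 1)
  expect_equal(unname(threshold_from_survey(svy3)), 25)

  # shares must sum to one
  svy3$share <- 0.9
  expect_error(threshold_from_survey(svy3), "sum to 1")

  # the standard defaults are wired into the mode constructor
  expect_equal(travel_mode("walking")$t0_min, 30)
  expect_equal(travel_mode("cycling")$t0_min, 25)
  expect_equal(travel_mode("driving")$t0_min, 30)
  expect_equal(unname(DEFAULT_THRESHOLDS), c(30, 25, 30))
  expect_equal(travel_mode("walking")$speed_kmh, 5)
  expect_equal(travel_mode("cycling")$speed_kmh, 15)
  expect_equal(travel_mode("driving")$speed_kmh, 40)
})
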