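test_that("Gaussian decay hits its endpoints and midpoint value", {
  expect_equal(gaussian_decay(0, 30), 1, tolerance = 1e-15)
  expect_equal(gaussian_decay(30, 30), 0, tolerance = 1e-15)
  # direct evaluation at t = 15, t0 = 30
  eh <- exp(-0.5)
  expect_equal(gaussian_decay(15, 30),
               (exp(-0.5 * 0.25) - eh) / (1 - eh), tolerance = 1e-12)
  expect_equal(gaussian_decay(31, 30), 0)
  expect_equal(gaussian_decay(Inf, 30), 0)
  expect_error(gaussian_decay(-1, 30), "non-negative")
  expect_error(gaussian_decay(5, 0), "positive")

  # strictly decreasing on [0, t0], continuous at the threshold
  t <- seq(0, 30, by = 0.5)
  g <- gaussian_decay(t, 30)
  expect_true(all(diff(g) < 0))
  expect_lt(gaussian_decay(30 - 1e-9, 30), 1e-8)
})

test_that("Huff probabilities normalise and follow the weights", {
  spec <- decay_spec(30)
  od1 <- matrix(c(10, Inf), 1, 2)
  sup <- data.frame(park_id = 1:2, Sj = c(0.5, 0.9))
  expect_equal(as.numeric(huff_matrix(sup, od1, spec)), c(1, 0))

  # equal S, equal t: an even split
  od2 <- matrix(c(12, 12), 1, 2)
  supeq <- data.frame(park_id = 1:2, Sj = c(0.4, 0.4))
  expect_equal(as.numeric(huff_matrix(supeq, od2, spec)), c(0.5, 0.5))

  # S = (2, 1) at equal times: probabilities 2/3, 1/3
  sup21 <- data.frame(park_id = 1:2, Sj = c(2, 1))
  expect_equal(as.numeric(huff_matrix(sup21, od2, spec)),
               c(2, 1) / 3, tolerance = 1e-12)

  # all-zero attractiveness with reachable parks: zero row plus warning
  sup0 <- data.frame(park_id = 1:2, Sj = c(0, 0))
  expect_warning(p0 <- huff_matrix(sup0, od2, spec), "all-zero")
  expect_equal(as.numeric(p0), c(0, 0))
})

test_that("worked single-cell example reproduces ratios, access, conservation", {
  spec <- decay_spec(30)
  od <- matrix(0, 1, 1)
  sup <- data.frame(park_id = 1, Sj = 0.6)
  prob <- huff_matrix(sup, od, spec)
  expect_equal(as.numeric(prob), 1)
  ratios <- supply_demand_ratios(sup, 200, prob, od, spec)
  expect_equal(ratios$Rj, 0.6 / 200)
  A <- accessibility_scores(prob, ratios, od, spec)
  expect_equal(A, 0.003)
  expect_equal(200 * A, 0.6)                 # P * A returns the supply

  # park with no cell inside the threshold: R = 0 by convention
  od_far <- matrix(45, 1, 1)
  prob_far <- huff_matrix(sup, od_far, spec)
  r_far <- supply_demand_ratios(sup, 200, prob_far, od_far, spec)
  expect_equal(r_far$Rj, 0)
  expect_equal(accessibility_scores(prob_far, r_far, od_far, spec), 0)

  # doubling the population halves the ratios
  r2 <- supply_demand_ratios(sup, 400, prob, od, spec)
  expect_equal(r2$Rj, ratios$Rj / 2)
  expect_error(supply_demand_ratios(sup, -5, prob, od, spec), "non-negative")
})

test_that("Huff variants alter weights but keep normalisation and conservation", {
  city <- make_scenario("baseline", seed = 4, dims = c(12, 12),
                        total_population = 4000,
                        n_parks = c(comprehensive = 1, community = 2,
                                    street = 2),
                        n_pois = 120, n_residential_pois = 150,
                        n_shortcuts = 10, ring_radii = c(300, 700))
  sup <- park_supply(city)
  od <- od_travel_times(city$network, city$grid, city$parks,
                        city$entrances, travel_mode("walking"))
  for (variant in c("gaussian", "gaussian_over_time",
                    "gaussian_times_time")) {
    spec <- decay_spec(30, variant)
    prob <- suppressWarnings(huff_matrix(sup, od, spec))
    rs <- rowSums(prob)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
    ratios <- supply_demand_ratios(sup, city$grid$population, prob, od, spec)
    A <- accessibility_scores(prob, ratios, od, spec)
    lhs <- sum(city$grid$population * A)
    rhs <- sum(ratios$Sj[ratios$Dj > 0])
    expect_lt(abs(lhs - rhs) / rhs, 1e-9)
  }
})

test_that("zonal summary matches hand arithmetic on a six-cell toy", {
  grid <- build_grid(c(0, 0, 300, 200), 100)
  grid$zone <- rep(c("north", "south"), each = 3)
  grid$population <- c(10, 10, 0, 5, 5, 5)
  A <- c(1, 3, 99, 0, 2, 4)                # cell 3 unpopulated: ignored
  zs <- zone_summary(A, grid)
  north <- zs[zs$zone == "north", ]
  expect_equal(north$mean, 2)
  expect_equal(north$sd, sd(c(1, 3)))
  expect_equal(north$underserved_pct, 0)
  south <- zs[zs$zone == "south", ]
  expect_equal(south$min, 0)
  expect_equal(south$max, 4)
  expect_equal(south$underserved_pct, 100 / 3)
  all_row <- zs[zs$zone == "ALL", ]
  expect_equal(all_row$n_cells, 5)
  expect_equal(all_row$underserved_pct, 20)   # 1 of 5 populated at zero

  # constant surface: zero dispersion
  zs2 <- zone_summary(rep(2, 6), grid)
  expect_equal(zs2$sd[zs2$zone == "ALL"], 0)

  # a zone with no populated cells yields an NA row and a warning
  grid$population[4:6] <- 0
  expect_warning(zs3 <- zone_summary(A, grid), "no populated cells")
  expect_true(is.na(zs3$mean[zs3$zone == "south"]))
})

test_that("park_access object carries a consistent surface and methods", {
  city <- toy_city()
  fit <- park_access(city, "walking")
  expect_s3_class(fit, "park_access")
  expect_length(fit$A, nrow(city$grid))
  expect_true(all(fit$A >= 0))
  # every cell reaches a park in the toy city
  expect_true(all(fit$A > 0))
  expect_lt(conservation_error(fit), 1e-9)
  expect_output(print(fit), "park_access")
  expect_output(print(summary(fit)), "conservation")
  # cells with no reachable park score exactly zero
  fit15 <- park_access(city, travel_mode("walking", t0_min = 2))
  unreach <- rowSums(unclass(fit15$od) <= 2) == 0
  expect_true(all(fit15$A[unreach] == 0))
})
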