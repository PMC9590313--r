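test_that("equality index rescales accessibility by the top ratio", {
  A <- c(0.004, 0.002, 0)
  R <- c(0.8, 0.1)
  E <- equality_index(A, R)
  expect_equal(E, c(0.8, 0.4, 0))           # max cell takes max(R)
  expect_equal(equality_index(c(0, 0), R), c(0, 0))
})

test_that("six-class scheme reproduces the printed ranges and labels", {
  cases <- data.frame(
    E = c(0, 0.1, 0.25, 0.3, 0.6, 0.75, 0.9, 1.0, 1.2),
    class = c("I", "II", "III", "III", "IV", "V", "V", "V", "VI"))
  out <- classify_equality(cases$E)
  expect_equal(out$class, cases$class)
  expect_equal(out$status[out$Ei == 0], "No supply")
  expect_equal(out$equality[out$Ei == 0], "Serious inequality")
  expect_equal(out$status[out$Ei == 0.6], "Good")
  expect_equal(out$equality[out$Ei == 0.6], "Equality")
  expect_equal(out$status[out$Ei == 1.2], "Oversupply")
  expect_equal(out$equality[out$Ei == 1.2], "Serious inequality")
  expect_error(classify_equality(-0.1), "non-negative")
})

test_that("trapezoid Gini equals the pairwise oracle and the hand cases", {
  # equal per-capita resource: diagonal Lorenz, Gini 0
  lg <- lorenz_gini(rep(10, 5), rep(3, 5))
  expect_equal(lg$gini, 0, tolerance = 1e-12)

  # two equal-population units, all resource in one: 0.5
  lg2 <- lorenz_gini(c(1, 1), c(0, 1))
  expect_equal(lg2$gini, 0.5, tolerance = 1e-12)

  # shares (0.2, 0.8): trapezoid gives 0.3, as does the pairwise formula
  lg3 <- lorenz_gini(c(1, 1), c(0.2, 0.8))
  expect_equal(lg3$gini, 0.3, tolerance = 1e-12)
  expect_equal(lg3$gini, gini_pairwise(c(0.2, 0.8)), tolerance = 1e-12)

  # oracle equivalence on random equal-population vectors
  set.seed(42)
  for (k in 1:25) {
    n <- sample(2:200, 1)
    x <- rgamma(n, shape = 0.8)
    lg <- lorenz_gini(rep(1, n), x)
    expect_equal(lg$gini, gini_pairwise(x), tolerance = 1e-9)
  }

  expect_error(lorenz_gini(c(1, 1), c(0, 0)), "zero")
  expect_error(lorenz_gini(c(0, 0), c(1, 1)), "positive total")
})

test_that("Lorenz curve is monotone, convex, with exact endpoints", {
  set.seed(7)
  pop <- rpois(60, 40) + 1
  res <- pop * rgamma(60, 2)
  lg <- lorenz_gini(pop, res)
  P <- lg$points$P; Q <- lg$points$Q
  expect_equal(P[1], 0); expect_equal(Q[1], 0)
  expect_equal(P[length(P)], 1); expect_equal(Q[length(Q)], 1)
  expect_true(all(diff(P) >= -1e-12))
  expect_true(all(diff(Q) >= -1e-12))
  # under ascending per-capita sort the curve sits at or below the diagonal
  expect_true(all(Q <= P + 1e-12))
  # and its slopes (per-capita resource) are non-decreasing: convexity
  slopes <- diff(Q) / diff(P)
  expect_true(all(diff(slopes) >= -1e-9))

  # the literal rectangle form is exposed only as a debug attribute
  lgu <- lorenz_gini(rep(1, 4), rep(2, 4), literal = TRUE)
  expect_equal(attr(lgu, "gini_literal"), 1 - 1 / 4, tolerance = 1e-12)
  expect_equal(lgu$gini, 0, tolerance = 1e-12)
})

test_that("Gini banding matches the five printed segments", {
  expect_equal(classify_gini(0.15), "Absolute equality")
  expect_equal(classify_gini(0.25), "Equality")
  expect_equal(classify_gini(0.339), "Relatively equality")
  expect_equal(classify_gini(0.45), "Low inequality")
  expect_equal(classify_gini(0.55), "High inequality")
  # boundaries fall to the lower band
  expect_equal(classify_gini(c(0.2, 0.3, 0.4, 0.5)),
               c("Absolute equality", "Equality", "Relatively equality",
                 "Low inequality"))
  expect_error(classify_gini(1.2), "\\[0, 1\\]")
})

test_that("lattice weights give the right neighbour counts, row-standardised", {
  grid <- build_grid(c(0, 0, 300, 300), 100)
  Wq <- build_weights(grid, "queen")
  # centre cell of a 3x3: 8 neighbours; corners: 3
  expect_length(Wq$nb[[5]], 8)
  expect_length(Wq$nb[[1]], 3)
  Wr <- build_weights(grid, "rook")
  expect_length(Wr$nb[[5]], 4)
  expect_length(Wr$nb[[1]], 2)
  for (i in seq_along(Wq$nb))
    expect_equal(sum(Wq$w[[i]]), 1)
  Wd <- build_weights(grid, "distance_band", band = 105)
  expect_equal(lengths(Wd$nb), lengths(Wr$nb))   # 100 m band = rook here
  expect_error(build_weights(grid, "hexagon"), "arg")
})

test_that("local Moran matches brute force and flags checkerboards negative", {
  set.seed(31)
  grid <- build_grid(c(0, 0, 1000, 1000), 100)
  W <- build_weights(grid, "queen")
  x <- rnorm(nrow(grid))
  fast <- local_moran(x, W, permutations = 99, seed = 5)
  expect_equal(fast$Ii, local_moran_bruteforce(x, W), tolerance = 1e-10)

  # 4x4 rook checkerboard: every neighbour differs, all I_i negative
  g4 <- build_grid(c(0, 0, 400, 400), 100)
  W4 <- build_weights(g4, "rook")
  chess <- (g4$row + g4$col) %% 2
  lm4 <- local_moran(chess, W4, permutations = 99, seed = 5)
  expect_true(all(lm4$Ii < 0))

  expect_error(local_moran(rep(1, nrow(g4)), W4), "constant field")
})

test_that("homogeneous blocks come out as significant HH and LL cores", {
  g <- build_grid(c(0, 0, 800, 800), 100)
  W <- build_weights(g, "queen")
  set.seed(9)
  x <- ifelse(g$x < 400, 10, 1) + rnorm(nrow(g), 0, 0.01)
  lm <- local_moran(x, W, permutations = 999, alpha = 0.05, seed = 17)
  interior_hi <- g$x < 300 & g$y > 100 & g$y < 700
  interior_lo <- g$x > 500 & g$y > 100 & g$y < 700
  expect_true(all(lm$label[interior_hi] == "HH"))
  expect_true(all(lm$label[interior_lo] == "LL"))
})

test_that("LISA labels are invariant to positive affine transforms", {
  set.seed(13)
  g <- build_grid(c(0, 0, 700, 700), 100)
  W <- build_weights(g, "queen")
  x <- rnorm(nrow(g)) + (g$x > 350) * 1.5
  a <- local_moran(x, W, permutations = 199, seed = 3)
  b <- local_moran(3.2 * x + 11, W, permutations = 199, seed = 3)
  expect_equal(a$Ii, b$Ii, tolerance = 1e-9)
  expect_equal(a$label, b$label)
})

test_that("summed local Moran recovers the global statistic", {
  set.seed(23)
  g <- build_grid(c(0, 0, 900, 900), 100)
  W <- build_weights(g, "queen")
  for (k in 1:5) {
    x <- rnorm(nrow(g)) + rep(rnorm(9), each = 9) # mild structure
    z <- x - mean(x)
    # independent global Moran: (n / S0) * sum_ij w_ij z_i z_j / sum z^2
    num <- 0; S0 <- 0
    for (i in seq_along(W$nb)) {
      num <- num + sum(W$w[[i]] * z[i] * z[W$nb[[i]]])
      S0 <- S0 + sum(W$w[[i]])
    }
    global <- (length(x) / S0) * num / sum(z^2)
    lm <- local_moran(x, W, permutations = 19, seed = 1)
    expect_equal(mean(lm$Ii), global, tolerance = 1e-10)
  }
})
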