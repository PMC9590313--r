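# Equity statistics: the equality index and its six-class scheme, Lorenz
# curve and Gini coefficient with banding, and local Moran's I (LISA) with
# conditional-permutation inference on the grid lattice.

#' Equality index per cell
#'
#' E_i = a_i * max(R_j) / max(a_i): cell accessibility rescaled so its
#' maximum equals the maximum park supply-demand ratio. If every a_i is 0,
#' all E_i are 0.
#'
#' @param A cell accessibility vector a_i.
#' @param R park supply-demand ratios R_j.
#' @return E_i vector.
#' @export
equality_index <- function(A, R) {
  maxA <- max(A)
  if (maxA == 0) return(rep(0, length(A)))
  A * max(R) / maxA
}

.equality_classes <- data.frame(
  class = c("I", "II", "III", "IV", "V", "VI"),
  status = c("No supply", "Very weak", "Weak", "Good", "Very good",
             "Oversupply"),
  equality = c("Serious inequality", "Serious inequality",
               "Relative inequality", "Equality", "Relative equality",
               "Serious inequality"),
  stringsAsFactors = FALSE
)

#' Six-class equality classification
#'
#' Bins the equality index exactly as the standard scheme prints it:
#' E = 0 is class I (no supply); 0 < E < 0.25 class II (very weak);
#' 0.25 <= E < 0.5 class III (weak); 0.5 <= E < 0.75 class IV (good);
#' 0.75 <= E <= 1 class V (very good); E > 1 class VI (oversupply).
#'
#' @param E equality-index vector (non-negative).
#' @return data.frame with \code{Ei}, \code{class}, \code{status},
#'   \code{equality} columns.
#' @export
classify_equality <- function(E) {
  if (any(!is.finite(E)) || any(E < 0))
    stop("equality index must be finite and non-negative")
  cls <- character(length(E))
  cls[E == 0] <- "I"
  cls[E > 0 & E < 0.25] <- "II"
  cls[E >= 0.25 & E < 0.5] <- "III"
  cls[E >= 0.5 & E < 0.75] <- "IV"
  cls[E >= 0.75 & E <= 1] <- "V"
  cls[E > 1] <- "VI"
  k <- match(cls, .equality_classes$class)
  data.frame(Ei = E, class = cls, status = .equality_classes$status[k],
             equality = .equality_classes$equality[k],
             stringsAsFactors = FALSE)
}

#' Lorenz curve and Gini coefficient
#'
#' Units are sorted ascending by resource per capita; cumulative
#' population share P_k and resource share Q_k trace the Lorenz curve,
#' and the Gini coefficient is computed by the trapezoid rule
#' G = 1 - sum (P_k - P_(k-1)) (Q_k + Q_(k-1)). The default resource in
#' the pipeline is population-weighted accessibility P_i * A_i.
#'
#' @param population per-unit population (must sum to > 0).
#' @param resource per-unit non-negative resource.
#' @param literal also return the non-standard rectangle form
#'   1 - sum(dP * dQ) as attribute \code{gini_literal} (debug aid; that
#'   form does not vanish at perfect equality).
#' @return object of class \code{lorenz_gini}: \code{points} data.frame
#'   (P, Q from (0,0) to (1,1)), \code{gini}, \code{band}.
#' @export
lorenz_gini <- function(population, resource, literal = FALSE) {
  if (length(population) != length(resource))
    stop("population and resource lengths differ")
  if (any(population < 0) || sum(population) <= 0)
    stop("population must be non-negative with positive total")
  if (any(resource < 0)) stop("resource must be non-negative")
  if (sum(resource) == 0)
    stop("total resource is zero; Gini undefined")

  keep <- population > 0 | resource > 0
  pop <- population[keep]; res <- resource[keep]
  percap <- ifelse(pop > 0, res / pop, Inf)   # pop-0 units with resource last
  o <- order(percap)
  P <- c(0, cumsum(pop[o]) / sum(pop))
  Q <- c(0, cumsum(res[o]) / sum(res))
  dP <- diff(P)
  gini <- 1 - sum(dP * (Q[-1] + Q[-length(Q)]))
  out <- structure(list(points = data.frame(P = P, Q = Q), gini = gini,
                        band = classify_gini(min(max(gini, 0), 1))),
                   class = "lorenz_gini")
  if (literal) attr(out, "gini_literal") <- 1 - sum(dP * diff(Q))
  out
}

#' @export
print.lorenz_gini <- function(x, ...) {
  cat(sprintf("<lorenz_gini> %d units, Gini = %.4f (%s)\n",
              nrow(x$points) - 1L, x$gini, x$band))
  invisible(x)
}

#' Plot a Lorenz curve
#' @param x a \code{lorenz_gini} object.
#' @param ... passed to \code{plot}.
#' @export
plot.lorenz_gini <- function(x, ...) {
  graphics::plot(x$points$P, x$points$Q, type = "l", lwd = 2,
                 xlab = "Cumulative population share",
                 ylab = "Cumulative resource share",
                 main = sprintf("Lorenz curve (Gini = %.3f)", x$gini), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Gini coefficient band
#'
#' The five-band reading of the Gini coefficient used for resource-equity
#' reporting: below 0.2 absolute equality; 0.2-0.3 equality; 0.3-0.4
#' relative equality; 0.4-0.5 low inequality (0.4 is the usual warning
#' line); above 0.5 high inequality. Boundary values go to the lower band.
#'
#' @param g Gini value in [0, 1] (vectorised).
#' @return character band labels.
#' @export
classify_gini <- function(g) {
  if (any(!is.finite(g)) || any(g < 0) || any(g > 1))
    stop("Gini must lie in [0, 1]")
  bands <- c("Absolute equality", "Equality", "Relatively equality",
             "Low inequality", "High inequality")
  bands[findInterval(g, c(0.2, 0.3, 0.4, 0.5), left.open = TRUE) + 1L]
}

#' Spatial weights on the demand-grid lattice
#'
#' Binary contiguity (queen or rook) or a distance band on centroids,
#' row-standardised. Isolated cells get empty rows and are excluded from
#' LISA labelling.
#'
#' @param grid demand grid with \code{row}, \code{col} (and \code{x},
#'   \code{y} for the distance band).
#' @param scheme \code{"queen"}, \code{"rook"} or \code{"distance_band"}.
#' @param band distance threshold in metres for
#'   \code{scheme = "distance_band"}.
#' @return object of class \code{listw_lattice}: list with \code{nb}
#'   (neighbour index lists) and \code{w} (matching weight lists, rows
#'   summing to 1).
#' @export
build_weights <- function(grid, scheme = c("queen", "rook", "distance_band"),
                          band = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(grid)
  if (scheme %in% c("queen", "rook")) {
    key <- function(r, c) paste(r, c)
    lookup <- new.env(hash = TRUE, size = n)
    for (i in seq_len(n)) assign(key(grid$row[i], grid$col[i]), i, lookup)
    offs <- if (scheme == "rook")
      cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
    else
      cbind(rep(-1:1, each = 3), rep(-1:1, 3))[-5, ]
    nb <- lapply(seq_len(n), function(i) {
      out <- integer(0)
      for (k in seq_len(nrow(offs))) {
        j <- mget(key(grid$row[i] + offs[k, 1], grid$col[i] + offs[k, 2]),
                  lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(j)) out <- c(out, j)
      }
      out
    })
  } else {
    if (is.null(band) || band <= 0) stop("distance_band scheme needs band > 0")
    nb <- lapply(seq_len(n), function(i) {
      d2 <- (grid$x - grid$x[i])^2 + (grid$y - grid$y[i])^2
      setdiff(which(d2 <= band^2), i)
    })
  }
  w <- lapply(nb, function(j) if (length(j)) rep(1 / length(j), length(j))
              else numeric(0))
  structure(list(nb = nb, w = w, scheme = scheme, n = n),
            class = "listw_lattice")
}

spatial_lag <- function(x, W) {
  vapply(seq_along(W$nb), function(i) {
    j <- W$nb[[i]]
    if (!length(j)) NA_real_ else sum(W$w[[i]] * x[j])
  }, 0)
}

#' Local Moran's I with conditional-permutation inference
#'
#' The standard local decomposition of Moran's I on row-standardised
#' weights: I_i = (x_i - xbar) / m2 * sum_j w_ij (x_j - xbar), with
#' m2 = sum_k (x_k - xbar)^2 / n. Pseudo p-values come from conditional
#' permutations: x_i is held fixed while its neighbours' values are drawn
#' from the remaining n-1 observations; the p-value is one-sided in the
#' direction of the observed statistic, (count + 1) / (nsim + 1). Cells
#' significant at \code{alpha} are labelled by the quadrant of (value,
#' spatial lag) around the mean: HH, HL, LH or LL; all others (and
#' isolated cells) are "not-significant".
#'
#' @param x value vector (e.g., the equality index E_i).
#' @param W weights from \code{\link{build_weights}}.
#' @param permutations number of conditional permutations (default 999).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed for the permutations.
#' @return data.frame with \code{Ii}, \code{p_value}, \code{label}.
#' @export
local_moran <- function(x, W, permutations = 999, alpha = 0.05, seed = 1L) {
  n <- length(x)
  if (n != W$n) stop("value vector and weights are not aligned")
  xb <- mean(x)
  m2 <- sum((x - xb)^2) / n
  if (m2 == 0) stop("constant field: local Moran's I undefined (zero variance)")
  z <- x - xb
  lag <- spatial_lag(z, W)            # lag of deviations
  Ii <- z / m2 * lag

  set.seed(seed)
  p <- rep(NA_real_, n)
  zs <- z
  for (i in seq_len(n)) {
    k <- length(W$nb[[i]])
    if (!k) next
    # draw k neighbour deviations per permutation from the other n-1 cells
    pool <- zs[-i]
    draws <- matrix(pool[sample.int(n - 1L, permutations * k, replace = TRUE)],
                    permutations, k)
    Isim <- z[i] / m2 * drop(draws %*% W$w[[i]])
    p[i] <- if (Ii[i] >= 0) (sum(Isim >= Ii[i]) + 1) / (permutations + 1)
            else            (sum(Isim <= Ii[i]) + 1) / (permutations + 1)
  }

  label <- rep("not-significant", n)
  sig <- !is.na(p) & p <= alpha
  hi <- z >= 0; lag_hi <- lag >= 0
  label[sig & hi & lag_hi]   <- "HH"
  label[sig & hi & !lag_hi]  <- "HL"
  label[sig & !hi & lag_hi]  <- "LH"
  label[sig & !hi & !lag_hi] <- "LL"
  data.frame(Ii = Ii, p_value = p, label = label, stringsAsFactors = FALSE)
}
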