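# Gauss-Legendre rule on [-1, 1] via the Golub-Welsch eigenvalue method;
# cached per node count. Used to reduce the bivariate-normal orthant
# probability to a 1-D integral that can be evaluated for many correlations
# at once (the grid-search oracle needs thousands of evaluations).
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre_rule <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  rule <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
  .gl_cache[[key]] <- rule
  rule
}

# P(Z1 > t1, Z2 > t2) for standard bivariate normals with correlation r.
# Vectorised over r (t1, t2 scalar). Uses
#   P = int_{t1}^{inf} phi(z) Phi((r z - t2) / sqrt(1 - r^2)) dz
# on a fixed high-order Gauss-Legendre grid; the integrand is analytic so
# the rule converges essentially to machine precision.
bvn_upper_tail <- function(r, t1, t2 = t1, nodes = 128L) {
  if (any(abs(r) > 1)) stop("correlation must lie in [-1, 1]", call. = FALSE)
  out <- numeric(length(r))
  hi <- 8.5
  lo <- max(t1, -8.5)
  p2 <- stats::pnorm(t2, lower.tail = FALSE)
  if (lo >= hi) return(out)  # upper tail beyond numeric support
  rule <- gauss_legendre_rule(nodes)
  z <- (hi - lo) / 2 * rule$x + (hi + lo) / 2
  w <- (hi - lo) / 2 * rule$w * stats::dnorm(z)
  inner <- abs(r) < 1
  if (any(inner)) {
    s <- sqrt(1 - r[inner]^2)
    # rows: correlations, cols: quadrature nodes
    arg <- (outer(r[inner], z) - t2) / s
    out[inner] <- as.numeric(stats::pnorm(arg) %*% w)
  }
  # comonotone / antimonotone limits, exact
  out[r == 1] <- stats::pnorm(max(t1, t2), lower.tail = FALSE)
  out[r == -1] <- pmax(0, 1 - stats::pnorm(t1) - stats::pnorm(t2))
  # guard tiny negative round-off and cap by the marginals
  pmin(pmax(out, 0), min(stats::pnorm(t1, lower.tail = FALSE), p2))
}

#' Cell probabilities of a dichotomized bivariate-normal liability
#'
#' Under the liability-threshold model both pair members carry a standard
#' normal liability with correlation `r`, and "affection" (extreme-group
#' membership) occurs above the threshold `t`. The symmetric 2x2 pair table
#' then has cell probabilities both-high \eqn{P(Z_1 > t, Z_2 > t)},
#' discordant \eqn{2 P(Z_1 > t, Z_2 \le t)}, and both-low the remainder;
#' they sum to 1.
#'
#' @param r Latent correlation(s) in `[-1, 1]` (the endpoints are evaluated
#'   as exact comonotone/antimonotone limits).
#' @param threshold Liability threshold (z-units).
#' @return For scalar `r` a named vector `(p_both_high, p_discordant,
#'   p_both_low)`; for vector `r` a matrix with those columns.
#' @export
#' @examples
#' cell_probabilities(0, qnorm(0.95))     # independence: 0.05^2 both-high
#' cell_probabilities(0.78, 1.76)
cell_probabilities <- function(r, threshold) {
  p_hh <- bvn_upper_tail(r, threshold)
  p_hi <- stats::pnorm(threshold, lower.tail = FALSE)
  p_disc <- pmax(2 * (p_hi - p_hh), 0)
  p_ll <- pmax(1 - 2 * p_hi + p_hh, 0)
  out <- cbind(p_both_high = p_hh, p_discordant = p_disc, p_both_low = p_ll)
  if (length(r) == 1L) out[1, ] else out
}
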