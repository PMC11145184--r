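#' Input-output responses
#'
#' An input-output response is a nonnegative linear combination of
#' steady-state probabilities, `r(x) = sum_i lambda_i u_i*(x)` with
#' `0 <= lambda_i <= 1`, viewed as a function of the input concentration x
#' changed quasi-statically. At thermodynamic equilibrium every such response
#' collapses to a ratio of degree-l polynomials with positive denominator
#' coefficients dominating the numerator coefficients, where l is the maximum
#' number of concurrently bound input sites — independently of the complexity
#' of the underlying graph.
#'
#' @name responses
NULL

check_weights <- function(g, weights) {
  if (is.null(names(weights))) {
    if (length(weights) != length(g$vertices))
      stop("unnamed weights must have one entry per vertex")
    names(weights) <- g$vertices
  }
  if (!all(g$vertices %in% names(weights))) stop("weights missing for some vertices")
  w <- weights[g$vertices]
  if (any(w < 0 | w > 1)) stop("output weights must lie in [0, 1]")
  w
}

#' Evaluate a response directly on the graph
#'
#' @param g a strongly connected `lf_graph`.
#' @param weights output weights `lambda` in `[0,1]`, named by vertex (or in
#'   vertex order).
#' @param x input concentration(s).
#' @return numeric vector of response values in `[0, 1]`.
#' @export
response_value <- function(g, weights, x) {
  weights <- check_weights(g, weights)
  vapply(x, function(xx) sum(weights * steady_state(g, xx)), 0)
}

#' Fractional saturation output weights
#'
#' The average number of input-bound sites normalized by the total number of
#' sites: `lambda_i = |pattern(i)| / m`.
#'
#' @param g an `lf_graph` with `n_sites >= 1`.
#' @return named weight vector.
#' @export
fractional_saturation <- function(g) {
  stopifnot(inherits(g, "lf_graph"))
  if (g$n_sites < 1L) stop("fractional saturation needs at least one input site")
  w <- lengths(g$patterns) / g$n_sites
  names(w) <- g$vertices
  w
}

#' Rational response objects
#'
#' `rational_response(alpha, beta)` wraps numerator/denominator coefficient
#' sequences (ascending powers of x, equal length l+1). The equilibrium
#' constraints — all `beta_i > 0` and `0 <= alpha_i <= beta_i` — guarantee
#' `0 <= r(x) <= 1` on `[0, Inf)`; `constraint_flag` records whether they
#' hold.
#'
#' @param alpha numerator coefficients (length l+1, nonnegative).
#' @param beta denominator coefficients (length l+1, nonnegative with
#'   positive constant and leading terms; all positive in the equilibrium
#'   case).
#' @return object of class `hb_response` with fields `alpha`, `beta`, `l`,
#'   `constraint_flag`.
#' @examples
#' r <- rational_response(c(0, 1), c(1, 1))  # x / (1 + x)
#' predict(r, c(0.5, 1, 2))
#' @export
rational_response <- function(alpha, beta) {
  if (length(alpha) != length(beta)) stop("alpha and beta must have equal length")
  if (length(beta) < 2L) stop("degree l must be at least 1")
  if (any(!is.finite(alpha)) || any(!is.finite(beta))) stop("non-finite coefficient")
  if (any(alpha < 0)) stop("alpha coefficients must be nonnegative")
  if (any(beta < 0) || beta[1] <= 0 || beta[length(beta)] <= 0)
    stop("beta coefficients must be nonnegative with positive ends")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 l = length(beta) - 1L,
                 constraint_flag = all(beta > 0) && all(alpha <= beta)),
            class = "hb_response")
}

#' @export
print.hb_response <- function(x, ...) {
  cat(sprintf("<hb_response> degree l = %d, equilibrium constraints: %s\n",
              x$l, if (x$constraint_flag) "satisfied" else "violated"))
  cat("  alpha:", signif(x$alpha, 4), "\n  beta: ", signif(x$beta, 4), "\n")
  invisible(x)
}

#' @export
predict.hb_response <- function(object, x, ...) {
  poly_val(object$alpha, x) / poly_val(object$beta, x)
}

#' Extract the rational form of an equilibrium response
#'
#' Under detailed balance, each vertex weight is `gamma_i x^{b_i}` with
#' `b_i` the number of bound input sites, so the response collapses to
#' `r(x) = sum_j alpha_j x^j / sum_j beta_j x^j` with
#' `beta_j = sum over vertices binding j sites of gamma_i` and
#' `alpha_j = sum lambda_i gamma_i` over the same vertices. The degree `l` is
#' the maximum number of concurrently bound sites.
#'
#' @inheritParams response_value
#' @return an `hb_response` whose evaluation coincides with
#'   [response_value()].
#' @export
equilibrium_rational_form <- function(g, weights) {
  weights <- check_weights(g, weights)
  mv <- mu_vector(g)
  l <- max(mv$degree)
  if (l < 1L) stop("graph binds no input; response is constant")
  alpha <- beta <- numeric(l + 1L)
  for (j in 0:l) {
    vs <- g$vertices[mv$degree == j]
    if (!length(vs))
      stop("no vertex binds exactly ", j,
           " sites; degrees must be contiguous for a binding graph")
    beta[j + 1L] <- sum(mv$gamma[vs])
    alpha[j + 1L] <- sum(weights[vs] * mv$gamma[vs])
  }
  rational_response(alpha, beta)
}

#' Sample equilibrium-constrained rational responses
#'
#' Coefficients are drawn the way the universal equilibrium region is built:
#' `log10 beta_i` uniform on `[-a, a]`, then `log10 alpha_i` uniform on
#' `[-a, log10 beta_i]`, so the constraints `0 < alpha_i <= beta_i` hold by
#' construction. Every constrained coefficient vector is realizable by some
#' equilibrium binding graph, so sampling coefficients directly samples
#' equilibrium responses.
#'
#' `sample_unconstrained_coefficients` instead draws `log10 alpha_i` uniform
#' on `[-a, a]` independently of beta, so numerator coefficients can exceed
#' denominator ones (responses no longer confined to equilibrium behavior,
#' and may exceed 1).
#'
#' @param n number of draws.
#' @param l polynomial degree (= number of input sites when sampling the
#'   universal region).
#' @param a exponent half-range (> 0), coefficients span `[10^-a, 10^a]`.
#' @param zero_mass probability that an individual alpha coefficient is set
#'   exactly to 0 (default 0: the boundary of the constraint set, unreachable
#'   by log-uniform draws, e.g. a strict fractional-saturation numerator).
#' @return list with matrices `alpha`, `beta` (`n` rows, `l+1` columns).
#' @export
sample_equilibrium_coefficients <- function(n, l, a, zero_mass = 0) {
  if (l < 1L) stop("l must be >= 1")
  if (a <= 0) stop("a must be positive")
  lb <- matrix(stats::runif(n * (l + 1L), -a, a), n, l + 1L)
  la <- matrix(stats::runif(n * (l + 1L), 0, 1), n, l + 1L)
  la <- -a + la * (lb + a)   # uniform on [-a, log10 beta]
  alpha <- 10^la
  if (zero_mass > 0) {
    z <- matrix(stats::runif(n * (l + 1L)) < zero_mass, n, l + 1L)
    alpha[z] <- 0
  }
  list(alpha = alpha, beta = 10^lb)
}

#' @rdname sample_equilibrium_coefficients
#' @export
sample_unconstrained_coefficients <- function(n, l, a) {
  if (l < 1L) stop("l must be >= 1")
  if (a <= 0) stop("a must be positive")
  list(alpha = matrix(10^stats::runif(n * (l + 1L), -a, a), n, l + 1L),
       beta = matrix(10^stats::runif(n * (l + 1L), -a, a), n, l + 1L))
}

#' @rdname sample_equilibrium_coefficients
#' @return `sample_equilibrium_response` / `sample_unconstrained_response`:
#'   a single `hb_response`.
#' @export
sample_equilibrium_response <- function(l, a, zero_mass = 0) {
  co <- sample_equilibrium_coefficients(1L, l, a, zero_mass = zero_mass)
  rational_response(co$alpha[1, ], co$beta[1, ])
}

#' @rdname sample_equilibrium_coefficients
#' @export
sample_unconstrained_response <- function(l, a) {
  co <- sample_unconstrained_coefficients(1L, l, a)
  rational_response(co$alpha[1, ], co$beta[1, ])
}
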