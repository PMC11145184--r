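#' Intrinsic sharpness of an input-output response
#'
#' A bounded response on `[0, Inf)` is normalized intrinsically: `x_half` is
#' the smallest positive concentration at which the response is halfway
#' between its infimum `m(r)` and supremum `M(r)`, and the normalized
#' response is `q(y) = r(y * x_half)`. *Steepness* `s` is the global maximum
#' of `|dq/dy|`; *position* `p` is the smallest `y` attaining it. Both are
#' dimensionless and invariant under rescaling of the concentration axis.
#' The unnormalized counterparts satisfy `s = s_u * x_half` and
#' `p = p_u / x_half`.
#'
#' For rational responses all extrema and crossings are found by polynomial
#' root isolation on exact derivative numerators (no generic numeric
#' optimization): if `r = A/B` then the slope is `C/B^2` with
#' `C = A'B - AB'`, and the slope's critical points are roots of
#' `C'B - 2CB'`.
#'
#' @name sharpness
NULL

# tolerances (documented; override via options(hillbarrier.*))
.ps_tols <- function() {
  list(im = getOption("hillbarrier.im_tol", 1e-7),
       tie = getOption("hillbarrier.tie_tol", 1e-9),
       const = getOption("hillbarrier.const_tol", 1e-13))
}

#' Extrema and half-point of a response
#'
#' @param r an `hb_response` (see [rational_response()]).
#' @return list with `m_r` (infimum over `[0, Inf)`), `M_r` (supremum), and
#'   `x_half` (smallest positive `x` with `r(x) = (m_r + M_r)/2`). `x_half`
#'   is strictly positive even when `r(0)` already sits at the halfway value.
#' @export
response_extrema <- function(r) {
  stopifnot(inherits(r, "hb_response"))
  tol <- .ps_tols()
  sc <- .x_scale(r$beta)
  ex <- .extrema_rational(r$alpha * sc$pw, r$beta * sc$pw, tol)
  if (is.null(ex)) stop("response is constant: no half-crossing exists")
  ex$x_half <- ex$x_half * sc$xc
  ex$C <- NULL
  ex
}

# characteristic concentration scale of a rational response; rescaling
# x -> x / xc conditions the coefficient vector before any root finding and
# makes position/steepness scale-invariant by construction
.x_scale <- function(beta) {
  l <- length(beta) - 1L
  xc <- (beta[1] / beta[l + 1L])^(1 / l)
  if (!is.finite(xc) || xc <= 0) xc <- 1
  list(xc = xc, pw = xc^(0:l))
}

.extrema_rational <- function(alpha, beta, tol = .ps_tols()) {
  la <- length(alpha)
  A1 <- poly_deriv(alpha); B1 <- poly_deriv(beta)
  C <- poly_add(poly_mul(A1, beta), -poly_mul(alpha, B1))  # slope numerator
  crit <- poly_pos_roots(C, im_tol = tol$im)
  r0 <- alpha[1] / beta[1]
  rinf <- alpha[la] / beta[la]
  vals <- c(r0, rinf,
            if (length(crit)) poly_val(alpha, crit) / poly_val(beta, crit))
  m_r <- min(vals); M_r <- max(vals)
  if (M_r - m_r <= tol$const * max(M_r, 1)) return(NULL)
  h <- (m_r + M_r) / 2
  cross <- poly_add(alpha, -h * beta)
  # deflate an (approximate) root at x = 0: r(0) may itself equal h
  scale <- max(abs(cross))
  if (abs(cross[1]) <= 1e-11 * scale) cross <- cross[-1]
  roots <- poly_pos_roots(cross, im_tol = tol$im)
  roots <- roots[roots > 0]
  x_half <- if (length(roots)) roots[1] else NA_real_
  # guard against root-finding failure on ill-conditioned coefficients
  ok <- is.finite(x_half) &&
    abs(poly_val(alpha, x_half) / poly_val(beta, x_half) - h) <=
      1e-6 * max(M_r - m_r, 1e-12)
  if (!ok) {
    x_half <- .halfpoint_bisect(function(x) poly_val(alpha, x) / poly_val(beta, x), h)
    if (!is.finite(x_half)) return(NULL)
  }
  list(m_r = m_r, M_r = M_r, x_half = x_half, C = C)
}

# fallback: locate the first sign change of r - h on a log grid and bisect
.halfpoint_bisect <- function(f, h) {
  xs <- 10^seq(-12, 12, length.out = 2401)
  d <- f(xs) - h
  k <- which(d[-1] * d[-length(d)] <= 0)
  if (!length(k)) return(NA_real_)
  k <- k[1]
  stats::uniroot(function(x) f(x) - h, c(xs[k], xs[k + 1]), tol = 1e-14)$root
}

#' Position and steepness of a response
#'
#' @param r a response: an `hb_response`, a Hill response from
#'   [hill_response()], or a plain function of `x` (handled numerically).
#' @param ... passed to methods.
#' @return list of class `hb_sharpness`: `p`, `s`, `p_u`, `s_u`, `x_half`,
#'   `m_r`, `M_r`.
#' @examples
#' position_steepness(rational_response(c(0, 0, 1), c(1, 0.01, 1)))
#' @export
position_steepness <- function(r, ...) UseMethod("position_steepness")

#' @export
position_steepness.hb_response <- function(r, ...) {
  out <- ps_rational(r$alpha, r$beta)
  if (is.null(out)) stop("response is constant: sharpness undefined")
  structure(out, class = "hb_sharpness")
}

#' @export
print.hb_sharpness <- function(x, ...) {
  cat(sprintf("<hb_sharpness> p = %.6g, s = %.6g (x_half = %.6g, range [%.4g, %.4g])\n",
              x$p, x$s, x$x_half, x$m_r, x$M_r))
  invisible(x)
}

# core rational-function path; returns NULL for (numerically) constant input
ps_rational <- function(alpha, beta, tol = .ps_tols()) {
  sc <- .x_scale(beta)
  out <- .ps_rational_scaled(alpha * sc$pw, beta * sc$pw, tol)
  if (is.null(out)) return(NULL)
  # map back to the original concentration axis; p and s are scale-free
  out$x_half <- out$x_half * sc$xc
  out$p_u <- out$p_u * sc$xc
  out$s_u <- out$s_u / sc$xc
  out
}

.ps_rational_scaled <- function(alpha, beta, tol = .ps_tols()) {
  ex <- .extrema_rational(alpha, beta, tol)
  if (is.null(ex)) return(NULL)
  C <- ex$C
  B1 <- poly_deriv(beta)
  C1 <- poly_deriv(C)
  # critical points of the slope g = C / B^2: roots of C'B - 2 C B'
  D <- poly_add(poly_mul(C1, beta), -2 * poly_mul(C, B1))
  cand <- c(0, poly_pos_roots(D, im_tol = tol$im))
  gval <- abs(poly_val(C, cand)) / poly_val(beta, cand)^2
  s_u <- max(gval)
  if (!is.finite(s_u) || s_u <= 0) return(NULL)
  p_u <- min(cand[gval >= s_u * (1 - tol$tie)])
  list(p = p_u / ex$x_half, s = s_u * ex$x_half,
       p_u = p_u, s_u = s_u, x_half = ex$x_half,
       m_r = ex$m_r, M_r = ex$M_r)
}

# lean vectorized entry used by samplers: rows of coefficient matrices in,
# (p, s) matrix out (NA rows for degenerate draws)
ps_points <- function(alpha, beta) {
  n <- nrow(alpha)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("p", "s")))
  for (k in seq_len(n)) {
    r <- ps_rational(alpha[k, ], beta[k, ])
    if (!is.null(r)) out[k, ] <- c(r$p, r$s)
  }
  out
}

#' Hill functions and the Hill line
#'
#' `hill_response(h)` wraps the Hill function `H_h(x) = x^h / (1 + x^h)` so
#' that [position_steepness()] can be applied to it (computed numerically,
#' independently of the closed form). `hill_point(h)` gives the closed-form
#' (p, s) point: for `h > 1` the maximal slope of `H_h` sits at
#' `y^h = (h-1)/(h+1)`, so `p = ((h-1)/(h+1))^(1/h)` and
#' `s = p^(h-1) (h+1)^2 / (4h)`; for `h = 1` the slope is maximal at 0 with
#' `s = 1`, and for `h < 1` the slope diverges at 0 (`p = 0`, `s = Inf`).
#' `hill_line(h)` tabulates the locus traced by these points.
#'
#' @param h Hill coefficient (> 0).
#' @return `hill_point`: named numeric `c(p, s)`.
#' @examples
#' hill_point(4)
#' @export
hill_point <- function(h) {
  if (h <= 0) stop("h must be positive")
  if (h < 1) return(c(p = 0, s = Inf))
  if (h == 1) return(c(p = 0, s = 1))
  p <- ((h - 1) / (h + 1))^(1 / h)
  s <- p^(h - 1) * (h + 1)^2 / (4 * h)
  c(p = p, s = s)
}

#' @rdname hill_point
#' @return `hill_line`: data frame with columns `h`, `p`, `s`.
#' @export
hill_line <- function(h = seq(1, 8, by = 0.05)) {
  pts <- t(vapply(h, hill_point, c(p = 0, s = 0)))
  data.frame(h = h, p = pts[, "p"], s = pts[, "s"])
}

#' @rdname hill_point
#' @return `hill_response`: an object of class `hb_hill`.
#' @export
hill_response <- function(h) {
  if (h <= 0) stop("h must be positive")
  structure(list(h = h), class = "hb_hill")
}

#' @export
predict.hb_hill <- function(object, x, ...) x^object$h / (1 + x^object$h)

#' @export
position_steepness.hb_hill <- function(r, ...) {
  h <- r$h
  f <- function(x) x^h / (1 + x^h)
  # numeric route (grid scan + derivative root-finding), independent of the
  # closed-form Hill line
  ex <- list(m_r = 0, M_r = 1,
             x_half = stats::uniroot(function(x) f(x) - 0.5, c(1e-8, 1e8),
                                     tol = 1e-14)$root)
  slope <- function(x) ifelse(x == 0, if (h > 1) 0 else if (h == 1) 1 else Inf,
                              h * x^(h - 1) / (1 + x^h)^2)
  out <- .ps_numeric_slope(slope, ex)
  structure(out, class = "hb_sharpness")
}

#' @export
position_steepness.function <- function(r, lo = 1e-8, hi = 1e8,
                                        n_grid = 1001, ...) {
  ex <- .extrema_numeric(r, lo = lo, hi = hi, n_grid = n_grid)
  if (is.null(ex)) stop("response appears constant on the probed range")
  slope <- function(x) {
    # the response may only be evaluable for x > 0 (graph steady states)
    xx <- pmax(x, 2e-9)
    hstep <- pmin(pmax(abs(xx), 1e-4) * 1e-6, xx / 2)
    (r(xx + hstep) - r(xx - hstep)) / (2 * hstep)
  }
  structure(.ps_numeric_slope(slope, ex, lo = lo, hi = hi, n_grid = n_grid),
            class = "hb_sharpness")
}

.extrema_numeric <- function(f, lo = 1e-8, hi = 1e8, n_grid = 1001) {
  xs <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  v <- f(xs)
  m_r <- min(v); M_r <- max(v)
  # refine extrema locally
  refine <- function(idx, what) {
    if (idx <= 1 || idx >= length(xs)) return(v[idx])
    o <- stats::optimize(f, c(xs[idx - 1], xs[idx + 1]),
                         maximum = (what == "max"), tol = 1e-12)
    if (what == "max") o$objective else o$objective
  }
  M_r <- max(M_r, refine(which.max(v), "max"))
  m_r <- min(m_r, refine(which.min(v), "min"))
  if (M_r - m_r < 1e-12) return(NULL)
  h <- (m_r + M_r) / 2
  d <- v - h
  k <- which(d[-1] * d[-length(d)] <= 0 & xs[-1] > 0)
  if (!length(k)) return(NULL)
  k <- k[1]
  x_half <- stats::uniroot(function(x) f(x) - h, c(max(xs[k], 1e-15), xs[k + 1]),
                           tol = 1e-14)$root
  list(m_r = m_r, M_r = M_r, x_half = x_half)
}

.ps_numeric_slope <- function(slope, ex, lo = 1e-9, hi = 1e9, n_grid = 4001) {
  xs <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  g <- abs(slope(xs))
  g0 <- abs(slope(0))
  if (!is.finite(g0)) {
    # slope diverges at the origin: sharpness is unbounded there
    return(list(p = 0, s = Inf, p_u = 0, s_u = Inf, x_half = ex$x_half,
                m_r = ex$m_r, M_r = ex$M_r))
  }
  k <- which.max(g)
  # five-point-stencil derivative of |slope|: accurate sign for root finding
  dslope <- function(x) {
    hh <- pmax(abs(x), 1e-6) * 1e-4
    (-abs(slope(x + 2 * hh)) + 8 * abs(slope(x + hh)) -
       8 * abs(slope(x - hh)) + abs(slope(x - 2 * hh))) / (12 * hh)
  }
  p_u <- NA_real_; s_u <- NA_real_
  if (k > 1L && k < length(xs)) {
    da <- dslope(xs[k - 1]); db <- dslope(xs[k + 1])
    if (is.finite(da) && is.finite(db) && da > 0 && db < 0) {
      p_u <- stats::uniroot(dslope, c(xs[k - 1], xs[k + 1]), tol = 1e-15)$root
      s_u <- abs(slope(p_u))
    }
  }
  if (!is.finite(s_u)) {
    o <- stats::optimize(function(x) abs(slope(x)),
                         c(if (k > 1L) xs[k - 1] else 0,
                           if (k < length(xs)) xs[k + 1] else xs[k] * 10),
                         maximum = TRUE, tol = 1e-13)
    s_u <- o$objective; p_u <- o$maximum
  }
  if (g0 >= s_u * (1 - 1e-9)) {
    s_u <- max(s_u, g0); p_u <- 0
  }
  list(p = p_u / ex$x_half, s = s_u * ex$x_half,
       p_u = p_u, s_u = s_u, x_half = ex$x_half,
       m_r = ex$m_r, M_r = ex$M_r)
}
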