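# fixtures are built in code; no data files

k2_graph <- function(a = 2, b = 1) {
  lf_graph(data.frame(source = c("1", "2"), target = c("2", "1"),
                      rate = c(a, b), binds_input = c(0L, 0L)),
           patterns = list("1" = integer(), "2" = integer()), n_sites = 0L)
}

reversible_triangle <- function(rates = rep(1, 6)) {
  lf_graph(data.frame(source = c("1", "2", "2", "3", "3", "1"),
                      target = c("2", "1", "3", "2", "1", "3"),
                      rate = rates, binds_input = 0L),
           patterns = list("1" = integer(), "2" = integer(), "3" = integer()),
           n_sites = 0L)
}

# resample rates of a reversible graph so the cycle condition holds:
# vertex weights gamma drawn log-uniform, each pair's rate ratio set to the
# weight ratio
equilibrate_rates <- function(g, a = 2) {
  gamma <- 10^stats::runif(length(g$vertices), -a, a)
  names(gamma) <- g$vertices
  key <- paste(pmin(g$edges$source, g$edges$target),
               pmax(g$edges$source, g$edges$target))
  base <- 10^stats::runif(nrow(g$edges), -a, a)
  base <- base[match(key, unique(key))]
  g$edges$rate <- base * gamma[g$edges$target]
  g
}

# independent dense-grid + local-refinement oracle for (p, s): slope by
# central finite differences of the response itself, never via the
# derivative-numerator root isolation used by the package
grid_ps_oracle <- function(alpha, beta) {
  f <- function(x) poly_val_oracle(alpha, x) / poly_val_oracle(beta, x)
  la <- length(alpha)
  xs <- c(0, 10^seq(-12, 12, length.out = 9601))
  v <- c(f(0), f(xs[-1]))
  rinf <- alpha[la] / beta[la]
  ref <- function(idx, maxi) {
    lo <- if (idx <= 1) 0 else xs[idx - 1]
    hi <- if (idx >= length(xs)) xs[idx] * 1e4 else xs[idx + 1]
    stats::optimize(f, c(lo, hi), maximum = maxi, tol = 1e-12)$objective
  }
  M_r <- max(max(v), rinf, ref(which.max(v), TRUE))
  m_r <- min(min(v), rinf, ref(which.min(v), FALSE))
  if (M_r - m_r < 1e-11) return(NULL)
  h <- (m_r + M_r) / 2
  d <- v - h
  near0 <- abs(d[1]) <= 1e-10 * max(abs(d))
  k <- which(d[-1] * d[-length(d)] <= 0)
  if (near0) k <- k[k > 1]
  if (!length(k)) return(NULL)
  k <- k[1]
  x_half <- stats::uniroot(function(x) f(x) - h,
                           c(max(xs[k], 1e-14), xs[k + 1]), tol = 1e-14)$root
  # slope of the normalized response q(y) = f(y * x_half) by complex-step
  # differentiation (no subtractive cancellation, so the grid can span the
  # whole relevant range)
  qslope <- function(y) {
    x <- y * x_half
    st <- x * 1e-8
    abs(Im(f(x + 1i * st)) / st) * x_half
  }
  ys <- 10^seq(-8, 6, length.out = 10501)
  gv <- qslope(ys)
  kk <- which.max(gv)
  o <- stats::optimize(qslope, c(ys[max(kk - 1, 1)], ys[min(kk + 1, length(ys))]),
                       maximum = TRUE, tol = 1e-10)
  g0 <- x_half * abs(alpha[2] * beta[1] - alpha[1] * beta[2]) / beta[1]^2
  tie <- abs(g0 - o$objective) <= 1e-5 * max(g0, o$objective)
  if (g0 >= o$objective) {
    s <- g0; p <- 0
  } else {
    s <- o$objective; p <- o$maximum
  }
  list(p = p, s = s, x_half = x_half, m_r = m_r, M_r = M_r, tie = tie)
}

poly_val_oracle <- function(a, x) {
  r <- rep(a[length(a)], length(x))
  if (length(a) > 1L) for (k in (length(a) - 1L):1L) r <- r * x + a[k]
  r
}
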