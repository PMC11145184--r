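# Dense univariate polynomial helpers. Coefficients are numeric vectors in
# ascending degree order: c(a0, a1, ...) represents a0 + a1*x + ...

poly_trim <- function(a, rel = 0) {
  if (!length(a)) return(0)
  top <- max(abs(a))
  if (top == 0) return(0)
  keep <- which(abs(a) > rel * top)
  if (!length(keep)) return(0)
  a[seq_len(max(keep))]
}

poly_val <- function(a, x) {
  r <- rep(a[length(a)], length(x))
  if (length(a) > 1L)
    for (k in (length(a) - 1L):1L) r <- r * x + a[k]
  r
}

poly_mul <- function(a, b) {
  r <- numeric(length(a) + length(b) - 1L)
  for (k in seq_along(a))
    r[k:(k + length(b) - 1L)] <- r[k:(k + length(b) - 1L)] + a[k] * b
  r
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  length(a) <- n; length(b) <- n
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  a + b
}

poly_deriv <- function(a) {
  if (length(a) <= 1L) return(0)
  a[-1L] * seq_len(length(a) - 1L)
}

poly_degree <- function(a, rel = 1e-12) {
  a <- poly_trim(a, rel = rel)
  if (length(a) == 1L && a[1] == 0) return(-Inf)
  length(a) - 1L
}

# strictly positive real roots of a polynomial, ascending; relative
# imaginary-part tolerance decides realness. polyroot() can lose several
# digits on badly scaled coefficients, so real roots are polished by a few
# guarded Newton steps.
poly_pos_roots <- function(a, im_tol = 1e-7) {
  a <- poly_trim(a, rel = 1e-14)
  if (length(a) <= 1L) return(numeric(0))
  z <- polyroot(a)
  re <- Re(z)
  real <- abs(Im(z)) <= im_tol * (1 + abs(re))
  r <- re[real & re > 0]
  if (!length(r)) return(numeric(0))
  d <- poly_deriv(a)
  for (it in 1:4) {
    fr <- poly_val(a, r)
    dr <- poly_val(d, r)
    step <- ifelse(dr != 0, fr / dr, 0)
    cand <- r - step
    ok <- cand > 0 & abs(poly_val(a, cand)) <= abs(fr)
    r <- ifelse(ok, cand, r)
  }
  sort(r)
}
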