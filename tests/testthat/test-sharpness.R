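test_that("extrema and half-point are exact for canonical responses", {
  # Hill-type rational response H_2: m = 0, M = 1, x_half = 1
  h2 <- rational_response(c(0, 0, 1), c(1, 0, 1))
  ex <- response_extrema(h2)
  expect_equal(ex$m_r, 0)
  expect_equal(ex$M_r, 1)
  expect_equal(ex$x_half, 1, tolerance = 1e-12)

  # decreasing response K/(K + x): x_half = K
  dec <- rational_response(c(5, 0), c(5, 1))
  exd <- response_extrema(dec)
  expect_equal(exd$x_half, 5, tolerance = 1e-12)
  expect_equal(c(exd$m_r, exd$M_r), c(0, 1))

  expect_error(response_extrema(rational_response(c(2, 2), c(4, 4))), "constant")
})

test_that("half-point stays strictly positive when r(0) already sits halfway", {
  # rise-then-fall response tuned (by fixed-point iteration on its own
  # extrema) so that r(0) equals (m + M)/2 to machine precision
  beta <- c(2, 10, 4)
  alpha <- c(1, 20, 1)
  for (it in 1:60) {
    ex <- response_extrema(rational_response(alpha, beta))
    alpha[1] <- (ex$m_r + ex$M_r) / 2 * beta[1]
  }
  r <- rational_response(alpha, beta)
  ex <- response_extrema(r)
  expect_equal(alpha[1] / beta[1], (ex$m_r + ex$M_r) / 2, tolerance = 1e-12)
  expect_gt(ex$x_half, 0.01)   # the next crossing, not the origin
  expect_equal(predict(r, ex$x_half), (ex$m_r + ex$M_r) / 2, tolerance = 1e-9)
})

test_that("position and steepness of Hill responses match the closed forms", {
  for (h in c(1, 1.5, 2, 3, 4, 6, 8)) {
    hp <- hill_point(h)
    ps <- position_steepness(hill_response(h))
    expect_equal(ps$p, hp[["p"]], tolerance = 1e-9)
    expect_equal(ps$s, hp[["s"]], tolerance = 1e-9)
    expect_equal(ps$x_half, 1, tolerance = 1e-12)
  }
  # closed-form spot values
  expect_equal(hill_point(1), c(p = 0, s = 1))
  expect_equal(hill_point(2), c(p = 3^-0.5, s = 2 * 3^-0.5 * 9 / 16))
  expect_equal(hill_point(4),
               c(p = (3 / 5)^0.25, s = 4 * (3 / 5)^0.75 / (8 / 5)^2))
  expect_error(hill_point(0), "positive")

  # integer Hill functions through the rational path agree too
  ps4 <- position_steepness(rational_response(c(0, 0, 0, 0, 1), c(1, 0, 0, 0, 1)))
  expect_equal(ps4$p, hill_point(4)[["p"]], tolerance = 1e-9)
  expect_equal(ps4$s, hill_point(4)[["s"]], tolerance = 1e-9)
})

test_that("sharpness is scale invariant and obeys the normalization identities", {
  set.seed(7)
  co <- sample_equilibrium_coefficients(25, 3, 2)
  for (k in 1:25) {
    ps <- position_steepness(rational_response(co$alpha[k, ], co$beta[k, ]))
    # s = s_u * x_half and p = p_u / x_half
    expect_equal(ps$s, ps$s_u * ps$x_half, tolerance = 1e-10)
    expect_equal(ps$p, ps$p_u / ps$x_half, tolerance = 1e-10)
    for (cc in c(1e-3, 1e3)) {
      sc <- cc^(0:3)
      psc <- position_steepness(rational_response(co$alpha[k, ] * sc,
                                                  co$beta[k, ] * sc))
      expect_equal(psc$p, ps$p, tolerance = 1e-9)
      expect_equal(psc$s, ps$s, tolerance = 1e-9)
    }
  }
})

test_that("root-isolation optimum matches an independent grid oracle", {
  set.seed(11)
  n_checked <- 0L
  while (n_checked < 400L) {
    l <- sample(1:4, 1)
    co <- sample_equilibrium_coefficients(1, l, 2)
    orc <- grid_ps_oracle(co$alpha[1, ], co$beta[1, ])
    if (is.null(orc)) next
    ps <- position_steepness(rational_response(co$alpha[1, ], co$beta[1, ]))
    expect_equal(ps$s, orc$s, tolerance = 1e-6 * max(1, orc$s))
    # position is only well-posed when boundary and interior maxima are not
    # in a numerical dead heat
    if (!orc$tie) expect_equal(ps$p, orc$p, tolerance = 1e-4 * max(1, orc$p))
    n_checked <- n_checked + 1L
  }
})

test_that("the global slope maximum is found across well-separated local maxima", {
  # mixture of two steep steps four decades apart: the slope has two local
  # maxima; the earlier one is (slightly) higher, so position must sit on it
  a <- 1e-2; b <- 1e2
  alpha <- c(0, 0, (a^2 + b^2) / 2, 0, 1)
  beta <- c(a^2 * b^2, 0, a^2 + b^2, 0, 1)
  ps <- position_steepness(rational_response(alpha, beta))
  orc <- grid_ps_oracle(alpha, beta)
  expect_equal(ps$s, orc$s, tolerance = 1e-6 * max(1, orc$s))
  expect_equal(ps$p, orc$p, tolerance = 1e-4)
  expect_lt(ps$p, 1)  # the earlier of the two slope peaks
})
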