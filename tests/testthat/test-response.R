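test_that("direct response evaluation respects weight bounds and limits", {
  g <- lf_hypercube(2)
  n <- length(g$vertices)
  expect_equal(response_value(g, rep(1, n), c(0.5, 2)), c(1, 1))
  expect_equal(response_value(g, rep(0, n), 1), 0)
  expect_error(response_value(g, rep(1.5, n), 1), "\\[0, 1\\]")

  # single-site occupancy is half-maximal at x = k_off / k_on
  c1 <- lf_hypercube(1, rates = c("{}->{1}" = 2, "{1}->{}" = 6))
  expect_equal(response_value(c1, c("{}" = 0, "{1}" = 1), 3), 0.5)
})

test_that("fractional saturation weights count bound sites over m", {
  g <- lf_hypercube(2)
  w <- fractional_saturation(g)
  expect_equal(w[c("{}", "{1}", "{2}", "{1,2}")],
               c("{}" = 0, "{1}" = 0.5, "{2}" = 0.5, "{1,2}" = 1))
  g4 <- lf_hypercube(4)
  expect_equal(fractional_saturation(g4)[["{1,2,3}"]], 3 / 4)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("equilibrium responses collapse to the constrained rational form", {
  # single site: r = x / (K + x)
  c1 <- lf_hypercube(1, rates = c("{}->{1}" = 2, "{1}->{}" = 6))
  rf <- equilibrium_rational_form(c1, c("{}" = 0, "{1}" = 1))
  xs <- 10^seq(-2, 2, length.out = 9)
  expect_equal(predict(rf, xs), xs / (3 + xs), tolerance = 1e-12)
  expect_equal(rf$alpha[1], 0)
  expect_true(rf$constraint_flag)

  # weights identically 1 give alpha = beta
  rf1 <- equilibrium_rational_form(c1, c("{}" = 1, "{1}" = 1))
  expect_equal(rf1$alpha, rf1$beta)

  set.seed(83)
  for (rep in 1:6) {
    g <- random_binding_graph(2, k_internal = sample(1:3, 1), a = 2,
                              equilibrium = TRUE)
    lam <- setNames(runif(length(g$vertices)), g$vertices)
    rf <- equilibrium_rational_form(g, lam)
    expect_equal(rf$l, 2L)
    expect_true(all(rf$beta > 0))
    expect_true(all(rf$alpha >= 0 & rf$alpha <= rf$beta))
    expect_lt(max(abs(predict(rf, xs) - response_value(g, lam, xs))), 1e-10)
  }

  # mutual exclusion: degree is the maximum bound count l, here l = 1 < m = 2
  set.seed(89)
  mx <- equilibrate_rates(lf_hypercube_substructure(2, removed_vertices = list(c(1, 2))))
  rfx <- equilibrium_rational_form(mx, fractional_saturation(mx))
  expect_equal(rfx$l, 1L)
  expect_lt(max(abs(predict(rfx, xs) -
                      response_value(mx, fractional_saturation(mx), xs))), 1e-10)
})

test_that("convex combinations of output weights stay inside the constraint set", {
  set.seed(97)
  g <- random_binding_graph(2, k_internal = 2, a = 2, equilibrium = TRUE)
  n <- length(g$vertices)
  l1 <- setNames(runif(n), g$vertices)
  l2 <- setNames(runif(n), g$vertices)
  for (t in c(0, 0.25, 0.8, 1)) {
    rf <- equilibrium_rational_form(g, t * l1 + (1 - t) * l2)
    expect_true(rf$constraint_flag)
  }
})

test_that("coefficient samplers respect their ranges and are seed-reproducible", {
  set.seed(1); d1 <- sample_equilibrium_coefficients(500, 2, 3)
  set.seed(1); d2 <- sample_equilibrium_coefficients(500, 2, 3)
  expect_identical(d1, d2)
  expect_true(all(d1$beta >= 1e-3 & d1$beta <= 1e3))
  expect_true(all(d1$alpha >= 1e-3 & d1$alpha <= d1$beta))

  # constrained draws are bona fide responses: 0 <= r <= 1 everywhere
  xs <- 10^seq(-5, 5, length.out = 41)
  set.seed(2)
  co <- sample_equilibrium_coefficients(1000, 2, 2)
  for (k in seq_len(1000)) {
    r <- poly_val_oracle(co$alpha[k, ], xs) / poly_val_oracle(co$beta[k, ], xs)
    expect_true(all(r >= 0 & r <= 1))
  }

  # unconstrained draws violate the coefficient condition a sizeable fraction
  # of the time and can exceed 1
  set.seed(3)
  un <- sample_unconstrained_coefficients(1000, 2, 2)
  viol <- rowSums(un$alpha > un$beta) > 0
  expect_gt(mean(viol), 0.5)
  r <- rational_response(un$alpha[which(viol)[1], ], un$beta[which(viol)[1], ])
  expect_false(r$constraint_flag)
  expect_gt(max(vapply(seq_len(1000), function(k)
    max(poly_val_oracle(un$alpha[k, ], xs) / poly_val_oracle(un$beta[k, ], xs)),
    0)), 1)

  # optional zero mass reaches the alpha = 0 boundary
  set.seed(4)
  z <- sample_equilibrium_coefficients(200, 2, 2, zero_mass = 0.5)
  expect_gt(sum(z$alpha == 0), 0)
  expect_error(sample_equilibrium_coefficients(5, 0, 2), "l must be")
  expect_error(sample_equilibrium_coefficients(5, 2, -1), "a must be")
})
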