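test_that("spanning tree enumeration matches hand counts and tree invariants", {
  t_k2 <- spanning_trees(k2_graph(), "1")
  expect_length(t_k2, 1L)
  expect_equal(t_k2[[1]][, "from"], c(from = 2L))

  # reversible triangle: one tree per choice of excluded vertex pairing
  t_tri <- spanning_trees(reversible_triangle(), "1")
  expect_length(t_tri, 3L)
  for (tr in t_tri) {
    expect_equal(nrow(tr), 2L)               # n - 1 edges
    expect_false(1L %in% tr[, "from"])       # root has no outgoing edge
    expect_equal(anyDuplicated(tr[, "from"]), 0L)  # one out-edge per vertex
  }

  t_c2 <- spanning_trees(lf_hypercube(2), "{}")
  expect_length(t_c2, 4L)  # square cycle: drop any one of the 4 undirected edges

  expect_error(spanning_trees(lf_hypercube(4), "{}"), "cap")
})

test_that("determinant tree counts agree with exhaustive enumeration", {
  expect_equal(count_spanning_trees(k2_graph(), "2"), 1)
  for (root in c("{}", "{1,2}"))
    expect_equal(count_spanning_trees(lf_hypercube(2), root), 4)
  c3 <- lf_hypercube(3)
  n_enum <- length(spanning_trees(c3, "{1}", cap = 8))
  expect_equal(count_spanning_trees(c3, "{1}"), n_enum)
  expect_equal(count_spanning_trees(c3, "{2,3}"), n_enum)  # vertex-transitive
})

test_that("tree polynomials and Laplacian minors give the same rho, exactly", {
  # dyadic-rational rates make both routes exact in binary floating point
  set.seed(101)
  for (rep in 1:10) {
    g <- random_reversible_graph(sample(3:6, 1), extra = sample(0:3, 1))
    rp <- rho_poly(g)
    for (x in c(1, 2)) {
      via_minors <- rho_at(g, x, exact = TRUE)
      via_trees <- vapply(rp, function(co) sum(co * x^(seq_along(co) - 1L)), 0)
      expect_identical(unname(via_minors), unname(via_trees))
    }
  }
})

test_that("steady states normalize, lie in the Laplacian kernel, match symmetry", {
  expect_equal(unname(steady_state(k2_graph(2, 1))), c(1, 2) / 3)
  expect_equal(unname(steady_state(reversible_triangle())), rep(1, 3) / 3)
  set.seed(7)
  g <- random_binding_graph(2, k_internal = 2, a = 2, equilibrium = FALSE)
  for (x in c(0.05, 1, 30)) {
    u <- steady_state(g, x)
    expect_equal(sum(u), 1, tolerance = 1e-12)
    expect_true(all(u > 0 & u < 1))
    expect_lt(max(abs(lf_laplacian(g, x) %*% u)), 1e-10)
  }
  # rho is a kernel vector of L (Matrix-Tree identity)
  rp <- rho_poly(lf_hypercube(2))
  for (x in c(0.5, 3)) {
    v <- vapply(rp, function(co) sum(co * x^(seq_along(co) - 1L)), 0)
    expect_lt(max(abs(lf_laplacian(lf_hypercube(2), x) %*% v)) / max(v), 1e-14)
  }
})

test_that("cycle condition detects detailed balance and its violation", {
  expect_true(cycle_condition(lf_hypercube(2)))
  g <- lf_hypercube(2, rates = c("{}->{1}" = 2))  # one side of the square doubled
  expect_false(cycle_condition(g))
  # a reversible tree has no cycles: vacuously at equilibrium
  tree <- lf_graph(data.frame(source = c("1", "2", "2", "3"),
                              target = c("2", "1", "3", "2"),
                              rate = c(5, 1, 2, 9), binds_input = 0L),
                   patterns = list("1" = integer(), "2" = integer(),
                                   "3" = integer()))
  expect_true(cycle_condition(tree))
  cyc <- lf_graph(data.frame(source = c("1", "2", "3"), target = c("2", "3", "1"),
                             rate = 1, binds_input = 0L),
                  patterns = list("1" = integer(), "2" = integer(), "3" = integer()))
  expect_error(cycle_condition(cyc), "reversible")
})

test_that("equilibrium vertex weights reproduce the general steady state", {
  c1 <- lf_hypercube(1, rates = c("{}->{1}" = 3, "{1}->{}" = 5))
  mv <- mu_vector(c1)
  expect_equal(mv$gamma[["{}"]], 1)
  expect_equal(mv$gamma[["{1}"]], 3 / 5)
  expect_equal(unname(mv$degree), c(0L, 1L))

  set.seed(23)
  for (rep in 1:5) {
    g <- random_binding_graph(2, k_internal = sample(1:3, 1), a = 2,
                              equilibrium = TRUE)
    mv <- mu_vector(g)
    expect_equal(unname(mv$degree), unname(lengths(g$patterns)))
    for (x in 10^seq(-3, 3, by = 1.5))
      expect_lt(max(abs(steady_state(g, x) - equilibrium_steady_state(g, x))),
                1e-10)
  }
  # nonequilibrium labels are rejected
  set.seed(5)
  gn <- random_binding_graph(2, k_internal = 2, a = 2, equilibrium = FALSE)
  expect_error(mu_vector(gn), "cycle condition")
})

test_that("path entropy is the log label-ratio product, additive and antisymmetric", {
  g <- k2_graph(2, 1)
  expect_equal(path_entropy(g, c("1", "2")), log(2))
  expect_equal(path_entropy(g, c("2", "1")), -log(2))
  tri <- reversible_triangle(c(3, 1, 4, 2, 5, 7))
  p12 <- path_entropy(tri, c("1", "2"))
  p23 <- path_entropy(tri, c("2", "3"))
  expect_equal(path_entropy(tri, c("1", "2", "3")), p12 + p23)
  # cycles generate no entropy at equilibrium
  set.seed(31)
  ge <- random_binding_graph(2, k_internal = 1, a = 2, equilibrium = TRUE)
  cyc <- c("{}", "{1}", "{1,2}", "{2}", "{}")
  expect_lt(abs(path_entropy(ge, cyc, x = 2.5)), 1e-12)
  expect_error(path_entropy(g, c("1", "1")), "not allowed|reversible|unknown")
})

test_that("denominator degree is m at equilibrium but exceeds it away from it", {
  set.seed(77)
  ge <- random_binding_graph(2, k_internal = 1, a = 2, equilibrium = TRUE)
  mv <- mu_vector(ge)
  expect_equal(max(mv$degree), 2L)
  gn <- random_binding_graph(2, k_internal = 1, a = 2, equilibrium = FALSE)
  den <- Reduce(function(a, b) {
    n <- max(length(a), length(b)); length(a) <- n; length(b) <- n
    a[is.na(a)] <- 0; b[is.na(b)] <- 0; a + b
  }, rho_poly(gn))
  expect_equal(length(den) - 1L, 3L)  # 2^m - 1 for the hypercube square
  expect_true(all(den > 0))
})
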