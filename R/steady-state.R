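#' Exact steady states by the Matrix-Tree theorem
#'
#' For a strongly connected graph the one-dimensional kernel of the Laplacian
#' is spanned by the vector whose i-th component is the sum, over all spanning
#' trees rooted at i, of the product of edge labels along the tree. These
#' functions compute that vector both by exhaustive enumeration (small-graph
#' oracle) and by determinants of Laplacian minors, together with equilibrium
#' shortcuts (path label-ratio products) and thermodynamic diagnostics.
#'
#' @name steady-state
NULL

# ---- spanning tree machinery -----------------------------------------------

#' Enumerate spanning trees rooted at a vertex
#'
#' Brute-force oracle: every non-root vertex picks one outgoing edge and the
#' resulting functional graph is kept iff every vertex reaches the root (no
#' cycles). Intended for graphs up to `cap` vertices.
#'
#' @param g an `lf_graph`, strongly connected.
#' @param root vertex identifier.
#' @param cap maximum vertex count accepted (default 10).
#' @return list of trees; each tree is an integer matrix with columns
#'   `from`, `to` being vertex indices of the edges (directed toward the root).
#' @export
spanning_trees <- function(g, root, cap = 10L) {
  stopifnot(inherits(g, "lf_graph"))
  n <- length(g$vertices)
  if (n > cap) stop("graph exceeds the enumeration cap (", cap, " vertices)")
  r <- match(root, g$vertices)
  if (is.na(r)) stop("unknown root vertex")
  ei <- edge_index(g)
  nonroot <- setdiff(seq_len(n), r)
  out_edges <- lapply(nonroot, function(v) which(ei$i == v))
  if (any(!lengths(out_edges))) return(list())
  trees <- list()
  choice <- rep(1L, length(nonroot))
  repeat {
    sel <- vapply(seq_along(nonroot), function(k) out_edges[[k]][choice[k]], 0L)
    # functional graph acyclic iff every vertex reaches root
    nxt <- rep(NA_integer_, n)
    nxt[nonroot] <- ei$j[sel]
    ok <- TRUE
    for (v in nonroot) {
      seen <- integer(0); w <- v
      while (!is.na(nxt[w])) {
        if (w %in% seen) { ok <- FALSE; break }
        seen <- c(seen, w); w <- nxt[w]
      }
      if (!ok) break
    }
    if (ok) trees[[length(trees) + 1L]] <-
        cbind(from = nonroot, to = ei$j[sel], edge = sel)
    k <- length(nonroot)
    while (k >= 1L) {
      if (choice[k] < length(out_edges[[k]])) { choice[k] <- choice[k] + 1L; break }
      choice[k] <- 1L; k <- k - 1L
    }
    if (k < 1L) break
  }
  trees
}

# Fraction-free (Bareiss) determinant: exact for integer matrices whose
# intermediate minors stay below 2^53.
det_bareiss <- function(M) {
  n <- nrow(M)
  if (n == 0L) return(1)
  if (n == 1L) return(M[1, 1])
  sign <- 1
  prev <- 1
  for (k in seq_len(n - 1L)) {
    if (M[k, k] == 0) {
      piv <- which(M[(k + 1L):n, k] != 0)
      if (!length(piv)) return(0)
      p <- k + piv[1]
      tmp <- M[k, ]; M[k, ] <- M[p, ]; M[p, ] <- tmp
      sign <- -sign
    }
    rows <- (k + 1L):n
    M[rows, rows] <- (M[rows, rows, drop = FALSE] * M[k, k] -
                        outer(M[rows, k], M[k, rows])) / prev
    M[rows, k] <- 0
    prev <- M[k, k]
  }
  sign * M[n, n]
}

#' Count spanning trees rooted at a vertex (exact)
#'
#' All labels are treated as 1 (structure only). Uses the Matrix-Tree
#' theorem: the count equals (up to sign) the determinant of the Laplacian
#' with the root's row and column deleted, evaluated in exact integer
#' arithmetic by fraction-free elimination.
#'
#' @inheritParams spanning_trees
#' @return integer-valued double.
#' @examples
#' count_spanning_trees(lf_hypercube(2), "{}")  # 4
#' @export
count_spanning_trees <- function(g, root) {
  stopifnot(inherits(g, "lf_graph"))
  v <- validate_graph(g)
  if (!v$strongly_connected) stop("graph is not strongly connected")
  n <- length(g$vertices)
  r <- match(root, g$vertices)
  if (is.na(r)) stop("unknown root vertex")
  L <- matrix(0, n, n)
  ei <- edge_index(g)
  L[cbind(ei$j, ei$i)] <- 1
  diag(L) <- diag(L) - colSums(L)
  d <- det_bareiss(L[-r, -r, drop = FALSE])
  (-1)^(n - 1) * d
}

# ---- rho: tree polynomial vector -------------------------------------------

#' Tree-sum polynomial vector rho(G)
#'
#' Symbolic mode (`rho_poly`) enumerates spanning trees and returns, per
#' vertex, the coefficients of the polynomial in the input concentration x
#' whose value is the sum over trees rooted there of the product of effective
#' edge labels. Numeric mode (`rho_at`) evaluates the same vector at a fixed
#' x from determinants of Laplacian first minors, avoiding enumeration.
#'
#' @inheritParams spanning_trees
#' @return `rho_poly`: named list of ascending coefficient vectors (all
#'   nonnegative). `rho_at`: named numeric vector.
#' @export
rho_poly <- function(g, cap = 10L) {
  stopifnot(inherits(g, "lf_graph"))
  ei <- edge_index(g)
  out <- vector("list", length(g$vertices))
  names(out) <- g$vertices
  for (v in g$vertices) {
    trees <- spanning_trees(g, v, cap = cap)
    if (!length(trees)) stop("no spanning trees rooted at ", v,
                             " (graph not strongly connected?)")
    co <- numeric(sum(ei$flag) + 1L)
    for (tr in trees) {
      e <- tr[, "edge"]
      deg <- sum(ei$flag[e]) + 1L
      co[deg] <- co[deg] + prod(ei$rate[e])
    }
    out[[v]] <- poly_trim(co)
  }
  out
}

#' @rdname rho_poly
#' @param x input concentration (> 0).
#' @param exact use fraction-free elimination (exact when the scaled labels
#'   are integers); otherwise LU via [det()].
#' @export
rho_at <- function(g, x, exact = FALSE) {
  stopifnot(inherits(g, "lf_graph"))
  if (x <= 0) stop("x must be positive")
  L <- lf_laplacian(g, x)
  n <- nrow(L)
  sgn <- (-1)^(n - 1)
  vals <- vapply(seq_len(n), function(r) {
    M <- L[-r, -r, drop = FALSE]
    if (exact) det_bareiss(M) else det(M)
  }, 0)
  out <- sgn * vals
  names(out) <- g$vertices
  out
}

#' Steady-state probability distribution
#'
#' The normalized tree-sum vector (the unique kernel direction of the
#' Laplacian); valid for any strongly connected graph, at or away from
#' thermodynamic equilibrium. Computed by Grassmann-Taksar-Heyman state
#' elimination, which involves only additions and divisions of nonnegative
#' quantities and therefore achieves componentwise relative accuracy even
#' for vanishingly small probabilities (important when conditioning on
#' binding-pattern blocks at extreme concentrations).
#'
#' @param g an `lf_graph`, strongly connected.
#' @param x input concentration (> 0).
#' @return named numeric vector summing to 1.
#' @export
steady_state <- function(g, x = 1) {
  stopifnot(inherits(g, "lf_graph"))
  if (!is.numeric(x) || length(x) != 1L || x <= 0) stop("x must be a positive scalar")
  ei <- edge_index(g)
  n <- length(g$vertices)
  A <- matrix(0, n, n)
  A[cbind(ei$i, ei$j)] <- ei$rate * x^ei$flag
  u <- gth_kernel(A)
  names(u) <- g$vertices
  u
}

# Grassmann-Taksar-Heyman stationary vector of a rate matrix A[i, j] = rate
# i -> j (diagonal ignored). Subtraction-free, hence componentwise accurate.
gth_kernel <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(1)
  for (k in n:2) {
    idx <- seq_len(k - 1L)
    s <- sum(A[k, idx])
    if (s <= 0) stop("graph is not strongly connected")
    A[idx, idx] <- A[idx, idx] + outer(A[idx, k], A[k, idx]) / s
  }
  u <- numeric(n)
  u[1] <- 1
  for (k in 2:n)
    u[k] <- sum(u[seq_len(k - 1L)] * A[seq_len(k - 1L), k]) / sum(A[k, seq_len(k - 1L)])
  u / sum(u)
}

# ---- thermodynamic diagnostics ---------------------------------------------

# spanning tree (undirected, over reversible pairs) from vertex 1:
# returns parent index, parent edge (forward i->v), and reverse edge
reversible_tree <- function(g) {
  ei <- edge_index(g)
  n <- length(g$vertices)
  rev_of <- match(paste0(ei$j, ",", ei$i), paste0(ei$i, ",", ei$j))
  if (any(is.na(rev_of))) stop("graph is not reversible")
  parent <- rep(NA_integer_, n)
  pedge <- rep(NA_integer_, n)  # edge parent -> v
  seen <- logical(n); seen[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (e in which(ei$i == v)) {
      w <- ei$j[e]
      if (!seen[w]) {
        seen[w] <- TRUE; parent[w] <- v; pedge[w] <- e
        queue <- c(queue, w)
      }
    }
  }
  if (!all(seen)) stop("graph is not connected")
  list(parent = parent, pedge = pedge, rev_of = rev_of, ei = ei)
}

# per-vertex log(rate-ratio) potential and net binding count along tree paths
tree_potentials <- function(g) {
  tr <- reversible_tree(g)
  ei <- tr$ei
  n <- length(g$vertices)
  pot <- rep(NA_real_, n); pot[1] <- 0
  net <- rep(NA_integer_, n); net[1] <- 0L
  order <- integer(0); queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    kids <- which(tr$parent == v)
    for (w in kids) {
      e <- tr$pedge[w]; er <- tr$rev_of[e]
      pot[w] <- pot[v] + log(ei$rate[e]) - log(ei$rate[er])
      net[w] <- net[v] + ei$flag[e] - ei$flag[er]
      queue <- c(queue, w)
    }
  }
  list(pot = pot, net = net, tr = tr)
}

#' Detailed balance via the cycle condition
#'
#' A reversible graph can reach thermodynamic equilibrium iff the product of
#' forward/backward label ratios equals 1 around every cycle. Binding-edge
#' concentration factors cancel around any cycle (patterns return to
#' themselves), so the check involves rate constants only. The test is run on
#' a fundamental cycle basis built from a spanning tree: each non-tree
#' reversible pair closes one basis cycle.
#'
#' @param g a reversible `lf_graph`.
#' @param tol tolerance on |log of the cycle label-ratio product| (scale-free).
#' @return logical.
#' @export
cycle_condition <- function(g, tol = 1e-9) {
  stopifnot(inherits(g, "lf_graph"))
  tp <- tree_potentials(g)
  ei <- tp$tr$ei
  rev_of <- tp$tr$rev_of
  tree_edges <- stats::na.omit(tp$tr$pedge)
  in_tree <- logical(length(ei$i))
  in_tree[tree_edges] <- TRUE
  in_tree[rev_of[tree_edges]] <- TRUE
  for (e in which(!in_tree)) {
    # cycle: tree path 1->i, edge i->j, tree path j->1
    lg <- tp$pot[ei$i[e]] + log(ei$rate[e]) - log(ei$rate[rev_of[e]]) - tp$pot[ei$j[e]]
    if (abs(lg) > tol) return(FALSE)
  }
  TRUE
}

#' Equilibrium vertex weights from path label-ratio products
#'
#' At thermodynamic equilibrium the steady state is determined by the vector
#' of path products from a reference vertex: traversing any reversible path
#' from the reference to vertex i and multiplying forward/backward label
#' ratios yields `mu_i = gamma_i * x^{b_i}`, where `b_i` is the number of
#' input sites bound in i (the reference must have an empty binding pattern)
#' and `gamma_i` is x-free. Path independence is guaranteed by the cycle
#' condition, which is checked first.
#'
#' @param g a reversible `lf_graph` satisfying the cycle condition.
#' @param reference vertex with empty binding pattern (default: first such).
#' @param tol tolerance passed to [cycle_condition()].
#' @return list with named vectors `gamma` (positive, reference = 1) and
#'   `degree` (x exponent, equal to the pattern size), plus `reference`.
#' @export
mu_vector <- function(g, reference = NULL, tol = 1e-9) {
  stopifnot(inherits(g, "lf_graph"))
  if (is.null(reference)) {
    empt <- g$vertices[lengths(g$patterns) == 0L]
    if (!length(empt)) stop("no vertex with empty binding pattern")
    reference <- empt[1]
  }
  r <- match(reference, g$vertices)
  if (is.na(r)) stop("unknown reference vertex")
  if (length(g$patterns[[reference]]))
    stop("reference vertex must have an empty binding pattern")
  if (!cycle_condition(g, tol = tol))
    stop("cycle condition violated: graph cannot reach equilibrium")
  # root the potential tree at the reference by re-indexing: recompute with
  # the reference first
  perm <- c(r, setdiff(seq_along(g$vertices), r))
  g2 <- g
  g2$vertices <- g$vertices[perm]
  g2$patterns <- g$patterns[perm]
  tp <- tree_potentials(g2)
  gamma <- exp(tp$pot)
  deg <- tp$net
  names(gamma) <- names(deg) <- g2$vertices
  psize <- lengths(g2$patterns)
  if (!all(deg == psize))
    stop("net binding along paths disagrees with vertex patterns")
  list(gamma = gamma[g$vertices], degree = deg[g$vertices], reference = reference)
}

#' Equilibrium steady state from vertex weights
#'
#' Normalizes `gamma_i x^{b_i}` — the grand-canonical partition-function
#' route, valid only under detailed balance.
#'
#' @inheritParams mu_vector
#' @param x input concentration (> 0).
#' @return named probability vector.
#' @export
equilibrium_steady_state <- function(g, x = 1, reference = NULL) {
  mv <- mu_vector(g, reference = reference)
  w <- mv$gamma * x^mv$degree
  w / sum(w)
}

#' Entropy generated along a reversible path
#'
#' The log of the product of forward/backward label ratios along a path of
#' reversible edges; zero around every cycle exactly when the graph can reach
#' thermodynamic equilibrium. Additive under concatenation, antisymmetric
#' under reversal.
#'
#' @param g a `lf_graph`.
#' @param path character vector of consecutive vertex identifiers.
#' @param x input concentration entering binding-edge labels (default 1).
#' @return numeric scalar, `log mu(P)`.
#' @export
path_entropy <- function(g, path, x = 1) {
  stopifnot(inherits(g, "lf_graph"), length(path) >= 2L)
  ei <- edge_index(g)
  idx <- match(path, g$vertices)
  if (anyNA(idx)) stop("unknown vertex in path")
  key <- paste0(ei$i, ",", ei$j)
  tot <- 0
  for (k in seq_len(length(idx) - 1L)) {
    e <- match(paste0(idx[k], ",", idx[k + 1L]), key)
    er <- match(paste0(idx[k + 1L], ",", idx[k]), key)
    if (is.na(e) || is.na(er))
      stop("path step ", path[k], " -> ", path[k + 1L],
           " is not a reversible edge pair")
    tot <- tot + log(ei$rate[e] * x^ei$flag[e]) - log(ei$rate[er] * x^ei$flag[er])
  }
  tot
}
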