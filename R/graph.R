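#' Labelled directed graphs for the linear framework
#'
#' A linear framework graph represents a finite-state, continuous-time Markov
#' process: vertices are molecular states, directed edges are transitions, and
#' each edge carries a positive rate constant (units 1/time). Edges at which
#' one molecule of the input ligand binds are flagged, so that the effective
#' transition label at input concentration `x` is `rate * x^binds_input`
#' (first-order mass-action binding). Unbinding, and any transition that does
#' not consume input ligand, is zeroth order in `x`. Each vertex carries a
#' *binding pattern*: the subset of the `m` input sites occupied in that
#' state. Concentrations of all other ligands are folded into the rate
#' constants (they are held constant by the reservoir assumption).
#'
#' @param edges a data frame (or object coercible to one) with columns
#'   `source`, `target`, `rate`, `binds_input`; one row per directed edge.
#' @param patterns named list mapping every vertex identifier to an integer
#'   vector of bound sites (possibly empty), each a subset of `1:n_sites`.
#' @param n_sites number of input binding sites `m >= 0`. Defaults to the
#'   largest site index appearing in `patterns`.
#'
#' @return an object of class `lf_graph` with fields `vertices`, `patterns`,
#'   `edges`, `n_sites`.
#' @examples
#' g <- lf_graph(
#'   data.frame(source = c("1", "2"), target = c("2", "1"),
#'              rate = c(2, 1), binds_input = c(0, 0)),
#'   patterns = list("1" = integer(), "2" = integer()), n_sites = 0)
#' steady_state(g, x = 1)  # (1/3, 2/3)
#' @export
lf_graph <- function(edges, patterns, n_sites = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("source", "target", "rate", "binds_input")
  if (!all(need %in% names(edges)))
    stop("`edges` must have columns source, target, rate, binds_input")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (is.null(names(patterns)) || any(!nzchar(names(patterns))))
    stop("`patterns` must be a fully named list")
  patterns <- lapply(patterns, function(p) sort(unique(as.integer(p))))
  vertices <- names(patterns)
  if (anyDuplicated(vertices)) stop("duplicate vertex identifiers in `patterns`")
  if (is.null(n_sites)) {
    n_sites <- if (length(unlist(patterns))) max(unlist(patterns)) else 0L
  }
  n_sites <- as.integer(n_sites)
  if (n_sites < 0) stop("n_sites must be >= 0")

  bad <- setdiff(c(edges$source, edges$target), vertices)
  if (length(bad)) stop("edge references unknown vertex: ", paste(bad, collapse = ", "))
  if (any(!is.finite(edges$rate)) || any(edges$rate <= 0))
    stop("all edge rates must be strictly positive and finite")
  if (!all(edges$binds_input %in% c(0, 1)))
    stop("binds_input must be 0 or 1 (binding is first order in the input)")
  edges$binds_input <- as.integer(edges$binds_input)
  if (any(edges$source == edges$target)) stop("self-loops are not allowed")
  if (anyDuplicated(edges[, c("source", "target")]))
    stop("at most one edge per ordered vertex pair")
  for (p in patterns) {
    if (length(p) && (min(p) < 1L || max(p) > n_sites))
      stop("binding pattern uses a site outside 1..n_sites")
  }
  # binding edges must add exactly one site; flag-0 edges must not gain a site
  for (k in seq_len(nrow(edges))) {
    ps <- patterns[[edges$source[k]]]
    pt <- patterns[[edges$target[k]]]
    gained <- setdiff(pt, ps)
    lost <- setdiff(ps, pt)
    if (edges$binds_input[k] == 1L) {
      if (length(gained) != 1L || length(lost) != 0L)
        stop("binding edge ", edges$source[k], "->", edges$target[k],
             " must add exactly one input site to the pattern")
    } else if (length(gained) != 0L) {
      stop("edge ", edges$source[k], "->", edges$target[k],
           " gains input site(s) but is not flagged binds_input = 1")
    }
  }
  structure(
    list(vertices = vertices, patterns = patterns,
         edges = edges[, need], n_sites = n_sites),
    class = "lf_graph")
}

#' @export
print.lf_graph <- function(x, ...) {
  v <- validate_graph(x)
  cat(sprintf(
    "<lf_graph> %d vertices, %d edges, %d input site(s); strongly connected: %s, reversible: %s\n",
    length(x$vertices), nrow(x$edges), x$n_sites, v$strongly_connected, v$reversible))
  invisible(x)
}

#' @export
format.lf_graph <- function(x, ...) {
  sprintf("<lf_graph: %d vertices, %d edges>", length(x$vertices), nrow(x$edges))
}

pattern_label <- function(p) {
  if (!length(p)) "{}" else paste0("{", paste(p, collapse = ","), "}")
}

#' Hypercube binding graph
#'
#' Builds the hypercube structure `C_m`: one vertex per subset of the `m`
#' input sites, reversible edges between subsets differing in exactly one
#' site, with the binding direction flagged (label `rate * x`). Vertices are
#' named by their pattern, e.g. `"{}"`, `"{1}"`, `"{1,2}"`.
#'
#' @param m number of input binding sites (>= 1).
#' @param rates optional named numeric vector of rates keyed
#'   `"source->target"` using the pattern labels; edges not named get
#'   `default_rate`.
#' @param default_rate rate used for unspecified edges (default 1, so that a
#'   bare structure supports tree counting).
#' @return an `lf_graph` with `2^m` vertices and `m * 2^m` directed edges.
#' @examples
#' cube <- lf_hypercube(2)
#' length(cube$vertices)  # 4
#' @export
lf_hypercube <- function(m, rates = NULL, default_rate = 1) {
  m <- as.integer(m)
  if (m < 1) stop("m must be >= 1")
  subsets <- hypercube_patterns(m)
  labels <- vapply(subsets, pattern_label, "")
  src <- tgt <- character(0); flg <- integer(0)
  for (i in seq_along(subsets)) {
    S <- subsets[[i]]
    for (s in setdiff(seq_len(m), S)) {
      j <- match(pattern_label(sort(c(S, s))), labels)
      src <- c(src, labels[i], labels[j])
      tgt <- c(tgt, labels[j], labels[i])
      flg <- c(flg, 1L, 0L)
    }
  }
  key <- paste0(src, "->", tgt)
  r <- rep(default_rate, length(key))
  if (!is.null(rates)) {
    unknown <- setdiff(names(rates), key)
    if (length(unknown)) stop("rate given for nonexistent edge: ", unknown[1])
    r[match(names(rates), key)] <- rates
  }
  names(subsets) <- labels
  lf_graph(data.frame(source = src, target = tgt, rate = r, binds_input = flg,
                      stringsAsFactors = FALSE),
           patterns = subsets, n_sites = m)
}

hypercube_patterns <- function(m) {
  subsets <- list(integer(0))
  for (s in seq_len(m))
    subsets <- c(subsets, lapply(subsets, function(S) c(S, s)))
  lapply(subsets, sort)
}

#' Hypercube substructure
#'
#' Removes vertices (mutual exclusion: patterns that cannot occur) and/or
#' reversible edge pairs (ordered binding: transitions that are not used)
#' from `C_m`. The result must remain strongly connected and reversible.
#'
#' @param m number of input sites.
#' @param removed_vertices list of patterns (integer vectors) to delete.
#' @param removed_edge_pairs list of two-element lists of patterns; both
#'   directions between the two patterns are deleted.
#' @inheritParams lf_hypercube
#' @return an `lf_graph` substructure of `C_m`.
#' @export
lf_hypercube_substructure <- function(m, removed_vertices = list(),
                                      removed_edge_pairs = list(),
                                      rates = NULL, default_rate = 1) {
  g <- lf_hypercube(m, rates = rates, default_rate = default_rate)
  drop_v <- vapply(removed_vertices, function(p) pattern_label(sort(as.integer(p))), "")
  keep <- !(g$vertices %in% drop_v)
  verts <- g$vertices[keep]
  ed <- g$edges[g$edges$source %in% verts & g$edges$target %in% verts, ]
  for (pair in removed_edge_pairs) {
    a <- pattern_label(sort(as.integer(pair[[1]])))
    b <- pattern_label(sort(as.integer(pair[[2]])))
    ed <- ed[!((ed$source == a & ed$target == b) | (ed$source == b & ed$target == a)), ]
  }
  g2 <- lf_graph(ed, patterns = g$patterns[verts], n_sites = m)
  v <- validate_graph(g2)
  if (!v$strongly_connected || !v$reversible)
    stop("removal breaks strong connectivity or reversibility")
  g2
}

#' Laplacian matrix of a linear framework graph
#'
#' Returns the generator `L(G)` of the master equation `du/dt = L(G) u`:
#' off-diagonal entry `(j, i)` equals the effective label of the edge
#' `i -> j` at input concentration `x`, and each diagonal entry makes its
#' column sum to zero (conservation of probability).
#'
#' @param g an `lf_graph`.
#' @param x input ligand concentration (> 0); binding edges contribute
#'   `rate * x`.
#' @return a square numeric matrix with dimnames the vertex identifiers.
#' @export
lf_laplacian <- function(g, x = 1) {
  stopifnot(inherits(g, "lf_graph"))
  if (!is.numeric(x) || length(x) != 1L || x <= 0) stop("x must be a positive scalar")
  n <- length(g$vertices)
  L <- matrix(0, n, n, dimnames = list(g$vertices, g$vertices))
  lab <- g$edges$rate * x^g$edges$binds_input
  i <- match(g$edges$source, g$vertices)
  j <- match(g$edges$target, g$vertices)
  L[cbind(j, i)] <- lab
  diag(L) <- diag(L) - colSums(L)
  L
}

#' Structural validity report
#'
#' A graph has a unique steady state iff it is strongly connected; detailed
#' balance additionally requires reversibility (every edge accompanied by its
#' reverse).
#'
#' @param g an `lf_graph`.
#' @return list with logical fields `strongly_connected` and `reversible`.
#' @export
validate_graph <- function(g) {
  stopifnot(inherits(g, "lf_graph"))
  n <- length(g$vertices)
  i <- match(g$edges$source, g$vertices)
  j <- match(g$edges$target, g$vertices)
  adj_out <- split(j, factor(i, levels = seq_len(n)))
  adj_in <- split(i, factor(j, levels = seq_len(n)))
  reach <- function(adj) {
    seen <- logical(n); seen[1] <- TRUE; stack <- 1L
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- adj[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      stack <- c(stack, new)
    }
    all(seen)
  }
  sc <- n <= 1L || (reach(adj_out) && reach(adj_in))
  rev <- all(paste0(j, ",", i) %in% paste0(i, ",", j))
  list(strongly_connected = sc, reversible = rev)
}

# index-based edge lookup helpers used across modules
edge_index <- function(g) {
  list(i = match(g$edges$source, g$vertices),
       j = match(g$edges$target, g$vertices),
       rate = g$edges$rate, flag = g$edges$binds_input)
}
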