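#' Coarse-graining onto binding patterns
#'
#' Any strongly connected reversible graph, however complicated its internal
#' states (conformations, coregulators, other ligands), can be coarse-grained
#' onto the hypercube substructure indexed by input-binding patterns: vertices
#' sharing a pattern are merged, and the coarse edge labels are chosen so that
#' the coarse steady state equals the block sums of the fine steady state and
#' the coarse graph satisfies the cycle condition, even when the fine graph
#' does not.
#'
#' @name coarse-graining
NULL

#' Partition vertices by input-binding pattern
#'
#' @param g an `lf_graph`.
#' @return named list mapping pattern labels (e.g. `"{1,2}"`) to character
#'   vectors of vertices carrying that pattern.
#' @export
partition_by_pattern <- function(g) {
  stopifnot(inherits(g, "lf_graph"))
  lab <- vapply(g$patterns, pattern_label, "")
  split(g$vertices, lab)[unique(lab)]
}

#' Coarse-grain a graph onto its binding-pattern substructure
#'
#' Builds the coarse graph whose vertices are the occupied binding patterns.
#' A coarse edge `w -> z` exists iff some fine edge crosses between the
#' blocks; its label is `Q * sum of rho_j(G) over the target block`,
#' evaluated at concentration `x`. With these labels the coarse graph
#' satisfies the cycle condition by construction and its steady state equals
#' the block sums of the fine steady state (at the same `x`), whether or not
#' the fine graph is at equilibrium. `Q` fixes dimensions only; it cancels
#' from all steady-state quantities.
#'
#' @param g a strongly connected, reversible `lf_graph`.
#' @param x input concentration at which labels are evaluated (default 1).
#' @param Q positive dimensional constant (default 1).
#' @return an `lf_graph` over pattern vertices, with attributes `provenance`
#'   (list with the partition, `x`, and `Q`).
#' @export
coarse_grain <- function(g, x = 1, Q = 1) {
  stopifnot(inherits(g, "lf_graph"))
  v <- validate_graph(g)
  if (!v$strongly_connected || !v$reversible)
    stop("coarse-graining requires a strongly connected, reversible graph")
  if (Q <= 0) stop("Q must be positive")
  part <- partition_by_pattern(g)
  rho <- rho_at(g, x)
  block_sum <- vapply(part, function(vs) sum(rho[vs]), 0)
  block_of <- rep(names(part), lengths(part))
  names(block_of) <- unlist(part)
  # coarse edges: ordered block pairs crossed by at least one fine edge
  bs <- block_of[g$edges$source]
  bt <- block_of[g$edges$target]
  cross <- bs != bt
  pairs <- unique(data.frame(source = bs[cross], target = bt[cross],
                             stringsAsFactors = FALSE))
  pat_of <- function(lab) {
    if (lab == "{}") integer(0)
    else as.integer(strsplit(sub("\\}$", "", sub("^\\{", "", lab)), ",")[[1]])
  }
  flag <- integer(nrow(pairs)); rate <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ps <- pat_of(pairs$source[k]); pt <- pat_of(pairs$target[k])
    flag[k] <- as.integer(length(pt) == length(ps) + 1L && all(ps %in% pt))
    lab_val <- Q * block_sum[[pairs$target[k]]]
    # store rate so that rate * x^flag reproduces the label at this x
    rate[k] <- lab_val / x^flag[k]
  }
  patterns <- lapply(names(part), pat_of)
  names(patterns) <- names(part)
  cg <- lf_graph(data.frame(source = pairs$source, target = pairs$target,
                            rate = rate, binds_input = flag,
                            stringsAsFactors = FALSE),
                 patterns = patterns, n_sites = g$n_sites)
  attr(cg, "provenance") <- list(partition = part, x = x, Q = Q)
  cg
}

#' Conditional steady-state probabilities within pattern blocks
#'
#' `chi_i` is the steady-state probability of fine vertex i conditioned on
#' its binding-pattern block. At thermodynamic equilibrium these are
#' independent of the input concentration (the concentration factors cancel
#' within a block); away from equilibrium they generically vary with x.
#'
#' @inheritParams coarse_grain
#' @return named numeric vector over fine vertices; each block sums to 1.
#' @export
conditional_probabilities <- function(g, x = 1) {
  u <- steady_state(g, x)
  part <- partition_by_pattern(g)
  chi <- u
  for (vs in part) chi[vs] <- u[vs] / sum(u[vs])
  chi
}

#' Response via the coarse-grained graph
#'
#' Evaluates the input-output response `r(x) = sum_i lambda_i u_i*` through
#' the coarse route: block conditional probabilities times the coarse steady
#' state. Agrees with the direct fine-graph evaluation at every x.
#'
#' @inheritParams coarse_grain
#' @param weights named vector of output weights `lambda_i` in `[0, 1]`.
#' @param x_grid concentrations at which to evaluate.
#' @return numeric vector along `x_grid`.
#' @export
coarse_response <- function(g, weights, x_grid) {
  stopifnot(inherits(g, "lf_graph"))
  weights <- check_weights(g, weights)
  part <- partition_by_pattern(g)
  vapply(x_grid, function(x) {
    cg <- coarse_grain(g, x)
    uS <- steady_state(cg, x)
    chi <- conditional_probabilities(g, x)
    tot <- 0
    for (S in names(part)) {
      vs <- part[[S]]
      tot <- tot + sum(weights[vs] * chi[vs]) * uS[[S]]
    }
    tot
  }, 0)
}
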