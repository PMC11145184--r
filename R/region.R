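#' Position-steepness region estimation
#'
#' The set of (p, s) points attainable by equilibrium responses with a given
#' number of input binding sites is estimated by sampling coefficient vectors
#' of the equilibrium rational form, binning the resulting (p, s) points on a
#' square grid, and then pushing the occupied region outward with a two-phase
#' mutation search along its working boundary. At equilibrium the region
#' never extends beyond the Hill point of `H_m` in both coordinates; a
#' nonequilibrium sampler on the hypercube demonstrably escapes it.
#'
#' @name region
NULL

# cell indices can be astronomically large in the wings (responses with tiny
# x_half); keep them as exact doubles and format without scientific notation
cell_key <- function(ip, is) sprintf("%.0f,%.0f", ip, is)

#' Working boundary of an occupancy grid
#'
#' A cell counts as boundary iff it is occupied and at least one of its four
#' axis neighbors (above/below in the column, left/right in the row) is
#' empty.
#'
#' @param cells integer matrix (or data frame) with two columns of cell
#'   indices `(ip, is)`; one row per occupied cell.
#' @return logical vector along the rows of `cells`.
#' @export
working_boundary <- function(cells) {
  cells <- as.matrix(cells)
  if (!nrow(cells)) return(logical(0))
  occ <- cell_key(cells[, 1], cells[, 2])
  nb_empty <- function(dp, ds) !(cell_key(cells[, 1] + dp, cells[, 2] + ds) %in% occ)
  nb_empty(1, 0) | nb_empty(-1, 0) | nb_empty(0, 1) | nb_empty(0, -1)
}

#' Equilibrium coefficient sampler for region estimation
#'
#' Bundles the draw/mutate/evaluate triple used by [estimate_region()] to
#' explore the universal equilibrium region: parameters are the `2(l+1)`
#' rational-form coefficients, drawn as in
#' [sample_equilibrium_coefficients()]; mutation multiplies each coefficient
#' by `10^eps` with `eps ~ U(-delta, delta)` independently, clips to the
#' sampling box `[10^-a, 10^a]`, and re-clips each numerator coefficient to
#' stay below its denominator partner.
#'
#' @param l degree (= number of input sites).
#' @param a exponent half-range.
#' @param delta mutation half-width in log10 units (default 0.25).
#' @return a sampler list with functions `sample()`, `mutate(params)`,
#'   `evaluate(params)` (returns `c(p, s)` or `NULL`).
#' @export
equilibrium_coefficient_sampler <- function(l, a, delta = 0.25) {
  k <- l + 1L
  clip <- function(v) pmin(pmax(v, 10^(-a)), 10^a)
  list(
    sample = function() {
      co <- sample_equilibrium_coefficients(1L, l, a)
      c(co$alpha[1, ], co$beta[1, ])
    },
    mutate = function(params) {
      p <- clip(params * 10^stats::runif(2L * k, -delta, delta))
      p[1:k] <- pmin(p[1:k], p[(k + 1L):(2L * k)])
      p
    },
    evaluate = function(params) {
      r <- ps_rational(params[1:k], params[(k + 1L):(2L * k)])
      if (is.null(r)) NULL else c(r$p, r$s)
    })
}

#' Estimate a (p, s) region by boundary exploration
#'
#' Phase 0 seeds the occupancy grid with `n_init` independent draws. The
#' main loop then repeatedly picks a working-boundary cell and (phase 1)
#' mutates its archived parameter set until a mutant lands in an empty cell,
#' then (phase 2) chooses a target point outside the boundary — the cell
#' center displaced outward along the empty-neighbor direction — and
#' greedily mutates to shrink the distance to it, which prevents the search
#' from stalling in deep valleys of the boundary. The run converges when no
#' new boundary cell has appeared for `stagnation_limit` consecutive
#' iterations (one boundary cell processed per iteration).
#'
#' @param sampler a sampler triple, e.g. [equilibrium_coefficient_sampler()].
#' @param n_init number of seeding draws (default 1e5).
#' @param cell_size side length of the square grid cells (default 0.005).
#' @param stagnation_limit convergence patience in iterations (default 1500).
#' @param max_iter hard cap on iterations (default `40 * stagnation_limit`).
#' @param phase_tries mutation attempts per phase per iteration (default 200).
#' @param target_offset phase-2 target displacement in cells (default 3).
#' @param seed optional integer seed; the whole run is reproducible given it.
#' @return object of class `hb_region`: `occupancy` (data frame `ip, is,
#'   count`), `boundary` (logical along occupancy), `cell_size`,
#'   `hyperparams`, `trace` (new boundary cells per iteration), `n_points`.
#' @export
estimate_region <- function(sampler, n_init = 1e5, cell_size = 0.005,
                            stagnation_limit = 1500,
                            max_iter = 40L * stagnation_limit,
                            phase_tries = 200L, target_offset = 3,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  occ <- new.env(parent = emptyenv())   # key -> count
  arch <- new.env(parent = emptyenv())  # key -> list(cell, params, point)
  bnd <- new.env(parent = emptyenv())   # key -> TRUE for boundary cells
  new_bnd_flag <- FALSE

  is_occ <- function(k) !is.null(occ[[k]])
  refresh_bnd <- function(cell) {
    k <- cell_key(cell[1], cell[2])
    if (!is_occ(k)) return(invisible())
    open <- !is_occ(cell_key(cell[1] + 1, cell[2])) ||
      !is_occ(cell_key(cell[1] - 1, cell[2])) ||
      !is_occ(cell_key(cell[1], cell[2] + 1)) ||
      !is_occ(cell_key(cell[1], cell[2] - 1))
    if (open) {
      if (is.null(bnd[[k]])) { bnd[[k]] <- TRUE; new_bnd_flag <<- TRUE }
    } else if (!is.null(bnd[[k]])) rm(list = k, envir = bnd)
    invisible()
  }
  add_point <- function(pt, params) {
    cell <- floor(pt / cell_size)
    k <- cell_key(cell[1], cell[2])
    if (is.null(occ[[k]])) {
      occ[[k]] <- 1L
      arch[[k]] <- list(cell = cell, params = params, point = pt)
      refresh_bnd(cell)
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
        refresh_bnd(cell + d)
      TRUE
    } else {
      occ[[k]] <- occ[[k]] + 1L
      FALSE
    }
  }

  n_fail <- 0L
  for (i in seq_len(n_init)) {
    par <- sampler$sample()
    pt <- sampler$evaluate(par)
    if (is.null(pt) || !all(is.finite(pt))) { n_fail <- n_fail + 1L; next }
    add_point(pt, par)
  }
  if (n_fail >= n_init) stop("sampler failed on every initialization draw")
  new_bnd_flag <- FALSE  # seeding growth does not count toward stagnation

  trace <- integer(0)
  stagnant <- 0L
  iter <- 0L
  while (stagnant < stagnation_limit && iter < max_iter) {
    iter <- iter + 1L
    keys <- ls(bnd)
    if (!length(keys)) break
    k <- keys[sample.int(length(keys), 1L)]
    entry <- arch[[k]]
    new_cells <- 0L

    # phase 1: mutate until an empty cell is hit
    for (t in seq_len(phase_tries)) {
      mp <- sampler$mutate(entry$params)
      pt <- sampler$evaluate(mp)
      if (is.null(pt) || !all(is.finite(pt))) next
      if (add_point(pt, mp)) { new_cells <- new_cells + 1L; break }
    }

    # phase 2: pull toward a target beyond the boundary
    dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    open <- !vapply(seq_len(4), function(d)
      is_occ(cell_key(entry$cell[1] + dirs[d, 1], entry$cell[2] + dirs[d, 2])),
      TRUE)
    if (any(open)) {
      dir <- colSums(dirs[open, , drop = FALSE])
      nn <- sqrt(sum(dir^2))
      if (nn > 0) {
        target <- (entry$cell + 0.5) * cell_size + target_offset * cell_size * dir / nn
        cur_par <- entry$params
        cur_d <- sqrt(sum((entry$point - target)^2))
        for (t in seq_len(phase_tries)) {
          mp <- sampler$mutate(cur_par)
          pt <- sampler$evaluate(mp)
          if (is.null(pt) || !all(is.finite(pt))) next
          if (add_point(pt, mp)) new_cells <- new_cells + 1L
          d <- sqrt(sum((pt - target)^2))
          if (d < cur_d) { cur_d <- d; cur_par <- mp }
        }
      }
    }

    if (new_bnd_flag) { stagnant <- 0L } else stagnant <- stagnant + 1L
    new_bnd_flag <- FALSE
    trace <- c(trace, new_cells)
  }

  keys <- ls(occ)
  ij <- do.call(rbind, strsplit(keys, ",", fixed = TRUE))
  occupancy <- data.frame(ip = as.numeric(ij[, 1]), is = as.numeric(ij[, 2]),
                          count = vapply(keys, function(k) occ[[k]], 0L),
                          row.names = NULL)
  structure(list(
    occupancy = occupancy,
    boundary = working_boundary(occupancy[, c("ip", "is")]),
    cell_size = cell_size,
    hyperparams = list(n_init = n_init, stagnation_limit = stagnation_limit,
                       max_iter = max_iter, phase_tries = phase_tries,
                       target_offset = target_offset, seed = seed),
    trace = trace, n_points = n_init - n_fail,
    iterations = iter),
    class = "hb_region")
}

#' @export
print.hb_region <- function(x, ...) {
  cat(sprintf("<hb_region> %d occupied cells (%d boundary), cell size %g, %d iterations\n",
              nrow(x$occupancy), sum(x$boundary), x$cell_size, x$iterations))
  invisible(x)
}

#' Plot an estimated (p, s) region
#'
#' Draws the occupied cells (boundary cells darker) with the Hill line
#' overlaid and integer Hill coefficients marked. Axis limits default to the
#' neighborhood of the Hill line; the sparse grid itself is unbounded.
#'
#' @param x an `hb_region`.
#' @param xlim,ylim plot window in (p, s) units.
#' @param hill_h range of Hill coefficients for the overlay line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hb_region <- function(x, xlim = c(0, 1), ylim = c(0, 2),
                           hill_h = seq(1, 8, by = 0.02), ...) {
  cs <- x$cell_size
  occ <- x$occupancy
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "position p",
                 ylab = "steepness s", ...)
  graphics::rect(occ$ip * cs, occ$is * cs, (occ$ip + 1) * cs, (occ$is + 1) * cs,
                 col = ifelse(x$boundary, "grey35", "grey75"), border = NA)
  hl <- hill_line(hill_h)
  graphics::lines(hl$p, hl$s, col = "blue", lwd = 1.5)
  ih <- hill_line(seq_len(max(hill_h)))
  graphics::points(ih$p, ih$s, pch = 19, col = "blue", cex = 0.6)
  graphics::text(ih$p, ih$s, labels = ih$h, pos = 4, col = "blue", cex = 0.8)
  invisible(x)
}

#' Nonequilibrium (p, s) samples on the hypercube
#'
#' Draws independent log-uniform edge labels on `C_m` with no cycle
#' constraint (detailed balance generically violated), computes the
#' fractional-saturation response exactly — for `m <= 3` via the spanning
#' tree polynomial in x, otherwise numerically from Laplacian minors — and
#' returns its (p, s) point per draw.
#'
#' @param m number of input sites (>= 2).
#' @param a exponent half-range for log10 rates.
#' @param n number of draws.
#' @param equilibrium if `TRUE`, labels are instead derived from random
#'   vertex weights (log10 gamma uniform in `[-a, a]`), which satisfies the
#'   cycle condition by construction — the equilibrium control.
#' @param seed optional integer seed.
#' @return data frame with columns `p`, `s` (NA for degenerate draws) and
#'   attribute `rates`: the matrix of sampled rate constants.
#' @export
noneq_ps_sample <- function(m, a, n, equilibrium = FALSE, seed = NULL) {
  if (m < 2) stop("m must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  g <- lf_hypercube(m)
  n_edges <- nrow(g$edges)
  lam <- fractional_saturation(g)
  use_sym <- m <= 3L
  if (use_sym) {
    tree_tab <- lapply(g$vertices, function(v) {
      trees <- spanning_trees(g, v, cap = 8L)
      list(edges = t(vapply(trees, function(tr) tr[, "edge"], integer(2^m - 1L))),
           deg = vapply(trees, function(tr) sum(g$edges$binds_input[tr[, "edge"]]), 0L))
    })
  }
  rates <- matrix(NA_real_, n, n_edges)
  out <- matrix(NA_real_, n, 2)
  nv <- length(g$vertices)
  for (k in seq_len(n)) {
    if (equilibrium) {
      gam <- 10^stats::runif(nv, -a, a)
      names(gam) <- g$vertices
      base <- 10^stats::runif(n_edges, -a, a)
      # symmetrize the base rate over reversible pairs, then tilt by weights
      key <- paste(pmin(g$edges$source, g$edges$target),
                   pmax(g$edges$source, g$edges$target))
      base <- base[match(key, unique(key))]
      rt <- base * gam[g$edges$target]
    } else {
      rt <- 10^stats::runif(n_edges, -a, a)
    }
    rates[k, ] <- rt
    if (use_sym) {
      maxdeg <- 2^m - 1L
      num <- numeric(maxdeg + 1L); den <- numeric(maxdeg + 1L)
      lrt <- log(rt)
      for (vi in seq_len(nv)) {
        tt <- tree_tab[[vi]]
        prods <- exp(rowSums(matrix(lrt[tt$edges], nrow(tt$edges))))
        co <- numeric(maxdeg + 1L)
        agg <- tapply(prods, tt$deg, sum)
        co[as.integer(names(agg)) + 1L] <- agg
        den <- den + co
        num <- num + lam[[vi]] * co
      }
      r <- ps_rational(num, den)
      if (!is.null(r)) out[k, ] <- c(r$p, r$s)
    } else {
      gk <- g
      gk$edges$rate <- rt
      f <- function(x) vapply(x, function(xx) sum(lam * steady_state(gk, xx)), 0)
      ps <- tryCatch(position_steepness(f), error = function(e) NULL)
      if (!is.null(ps)) out[k, ] <- c(ps$p, ps$s)
    }
  }
  res <- data.frame(p = out[, 1], s = out[, 2])
  attr(res, "rates") <- rates
  res
}

#' Filter points that exceed the Hill barrier
#'
#' Returns the rows whose position and steepness both strictly exceed those
#' of the Hill function `H_h`. Either coordinate alone may exceed its Hill
#' value at equilibrium, but not both simultaneously; points passing this
#' filter therefore certify nonequilibrium behavior.
#'
#' @param points data frame with columns `p`, `s`.
#' @param h Hill coefficient of the reference barrier.
#' @return the filtered data frame.
#' @export
exceeds_hill_barrier <- function(points, h) {
  hp <- hill_point(h)
  ok <- !is.na(points$p) & points$p > hp[["p"]] & points$s > hp[["s"]]
  points[ok, , drop = FALSE]
}
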