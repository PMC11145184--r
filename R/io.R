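#' Graph file formats and fixture generators
#'
#' Graphs are serialized as an edge-list TSV (columns `source`, `target`,
#' `rate`, `binds_input`; '.' decimal, 17 significant digits) plus a
#' companion JSON file mapping each vertex to its binding pattern, e.g.
#' `{"v3": [1, 2]}`. The pair round-trips exactly.
#'
#' @name graph-io
NULL

#' @rdname graph-io
#' @param g an `lf_graph`.
#' @param path_edges path of the edge-list TSV.
#' @param path_patterns path of the pattern JSON.
#' @export
write_graph_files <- function(g, path_edges, path_patterns) {
  stopifnot(inherits(g, "lf_graph"))
  ed <- g$edges
  ed$rate <- formatC(ed$rate, digits = 17, format = "g")
  utils::write.table(ed, path_edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pat <- g$patterns
  pat <- lapply(pat, function(p) if (length(p)) as.integer(p) else integer(0))
  jsonlite::write_json(list(n_sites = g$n_sites, patterns = pat),
                       path_patterns, auto_unbox = TRUE, digits = NA)
  invisible(g)
}

#' @rdname graph-io
#' @return `read_graph_files`: a validated `lf_graph`.
#' @export
read_graph_files <- function(path_edges, path_patterns) {
  ed <- utils::read.table(path_edges, sep = "\t", header = TRUE,
                          comment.char = "", quote = "",
                          colClasses = c("character", "character",
                                         "numeric", "integer"))
  if (!identical(names(ed), c("source", "target", "rate", "binds_input")))
    stop("edge file must have header: source target rate binds_input")
  meta <- jsonlite::read_json(path_patterns, simplifyVector = TRUE)
  pats <- meta$patterns
  pats <- lapply(pats, function(p) if (is.null(p) || !length(p)) integer(0) else as.integer(p))
  lf_graph(ed, patterns = pats, n_sites = meta$n_sites)
}

#' Random binding graphs with internal structure
#'
#' Generates test systems whose vertices carry both an input-binding pattern
#' and hidden internal states (conformations, a second ligand, ...): each
#' occupied pattern of `C_m` gets `k_internal` internal copies, internal
#' copies of a pattern are connected in a reversible chain, and every
#' hypercube edge is realized at every internal copy (copy k of pattern S
#' binds to copy k of S plus one site), so binding and internal transitions
#' interleave in cycles, as they do when a conformation or a second ligand
#' persists through input binding. Rates are drawn log-uniformly.
#'
#' With `equilibrium = TRUE` every vertex receives a random weight
#' `log10 gamma` uniform on `[-a, a]` and each reversible pair's rate ratio
#' is set to the weight ratio (times x on binding edges), so the cycle
#' condition holds by construction. Otherwise all rates are independent and
#' detailed balance generically fails.
#'
#' @param m number of input binding sites.
#' @param k_internal internal states per binding pattern (default 2).
#' @param a exponent half-range for log10 rates/weights (default 2).
#' @param equilibrium sample at thermodynamic equilibrium? (default TRUE)
#' @param extra_internal_edges additional random internal reversible pairs
#'   between copies of the same pattern (default 0).
#' @return an `lf_graph` with `2^m * k_internal` vertices.
#' @export
random_binding_graph <- function(m, k_internal = 2L, a = 2, equilibrium = TRUE,
                                 extra_internal_edges = 0L) {
  stopifnot(m >= 1, k_internal >= 1)
  pats <- hypercube_patterns(m)
  plab <- vapply(pats, pattern_label, "")
  vname <- function(pl, k) if (k_internal == 1L) pl else paste0(pl, "#", k)
  vertices <- unlist(lapply(plab, function(pl) vapply(seq_len(k_internal),
                                                      function(k) vname(pl, k), "")))
  patterns <- rep(pats, each = k_internal)
  names(patterns) <- vertices

  src <- tgt <- character(0); flg <- integer(0)
  # internal chains within each pattern
  if (k_internal > 1L) {
    for (pl in plab) for (k in seq_len(k_internal - 1L)) {
      src <- c(src, vname(pl, k), vname(pl, k + 1L))
      tgt <- c(tgt, vname(pl, k + 1L), vname(pl, k))
      flg <- c(flg, 0L, 0L)
    }
  }
  # binding/unbinding edges between adjacent patterns, one per internal copy
  for (i in seq_along(pats)) {
    S <- pats[[i]]
    for (s in setdiff(seq_len(m), S)) {
      j <- match(pattern_label(sort(c(S, s))), plab)
      for (ki in seq_len(k_internal)) {
        src <- c(src, vname(plab[i], ki), vname(plab[j], ki))
        tgt <- c(tgt, vname(plab[j], ki), vname(plab[i], ki))
        flg <- c(flg, 1L, 0L)
      }
    }
  }
  ed <- data.frame(source = src, target = tgt, rate = 1, binds_input = flg,
                   stringsAsFactors = FALSE)
  ed <- ed[!duplicated(ed[, c("source", "target")]), ]

  n_pair <- nrow(ed) / 2L
  if (equilibrium) {
    gamma <- 10^stats::runif(length(vertices), -a, a)
    names(gamma) <- vertices
    key <- paste(pmin(ed$source, ed$target), pmax(ed$source, ed$target))
    base <- 10^stats::runif(nrow(ed), -a, a)
    base <- base[match(key, unique(key))]
    ed$rate <- base * gamma[ed$target]
    g <- lf_graph(ed, patterns = patterns, n_sites = m)
    attr(g, "gamma") <- gamma
  } else {
    ed$rate <- 10^stats::runif(nrow(ed), -a, a)
    g <- lf_graph(ed, patterns = patterns, n_sites = m)
  }
  g
}

#' Hypercube with one extra non-input site
#'
#' The `C_(m+1)`-style structure: the input ligand binds at sites `1..m` and
#' a second, non-input ligand occupies an additional site, represented as two
#' internal copies of every binding pattern (free/occupied) with the second
#' ligand's concentration folded into its binding rates. This is the classic
#' transcription-factor-plus-polymerase arrangement.
#'
#' @inheritParams random_binding_graph
#' @return an `lf_graph` with `2^(m+1)` vertices; vertices with the second
#'   site occupied are suffixed `#2`.
#' @export
hypercube_plus_one <- function(m, a = 2, equilibrium = TRUE) {
  random_binding_graph(m, k_internal = 2L, a = a, equilibrium = equilibrium)
}

#' Random small strongly connected graphs (oracle fixtures)
#'
#' Draws a random reversible connected structure on `n` vertices (random
#' spanning tree plus `extra` reversible chords) with dyadic-rational rates
#' (`numerator/8`), exactly representable in binary floating point so that
#' tree-product identities can be checked bit-exactly. Patterns are empty
#' (no input sites) unless `m > 0`, in which case vertex patterns are
#' assigned along a random hypercube-consistent labelling.
#'
#' @param n number of vertices (>= 2).
#' @param extra number of chord pairs beyond the spanning tree.
#' @param max_num rates are `k/8` with `k` uniform on `1..max_num`.
#' @return an `lf_graph`.
#' @export
random_reversible_graph <- function(n, extra = 2L, max_num = 40L) {
  stopifnot(n >= 2)
  verts <- as.character(seq_len(n))
  src <- tgt <- integer(0)
  for (v in 2:n) {
    u <- sample.int(v - 1L, 1L)
    src <- c(src, u, v); tgt <- c(tgt, v, u)
  }
  tries <- 0L
  while (extra > 0L && tries < 50L) {
    uv <- sample.int(n, 2L)
    tries <- tries + 1L
    if (any(src == uv[1] & tgt == uv[2])) next
    src <- c(src, uv[1], uv[2]); tgt <- c(tgt, uv[2], uv[1])
    extra <- extra - 1L
  }
  rate <- sample.int(max_num, length(src), replace = TRUE) / 8
  pats <- rep(list(integer(0)), n)
  names(pats) <- verts
  lf_graph(data.frame(source = verts[src], target = verts[tgt], rate = rate,
                      binds_input = 0L, stringsAsFactors = FALSE),
           patterns = pats, n_sites = 0L)
}

#' Export helpers
#'
#' `steady_state_table` tabulates the steady state with patterns;
#' `region_cells` extracts the occupancy grid of an `hb_region` as a data
#' frame ready for CSV export.
#'
#' @param g an `lf_graph`; `x` input concentration.
#' @return data frame.
#' @export
steady_state_table <- function(g, x = 1) {
  u <- steady_state(g, x)
  data.frame(vertex = g$vertices,
             pattern = vapply(g$patterns, pattern_label, ""),
             probability = as.numeric(u[g$vertices]),
             row.names = NULL)
}

#' @rdname steady_state_table
#' @param region an `hb_region`.
#' @export
region_cells <- function(region) {
  stopifnot(inherits(region, "hb_region"))
  cbind(region$occupancy, boundary = region$boundary)
}
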