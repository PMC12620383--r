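#' Build a school-year friendship network from nominations
#'
#' Constructs the directed nomination graph for one roster at one wave and
#' its undirected projection under a configurable symmetrization rule:
#' `"union"` links two pupils if either nominates the other, `"intersection"`
#' only if both do, and `"directed"` keeps the directed graph for metric
#' computation. Self-nominations, duplicate nominations and nominees missing
#' from the roster are dropped with a warning.
#'
#' @param nominations Data frame with columns `nominator_id`, `nominee_id`
#'   and optionally `wave`.
#' @param roster Vector of pupil ids on the roster (all nodes, including
#'   isolates), or a cohort data frame with a `pupil_id` column.
#' @param wave Wave to select from `nominations` (ignored if no `wave`
#'   column); stored on the result.
#' @param symmetrization One of `"union"`, `"intersection"`, `"directed"`.
#' @param school_id Optional school label stored on the result.
#' @return An object of class `year_network` with fields `school_id`,
#'   `wave`, `symmetrization`, `graph` (directed igraph) and `proj`
#'   (the projection used for metrics).
#' @export
build_network <- function(nominations, roster, wave = 0L,
                          symmetrization = c("union", "intersection",
                                             "directed"),
                          school_id = NA) {
  symmetrization <- match.arg(symmetrization)
  if (is.data.frame(roster)) roster <- roster$pupil_id
  if (length(roster) == 0) pm_stop("build_network(): empty roster")
  roster <- as.character(roster)
  if (anyDuplicated(roster)) pm_stop("build_network(): duplicate roster ids")
  ed <- nominations
  if ("wave" %in% names(ed)) ed <- ed[ed$wave == wave, , drop = FALSE]
  from <- as.character(ed$nominator_id)
  to <- as.character(ed$nominee_id)
  off <- !(from %in% roster) | !(to %in% roster)
  if (any(off)) {
    pm_warn("OFF_ROSTER", "dropped %d nomination(s) with endpoints off roster",
            sum(off))
    from <- from[!off]; to <- to[!off]
  }
  self <- from == to
  if (any(self)) {
    pm_warn("SELF_NOMINATION", "dropped %d self-nomination(s)", sum(self))
    from <- from[!self]; to <- to[!self]
  }
  dup <- duplicated(paste(from, to))
  if (any(dup)) {
    pm_warn("DUPLICATE_NOMINATION", "dropped %d duplicate nomination(s)",
            sum(dup))
    from <- from[!dup]; to <- to[!dup]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = roster, stringsAsFactors = FALSE))
  proj <- switch(symmetrization,
    union = igraph::as_undirected(g, mode = "collapse"),
    intersection = igraph::as_undirected(g, mode = "mutual"),
    directed = g)
  structure(list(school_id = school_id, wave = wave,
                 symmetrization = symmetrization, graph = g, proj = proj),
            class = "year_network")
}

#' @export
print.year_network <- function(x, ...) {
  cat(sprintf("<year_network> school=%s wave=%s rule=%s: %d nodes, %d nominations, %d projected edges\n",
              x$school_id, x$wave, x$symmetrization,
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              igraph::ecount(x$proj)))
  invisible(x)
}

.net_proj <- function(net) {
  if (inherits(net, "year_network")) net$proj else net
}

#' Local clustering coefficient (0-10 scale)
#'
#' Fraction of closed pairs among a node's neighbours in the undirected
#' projection, times 10 (the reporting scale used throughout; disable with
#' `scale10 = FALSE`). Nodes of degree < 2 score 0.
#'
#' @param net A `year_network` or an igraph graph.
#' @param node Optional node name(s); default all nodes.
#' @param scale10 Multiply by 10 (default TRUE).
#' @return Named numeric vector.
#' @export
local_clustering <- function(net, node = NULL, scale10 = TRUE) {
  u <- .net_proj(net)
  vals <- igraph::transitivity(u, type = "local", isolates = "zero")
  vals[is.na(vals)] <- 0
  names(vals) <- igraph::V(u)$name
  if (scale10) vals <- 10 * vals
  .pick_nodes(vals, node)
}

.pick_nodes <- function(vals, node) {
  if (is.null(node)) return(vals)
  node <- as.character(node)
  miss <- setdiff(node, names(vals))
  if (length(miss) > 0) pm_stop("unknown node(s): %s", paste(miss, collapse = ", "))
  vals[node]
}

#' Eigenvector centrality (unit Euclidean norm, 0-10 scale)
#'
#' Leading eigenvector of the (undirected projection's) adjacency matrix,
#' computed by shifted power iteration (`A + I`, which shares eigenvectors
#' with `A` and is robust to bipartite oscillation) to a relative tolerance
#' of 1e-10, normalized to unit Euclidean norm, non-negative, times 10.
#' In disconnected graphs the result is the limit of power iteration from a
#' uniform positive start: mass concentrates on the component(s) with the
#' largest leading eigenvalue, and nodes outside them (including isolates,
#' which are zeroed exactly) score ~0.
#'
#' @inheritParams local_clustering
#' @return Named numeric vector (empty graph gives an empty vector).
#' @export
eigenvector_centrality <- function(net, node = NULL, scale10 = TRUE) {
  u <- .net_proj(net)
  n <- igraph::vcount(u)
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  nm <- igraph::V(u)$name
  if (igraph::ecount(u) == 0) return(.pick_nodes(stats::setNames(rep(0, n), nm), node))
  A <- as.matrix(igraph::as_adjacency_matrix(u, sparse = TRUE))
  if (igraph::is_directed(u)) A <- t(A)  # x_j grows with nominators of j
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(100000L)) {
    y <- as.numeric(A %*% x) + x
    ny <- sqrt(sum(y^2))
    if (ny == 0) { x <- rep(0, n); break }
    y <- y / ny
    if (max(abs(y - x)) <= 1e-10 * max(abs(y))) { x <- y; break }
    x <- y
  }
  x[abs(x) < 1e-12] <- 0
  deg <- igraph::degree(u)
  x[deg == 0] <- 0
  ns <- sqrt(sum(x^2))
  if (ns > 0) x <- x / ns
  vals <- stats::setNames((if (scale10) 10 else 1) * x, nm)
  .pick_nodes(vals, node)
}

#' Closeness centrality (Wasserman-Faust component-adjusted, 0-10 scale)
#'
#' For a node reaching `r` nodes (including itself) at total geodesic
#' distance `s` in a graph of `n` nodes:
#' `((r - 1) / s) * ((r - 1) / (n - 1))`, times 10. Isolates score 0. The
#' component adjustment keeps scores comparable across disconnected school
#' networks.
#'
#' @inheritParams local_clustering
#' @return Named numeric vector.
#' @export
closeness_centrality <- function(net, node = NULL, scale10 = TRUE) {
  u <- .net_proj(net)
  n <- igraph::vcount(u)
  nm <- igraph::V(u)$name
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  if (n == 1) return(.pick_nodes(stats::setNames(0, nm), node))
  d <- igraph::distances(u, mode = "out")
  vals <- apply(d, 1, function(row) {
    reach <- is.finite(row)
    r <- sum(reach)           # includes self (distance 0)
    if (r <= 1) return(0)
    s <- sum(row[reach])
    ((r - 1) / s) * ((r - 1) / (n - 1))
  })
  vals <- stats::setNames((if (scale10) 10 else 1) * vals, nm)
  .pick_nodes(vals, node)
}

#' Betweenness centrality (normalized, 0-10 scale)
#'
#' Shortest-path betweenness divided by `(n - 1)(n - 2) / 2`, times 10.
#'
#' @inheritParams local_clustering
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net, node = NULL, scale10 = TRUE) {
  u <- .net_proj(net)
  n <- igraph::vcount(u)
  nm <- igraph::V(u)$name
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  if (n < 3) return(.pick_nodes(stats::setNames(rep(0, n), nm), node))
  b <- igraph::betweenness(u, directed = igraph::is_directed(u))
  vals <- stats::setNames((if (scale10) 10 else 1) * b / ((n - 1) * (n - 2) / 2), nm)
  .pick_nodes(vals, node)
}

#' Gini coefficient of the degree sequence (0-10 scale)
#'
#' Heterogeneity of the school network's (undirected projection) degree
#' distribution: `G = sum_ij |d_i - d_j| / (2 n^2 mean(d))`, times 10.
#' Zero iff all degrees are equal; all-zero degree sequences are defined as
#' 0 with a warning.
#'
#' @inheritParams local_clustering
#' @return A single numeric score.
#' @export
gini_degree <- function(net, scale10 = TRUE) {
  u <- .net_proj(net)
  d <- igraph::degree(u, mode = "all")
  if (length(d) == 0) return(0)
  if (all(d == 0)) {
    pm_warn("ZERO_DEGREES", "all degrees zero; Gini degree defined as 0")
    return(0)
  }
  gini_index(d, scale10 = scale10)
}

#' Gini inequality index of a non-negative sequence
#'
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, the index underlying
#' [gini_degree()]; exposed for computing the coefficient directly from a
#' degree sequence.
#'
#' @param x Non-negative numeric values (e.g. a degree sequence).
#' @param scale10 Multiply by 10, the network-table reporting scale
#'   (default FALSE here).
#' @return The Gini index.
#' @export
gini_index <- function(x, scale10 = FALSE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0 || all(x == 0)) return(0)
  xs <- sort(x)
  # mean-difference form of the pairwise-sum definition
  g <- 2 * sum(seq_len(n) * xs) / (n * sum(xs)) - (n + 1) / n
  (if (scale10) 10 else 1) * g
}

#' Per-node metrics and school summary for a network
#'
#' @param net A `year_network`.
#' @param scale10 Report on the 0-10 scale (default TRUE).
#' @return A list with `nodes` (pupil_id, wave, clustering, eigenvector,
#'   closeness, betweenness) and `school` (school_id, wave, n_nodes,
#'   n_edges, gini_degree), plus a `meta` record of the symmetrization and
#'   scaling conventions.
#' @export
school_network_metrics <- function(net, scale10 = TRUE) {
  stopifnot(inherits(net, "year_network"))
  nodes <- data.frame(
    pupil_id = igraph::V(net$proj)$name,
    wave = net$wave,
    clustering = unname(local_clustering(net, scale10 = scale10)),
    eigenvector = unname(eigenvector_centrality(net, scale10 = scale10)),
    closeness = unname(closeness_centrality(net, scale10 = scale10)),
    betweenness = unname(betweenness_centrality(net, scale10 = scale10)),
    stringsAsFactors = FALSE
  )
  school <- data.frame(
    school_id = net$school_id, wave = net$wave,
    n_nodes = igraph::vcount(net$graph), n_edges = igraph::ecount(net$graph),
    gini_degree = suppressWarnings(gini_degree(net, scale10 = scale10)))
  list(nodes = nodes, school = school,
       meta = list(symmetrization = net$symmetrization, scale10 = scale10))
}
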