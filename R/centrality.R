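#' Build a simple weighted undirected graph from an edge table
#'
#' Validates the edge list (no self-loops, no duplicate unordered pairs) and
#' substitutes non-finite weights: an `Inf` odds-ratio weight, the "every
#' association shared" sentinel, is replaced by the maximum finite weight in
#' the network (configurable), so all analysis weights are finite and
#' positive.
#'
#' @param edges A tibble with columns `u`, `v`, `weight` (e.g. from
#'   [build_network()] or [read_edges()]).
#' @param inf_weight Replacement for infinite weights: `"max"` (default, the
#'   largest finite weight present, or 1 if none) or a positive number.
#' @return An undirected simple [igraph::igraph] with a `weight` edge
#'   attribute.
#' @export
as_weighted_graph <- function(edges, inf_weight = "max") {
  stopifnot(all(c("u", "v", "weight") %in% names(edges)))
  if (any(edges$u == edges$v)) abort("self-loops are not allowed")
  key <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v), sep = "\r")
  if (anyDuplicated(key)) abort("duplicate edges are not allowed")
  w <- edges$weight
  if (any(is.na(w)) || any(w <= 0, na.rm = TRUE)) {
    abort("edge weights must be positive (odds ratios of retained edges)")
  }
  if (any(is.infinite(w))) {
    sub <- if (identical(inf_weight, "max")) {
      if (any(is.finite(w))) max(w[is.finite(w)]) else 1
    } else {
      stopifnot(is.numeric(inf_weight), inf_weight > 0)
      inf_weight
    }
    w[is.infinite(w)] <- sub
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$u, to = edges$v), directed = FALSE
  )
  igraph::E(g)$weight <- w
  g
}

graph_matrices <- function(g) {
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE))
  A <- (W > 0) * 1
  list(W = W, A = A, nodes = igraph::V(g)$name)
}

#' Seven weighted centrality measures
#'
#' Computes, for every node of a weighted undirected graph, the seven
#' centrality measures used for consensus hub ranking:
#' \describe{
#'   \item{degree}{sum of incident edge weights (weighted degree/strength).}
#'   \item{betweenness, closeness}{shortest-path measures under the distance
#'     `1/weight` (stronger enrichment = closer); computed per connected
#'     component, isolated nodes score 0. Closeness of `v` is
#'     `(n_c - 1) / sum of distances` within its component of size `n_c`.}
#'   \item{eigenvector}{principal eigenvector of the weighted adjacency by
#'     power iteration (identity shift for bipartite safety, tolerance
#'     1e-10), non-negative, scaled to unit maximum.}
#'   \item{network}{`NC(v) = sum over neighbours u of ECC(u, v)` where the
#'     edge clustering coefficient `ECC(u, v)` is the weighted triangle count
#'     through the edge (geometric-mean weights) over
#'     `min(deg_u, deg_v) - 1` (unweighted degrees); 0 when the denominator
#'     or the triangle count vanishes.}
#'   \item{lac}{local average connectivity: the mean, over neighbours u of v,
#'     of u's degree within the subgraph induced by the neighbourhood
#'     `N(v)`.}
#'   \item{information}{resistance-based (current-flow) centrality with
#'     conductances equal to the weights, per component; isolated nodes 0.}
#' }
#'
#' @param g A weighted undirected igraph (see [as_weighted_graph()]).
#' @return A tibble: `node`, then one numeric column per measure.
#' @export
centrality_suite <- function(g) {
  if (igraph::vcount(g) == 0) abort("empty graph")
  if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
  gm <- graph_matrices(g)
  dist_g <- g
  igraph::E(dist_g)$weight <- 1 / igraph::E(g)$weight
  tibble(
    node = gm$nodes,
    degree = as.numeric(igraph::strength(g)),
    betweenness = as.numeric(igraph::betweenness(dist_g, directed = FALSE)),
    closeness = closeness_per_component(dist_g),
    eigenvector = eigenvector_power(gm$W),
    network = network_centrality(gm$W, gm$A),
    lac = local_average_connectivity(gm$A),
    information = information_centrality(gm$W)
  )
}

closeness_per_component <- function(dist_g) {
  n <- igraph::vcount(dist_g)
  D <- igraph::distances(dist_g, weights = igraph::E(dist_g)$weight)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
}

eigenvector_power <- function(W, tol = 1e-10, max_iter = 10000) {
  n <- nrow(W)
  if (n == 1) return(1)
  # identity shift keeps the dominant eigenvalue unique in magnitude on
  # bipartite components without changing the eigenvector
  M <- W + diag(n)
  x <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    y <- as.numeric(M %*% x)
    y <- y / max(y)
    if (max(abs(y - x)) < tol) break
    x <- y
  }
  y / max(y)
}

network_centrality <- function(W, A) {
  n <- nrow(W)
  deg <- rowSums(A)
  Wg <- W^(1 / 3)
  # weighted triangle count through each edge: sum over common neighbours of
  # the geometric mean of the three edge weights
  Tri <- (Wg %*% Wg) * Wg # Tri[u,v] = w_uv^(1/3) * sum_w (w_uw w_wv)^(1/3)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) return(0)
    ecc <- vapply(nb, function(u) {
      den <- min(deg[u], deg[v]) - 1
      tri <- Tri[u, v]
      if (den <= 0 || tri == 0) 0 else tri / den
    }, numeric(1))
    sum(ecc)
  }, numeric(1))
}

local_average_connectivity <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) return(0)
    sub <- A[nb, nb, drop = FALSE]
    mean(rowSums(sub))
  }, numeric(1))
}

information_centrality <- function(W) {
  n <- nrow(W)
  scores <- numeric(n)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
  )$membership
  for (k in unique(comp)) {
    idx <- which(comp == k)
    nc <- length(idx)
    if (nc < 2) next
    Wk <- W[idx, idx, drop = FALSE]
    L <- diag(rowSums(Wk)) - Wk
    C <- solve(L + matrix(1, nc, nc))
    Tt <- sum(diag(C))
    R <- rowSums(C)
    scores[idx] <- nc / (nc * diag(C) + Tt - 2 * R)
  }
  scores
}

#' Monte-Carlo edge-percolation centrality
#'
#' Each replicate retains every edge independently with probability
#' proportional to its normalized weight (`weight / sum(weight)`, so a
#' single-edge graph retains its edge with probability 1); a node's score is
#' its mean percolated connectivity across replicates, i.e. the average
#' fraction of the other nodes left in its component. Deterministic for a
#' fixed (graph, reps, seed).
#'
#' @param g A weighted undirected igraph.
#' @param reps Number of percolation replicates (default 1000).
#' @param seed RNG seed (required).
#' @return A tibble `node`, `epc`, with attributes `reps` and `seed`.
#' @export
epc <- function(g, reps = 1000, seed) {
  stopifnot(reps >= 1, !missing(seed))
  if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
  n <- igraph::vcount(g)
  w <- igraph::E(g)$weight
  prob <- w / sum(w)
  ends <- igraph::as_edgelist(g, names = FALSE)
  acc <- numeric(n)
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      keep <- stats::runif(length(prob)) <= prob
      sub <- igraph::graph_from_edgelist(ends[keep, , drop = FALSE],
                                         directed = FALSE)
      sub <- igraph::add_vertices(sub, max(0, n - igraph::vcount(sub)))
      cmp <- igraph::components(sub)
      acc <- acc + (cmp$csize[cmp$membership[seq_len(n)]] - 1) / (n - 1)
    }
  })
  structure(
    tibble(node = igraph::V(g)$name, epc = acc / reps),
    reps = reps, seed = seed
  )
}

#' Consensus hub ranking across centrality measures
#'
#' Ranks nodes under each centrality measure (score descending, ties broken
#' lexicographically by name), takes the top `top_t` of each list, and counts
#' for every node the number of measures whose top list contains it (its
#' agreement). Nodes with agreement at or above `min_agreement` form the
#' consensus hub list.
#'
#' @param scores A tibble with a `node` column and one numeric column per
#'   measure (e.g. from [centrality_suite()]).
#' @param top_t Size of each measure's top list (default 100).
#' @param min_agreement Agreement needed for consensus (default 5).
#' @return An object of class `centrality_report`: a list with `ranks` (tibble
#'   of per-measure ranks), `agreement` (tibble `node`, `agreement`), and
#'   `consensus` (tibble of consensus nodes sorted by agreement descending
#'   then name).
#' @export
consensus <- function(scores, top_t = 100, min_agreement = 5) {
  measures <- setdiff(names(scores), "node")
  if (top_t < 1 || min_agreement > length(measures)) {
    abort(sprintf("need top_t >= 1 and min_agreement <= %d measures",
                  length(measures)))
  }
  rank_one <- function(s) {
    ord <- order(-s, scores$node)
    r <- integer(length(s))
    r[ord] <- seq_along(s)
    r
  }
  ranks <- tibble(node = scores$node)
  for (mm in measures) ranks[[mm]] <- rank_one(scores[[mm]])
  in_top <- as.matrix(ranks[measures]) <= top_t
  agreement <- tibble(node = scores$node, agreement = rowSums(in_top)) |>
    dplyr::arrange(dplyr::desc(.data$agreement), .data$node)
  structure(
    list(
      ranks = ranks,
      agreement = agreement,
      consensus = dplyr::filter(agreement, .data$agreement >= min_agreement),
      top_t = top_t, min_agreement = min_agreement, measures = measures
    ),
    class = "centrality_report"
  )
}

#' @exportS3Method base::print
print.centrality_report <- function(x, ...) {
  cat(sprintf(
    "<centrality_report> %d consensus node(s) (agreement >= %d of %d measures, top %d lists)\n",
    nrow(x$consensus), x$min_agreement, length(x$measures), x$top_t
  ))
  print(x$consensus)
  invisible(x)
}

#' Tidy a centrality report
#'
#' @param x A `centrality_report`.
#' @param ... Unused.
#' @return `tidy()`: one row per node with its agreement and per-measure
#'   ranks; `glance()`: a one-row summary.
#' @export
tidy.centrality_report <- function(x, ...) {
  dplyr::left_join(x$agreement, x$ranks, by = "node")
}

#' @rdname tidy.centrality_report
#' @export
glance.centrality_report <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$agreement),
    n_measures = length(x$measures),
    top_t = x$top_t,
    min_agreement = x$min_agreement,
    n_consensus = nrow(x$consensus)
  )
}

#' Consensus hubs of an edge-weighted network, end to end
#'
#' Convenience wrapper: edge tibble -> weighted graph -> seven-measure suite
#' (optionally plus edge-percolation centrality) -> consensus report.
#'
#' @param edges Edge tibble (`u`, `v`, `weight`).
#' @param top_t,min_agreement See [consensus()].
#' @param with_epc Also compute [epc()] and include it as an eighth measure.
#' @param reps,seed Passed to [epc()] when `with_epc` is `TRUE`.
#' @return A `centrality_report`.
#' @export
consensus_hubs <- function(edges, top_t = 100, min_agreement = 5,
                           with_epc = FALSE, reps = 1000, seed = 1) {
  g <- as_weighted_graph(edges)
  scores <- centrality_suite(g)
  if (with_epc) {
    scores <- dplyr::left_join(scores, epc(g, reps = reps, seed = seed),
                               by = "node")
  }
  consensus(scores, top_t = top_t, min_agreement = min_agreement)
}

#' Plot per-measure score distributions of a centrality suite
#'
#' @param scores Output of [centrality_suite()].
#' @return A ggplot of score densities per measure (free scales).
#' @export
plot_centrality <- function(scores) {
  long <- tidyr::pivot_longer(scores, -"node",
                              names_to = "measure", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(.data$score)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::theme_minimal()
}
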