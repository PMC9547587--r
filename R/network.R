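#' Overlap-enrichment score of one node pair
#'
#' Scores how strongly two miRNAs share disease associations (or two diseases
#' share miRNA associations): the 2x2 overlap table of the two association
#' sets against the full universe, with the same one-sided hypergeometric
#' p-value and odds ratio as the list-enrichment machinery. The score is
#' symmetric in the pair.
#'
#' @param db An [assoc_db].
#' @param u,v Two distinct node names (miRNAs or diseases according to
#'   `mode`).
#' @param mode `"miRNA"` scores disease-set overlap over the `D_N` universe;
#'   `"disease"` scores miRNA-set overlap over `M_N`.
#' @return A list with elements `table` (one-row tibble `a,b,c,d,n`), `p`,
#'   and `odds_ratio`.
#' @export
pair_score <- function(db, u, v, mode = c("miRNA", "disease")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "assoc_db"), u != v)
  sets <- db_sets(db, mode)
  universe <- if (mode == "miRNA") db$D_N else db$M_N
  for (x in c(u, v)) {
    if (!x %in% names(sets)) abort(sprintf("unknown %s '%s'", mode, x))
  }
  a <- length(intersect(sets[[u]], sets[[v]]))
  b <- length(sets[[u]]) - a
  cc <- length(sets[[v]]) - a
  tab <- tibble(a = a, b = b, c = cc, d = universe - a - b - cc, n = universe)
  list(table = tab, p = fisher_pvalue(tab), odds_ratio = odds_ratio(tab))
}

#' Build a pairwise overlap-enrichment network
#'
#' Scores every unordered node pair with [pair_score()]'s construction
#' (N(N-1)/2 tests), corrects the p-values across all scored pairs
#' (Benjamini-Hochberg), retains the significant pairs (`q <= alpha`), ranks
#' them by `-log10 p` descending, and truncates to the `top_k` strongest
#' interactions. Edges are weighted by the odds ratio; `Inf` weights are kept
#' as sentinels on export and substituted downstream (see
#' [as_weighted_graph()]).
#'
#' @param db An [assoc_db].
#' @param mode `"miRNA"` for a miRNA-miRNA network, `"disease"` for
#'   disease-disease.
#' @param top_k Maximum number of edges retained (default 10000).
#' @param alpha Significance cutoff on the adjusted p-value (default 0.05).
#' @return A tibble of class `mirtrait_network` with columns `u`, `v`
#'   (`u < v` lexicographically), `a` (overlap count), `weight` (odds ratio),
#'   `p`, `q`, `neg_log10_p` (capped at 320 for underflow), in final ranking
#'   order. Tie-breaks: p ascending, then odds ratio descending among
#'   underflowed values, then (`u`, `v`) lexicographic. Attributes: `n_nodes`,
#'   `n_tested`, `n_significant`, `mode`, `alpha`, `top_k`.
#' @export
build_network <- function(db, mode = c("miRNA", "disease"), top_k = 10000,
                          alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "assoc_db"), top_k >= 1, alpha > 0, alpha <= 1)
  m <- if (mode == "miRNA") db$forward else db$inverse
  universe <- if (mode == "miRNA") db$D_N else db$M_N
  nodes <- sort(am_sources(m))
  if (length(nodes) < 2) abort(sprintf("need at least 2 %s nodes", mode))

  # node x entity sparse incidence; overlap counts via one crossprod
  ents <- sort(unique(m$target))
  X <- Matrix::sparseMatrix(
    i = match(m$source, nodes), j = match(m$target, ents),
    x = 1, dims = c(length(nodes), length(ents))
  )
  ov <- as.matrix(Matrix::tcrossprod(X))
  sizes <- Matrix::rowSums(X)
  idx <- which(upper.tri(ov), arr.ind = TRUE)
  a <- ov[idx]
  si <- sizes[idx[, 1]]
  sj <- sizes[idx[, 2]]
  p <- stats::phyper(a - 1, sj, universe - sj, si, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")

  keep <- which(q <= alpha)
  if (length(keep) == 0) {
    warn("build_network: no significant pair; returning an empty network")
  }
  ak <- a[keep]
  bk <- si[keep] - ak
  ck <- sj[keep] - ak
  dk <- universe - ak - bk - ck
  edges <- tibble(
    u = nodes[idx[keep, 1]],
    v = nodes[idx[keep, 2]],
    a = as.integer(ak),
    weight = odds_ratio(list(a = ak, b = bk, c = ck, d = dk)),
    p = !!p[keep],
    q = !!q[keep],
    neg_log10_p = neg_log10(!!p[keep])
  ) |>
    dplyr::arrange(
      dplyr::desc(.data$neg_log10_p), .data$p,
      dplyr::desc(.data$weight %na% -Inf), .data$u, .data$v
    ) |>
    dplyr::slice_head(n = as.integer(top_k))

  inform(sprintf(
    "build_network: %d %s nodes, %d pairs tested, %d significant, %d retained",
    length(nodes), mode, nrow(idx), length(keep), nrow(edges)
  ))
  structure(edges,
    class = c("mirtrait_network", class(edges)),
    n_nodes = length(nodes), n_tested = nrow(idx),
    n_significant = length(keep), mode = mode, alpha = alpha, top_k = top_k
  )
}

#' @exportS3Method base::print
print.mirtrait_network <- function(x, ...) {
  cat(sprintf(
    "<mirtrait_network> %d edges (of %d significant / %d tested pairs, %d %s nodes)\n",
    nrow(x), attr(x, "n_significant"), attr(x, "n_tested"),
    attr(x, "n_nodes"), attr(x, "mode")
  ))
  NextMethod()
}

#' Write / read an edge table
#'
#' Plain TSV with header `source, target, weight, p, q, neg_log10_p`, one
#' edge per row in ranking order, `Inf` weights written literally --
#' importable by Cytoscape's edge-table reader and by [read_edges()].
#'
#' @param edges An edge tibble from [build_network()] (or any tibble with
#'   columns `u`, `v`, `weight`, `p`, `q`, `neg_log10_p`).
#' @param path Output file path.
#' @return `export_edges` invisibly returns `path`; `read_edges` returns the
#'   edge tibble with the canonical column names.
#' @export
export_edges <- function(edges, path) {
  out <- tibble(
    source = edges$u, target = edges$v, weight = edges$weight,
    p = edges$p, q = edges$q, neg_log10_p = edges$neg_log10_p
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname export_edges
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) abort(sprintf("edge file not found: '%s'", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::rename(u = "source", v = "target")
}

#' Plot an overlap-enrichment network
#'
#' Force-directed layout with edge darkness proportional to `-log10 p`.
#'
#' @param object A `mirtrait_network` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirtrait_network <- function(object, ...) {
  g <- as_weighted_graph(object)
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  ed <- tibble::as_tibble(object) |>
    dplyr::left_join(nodes, by = c(u = "name")) |>
    dplyr::left_join(nodes, by = c(v = "name"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, alpha = .data$neg_log10_p)
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 1) +
    ggplot2::theme_void() +
    ggplot2::labs(alpha = expression(-log[10] ~ p))
}
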