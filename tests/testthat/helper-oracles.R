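# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (nested loops, direct enumeration, textbook formulas)
# and never share code with the implementation paths they check.

# ---- binomial coefficients via Pascal's rule (exact integer arithmetic up to
# the double rounding of values > 2^53; for n <= 60 the accumulated relative
# error is < 1e-13, far inside the 1e-12 tolerance used by the tests)
pascal_choose <- function(nmax) {
  C <- matrix(0, nmax + 1, nmax + 1)
  C[, 1] <- 1
  for (i in 2:(nmax + 1)) {
    for (j in 2:i) C[i, j] <- C[i - 1, j - 1] + C[i - 1, j]
  }
  C
}

# upper-tail hypergeometric by direct enumeration of the support:
# P(X >= a), X ~ Hypergeom(population n, successes K, draws q)
hyper_tail_oracle <- function(a, K, q, n, C = pascal_choose(n)) {
  lo <- max(0, q + K - n)
  hi <- min(q, K)
  if (a <= lo) return(1)
  ks <- a:hi
  if (length(ks) == 0 || a > hi) return(0)
  sum(C[K + 1, ks + 1] * C[n - K + 1, q - ks + 1]) / C[n + 1, q + 1]
}

# ---- nested-loop relational oracles over (source, target) pair tibbles
join_oracle <- function(a, b) {
  out <- list()
  for (x in unique(a$source)) {
    ks <- a$target[a$source == x]
    ys <- character()
    for (k in ks) ys <- c(ys, b$target[b$source == k])
    ys <- sort(unique(ys))
    if (length(ys) > 0) out[[x]] <- ys
  }
  xs <- sort(names(out))
  tibble::tibble(
    source = rep(xs, lengths(out[xs])),
    target = unlist(out[xs], use.names = FALSE)
  )
}

transpose_oracle <- function(m) {
  out <- tibble::tibble(source = m$target, target = m$source)
  out <- out[order(out$source, out$target), ]
  tibble::as_tibble(out)
}

pair_set <- function(m) sort(paste(m$source, m$target, sep = "\x01"))

random_pairs <- function(n_pairs, sources, targets) {
  tibble::tibble(
    source = sample(sources, n_pairs, replace = TRUE),
    target = sample(targets, n_pairs, replace = TRUE)
  )
}

# ---- textbook multiple-testing corrections (step procedures written out)
bonferroni_oracle <- function(p) pmin(1, length(p) * p)

holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, min(1, (m - i + 1) * p[o[i]]))
    q_sorted[i] <- run
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  run <- 1
  for (i in rev(seq_len(m))) {
    run <- min(run, min(1, m * p[o[i]] / i))
    q_sorted[i] <- run
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# drop bookkeeping attributes and classes so only the tabular content is
# compared
strip_attrs <- function(x) {
  keep <- c("names", "row.names")
  attributes(x)[setdiff(names(attributes(x)), keep)] <- NULL
  class(x) <- "data.frame"
  rownames(x) <- NULL
  x
}

# ---- small database helpers
toy_db <- function(pairs) {
  build_db(assoc_map(tibble::tibble(source = pairs[[1]], target = pairs[[2]])))
}

random_db <- function(n_mirnas, n_diseases, n_pairs) {
  pairs <- random_pairs(n_pairs,
                        sprintf("m%03d", seq_len(n_mirnas)),
                        sprintf("d%03d", seq_len(n_diseases)))
  build_db(assoc_map(pairs))
}

# unweighted helper graphs as edge tibbles
edge_tbl <- function(u, v, w = 1) tibble::tibble(u = u, v = v, weight = w)

star_edges <- function(k = 4) {
  edge_tbl(rep("center", k), sprintf("leaf%d", seq_len(k)))
}

cycle_edges <- function(n) {
  v <- sprintf("c%02d", seq_len(n))
  edge_tbl(v, c(v[-1], v[1]))
}

complete_edges <- function(n) {
  v <- sprintf("k%02d", seq_len(n))
  idx <- utils::combn(n, 2)
  edge_tbl(v[idx[1, ]], v[idx[2, ]])
}
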