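#' Contingency table for one disease against a miRNA list
#'
#' The 2x2 table underlying the enrichment test. With `n = M_N` miRNAs in the
#' database, a query list of size `a + b`, and a disease associated with
#' `a + c` miRNAs:
#' \describe{
#'   \item{a}{query miRNAs associated with the disease}
#'   \item{b}{query miRNAs not associated}
#'   \item{c}{non-query miRNAs associated}
#'   \item{d}{non-query miRNAs not associated}
#' }
#'
#' @param db An [assoc_db].
#' @param input_set Character vector of miRNA names already resolved to
#'   database keys (see [enrich()] for case-insensitive resolution).
#' @param disease A disease name present in the database.
#' @return A one-row tibble with columns `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(db, input_set, disease) {
  stopifnot(inherits(db, "assoc_db"))
  input_set <- unique(input_set)
  bad <- setdiff(input_set, db_mirnas(db))
  if (length(bad) > 0 || length(input_set) == 0) {
    abort(paste0("no usable input miRNAs: not in database: ",
                 paste(bad, collapse = ", ")))
  }
  if (!disease %in% db_diseases(db)) {
    abort(sprintf("unknown disease '%s'", disease))
  }
  assoc <- db$inverse$target[db$inverse$source == disease]
  a <- length(intersect(input_set, assoc))
  b <- length(input_set) - a
  cc <- length(assoc) - a
  n <- db$M_N
  tibble(a = a, b = b, c = cc, d = n - a - b - cc, n = n)
}

#' One-sided hypergeometric (Fisher exact) enrichment p-value
#'
#' The upper-tail probability `P(X >= a)` with
#' `X ~ Hypergeometric(population n, successes a + c, draws a + b)`: the
#' chance of drawing at least `a` disease-associated miRNAs in a random query
#' of the observed size. For a 2x2 table this coincides exactly with the
#' one-sided Fisher exact test, which is why the enrichment literature uses
#' the two names interchangeably.
#'
#' @param t A contingency table as returned by [build_contingency()] (a data
#'   frame or list with elements `a`, `b`, `c`, `d`).
#' @return The p-value, in (0, 1].
#' @examples
#' fisher_pvalue(list(a = 2, b = 1, c = 3, d = 14))  # 160/1140
#' @export
fisher_pvalue <- function(t) {
  with(t, {
    stopifnot(all(c(a, b, c, d) >= 0))
    stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  })
}

#' Sample odds ratio with explicit sentinels
#'
#' The unconditioned cross-product ratio `(a*d)/(b*c)` of the 2x2 table, with
#' no continuity correction: `Inf` when `a*d > 0` and `b*c = 0` (in
#' particular `b = 0`, every query miRNA associated with the disease -- the
#' conventional 'Inf' entry of enrichment reports), `0` when `a*d = 0` and
#' `b*c > 0`, and `NaN` (reported as not-applicable) for 0/0.
#'
#' @inheritParams fisher_pvalue
#' @return A non-negative number, `Inf`, or `NaN`.
#' @export
odds_ratio <- function(t) {
  with(t, {
    num <- as.numeric(a) * as.numeric(d)
    den <- as.numeric(b) * as.numeric(c)
    dplyr::case_when(
      num > 0 & den == 0 ~ Inf,
      num == 0 & den == 0 ~ NaN,
      .default = num / den
    )
  })
}

#' Multiple-testing correction
#'
#' Adjusts a vector of p-values for multiplicity, preserving input order.
#' `"bonferroni"` multiplies by the family size m (capped at 1); `"holm"` is
#' the step-down variant with a running maximum; `"bh"` is the
#' Benjamini-Hochberg step-up false-discovery-rate procedure (the default
#' everywhere in this package).
#'
#' @param ps Numeric vector of p-values in (0, 1].
#' @param method `"bonferroni"`, `"holm"`, or `"bh"`.
#' @return Adjusted q-values, same length and order as `ps`; always `>= ps`.
#' @export
adjust_pvalues <- function(ps, method = c("bh", "holm", "bonferroni")) {
  method <- match.arg(method)
  if (length(ps) < 1 || any(!is.finite(ps)) || any(ps <= 0) || any(ps > 1)) {
    abort("p-values must be a non-empty vector with values in (0, 1]")
  }
  stats::p.adjust(ps, method = c(bh = "BH", holm = "holm",
                                 bonferroni = "bonferroni")[[method]])
}

#' Disease enrichment of a miRNA list
#'
#' Tests every disease in the database for over-representation of the query
#' miRNA list: a one-sided hypergeometric test per disease
#' ([fisher_pvalue()]), correction across all `D_N` hypotheses
#' ([adjust_pvalues()]), and a q-value threshold. Query names are matched
#' case-insensitively against database keys; unknown names are dropped with a
#' warning (an error only if none resolve).
#'
#' @param db An [assoc_db].
#' @param mirnas Character vector of query miRNA names.
#' @param alpha Adjusted-p (q-value) cutoff; default 0.05.
#' @param method Correction method, see [adjust_pvalues()]; default `"bh"`.
#' @return A tibble of class `mirtrait_enrichment`, one row per disease with
#'   `q <= alpha`, sorted ascending by `q`, ties by descending odds ratio then
#'   name. Columns: `disease`, `a`, `b`, `c`, `d`, `odds_ratio`, `log2_or`
#'   (the effect size on the log scale; `Inf`/`NaN` sentinels propagate), `p`,
#'   `q`. Attributes record the resolved input, alpha, method and the family
#'   size tested.
#' @export
enrich <- function(db, mirnas, alpha = 0.05, method = c("bh", "holm", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(inherits(db, "assoc_db"), alpha > 0, alpha <= 1)
  keys <- db_mirnas(db)
  hit <- match(tolower(trimws(mirnas)), tolower(keys))
  rejects <- unique(mirnas[is.na(hit)])
  input <- unique(keys[hit[!is.na(hit)]])
  if (length(rejects) > 0) {
    warn(sprintf("enrich: dropped %d miRNA(s) not in database: %s",
                 length(rejects), paste(rejects, collapse = ", ")))
  }
  if (length(input) == 0) {
    abort(paste0("no input miRNAs found in database; rejects: ",
                 paste(rejects, collapse = ", ")))
  }

  q_size <- length(input)
  tab <- as_tibble(db$inverse) |>
    dplyr::group_by(disease = .data$source) |>
    dplyr::summarise(a = sum(.data$target %in% input), K = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(
      b = q_size - .data$a,
      c = .data$K - .data$a,
      d = db$M_N - q_size - .data$c
    ) |>
    dplyr::select(-"K")
  tab$p <- fisher_pvalue(tab)
  tab$q <- adjust_pvalues(tab$p, method)
  tab$odds_ratio <- odds_ratio(tab)
  tab$log2_or <- log2(tab$odds_ratio)

  out <- tab |>
    dplyr::filter(.data$q <= alpha) |>
    dplyr::arrange(.data$q, dplyr::desc(.data$odds_ratio %na% -Inf), .data$disease) |>
    dplyr::select("disease", "a", "b", "c", "d", "odds_ratio", "log2_or", "p", "q")
  structure(out,
    class = c("mirtrait_enrichment", class(out)),
    input = input, rejects = rejects,
    alpha = alpha, method = method, n_tested = db$D_N
  )
}

#' @exportS3Method base::print
print.mirtrait_enrichment <- function(x, ...) {
  cat(sprintf(
    "<mirtrait_enrichment> %d of %d diseases at q <= %g (%s; %d input miRNAs)\n",
    nrow(x), attr(x, "n_tested"), attr(x, "alpha"),
    attr(x, "method"), length(attr(x, "input"))
  ))
  NextMethod()
}

#' Tidy an enrichment result
#'
#' @param x A `mirtrait_enrichment` object.
#' @param ... Unused.
#' @return `tidy()` returns the records as a plain tibble; `glance()` a
#'   one-row summary (input size, hypotheses tested, significant count,
#'   method, alpha).
#' @export
tidy.mirtrait_enrichment <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.mirtrait_enrichment
#' @export
glance.mirtrait_enrichment <- function(x, ...) {
  tibble(
    n_input = length(attr(x, "input")),
    n_rejected = length(attr(x, "rejects")),
    n_tested = attr(x, "n_tested"),
    n_significant = nrow(x),
    method = attr(x, "method"),
    alpha = attr(x, "alpha")
  )
}

#' Volcano-style plot of an enrichment result
#'
#' Effect size (log2 odds ratio, infinite values shown at the finite maximum
#' with a triangular marker) against -log10 q.
#'
#' @param object A `mirtrait_enrichment` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirtrait_enrichment <- function(object, ...) {
  df <- tidy.mirtrait_enrichment(object)
  finite_max <- suppressWarnings(max(df$log2_or[is.finite(df$log2_or)], 0))
  df$capped <- !is.finite(df$log2_or)
  df$log2_or_plot <- ifelse(df$capped, finite_max, df$log2_or)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_or_plot,
                                   y = neg_log10(.data$q),
                                   shape = .data$capped)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                guide = "none") +
    ggplot2::labs(x = "log2 odds ratio (Inf capped)",
                  y = expression(-log[10] ~ q),
                  title = "Disease enrichment of miRNA list") +
    ggplot2::theme_minimal()
}
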