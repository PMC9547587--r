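#' Association maps
#'
#' An association map is the package's basic container for a directed
#' many-to-many relation: a tibble with character columns `source` and
#' `target`, one distinct pair per row. It represents, e.g., miRNA -> target
#' genes (the content of miRTarBase-style tables) or gene -> diseases
#' (DisGeNET-style tables). Names are stored exactly as read apart from
#' stripping surrounding whitespace; there is no case folding, because the
#' downstream merge is on literal gene symbols.
#'
#' @param pairs A data frame with at least two columns; the first two (or the
#'   columns named `source`/`target`) are taken as the relation.
#' @return A tibble of class `assoc_map` with columns `source`, `target`,
#'   deduplicated and sorted. Rows with an empty source or target are dropped;
#'   their count is kept in the `n_skipped` attribute.
#' @examples
#' assoc_map(data.frame(source = c("m1", "m1", "m1"),
#'                      target = c("g1", "g2", "g1")))
#' @export
assoc_map <- function(pairs) {
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2)
  if (all(c("source", "target") %in% names(pairs))) {
    pairs <- pairs[c("source", "target")]
  } else {
    pairs <- stats::setNames(pairs[1:2], c("source", "target"))
  }
  pairs <- tibble::as_tibble(pairs)
  pairs$source <- trimws(as.character(pairs$source))
  pairs$target <- trimws(as.character(pairs$target))
  keep <- !is.na(pairs$source) & !is.na(pairs$target) &
    pairs$source != "" & pairs$target != ""
  n_skipped <- sum(!keep)
  out <- dplyr::distinct(pairs[keep, ]) |>
    dplyr::arrange(.data$source, .data$target)
  new_assoc_map(out, n_skipped = n_skipped)
}

new_assoc_map <- function(tbl, n_skipped = 0L, n_dropped = 0L, dropped = character()) {
  structure(tbl,
    class = c("assoc_map", class(tibble::tibble())),
    n_skipped = as.integer(n_skipped),
    n_dropped = as.integer(n_dropped),
    dropped = dropped
  )
}

#' @exportS3Method base::as.data.frame
as.data.frame.assoc_map <- function(x, ...) {
  data.frame(source = x$source, target = x$target, stringsAsFactors = FALSE)
}

#' @exportS3Method base::print
print.assoc_map <- function(x, ...) {
  cat(sprintf(
    "<assoc_map> %d pairs: %d sources -> %d targets\n",
    nrow(x), dplyr::n_distinct(x$source), dplyr::n_distinct(x$target)
  ))
  NextMethod()
}

am_sources <- function(m) unique(m$source)
am_targets_of <- function(m, key) m$target[m$source == key]

#' Read a two-column mapping table
#'
#' Parses a delimited text file of (source, target) association rows, e.g. a
#' miRTarBase miRNA/target-gene export or a DisGeNET gene/disease export.
#' Columns are selected by header name or 0-based index, so dialects with
#' extra annotation columns parse without preprocessing.
#'
#' @param path Path to a delimited text file.
#' @param source_col,target_col Column selectors: a header name (string) or a
#'   0-based column index (number). Defaults: columns 0 and 1.
#' @param delimiter Field delimiter. Default tab; when `NULL` and the first
#'   line contains no tab, comma is used as a fallback.
#' @param header Does the file carry a header row? Default `TRUE`.
#' @return An [assoc_map]. Rows with an empty source or target are skipped and
#'   their count reported via a message and the `n_skipped` attribute.
#' @export
read_mapping <- function(path, source_col = 0, target_col = 1,
                         delimiter = NULL, header = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("mapping file not found: '%s'", path))
  }
  first <- readLines(path, n = 1L)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", first)) "\t" else ","
  }
  tbl <- utils::read.table(path,
    sep = delimiter, header = header, quote = "\"",
    colClasses = "character", check.names = FALSE,
    comment.char = "", stringsAsFactors = FALSE, fill = FALSE
  )
  pick <- function(sel, what) {
    if (is.character(sel)) {
      if (!sel %in% names(tbl)) {
        abort(sprintf("%s column '%s' not found (columns: %s)",
                      what, sel, paste(names(tbl), collapse = ", ")))
      }
      tbl[[sel]]
    } else {
      idx <- as.integer(sel) + 1L
      if (idx < 1L || idx > ncol(tbl)) {
        abort(sprintf("%s column index %s out of range (file has %d columns)",
                      what, sel, ncol(tbl)))
      }
      tbl[[idx]]
    }
  }
  m <- assoc_map(tibble(source = pick(source_col, "source"),
                        target = pick(target_col, "target")))
  if (attr(m, "n_skipped") > 0) {
    inform(sprintf("read_mapping: skipped %d row(s) with empty fields",
                   attr(m, "n_skipped")))
  }
  m
}

#' Merge two association maps on their shared key
#'
#' Composes an X -> K map with a K -> Y map into an X -> Y map: `x -> y` holds
#' iff some key `k` satisfies `k in a[x]` and `y in b[k]`. This is the core
#' merge that turns miRNA -> gene and gene -> disease relations into a
#' miRNA -> disease dictionary. Sources whose composed target set is empty
#' (miRNAs none of whose genes map to any disease) are dropped; their names
#' are kept in the `dropped` attribute and their count is reported.
#'
#' @param a An [assoc_map] from X to K.
#' @param b An [assoc_map] from K to Y.
#' @return An [assoc_map] from X to Y with attributes `n_dropped` and
#'   `dropped` recording sources of `a` lost in the merge.
#' @export
merge_on_key <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  merged <- dplyr::inner_join(
    tibble(source = a$source, key = a$target),
    tibble(key = b$source, target = b$target),
    by = "key", relationship = "many-to-many"
  ) |>
    dplyr::distinct(.data$source, .data$target) |>
    dplyr::arrange(.data$source, .data$target)
  dropped <- sort(setdiff(unique(a$source), unique(merged$source)))
  if (length(dropped) > 0) {
    inform(sprintf("merge_on_key: %d source(s) did not map to any target",
                   length(dropped)))
  }
  new_assoc_map(merged, n_dropped = length(dropped), dropped = dropped)
}

#' Transpose an association map
#'
#' Swaps sources and targets, e.g. turning the miRNA -> disease dictionary
#' into the disease -> miRNA inverse dictionary. Inverting twice recovers the
#' original pair set.
#'
#' @param m An [assoc_map].
#' @return The transposed [assoc_map].
#' @export
invert_map <- function(m) {
  stopifnot(is.data.frame(m))
  out <- tibble(source = m$target, target = m$source) |>
    dplyr::arrange(.data$source, .data$target)
  new_assoc_map(out)
}
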