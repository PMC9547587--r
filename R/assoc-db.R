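#' Build a bidirectional miRNA-disease association database
#'
#' Wraps a forward miRNA -> disease map together with its inverse
#' disease -> miRNA map and the two universe sizes: `M_N`, the number of
#' miRNAs, and `D_N`, the number of diseases. These universes are the
#' denominators of the spectrum-width statistics and the population sizes of
#' every enrichment contingency table downstream.
#'
#' @param forward An [assoc_map] from miRNA to disease (typically the result
#'   of [merge_on_key()] on a miRNA->gene and a gene->disease map).
#' @return An object of class `assoc_db`: a list with elements `forward`,
#'   `inverse` (both [assoc_map]s), `M_N` and `D_N`.
#' @examples
#' db <- build_db(assoc_map(data.frame(
#'   source = c("m1", "m1", "m2"), target = c("d1", "d2", "d2"))))
#' db$M_N; db$D_N
#' @export
build_db <- function(forward) {
  stopifnot(is.data.frame(forward))
  if (nrow(forward) == 0) {
    abort("cannot build a database from an empty forward map")
  }
  forward <- assoc_map(forward)
  inverse <- invert_map(forward)
  structure(
    list(
      forward = forward,
      inverse = inverse,
      M_N = dplyr::n_distinct(forward$source),
      D_N = dplyr::n_distinct(inverse$source)
    ),
    class = "assoc_db"
  )
}

#' @exportS3Method base::print
print.assoc_db <- function(x, ...) {
  cat(sprintf(
    "<assoc_db> %d miRNAs (M_N) <-> %d diseases (D_N), %d associations\n",
    x$M_N, x$D_N, nrow(x$forward)
  ))
  invisible(x)
}

db_mirnas <- function(db) am_sources(db$forward)
db_diseases <- function(db) am_sources(db$inverse)

# disease -> its miRNA set, as a list keyed by disease (and vice versa)
db_sets <- function(db, by = c("miRNA", "disease")) {
  by <- match.arg(by)
  m <- if (by == "miRNA") db$forward else db$inverse
  split(m$target, m$source)
}

#' Query the database by miRNA or disease name pattern
#'
#' Looks up every miRNA (or disease) whose name matches a regular expression,
#' case-insensitively and unanchored (a match anywhere in the name counts), in
#' R's default (POSIX 1003.2 extended, ICU-flavoured) regex dialect. So
#' `"neoplasm"` matches `"Colorectal Neoplasms"`, and `"mir-33[0-9]"` matches
#' `"hsa-miR-335-5p"`.
#'
#' @param db An [assoc_db].
#' @param pattern Regular expression (R's default dialect; see
#'   [base::regex]). Matching is case-insensitive and unanchored.
#' @param by Query side: `"miRNA"` keys (forward map) or `"disease"` keys
#'   (inverse map).
#' @return A tibble sorted by `name` with columns `name`, `n_associated`, and
#'   a list-column `associated` carrying the sorted associated-name sets.
#'   Zero matches give a zero-row tibble, not an error.
#' @export
query_db <- function(db, pattern, by = c("miRNA", "disease")) {
  by <- match.arg(by)
  stopifnot(inherits(db, "assoc_db"))
  ok <- tryCatch({
    suppressWarnings(grepl(pattern, "", ignore.case = TRUE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    abort(sprintf(
      "invalid regular expression '%s' (R's POSIX extended regex dialect)",
      pattern))
  }
  keys <- if (by == "miRNA") db_mirnas(db) else db_diseases(db)
  hits <- sort(keys[grepl(pattern, keys, ignore.case = TRUE)])
  sets <- db_sets(db, by)
  tibble(
    name = hits,
    n_associated = vapply(hits, function(k) length(sets[[k]]), integer(1)),
    associated = lapply(hits, function(k) sort(sets[[k]]))
  )
}

#' Write and read the database as a sorted TSV pair
#'
#' The database is persisted as two plain two-column TSV files,
#' `mirna2disease.tsv` (miRNA, disease) and `disease2mirna.tsv` (disease,
#' miRNA), one association per row, lexicographically sorted so the files are
#' byte-stable across runs.
#'
#' @param db An [assoc_db].
#' @param dir Output directory (created if absent).
#' @return `write_db` invisibly returns the two file paths; `read_db` returns
#'   the [assoc_db] rebuilt from `mirna2disease.tsv`.
#' @export
write_db <- function(db, dir) {
  stopifnot(inherits(db, "assoc_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwd <- file.path(dir, "mirna2disease.tsv")
  inv <- file.path(dir, "disease2mirna.tsv")
  write_pairs <- function(m, path, cols) {
    tbl <- stats::setNames(as.data.frame(m)[c("source", "target")], cols)
    readr::write_tsv(tbl[order(tbl[[1]], tbl[[2]]), ], path, progress = FALSE)
  }
  write_pairs(db$forward, fwd, c("miRNA", "disease"))
  write_pairs(db$inverse, inv, c("disease", "miRNA"))
  invisible(c(fwd, inv))
}

#' @rdname write_db
#' @export
read_db <- function(dir) {
  path <- file.path(dir, "mirna2disease.tsv")
  if (!file.exists(path)) {
    abort(sprintf("no database found: '%s' is missing", path))
  }
  build_db(read_mapping(path, delimiter = "\t", header = TRUE))
}
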