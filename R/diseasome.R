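#' Select a diseasome
#'
#' A diseasome is a user-specified set of related diseases, given either as an
#' explicit name list or as a keyword: a case-insensitive, unanchored regular
#' expression over disease names (so the keyword `"Neoplasm"` collects
#' "Colorectal Neoplasms", "Stomach Neoplasms", ...). Explicit names are
#' resolved case-insensitively; unknown names are dropped with a warning.
#'
#' @param db An [assoc_db].
#' @param diseases Explicit character vector of disease names (exclusive with
#'   `keyword`).
#' @param keyword Regular expression selecting diseases by name.
#' @return A sorted character vector of database disease names. An empty
#'   selection is an error naming the spec.
#' @export
select_diseasome <- function(db, diseases = NULL, keyword = NULL) {
  stopifnot(inherits(db, "assoc_db"))
  if (is.null(diseases) == is.null(keyword)) {
    abort("give exactly one of `diseases` or `keyword`")
  }
  keys <- db_diseases(db)
  if (!is.null(keyword)) {
    out <- sort(keys[grepl(keyword, keys, ignore.case = TRUE)])
    if (length(out) == 0) {
      abort(sprintf("keyword '%s' matched no disease", keyword))
    }
    return(out)
  }
  hit <- match(tolower(trimws(diseases)), tolower(keys))
  unknown <- unique(diseases[is.na(hit)])
  if (length(unknown) > 0) {
    warn(sprintf("select_diseasome: unknown disease(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  out <- sort(unique(keys[hit[!is.na(hit)]]))
  if (length(out) == 0) {
    abort(sprintf("no database disease matched the explicit list (%s)",
                  paste(diseases, collapse = ", ")))
  }
  out
}

#' miRNA abundance across a diseasome
#'
#' Counts, for each miRNA, the number of diseasome diseases whose miRNA set
#' contains it (occurrence counts diseases, not association multiplicity),
#' and keeps the miRNAs passing a user-specified count. miRNAs abundant
#' across a coherent diseasome are candidate shared regulators of its
#' underlying pathways.
#'
#' @param db An [assoc_db].
#' @param diseasome Character vector of database disease names, e.g. from
#'   [select_diseasome()].
#' @param min_count Minimum occurrence to report (default 1; the threshold
#'   used is recorded in the `min_count` attribute).
#' @return A tibble (`rank`, `mirna`, `occurrence`) sorted descending by
#'   occurrence, ties by name.
#' @export
abundance <- function(db, diseasome, min_count = 1) {
  stopifnot(inherits(db, "assoc_db"), min_count >= 1)
  diseasome <- unique(diseasome)
  bad <- setdiff(diseasome, db_diseases(db))
  if (length(bad) > 0) {
    abort(paste0("diseasome names not in database: ", paste(bad, collapse = ", ")))
  }
  out <- as_tibble(db$inverse) |>
    dplyr::filter(.data$source %in% diseasome) |>
    dplyr::count(mirna = .data$target, name = "occurrence") |>
    dplyr::filter(.data$occurrence >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$occurrence), .data$mirna) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  attr(out, "min_count") <- min_count
  attr(out, "diseasome_size") <- length(diseasome)
  out
}

#' Cross-keyword abundance report
#'
#' The multi-keyword layout of diseasome reports: rows are the miRNAs ranked
#' under the first keyword's diseasome, with one occurrence column per
#' keyword; miRNAs below `min_count` in a keyword show `NA` (printed as a
#' dash in the CLI).
#'
#' @param db An [assoc_db].
#' @param keywords Character vector of keyword regexes; the first keyword
#'   defines the row ranking.
#' @param min_count Minimum occurrence per keyword.
#' @param top Number of rows (by the first keyword's ranking).
#' @return A tibble: `rank`, `mirna`, then one column per keyword.
#' @export
abundance_table <- function(db, keywords, min_count = 1, top = 25) {
  stopifnot(length(keywords) >= 1)
  base <- abundance(db, select_diseasome(db, keyword = keywords[[1]]), min_count) |>
    dplyr::slice_head(n = as.integer(top)) |>
    dplyr::rename(!!keywords[[1]] := "occurrence")
  for (kw in keywords[-1]) {
    occ <- abundance(db, select_diseasome(db, keyword = kw), min_count) |>
      dplyr::select("mirna", !!kw := "occurrence")
    base <- dplyr::left_join(base, occ, by = "mirna")
  }
  base
}
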