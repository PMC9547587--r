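#' Spectrum widths
#'
#' The disease spectrum width of miRNA *i* is `DSW(i) = d_i / D_N`, the
#' fraction of all database diseases associated with it; a high DSW flags a
#' putative master-regulator miRNA. Symmetrically, the miRNA spectrum width of
#' disease *j* is `MSW(j) = m_j / M_N`, the fraction of all miRNAs associated
#' with it; a high MSW flags a multifactorial pathology. Denominators are the
#' merged-database universes (`D_N`, `M_N`), never the source-database sizes.
#' Widths are kept at full precision; printed tables conventionally round
#' half-up to 2 decimals (see [round_half_up()] via `format_spectrum()`).
#'
#' @param db An [assoc_db].
#' @param mirna,disease Entity name (exact match against database keys).
#' @return A one-row tibble with columns `name`, `count` (d_i or m_j) and
#'   `width`.
#' @examples
#' db <- build_db(assoc_map(data.frame(
#'   source = c("m1", "m2", "m2"), target = c("d1", "d1", "d2"))))
#' msw(db, "d1")  # 2 of 2 miRNAs -> width 1
#' @name spectrum
NULL

#' @rdname spectrum
#' @export
dsw <- function(db, mirna) {
  stopifnot(inherits(db, "assoc_db"))
  spectrum_record(db, mirna, side = "miRNA")
}

#' @rdname spectrum
#' @export
msw <- function(db, disease) {
  stopifnot(inherits(db, "assoc_db"))
  spectrum_record(db, disease, side = "disease")
}

spectrum_record <- function(db, name, side) {
  m <- if (side == "miRNA") db$forward else db$inverse
  universe <- if (side == "miRNA") db$D_N else db$M_N
  keys <- am_sources(m)
  if (!name %in% keys) {
    near <- utils::head(keys[order(utils::adist(tolower(name), tolower(keys)))], 5)
    abort(sprintf("unknown %s '%s'; nearest names: %s",
                  side, name, paste(near, collapse = ", ")))
  }
  count <- sum(m$source == name)
  tibble(name = name, count = count,
         width = spectrum_width(count, universe))
}

#' Spectrum width of a raw count
#'
#' The elementary ratio behind [dsw()] and [msw()]: an association count over
#' the corresponding universe size.
#'
#' @param count Number of associated entities (`d_i` or `m_j`).
#' @param universe Universe size (`D_N` or `M_N`).
#' @return `count / universe`, at full precision.
#' @export
spectrum_width <- function(count, universe) {
  stopifnot(universe >= 1, all(count >= 0))
  count / universe
}

#' Rank entities by spectrum width
#'
#' @param db An [assoc_db].
#' @param by `"DSW"` ranks miRNAs by disease spectrum width; `"MSW"` ranks
#'   diseases by miRNA spectrum width.
#' @param top Number of rows to return (clamped to the universe size).
#' @return A tibble (`rank`, `name`, `count`, `width`) in descending width
#'   order; ties broken lexicographically by name.
#' @export
rank_spectrum <- function(db, by = c("DSW", "MSW"), top = 10) {
  by <- match.arg(by)
  stopifnot(inherits(db, "assoc_db"), top >= 1)
  m <- if (by == "DSW") db$forward else db$inverse
  universe <- if (by == "DSW") db$D_N else db$M_N
  out <- as_tibble(m) |>
    dplyr::count(.data$source, name = "count") |>
    dplyr::rename(name = "source") |>
    dplyr::mutate(width = spectrum_width(.data$count, universe)) |>
    dplyr::arrange(dplyr::desc(.data$width), .data$name) |>
    dplyr::slice_head(n = as.integer(top)) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  out
}

# Table-style formatting: widths rounded half-up to 2 decimals.
format_spectrum <- function(tbl, digits = 2) {
  dplyr::mutate(tbl, width = round_half_up(.data$width, digits))
}
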