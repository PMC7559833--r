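#' Construct an expert-by-item rating matrix
#'
#' The central data object of the package: a complete panel of integer
#' ratings, experts as rows and questionnaire items as columns, on a declared
#' Likert scale. Missing cells are rejected rather than imputed — the
#' content-validation procedure assumes every retained judge rated every
#' item, and a partial panel is outside its scope.
#'
#' @param ratings Integer matrix (or coercible), experts in rows, items in
#'   columns. Row and column names are the expert and item labels; unnamed
#'   dimensions get labels `"1"`, `"2"`, ...
#' @param scale A [likert_scale()].
#' @param panel_id Optional label for the panel.
#'
#' @return An object of class `rating_matrix`.
#' @seealso [read_ratings()], [write_ratings()], [load_fixture()]
#' @examples
#' m <- rating_matrix(matrix(c(5L, 4L, 5L, 5L), 2, 2), likert_scale(1, 5))
#' n_experts(m)
#' @export
rating_matrix <- function(ratings, scale = likert_scale(1, 5), panel_id = NULL) {
  assert_scale(scale)
  ratings <- as.matrix(ratings)
  if (is.null(rownames(ratings))) rownames(ratings) <- as.character(seq_len(nrow(ratings)))
  if (is.null(colnames(ratings))) colnames(ratings) <- as.character(seq_len(ncol(ratings)))
  x <- structure(
    list(
      ratings = ratings,
      scale = scale,
      panel_id = if (is.null(panel_id)) NA_character_ else as.character(panel_id)
    ),
    class = "rating_matrix"
  )
  validate_rating_matrix(x)
}

validate_rating_matrix <- function(x) {
  r <- x$ratings
  if (nrow(r) < 1L || ncol(r) < 1L) {
    stop("rating matrix must have at least one expert and one item", call. = FALSE)
  }
  if (anyNA(r)) {
    bad <- which(is.na(r), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "missing rating for expert '%s', item '%s'",
      rownames(r)[bad[1L]], colnames(r)[bad[2L]]
    ), call. = FALSE)
  }
  if (!is.numeric(r) || any(r != trunc(r))) {
    bad <- which(is.na(suppressWarnings(as.numeric(r))) | r != trunc(r), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-integer rating for expert '%s', item '%s'",
      rownames(r)[bad[1L]], colnames(r)[bad[2L]]
    ), call. = FALSE)
  }
  s <- x$scale
  out <- r < s$lowest | r > s$highest
  if (any(out)) {
    bad <- which(out, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "rating %d outside scale [%d, %d] for expert '%s', item '%s'",
      r[bad[1L], bad[2L]], s$lowest, s$highest,
      rownames(r)[bad[1L]], colnames(r)[bad[2L]]
    ), call. = FALSE)
  }
  if (anyDuplicated(rownames(r))) {
    stop(sprintf("duplicate expert label '%s'", rownames(r)[duplicated(rownames(r))][1L]),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(r))) {
    stop(sprintf("duplicate item label '%s'", colnames(r)[duplicated(colnames(r))][1L]),
         call. = FALSE)
  }
  storage.mode(x$ratings) <- "integer"
  x
}

#' Rating-matrix accessors
#'
#' @param x A `rating_matrix`.
#' @return `ratings()` the integer matrix; `expert_ids()`/`item_ids()` the
#'   ordered labels; `n_experts()`/`n_items()` counts; `rating_scale()` the
#'   [likert_scale()].
#' @name rating_matrix-accessors
NULL

#' @rdname rating_matrix-accessors
#' @export
ratings <- function(x) x$ratings

#' @rdname rating_matrix-accessors
#' @export
expert_ids <- function(x) rownames(x$ratings)

#' @rdname rating_matrix-accessors
#' @export
item_ids <- function(x) colnames(x$ratings)

#' @rdname rating_matrix-accessors
#' @export
n_experts <- function(x) nrow(x$ratings)

#' @rdname rating_matrix-accessors
#' @export
n_items <- function(x) ncol(x$ratings)

#' @rdname rating_matrix-accessors
#' @export
rating_scale <- function(x) x$scale

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf(
    "<rating_matrix> %s: %d experts x %d items on a %d..%d scale\n",
    ifelse(is.na(x$panel_id), "(unnamed panel)", x$panel_id),
    n_experts(x), n_items(x), x$scale$lowest, x$scale$highest
  ))
  print(utils::head(x$ratings, 6L))
  if (n_experts(x) > 6L) cat(sprintf("... %d more experts\n", n_experts(x) - 6L))
  invisible(x)
}

#' Subset a rating matrix by expert labels
#'
#' Keeps item order untouched; experts appear in the order given.
#'
#' @param x A `rating_matrix`.
#' @param experts Character vector of expert labels to keep.
#' @return A `rating_matrix` over the selected experts.
#' @export
subset_experts <- function(x, experts) {
  missing <- setdiff(experts, expert_ids(x))
  if (length(missing)) {
    stop(sprintf("unknown expert label(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  rating_matrix(x$ratings[experts, , drop = FALSE], x$scale, x$panel_id)
}

#' Read a rating matrix from delimited text
#'
#' Expects one header row of item labels and a leading column of expert
#' labels; every other cell an integer rating within the scale. The field
#' separator is sniffed from the header (tab if present, otherwise comma)
#' unless given. Row and column order are preserved exactly as in the file.
#'
#' @param source Path to a CSV/TSV file (or a connection).
#' @param scale A [likert_scale()] the ratings must respect.
#' @param sep Field separator; `NULL` (default) sniffs tab vs comma.
#' @param panel_id Optional panel label for the result.
#' @return A validated `rating_matrix`.
#' @export
read_ratings <- function(source, scale = likert_scale(1, 5), sep = NULL,
                         panel_id = NULL) {
  assert_scale(scale)
  lines <- readLines(source, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("rating file needs a header row and at least one expert row", call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != widths[[1L]])) {
    stop(sprintf("ragged row %d: %d fields where header has %d",
                 which(widths != widths[[1L]])[1L], widths[widths != widths[[1L]]][1L],
                 widths[[1L]]), call. = FALSE)
  }
  header <- trimws(parts[[1L]])
  item_labels <- header[-1L]
  body <- parts[-1L]
  expert_labels <- vapply(body, function(p) trimws(p[[1L]]), character(1))
  cells <- lapply(body, function(p) trimws(p[-1L]))
  num <- suppressWarnings(lapply(cells, as.numeric))
  for (i in seq_along(num)) {
    bad <- which(is.na(num[[i]]) | num[[i]] != trunc(num[[i]]))
    if (length(bad)) {
      stop(sprintf("non-integer cell '%s' at expert '%s', item '%s'",
                   cells[[i]][bad[1L]], expert_labels[i], item_labels[bad[1L]]),
           call. = FALSE)
    }
  }
  m <- do.call(rbind, num)
  dimnames(m) <- list(expert_labels, item_labels)
  rating_matrix(m, scale, panel_id)
}

#' Write a rating matrix as delimited text
#'
#' Emits the dialect [read_ratings()] accepts, so a write/read round trip
#' reproduces the matrix exactly (labels, order and values).
#'
#' @param x A `rating_matrix`.
#' @param sink Output file path (or connection).
#' @param sep Field separator (default comma).
#' @return Invisibly, `sink`.
#' @export
write_ratings <- function(x, sink, sep = ",") {
  stopifnot(inherits(x, "rating_matrix"))
  header <- paste(c("expert", item_ids(x)), collapse = sep)
  rows <- vapply(seq_len(n_experts(x)), function(i) {
    paste(c(expert_ids(x)[i], x$ratings[i, ]), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), sink, useBytes = TRUE)
  invisible(sink)
}
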