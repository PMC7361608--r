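#' Construct a per-wave response matrix
#'
#' The canonical container for one survey wave: an integer matrix of Likert
#' responses (participants in rows, items in columns, `NA` for missing) plus
#' the item metadata needed to validate and later trichotomize it.
#'
#' @param values Integer matrix or data frame, one row per participant, one
#'   column per item (column order must follow `items`).
#' @param items List of [item_spec()] objects, one per column.
#' @param participant_ids Character vector of unique participant identifiers.
#' @param wave_id Wave label, e.g. `"T1"`.
#' @return An object of class `response_matrix` with fields `wave_id`,
#'   `participants`, `items`, `values` (matrix with dimnames).
#' @export
response_matrix <- function(values, items, participant_ids, wave_id) {
  items <- as_item_list(items)
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  participant_ids <- as.character(participant_ids)
  if (anyDuplicated(participant_ids)) {
    stop("participant ids must be unique", call. = FALSE)
  }
  if (nrow(values) != length(participant_ids)) {
    stop("row count does not match number of participant ids", call. = FALSE)
  }
  if (ncol(values) != length(items)) {
    stop("column count does not match number of item specs", call. = FALSE)
  }
  dimnames(values) <- list(participant_ids, names(items))
  x <- structure(
    list(wave_id = as.character(wave_id), participants = participant_ids,
         items = items, values = values),
    class = "response_matrix"
  )
  validate_response_matrix(x)
  x
}

validate_response_matrix <- function(x) {
  for (id in names(x$items)) {
    sc <- x$items[[id]]$scale
    v <- x$values[, id]
    bad <- which(!is.na(v) & (v < sc$min | v > sc$max))
    if (length(bad)) {
      stop(sprintf(
        "out-of-range value %d for item '%s' (scale %d-%d) at participant '%s'",
        v[bad[1]], id, sc$min, sc$max, x$participants[bad[1]]
      ), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix wave '%s': %d participants x %d items, %d missing>\n",
              x$wave_id, length(x$participants), length(x$items),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Select a subset of items from a response matrix
#'
#' @param matrix A [response_matrix()].
#' @param item_ids Character vector of item ids to keep, or `NULL` to select
#'   by `block`.
#' @param block Item block(s) to keep when `item_ids` is `NULL`.
#' @return A [response_matrix()] restricted to the requested columns.
#' @export
subset_items <- function(matrix, item_ids = NULL, block = NULL) {
  stopifnot(inherits(matrix, "response_matrix"))
  if (is.null(item_ids)) {
    if (is.null(block)) stop("give 'item_ids' or 'block'", call. = FALSE)
    blocks <- vapply(matrix$items, `[[`, character(1), "block")
    item_ids <- names(matrix$items)[blocks %in% block]
  }
  missing <- setdiff(item_ids, names(matrix$items))
  if (length(missing)) {
    stop("unknown item(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  response_matrix(matrix$values[, item_ids, drop = FALSE],
                  matrix$items[item_ids], matrix$participants, matrix$wave_id)
}

#' Read one survey wave from CSV
#'
#' Expects a UTF-8 CSV with a header row, a `participant_id` column and one
#' column per item id. Blank cells and `NA` become missing responses; any
#' non-missing value outside its item's scale range raises a validation
#' error naming the row, item and value.
#'
#' @param path CSV file path.
#' @param item_specs List of [item_spec()] objects describing the expected
#'   item columns.
#' @param wave_id Wave label to attach.
#' @param id_col Name of the participant-id column.
#' @return A [response_matrix()].
#' @seealso [write_wave()] for the inverse.
#' @export
read_wave <- function(path, item_specs, wave_id, id_col = "participant_id") {
  item_specs <- as_item_list(item_specs)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("", "NA"))
  need <- c(id_col, names(item_specs))
  absent <- setdiff(need, names(tab))
  if (length(absent)) {
    stop("missing required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(tab[[id_col]])
  vals <- sapply(names(item_specs), function(id) {
    v <- tab[[id]]
    out <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop(sprintf("non-integer value '%s' for item '%s' in row %d",
                   v[bad[1]], id, bad[1]), call. = FALSE)
    }
    out
  })
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(NULL, names(item_specs)))
  response_matrix(vals, item_specs, ids, wave_id)
}

#' Write one survey wave to CSV
#'
#' Inverse of [read_wave()]: missing responses become blank cells, so a
#' write/read round trip reproduces the matrix cell-for-cell.
#'
#' @param matrix A [response_matrix()].
#' @param path Output CSV path.
#' @param id_col Name for the participant-id column.
#' @return `path`, invisibly.
#' @export
write_wave <- function(matrix, path, id_col = "participant_id") {
  stopifnot(inherits(matrix, "response_matrix"))
  out <- data.frame(matrix$participants, matrix$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c(id_col, colnames(matrix$values))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
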