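#' Define a Likert response scale
#'
#' A closed integer response range with its arithmetic midpoint. The midpoint
#' is an attainable response only when the range spans an even number of
#' steps (e.g. 1--7 has midpoint 4; 1--4 has midpoint 2.5, which no respondent
#' can select). Stance trichotomization ([binarize()]) splits responses at
#' this midpoint.
#'
#' @param min,max Integer endpoints of the scale, `max > min`.
#' @return An object of class `likert_scale` with fields `min`, `max`,
#'   `midpoint`.
#' @examples
#' likert_scale(1, 4)  # trust anchors: 1 = not at all, 4 = a lot
#' likert_scale(1, 7)
#' @export
likert_scale <- function(min, max) {
  min <- as.integer(min)
  max <- as.integer(max)
  if (length(min) != 1L || length(max) != 1L || is.na(min) || is.na(max)) {
    stop("'min' and 'max' must be single integers", call. = FALSE)
  }
  if (max <= min) stop("'max' must exceed 'min'", call. = FALSE)
  structure(
    list(min = min, max = max, midpoint = (min + max) / 2),
    class = "likert_scale"
  )
}

#' @export
print.likert_scale <- function(x, ...) {
  cat(sprintf("<likert_scale %d-%d, midpoint %.1f%s>\n",
              x$min, x$max, x$midpoint,
              if (has_midpoint(x)) "" else " (unattainable)"))
  invisible(x)
}

# midpoint attainable iff the span is even
has_midpoint <- function(scale) (scale$max - scale$min) %% 2L == 0L

#' Describe one survey item
#'
#' @param item_id Unique item identifier (the column name in wave CSV files).
#' @param label Human-readable item text.
#' @param scale A [likert_scale()].
#' @param block Item block: `"attitude"` items feed the networks,
#'   `"compliance"` and `"clarity"` items are scored into scales,
#'   `"attention"` marks attention-check items, `"demographic"` marks
#'   integer-coded background variables.
#' @return An object of class `item_spec`.
#' @examples
#' item_spec("trust_science", "Trust in science", likert_scale(1, 4))
#' @export
item_spec <- function(item_id, label = item_id, scale = likert_scale(1, 4),
                      block = c("attitude", "compliance", "clarity",
                                "attention", "demographic")) {
  stopifnot(is.character(item_id), length(item_id) == 1L, nzchar(item_id))
  if (!inherits(scale, "likert_scale")) {
    stop("'scale' must be a likert_scale", call. = FALSE)
  }
  block <- match.arg(block)
  structure(
    list(item_id = item_id, label = label, scale = scale, block = block),
    class = "item_spec"
  )
}

# validate a list of item_spec, unique ids; returns it named by item id
as_item_list <- function(items) {
  if (inherits(items, "item_spec")) items <- list(items)
  ok <- vapply(items, inherits, logical(1), "item_spec")
  if (!all(ok)) stop("'items' must be a list of item_spec objects", call. = FALSE)
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids)) {
    stop("duplicate item ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(items) <- ids
  items
}
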