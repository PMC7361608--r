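#' Drop participants who failed an attention check
#'
#' Retains exactly the rows whose response on the attention item equals the
#' prescribed correct value (a missing attention response counts as a
#' failure); the attention column is dropped from the returned matrix.
#'
#' @param matrix A [response_matrix()] containing `attention_item`.
#' @param attention_item Item id of the attention check.
#' @param expected The single correct response value.
#' @return A list with `matrix` (filtered [response_matrix()] without the
#'   attention column) and `report` (an exclusion report: `wave_id`,
#'   `failed_attention`, `unmatched`, `n_before`, `n_after`).
#' @export
apply_attention_exclusions <- function(matrix, attention_item, expected) {
  stopifnot(inherits(matrix, "response_matrix"))
  if (!attention_item %in% names(matrix$items)) {
    stop(sprintf("attention item '%s' not present in wave '%s'",
                 attention_item, matrix$wave_id), call. = FALSE)
  }
  v <- matrix$values[, attention_item]
  keep <- !is.na(v) & v == expected
  failed <- matrix$participants[!keep]
  keep_items <- setdiff(names(matrix$items), attention_item)
  out <- response_matrix(
    matrix$values[keep, keep_items, drop = FALSE],
    matrix$items[keep_items], matrix$participants[keep], matrix$wave_id
  )
  if (!any(keep)) {
    warning(sprintf("all %d participants failed the attention check in wave '%s'",
                    length(v), matrix$wave_id), call. = FALSE)
  }
  list(
    matrix = out,
    report = exclusion_report(matrix$wave_id, failed_attention = failed,
                              n_before = length(v))
  )
}

exclusion_report <- function(wave_id, failed_attention = character(0),
                             unmatched = character(0), n_before) {
  if (length(intersect(failed_attention, unmatched))) {
    stop("a participant cannot be both attention-failed and unmatched",
         call. = FALSE)
  }
  structure(
    list(wave_id = wave_id,
         failed_attention = failed_attention,
         unmatched = unmatched,
         n_before = n_before,
         n_after = n_before - length(failed_attention) - length(unmatched)),
    class = "exclusion_report"
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report wave '%s': %d -> %d (%d attention, %d unmatched)>\n",
              x$wave_id, x$n_before, x$n_after,
              length(x$failed_attention), length(x$unmatched)))
  invisible(x)
}

#' Restrict waves to the longitudinal panel
#'
#' Reduces every wave to the participants present in all waves (exact id
#' equality), in a common row order, mirroring the panel-matching
#' bookkeeping of longitudinal survey studies.
#'
#' @param waves List of two or more [response_matrix()] objects.
#' @return A list with `waves` (matched matrices, identical row order) and
#'   `reports` (per-wave exclusion reports listing the unmatched ids).
#' @export
match_waves <- function(waves) {
  if (length(waves) < 2L) stop("need at least two waves", call. = FALSE)
  lapply(waves, function(w) stopifnot(inherits(w, "response_matrix")))
  ids <- Reduce(intersect, lapply(waves, `[[`, "participants"))
  if (!length(ids)) {
    stop("no participant appears in every wave; no longitudinal panel exists",
         call. = FALSE)
  }
  # common order: order of appearance in the first wave
  ids <- waves[[1]]$participants[waves[[1]]$participants %in% ids]
  matched <- lapply(waves, function(w) {
    response_matrix(w$values[ids, , drop = FALSE], w$items, ids, w$wave_id)
  })
  reports <- lapply(waves, function(w) {
    exclusion_report(w$wave_id, unmatched = setdiff(w$participants, ids),
                     n_before = length(w$participants))
  })
  list(waves = matched, reports = reports)
}
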