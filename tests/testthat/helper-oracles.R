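# Independent reference implementations and fixture builders used across
# tests. The oracles deliberately use naive loops so they share no code
# path with the package's vectorised implementations.

# stance matrix with entries drawn from {-1, 0, +1, NA}
random_stance <- function(n, m, p_na = 0.1, wave_id = "T1") {
  s <- matrix(sample(c(-1L, 0L, 1L), n * m, replace = TRUE), n, m)
  s[matrix(runif(n * m) < p_na, n, m)] <- NA_integer_
  ids <- sprintf("p%02d", seq_len(n))
  items <- sprintf("i%02d", seq_len(m))
  dimnames(s) <- list(ids, items)
  structure(
    list(wave_id = wave_id, participants = ids, item_ids = items,
         stances = s, rule = list(rule = "midpoint", cutpoints = NULL)),
    class = "stance_matrix"
  )
}

# stance matrix from an explicit grid (rows = participants)
stance_fixture <- function(grid, wave_id = "T1") {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  ids <- sprintf("p%02d", seq_len(nrow(grid)))
  items <- sprintf("i%02d", seq_len(ncol(grid)))
  dimnames(grid) <- list(ids, items)
  structure(
    list(wave_id = wave_id, participants = ids, item_ids = items,
         stances = grid, rule = list(rule = "midpoint", cutpoints = NULL)),
    class = "stance_matrix"
  )
}

# naive double-loop participant projection
naive_project_participants <- function(stance, min_overlap = 5, threshold = 0.75) {
  s <- stance$stances
  n <- nrow(s)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      compared <- 0L; shared <- 0L
      for (k in seq_len(ncol(s))) {
        a <- s[i, k]; b <- s[j, k]
        if (!is.na(a) && !is.na(b) && a != 0L && b != 0L) {
          compared <- compared + 1L
          if (a == b) shared <- shared + 1L
        }
      }
      if (compared >= min_overlap && compared > 0 &&
          shared / compared >= threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          u = stance$participants[i], v = stance$participants[j],
          weight = shared / compared, sign = 1L, support = compared,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(u = character(0), v = character(0), weight = numeric(0),
               sign = integer(0), support = numeric(0))
}

# naive double-loop attitude projection
naive_project_attitudes <- function(stance) {
  s <- stance$stances
  m <- ncol(s)
  rows <- list()
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      C <- 0L; D <- 0L
      for (i in seq_len(nrow(s))) {
        x <- s[i, a]; y <- s[i, b]
        if (!is.na(x) && !is.na(y)) {
          if (x * y == 1L) C <- C + 1L
          if (x * y == -1L) D <- D + 1L
        }
      }
      net <- C - D
      if (net != 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          u = stance$item_ids[a], v = stance$item_ids[b],
          weight = abs(net), sign = sign(net), support = C + D,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(u = character(0), v = character(0), weight = numeric(0),
               sign = integer(0), support = numeric(0))
}

# canonical edge ordering for comparisons
sort_edges <- function(e) {
  e <- e[order(e$u, e$v), , drop = FALSE]
  rownames(e) <- NULL
  e$weight <- as.numeric(e$weight)
  e$sign <- as.integer(e$sign)
  e$support <- as.numeric(e$support)
  e
}

# small response matrix around a 1-7 battery
tiny_wave <- function(values, wave_id = "T1", scale = likert_scale(1, 7),
                      block = "attitude") {
  values <- as.matrix(values)
  items <- lapply(sprintf("q%d", seq_len(ncol(values))), item_spec,
                  scale = scale, block = block)
  response_matrix(values, items, sprintf("p%02d", seq_len(nrow(values))),
                  wave_id)
}
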