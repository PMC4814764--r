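# Independent brute-force oracles: naive cell-by-cell recomputations of the
# recurrence quantities, kept deliberately simple and separate from the
# package's implementations.

# random tier series with a configurable share of no-event seconds
random_tiers <- function(n, p_zero = 0.35) {
  sample(0:3, n, replace = TRUE,
         prob = c(p_zero, rep((1 - p_zero) / 3, 3)))
}

# naive CRP: explicit double loop
oracle_crp <- function(g, s) {
  m <- matrix(0L, length(g), length(s))
  for (i in seq_along(g)) {
    for (j in seq_along(s)) {
      if (g[i] != 0L && g[i] == s[j]) m[i, j] <- g[i]
    }
  }
  m
}

# naive maximal-run scanner along one orientation
oracle_lines <- function(m, orientation, min_line = 1L) {
  if (orientation == "horizontal") m <- t(m)
  out <- list()
  for (j in seq_len(ncol(m))) {
    i <- 1L
    while (i <= nrow(m)) {
      if (m[i, j] > 0L) {
        start <- i
        while (i <= nrow(m) && m[i, j] > 0L) i <- i + 1L
        len <- i - start
        if (len >= min_line) {
          out[[length(out) + 1]] <- data.frame(
            orientation = orientation, anchor = j, start = start,
            length = len, tier = m[start, j], stringsAsFactors = FALSE)
        }
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(orientation = character(0), anchor = integer(0),
                      start = integer(0), length = integer(0),
                      tier = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# naive recomputation of all seven global measures
oracle_measures <- function(m, min_line = 2L) {
  n_rec <- sum(m > 0)
  res <- list(rr = n_rec / length(m))
  for (o in c("vertical", "horizontal")) {
    runs <- oracle_lines(m, o, 1L)
    qual <- runs[runs$length >= min_line, , drop = FALSE]
    key <- if (o == "vertical") "v" else "h"
    res[[paste0("lam_", key)]] <- if (n_rec == 0) 0 else
      sum(qual$length) / n_rec
    res[[paste0("tt_", key)]] <- if (nrow(qual) == 0) 0 else mean(qual$length)
    res[[paste0("maxl_", key)]] <- if (nrow(runs) == 0) 0 else max(runs$length)
  }
  res
}

# naive diagonal profile (counts and per-diagonal rates)
oracle_profile <- function(m, window_s) {
  n <- nrow(m)
  tau <- seq.int(-window_s, window_s)
  count <- integer(length(tau))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- j - i
      if (m[i, j] > 0L && abs(d) <= window_s) {
        count[d + window_s + 1L] <- count[d + window_s + 1L] + 1L
      }
    }
  }
  list(tau = tau, count = count, rr = count / (n - abs(tau)))
}

# events table shorthand for fixtures
ev_row <- function(start, end, level, stream = "gesture", child = "c01",
                   category = "x") {
  data.frame(child_id = child, stream = stream, start_s = start, end_s = end,
             category = category,
             level = if (is.null(level)) NA_integer_ else as.integer(level),
             stringsAsFactors = FALSE)
}
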