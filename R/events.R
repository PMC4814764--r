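#' Read a coded-event table
#'
#' Reads a CSV of timed, leveled behavioral episodes with header
#' `child_id,stream,start_s,end_s,category,level`. Each row is one coded
#' event in one stream (`"gesture"` or `"speech"`): its start and end time in
#' seconds and, when one was assigned, a skill level on the 1-7 complexity
#' scale (levels 1-3 sensorimotor, 4-6 representational, 7 abstract). Events
#' without a level (e.g. emblems, short answers) leave the `level` field
#' empty.
#'
#' Rows are validated against the event invariants: `end_s > start_s`,
#' `level` in 1..7 when present, and no temporal overlap between two events
#' of the same stream of the same child. Violations raise an error naming the
#' offending file line(s).
#'
#' @param path Path to the events CSV.
#' @return A `data.frame` with columns `child_id`, `stream`, `start_s`,
#'   `end_s`, `category`, `level` (integer, `NA` when unassigned), sorted by
#'   child, stream and `start_s`.
#' @seealso [rasterize_events()], [read_child_meta()]
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(child_id = "character",
                                       stream = "character",
                                       category = "character"))
  required <- c("child_id", "stream", "start_s", "end_s", "category", "level")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("events file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$line <- seq_len(nrow(df)) + 1L  # header is line 1
  df$start_s <- suppressWarnings(as.numeric(df$start_s))
  df$end_s <- suppressWarnings(as.numeric(df$end_s))
  df$level <- suppressWarnings(as.integer(df$level))

  bad <- df$line[is.na(df$start_s) | is.na(df$end_s) |
                   !(df$stream %in% c("gesture", "speech"))]
  if (length(bad) > 0) {
    stop("malformed event row(s) at line(s) ", paste(bad, collapse = ", "),
         " of ", path)
  }
  bad <- df$line[df$end_s <= df$start_s]
  if (length(bad) > 0) {
    stop("end_s <= start_s at line(s) ", paste(bad, collapse = ", "),
         " of ", path)
  }
  bad <- df$line[!is.na(df$level) & !(df$level %in% 1:7)]
  if (length(bad) > 0) {
    stop("skill level outside 1..7 at line(s) ", paste(bad, collapse = ", "),
         " of ", path)
  }

  df <- df[order(df$child_id, df$stream, df$start_s), ]
  for (key in split(df, interaction(df$child_id, df$stream, drop = TRUE))) {
    if (nrow(key) < 2) next
    ov <- which(key$start_s[-1] < key$end_s[-nrow(key)])
    if (length(ov) > 0) {
      stop("overlapping ", key$stream[1], " events for child ",
           key$child_id[1], " at lines ",
           paste(paste(key$line[ov], key$line[ov + 1], sep = "/"),
                 collapse = ", "), " of ", path)
    }
  }
  rownames(df) <- NULL
  df[, required]
}

#' Read a child-metadata table
#'
#' CSV with header
#' `child_id,grade,age_months,math_score,language_score,avg_past_score`.
#' Math and language scores are national-test scores on a 1-5 scale; an empty
#' field marks a missing score.
#'
#' @param path Path to the metadata CSV.
#' @return A `data.frame`, one row per child.
#' @export
read_child_meta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(child_id = "character",
                                       grade = "character"))
  required <- c("child_id", "grade", "age_months", "math_score",
                "language_score", "avg_past_score")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("math_score", "language_score")) {
    bad <- !is.na(df[[col]]) & (df[[col]] < 1 | df[[col]] > 5)
    if (any(bad)) stop(col, " outside [1,5] for child ",
                       paste(df$child_id[bad], collapse = ", "))
  }
  df
}

#' Rasterize coded events into a 1 Hz skill-level series
#'
#' Turns the coded events of one stream into an integer series with one value
#' per second: bin `t` covers the half-open interval `[t, t+1)` seconds and
#' carries the skill level of the event that overlaps the majority of the bin
#' (at least 0.5 s); seconds with no leveled event carry 0. Events without an
#' assigned level contribute 0. When two adjacent events each cover exactly
#' half a bin, the later-starting event wins the bin.
#'
#' @param events Events `data.frame` (as from [read_events()]) restricted to
#'   a single stream of a single child.
#' @param duration_s Series length in seconds; must cover the last event.
#' @return A `skill_series` object: integer values in 0..7 with attributes
#'   `child_id`, `stream`, `t0_s`.
#' @examples
#' ev <- data.frame(child_id = "c01", stream = "gesture",
#'                  start_s = 5, end_s = 8, category = "movement", level = 3)
#' rasterize_events(ev, duration_s = 10)
#' @export
rasterize_events <- function(events, duration_s) {
  if (nrow(events) > 0) {
    if (length(unique(events$stream)) > 1) {
      stop("rasterize_events() expects events from a single stream")
    }
    if (duration_s < max(ceiling(events$end_s))) {
      stop("duration_s (", duration_s, ") does not cover the last event (",
           max(events$end_s), ")")
    }
  }
  values <- integer(duration_s)
  if (nrow(events) > 0) {
    events <- events[order(events$start_s), ]
    for (k in seq_len(nrow(events))) {
      lev <- events$level[k]
      lev <- if (is.na(lev)) 0L else as.integer(lev)
      first <- floor(events$start_s[k])
      last <- ceiling(events$end_s[k]) - 1
      for (t in first:last) {
        overlap <- min(events$end_s[k], t + 1) - max(events$start_s[k], t)
        # >= 0.5 s majority rule; later-starting events overwrite exact ties
        if (overlap >= 0.5 - 1e-9) values[t + 1] <- lev
      }
    }
  }
  new_skill_series(values,
                   child_id = if (nrow(events) > 0) events$child_id[1] else NA_character_,
                   stream = if (nrow(events) > 0) events$stream[1] else NA_character_)
}

#' @rdname rasterize_events
#' @param values Integer vector, values in 0..7 (0 = no event that second).
#' @param child_id,stream,t0_s Series identity attributes.
#' @export
new_skill_series <- function(values, child_id = NA_character_,
                             stream = NA_character_, t0_s = 0) {
  values <- as.integer(values)
  if (length(values) < 1) stop("a skill series needs at least one sample")
  if (any(is.na(values)) || any(values < 0 | values > 7)) {
    stop("skill-series values must be integers in 0..7")
  }
  structure(values, class = "skill_series",
            child_id = child_id, stream = stream, t0_s = t0_s)
}

#' Map skill levels to tiers
#'
#' Collapses the 1-7 level scale onto the three tiers that define a
#' recurrence match: levels 1-3 are sensorimotor (tier 1), 4-6
#' representational (tier 2), level 7 abstract (tier 3); 0 (no event) stays 0.
#'
#' @param series A `skill_series` or a bare integer vector with values 0..7.
#' @return A `tier_series`: integers 0..3, same length and attributes.
#' @export
to_tiers <- function(series) {
  values <- as.integer(series)
  if (any(is.na(values)) || any(values < 0 | values > 7)) {
    stop("skill levels must be integers in 0..7")
  }
  tiers <- c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L)[values + 1L]
  structure(tiers, class = "tier_series",
            child_id = attr(series, "child_id"),
            stream = attr(series, "stream"),
            t0_s = attr(series, "t0_s") %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.skill_series <- function(x, ...) {
  cat("<skill_series> child", attr(x, "child_id"), "stream",
      attr(x, "stream"), "length", length(x), "s\n")
  print(unclass(x)[seq_len(min(length(x), 30))])
  invisible(x)
}

#' @export
print.tier_series <- function(x, ...) {
  cat("<tier_series> child", attr(x, "child_id"), "stream",
      attr(x, "stream"), "length", length(x), "s\n")
  print(unclass(x)[seq_len(min(length(x), 30))])
  invisible(x)
}

#' Rasterize both streams of one child to a common duration
#'
#' Both streams are rasterized to the same length (the smallest whole second
#' covering the end of the later stream, unless `duration_s` is given), so
#' that the resulting cross-recurrence plot is square.
#'
#' @param events Events `data.frame` for one child (both streams).
#' @param duration_s Optional common duration override.
#' @return A list with elements `gesture` and `speech` (each a list with
#'   `levels` and `tiers`) plus `duration_s`.
#' @export
child_series <- function(events, duration_s = NULL) {
  if (is.null(duration_s)) {
    duration_s <- if (nrow(events) > 0) max(ceiling(events$end_s)) else 1L
  }
  out <- lapply(c(gesture = "gesture", speech = "speech"), function(s) {
    lv <- rasterize_events(events[events$stream == s, , drop = FALSE],
                           duration_s)
    list(levels = lv, tiers = to_tiers(lv))
  })
  out$duration_s <- as.integer(duration_s)
  out
}

#' Export the per-second series of one child
#'
#' Writes `t_s,gesture_level,speech_level,gesture_tier,speech_tier`.
#'
#' @param series A [child_series()] result.
#' @param path Output CSV path.
#' @export
write_series <- function(series, path) {
  df <- data.frame(t_s = seq_along(series$gesture$levels) - 1L,
                   gesture_level = as.integer(series$gesture$levels),
                   speech_level = as.integer(series$speech$levels),
                   gesture_tier = as.integer(series$gesture$tiers),
                   speech_tier = as.integer(series$speech$tiers))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert a whole-second-aligned series back to events
#'
#' Inverse of [rasterize_events()] for series whose episodes sit on whole
#' seconds: every maximal run of a constant nonzero level becomes one event.
#' Useful for round-trip checks and for episode-preserving permutation nulls.
#'
#' @param series A `skill_series` (or integer vector, values 0..7).
#' @param child_id,stream Identity fields for the emitted rows.
#' @return Events `data.frame` in the [read_events()] layout.
#' @export
series_to_events <- function(series, child_id = attr(series, "child_id"),
                             stream = attr(series, "stream")) {
  r <- rle(as.integer(series))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  data.frame(child_id = if (is.null(child_id) || is.na(child_id)) "x" else child_id,
             stream = if (is.null(stream) || is.na(stream)) "gesture" else stream,
             start_s = as.numeric(starts[keep]),
             end_s = as.numeric(ends[keep]),
             category = "episode",
             level = as.integer(r$values[keep]),
             stringsAsFactors = FALSE)
}
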