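#' Build a tier-matched categorical cross-recurrence plot
#'
#' Cell (i, j) of the plot compares gesture second i (rows, the vertical
#' axis) with speech second j (columns, the horizontal axis); it is recurrent
#' when both seconds display a skill level from the same tier, and carries
#' that tier (1 sensorimotor, 2 representational, 3 abstract). Seconds where
#' either stream shows no leveled event (tier 0) are never recurrent.
#'
#' @param gesture_tiers,speech_tiers `tier_series` (or integer vectors in
#'   0..3) of equal length.
#' @return A `crp` object: an integer matrix with values 0..3, gesture time
#'   on rows.
#' @examples
#' build_crp(c(1, 0, 2), c(2, 1, 0))
#' @export
build_crp <- function(gesture_tiers, speech_tiers) {
  g <- as.integer(gesture_tiers)
  s <- as.integer(speech_tiers)
  if (length(g) != length(s)) {
    stop("tier series differ in length (", length(g), " vs ", length(s), ")")
  }
  if (any(g < 0 | g > 3) || any(s < 0 | s > 3)) {
    stop("tier values must be integers in 0..3")
  }
  m <- outer(g, s, "==") * g  # g[i] recycles down columns: cell (i,j) = g[i]
  storage.mode(m) <- "integer"
  structure(m, class = c("crp", "matrix"))
}

#' @export
print.crp <- function(x, ...) {
  cat("<crp> ", nrow(x), "x", ncol(x), " (gesture x speech), RR = ",
      signif(mean(x > 0), 4), "\n", sep = "")
  invisible(x)
}

#' Extract maximal line structures from a cross-recurrence plot
#'
#' A vertical line is a maximal run of recurrent cells down one column
#' (successive gesture seconds matching a single speech second); a horizontal
#' line is the analogue along one row. Because each second has exactly one
#' tier, every run is tier-pure. All maximal runs with length at least
#' `min_line` are returned.
#'
#' @param crp A `crp` matrix.
#' @param orientation `"vertical"` or `"horizontal"`.
#' @param min_line Minimum run length to report (>= 1).
#' @return A `data.frame` with columns `orientation`, `anchor` (the fixed
#'   column for vertical lines, the fixed row for horizontal ones; 1-based),
#'   `start` (first index along the run, 1-based), `length`, `tier`.
#' @export
extract_lines <- function(crp, orientation = c("vertical", "horizontal"),
                          min_line = 1L) {
  orientation <- match.arg(orientation)
  if (min_line < 1) stop("min_line must be >= 1")
  m <- if (orientation == "vertical") unclass(crp) else t(unclass(crp))
  anchors <- integer(0); starts <- integer(0)
  lens <- integer(0); tiers <- integer(0)
  for (j in seq_len(ncol(m))) {
    r <- rle(m[, j] > 0)
    if (!any(r$values)) next
    run_ends <- cumsum(r$lengths)
    run_starts <- run_ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_line
    if (!any(keep)) next
    anchors <- c(anchors, rep.int(j, sum(keep)))
    starts <- c(starts, run_starts[keep])
    lens <- c(lens, r$lengths[keep])
    tiers <- c(tiers, m[run_starts[keep], j])
  }
  data.frame(orientation = rep.int(orientation, length(anchors)),
             anchor = anchors, start = starts, length = lens, tier = tiers,
             stringsAsFactors = FALSE)
}

#' Global anisotropic CRQA measures
#'
#' Computes, over the full plot: the recurrence rate RR (recurrent cells over
#' all cells), and — separately for vertical and horizontal line structures —
#' laminarity LAM (share of recurrent points lying in runs of length >=
#' `min_line`), trapping time TT (mean length of those runs, in seconds) and
#' MaxL (length of the longest run of any length >= 1). Vertical lines index
#' gestures lingering in a tier briefly visited by speech; horizontal lines
#' the reverse. With no recurrent points RR, LAM, TT and MaxL are all 0; with
#' recurrence but no qualifying lines LAM and TT are 0 while MaxL >= 1.
#'
#' @param crp A `crp` matrix.
#' @param min_line Minimum run length for a run to count as a line structure
#'   (default 2: an isolated point is not a line).
#' @return A `crqa_measures` list: `rr`, `lam_v`, `lam_h`, `tt_v`, `tt_h`,
#'   `maxl_v`, `maxl_h`, plus `n_recurrent`, `min_line`.
#' @export
crqa_measures <- function(crp, min_line = 2L) {
  n_rec <- sum(crp > 0)
  out <- list(rr = n_rec / (nrow(crp) * ncol(crp)))
  for (o in c(v = "vertical", h = "horizontal")) {
    runs <- extract_lines(crp, o, min_line = 1L)
    key <- names(which(c(v = "vertical", h = "horizontal") == o))
    qual <- runs[runs$length >= min_line, , drop = FALSE]
    out[[paste0("lam_", key)]] <-
      if (n_rec == 0) 0 else sum(qual$length) / n_rec
    out[[paste0("tt_", key)]] <-
      if (nrow(qual) == 0) 0 else mean(qual$length)
    out[[paste0("maxl_", key)]] <-
      if (nrow(runs) == 0) 0 else max(runs$length)
  }
  out$n_recurrent <- n_rec
  out$min_line <- as.integer(min_line)
  structure(out[c("rr", "lam_v", "lam_h", "tt_v", "tt_h",
                  "maxl_v", "maxl_h", "n_recurrent", "min_line")],
            class = "crqa_measures")
}

#' @export
print.crqa_measures <- function(x, ...) {
  cat(sprintf(paste0("CRQA measures (min_line = %d)\n",
                     "  RR    %0.3f\n",
                     "  LAM   V %0.3f  H %0.3f\n",
                     "  TT    V %0.1f  H %0.1f\n",
                     "  MaxL  V %d  H %d\n"),
              x$min_line, x$rr, x$lam_v, x$lam_h, x$tt_v, x$tt_h,
              as.integer(x$maxl_v), as.integer(x$maxl_h)))
  invisible(x)
}

#' Tier-restricted CRQA measures
#'
#' Restricts the line analysis to recurrent cells of one tier (the
#' tier-restricted plot of the sensorimotor or representational analysis).
#' `pct_rr` (the share of all recurrent points belonging to this tier, in
#' percent) and the tier laminarity values keep the full plot's
#' recurrent-point count as denominator, so that tier LAM values sum to the
#' global LAM and tier `pct_rr` values sum to 100. TT and MaxL are computed
#' over this tier's lines only.
#'
#' @param crp A `crp` matrix.
#' @param tier Tier to keep (1, 2 or 3).
#' @param min_line Minimum line length, as in [crqa_measures()].
#' @return A `tier_measures` list: `tier`, `pct_rr`, `lam_v`, `lam_h`,
#'   `tt_v`, `tt_h`, `maxl_v`, `maxl_h`.
#' @export
tier_measures <- function(crp, tier, min_line = 2L) {
  if (!tier %in% 1:3) stop("tier must be 1, 2 or 3")
  n_rec_all <- sum(crp > 0)
  n_rec_tier <- sum(crp == tier)
  out <- list(tier = as.integer(tier),
              pct_rr = if (n_rec_all == 0) 0 else 100 * n_rec_tier / n_rec_all)
  for (o in c(v = "vertical", h = "horizontal")) {
    key <- names(which(c(v = "vertical", h = "horizontal") == o))
    runs <- extract_lines(crp, o, min_line = 1L)
    runs <- runs[runs$tier == tier, , drop = FALSE]
    qual <- runs[runs$length >= min_line, , drop = FALSE]
    out[[paste0("lam_", key)]] <-
      if (n_rec_all == 0) 0 else sum(qual$length) / n_rec_all
    out[[paste0("tt_", key)]] <-
      if (nrow(qual) == 0) 0 else mean(qual$length)
    out[[paste0("maxl_", key)]] <-
      if (nrow(runs) == 0) 0 else max(runs$length)
  }
  out$min_line <- as.integer(min_line)
  structure(out, class = "tier_measures")
}

#' Relative-difference asymmetry scores
#'
#' Collapses the vertical/horizontal contrast into per-child asymmetry
#' scores: `vh_lam = LAM_V - LAM_H` (a difference of proportions),
#' `vh_tt = (TT_V - TT_H) / (TT_V + TT_H)` and
#' `vh_maxl = (MaxL_V - MaxL_H) / (MaxL_V + MaxL_H)` (relative differences in
#' [-1, 1]). Positive scores mean the vertical (gesture-lingering) structures
#' dominate. A relative difference with both operands 0 is undefined and
#' returned as `NA`.
#'
#' @param measures A [crqa_measures()] or [tier_measures()] result, or any
#'   list with fields `lam_v`, `lam_h`, `tt_v`, `tt_h`, `maxl_v`, `maxl_h`.
#' @return A list with `vh_lam`, `vh_tt`, `vh_maxl`.
#' @export
asymmetry_scores <- function(measures) {
  rel <- function(v, h) {
    if (v + h == 0) NA_real_ else (v - h) / (v + h)
  }
  list(vh_lam = measures$lam_v - measures$lam_h,
       vh_tt = rel(measures$tt_v, measures$tt_h),
       vh_maxl = rel(measures$maxl_v, measures$maxl_h))
}

#' Export a cross-recurrence plot as CSV
#'
#' Writes either the dense integer matrix (one row per gesture second) or a
#' sparse triplet table `i,j,tier` (1-based indices) for large plots.
#'
#' @param crp A `crp` matrix.
#' @param path Output path.
#' @param sparse Write triplets instead of the dense matrix.
#' @export
write_crp <- function(crp, path, sparse = FALSE) {
  if (sparse) {
    idx <- which(crp > 0, arr.ind = TRUE)
    df <- data.frame(i = idx[, 1], j = idx[, 2], tier = crp[idx])
    utils::write.csv(df[order(df$i, df$j), ], path, row.names = FALSE)
  } else {
    utils::write.table(unclass(crp), path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
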