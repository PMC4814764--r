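#' Parameters of the coupled-streams generator
#'
#' The generator emulates one child working through a hands-on task: a latent
#' sequence of understanding states (each with a tier — sensorimotor or
#' representational — and a geometric dwell time) drives both streams. Each
#' state is expressed, independently per stream, as one coded episode that
#' starts at the state onset plus a stream-specific lag plus rounded Gaussian
#' jitter, lasts a geometric number of seconds, and carries a level drawn
#' uniformly from the state's tier; with probability `p_mismatch` the episode
#' expresses the other tier instead (a gesture-speech mismatch).
#'
#' Defaults mirror a 12-child cohort of 5-12 minute sessions: 480 s
#' duration, ~20 s latent states, gesture episodes averaging 6 s vs speech
#' 3.5 s (the dwell asymmetry behind TT_V > TT_H), gestures leading speech by
#' 6 s (the cohort-level mean delay), 2 s of onset jitter and a 10% mismatch
#' rate.
#'
#' @param duration_s Session length in seconds (sessions run 300-720 s).
#' @param mean_state_dwell_s Mean dwell of a latent understanding state.
#' @param p_tier_R Probability a latent state is representational (tier 2)
#'   rather than sensorimotor (tier 1).
#' @param lag_gesture_s,lag_speech_s Delay (whole seconds, >= 0) from state
#'   onset to each stream's expression; `lag_speech_s - lag_gesture_s` is the
#'   intended gesture lead.
#' @param jitter_sd_s SD of the rounded Gaussian onset jitter, seconds.
#' @param mean_episode_gesture_s,mean_episode_speech_s Mean expressed-episode
#'   durations (>= 1 s).
#' @param p_express_gesture,p_express_speech Probability that a state is
#'   expressed at all in each stream.
#' @param p_mismatch Probability an episode expresses the other tier.
#' @param seed Integer seed.
#' @return A `gen_params` list.
#' @export
gen_params <- function(duration_s = 480L,
                       mean_state_dwell_s = 20,
                       p_tier_R = 0.4,
                       lag_gesture_s = 0L,
                       lag_speech_s = 6L,
                       jitter_sd_s = 2,
                       mean_episode_gesture_s = 6,
                       mean_episode_speech_s = 3.5,
                       p_express_gesture = 0.9,
                       p_express_speech = 0.8,
                       p_mismatch = 0.1,
                       seed = 1L) {
  p <- list(duration_s = as.integer(duration_s),
            mean_state_dwell_s = mean_state_dwell_s,
            p_tier_R = p_tier_R,
            lag_gesture_s = as.integer(lag_gesture_s),
            lag_speech_s = as.integer(lag_speech_s),
            jitter_sd_s = jitter_sd_s,
            mean_episode_gesture_s = mean_episode_gesture_s,
            mean_episode_speech_s = mean_episode_speech_s,
            p_express_gesture = p_express_gesture,
            p_express_speech = p_express_speech,
            p_mismatch = p_mismatch,
            seed = as.integer(seed))
  probs <- c(p$p_tier_R, p$p_express_gesture, p$p_express_speech, p$p_mismatch)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p$duration_s < 1) stop("duration_s must be positive")
  if (p$lag_gesture_s < 0 || p$lag_speech_s < 0) stop("lags must be >= 0")
  if (p$mean_episode_gesture_s < 1 || p$mean_episode_speech_s < 1) {
    stop("mean episode durations must be >= 1 s")
  }
  if (max(p$mean_episode_gesture_s, p$mean_episode_speech_s) >=
      3 * p$mean_state_dwell_s) {
    warning("episode means close to or above the state dwell: ",
            "episodes will be heavily clipped")
  }
  structure(p, class = "gen_params")
}

# geometric duration with mean m, support {1, 2, ...}
rdwell <- function(n, m) {
  if (m <= 1) rep.int(1L, n) else stats::rgeom(n, 1 / m) + 1L
}

# geometric duration through a shared uniform quantile: comonotonic across
# streams, so equal means give equal durations while marginals stay geometric
qdwell <- function(u, m) {
  if (m <= 1) 1L else as.integer(stats::qgeom(u, 1 / m)) + 1L
}

#' Simulate one child's coupled gesture and speech events
#'
#' Draws the latent state sequence and the expressed episodes of both
#' streams under `params` (see [gen_params()]), fully reproducibly from
#' `params$seed`. Episodes are truncated at the session end and within-stream
#' overlap is resolved by clipping an episode's start to the previous
#' episode's end.
#'
#' @param params A [gen_params()] list.
#' @param child_id Identifier used in the emitted event rows.
#' @return A list with `events` (both streams, in the [read_events()]
#'   layout), `truth` (ground truth: `intended_lead_s`
#'   = `lag_speech_s - lag_gesture_s`, positive when gestures lead, and
#'   `intended_tt_ratio` = gesture/speech mean episode duration), and
#'   `params`.
#' @export
simulate_child <- function(params = gen_params(), child_id = "sim01") {
  stopifnot(inherits(params, "gen_params"))
  set.seed(params$seed)

  # latent understanding states covering the session
  onsets <- integer(0); tiers <- integer(0)
  t <- 0L
  while (t < params$duration_s) {
    onsets <- c(onsets, t)
    tiers <- c(tiers, if (stats::runif(1) < params$p_tier_R) 2L else 1L)
    t <- t + rdwell(1, params$mean_state_dwell_s)
  }
  # one duration quantile per state, shared by both streams: durations are
  # comonotonic across streams (equal episode means -> identical episodes)
  u_dur <- stats::runif(length(onsets))

  express <- function(stream, lag, mean_episode, p_express) {
    rows <- list()
    for (k in seq_along(onsets)) {
      if (stats::runif(1) >= p_express) next
      jit <- if (params$jitter_sd_s > 0) {
        as.integer(round(stats::rnorm(1, 0, params$jitter_sd_s)))
      } else 0L
      start <- onsets[k] + lag + jit
      dur <- qdwell(u_dur[k], mean_episode)
      tier <- tiers[k]
      if (stats::runif(1) < params$p_mismatch) tier <- 3L - tier
      level <- if (tier == 1L) sample(1:3, 1) else sample(4:6, 1)
      rows[[length(rows) + 1]] <- data.frame(
        child_id = child_id, stream = stream,
        start_s = as.numeric(start), end_s = as.numeric(start + dur),
        category = if (tier == 1L) "sensorimotor" else "representational",
        level = level, stringsAsFactors = FALSE)
    }
    if (length(rows) == 0) {
      return(data.frame(child_id = character(0), stream = character(0),
                        start_s = numeric(0), end_s = numeric(0),
                        category = character(0), level = integer(0)))
    }
    ev <- do.call(rbind, rows)
    ev <- ev[order(ev$start_s), ]
    # clip into the session and resolve within-stream overlap
    ev$start_s <- pmax(ev$start_s, 0)
    ev$end_s <- pmin(ev$end_s, params$duration_s)
    if (nrow(ev) > 1) {
      # clip each start to the furthest end seen so far; episodes swallowed
      # whole (end <= clipped start) are dropped below
      high <- ev$end_s[1]
      for (k in 2:nrow(ev)) {
        ev$start_s[k] <- max(ev$start_s[k], high)
        high <- max(high, ev$end_s[k])
      }
    }
    ev <- ev[ev$end_s > ev$start_s, , drop = FALSE]
    rownames(ev) <- NULL
    ev
  }

  events <- rbind(
    express("gesture", params$lag_gesture_s, params$mean_episode_gesture_s,
            params$p_express_gesture),
    express("speech", params$lag_speech_s, params$mean_episode_speech_s,
            params$p_express_speech))

  list(events = events,
       truth = list(
         intended_lead_s = params$lag_speech_s - params$lag_gesture_s,
         intended_tt_ratio = params$mean_episode_gesture_s /
           params$mean_episode_speech_s,
         n_states = length(onsets)),
       params = params)
}

#' Simulate a cohort of children with linked covariates
#'
#' Draws per-child generator parameters from uniform ranges, simulates each
#' child with [simulate_child()], and fabricates a metadata table whose
#' covariates can be linearly linked to each child's ground truth so that
#' correlation recovery can be exercised: age declines with the intended
#' gesture lead at `age_lead_slope` months per second (younger children lead
#' more with gestures when the slope is negative), and the math score rises
#' with the intended trapping-time ratio when `math_tt_slope` is nonzero.
#'
#' @param n_children Number of children (>= 1).
#' @param params_ranges Named list of `c(min, max)` ranges overriding
#'   [gen_params()] defaults per child; numeric scalars are held fixed.
#'   Integer-valued parameters (`duration_s`, lags) are drawn on whole
#'   numbers.
#' @param seed Cohort seed; child `i` is simulated with seed
#'   `seed * 1000 + i` (keep `seed` below ~2e6).
#' @param age_lead_slope Months of age per second of intended gesture lead.
#' @param math_tt_slope Math-score points per unit of intended TT ratio.
#' @param noise_sd SD of the Gaussian noise added to linked covariates.
#' @param out_dir If non-`NULL`, the event and metadata tables are also
#'   written there (`events.csv`, `meta.csv`) in the [read_events()] /
#'   [read_child_meta()] dialects, plus a `scenario.yaml` capturing each
#'   child's parameters.
#' @return A list with `events` (all children), `meta`, `truth` (one row per
#'   child) and `params` (per-child `gen_params`).
#' @export
simulate_cohort <- function(n_children = 12L,
                            params_ranges = list(lag_speech_s = c(0L, 20L)),
                            seed = 1L,
                            age_lead_slope = -0.6,
                            math_tt_slope = 0,
                            noise_sd = 2,
                            out_dir = NULL) {
  if (n_children < 1) stop("n_children must be >= 1")
  base <- unclass(gen_params())
  set.seed(seed)
  draw <- function(name) {
    rng <- params_ranges[[name]]
    if (is.null(rng)) return(base[[name]])
    if (length(rng) == 1) return(rng)
    if (name %in% c("duration_s", "lag_gesture_s", "lag_speech_s")) {
      sample(seq.int(rng[1], rng[2]), 1)
    } else {
      stats::runif(1, rng[1], rng[2])
    }
  }
  fields <- setdiff(names(base), "seed")
  params <- lapply(seq_len(n_children), function(i) {
    args <- lapply(fields, draw)
    names(args) <- fields
    args$seed <- seed * 1000L + i
    do.call(gen_params, args)
  })

  children <- lapply(seq_len(n_children), function(i) {
    simulate_child(params[[i]], child_id = sprintf("c%02d", i))
  })
  events <- do.call(rbind, lapply(children, `[[`, "events"))
  truth <- do.call(rbind, lapply(seq_len(n_children), function(i) {
    data.frame(child_id = sprintf("c%02d", i),
               intended_lead_s = children[[i]]$truth$intended_lead_s,
               intended_tt_ratio = children[[i]]$truth$intended_tt_ratio,
               n_states = children[[i]]$truth$n_states)
  }))

  # covariates: linear link to ground truth plus noise (RNG state continues
  # from the cohort seed; child simulations used their own derived seeds)
  set.seed(seed + 500000L)
  lead <- truth$intended_lead_s
  age <- round(64 + age_lead_slope * (lead - mean(lead)) +
                 stats::rnorm(n_children, 0, noise_sd))
  clamp15 <- function(x) pmin(5, pmax(1, round(x)))
  math <- clamp15(4 + math_tt_slope * (truth$intended_tt_ratio -
                                         mean(truth$intended_tt_ratio)) +
                    stats::rnorm(n_children, 0, 0.8))
  lang <- clamp15(4 + stats::rnorm(n_children, 0, 0.8))
  grade <- ifelse(age <= stats::median(age), "KG", "1")
  meta <- data.frame(child_id = truth$child_id, grade = grade,
                     age_months = as.integer(age),
                     math_score = as.integer(math),
                     language_score = as.integer(lang),
                     avg_past_score = round(stats::runif(n_children, 0.5, 3), 2),
                     stringsAsFactors = FALSE)

  out <- list(events = events, meta = meta, truth = truth, params = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(events, file.path(out_dir, "events.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(meta, file.path(out_dir, "meta.csv"),
                     row.names = FALSE, na = "")
    yaml::write_yaml(lapply(params, unclass),
                     file.path(out_dir, "scenario.yaml"))
  }
  out
}
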