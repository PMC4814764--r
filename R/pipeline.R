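#' Analysis configuration
#'
#' Bundles the tunable settings of the pipeline. The defaults reproduce the
#' canonical analysis: a +/-60 s delay window, line structures of at least
#' 2 s, 1000 Monte Carlo permutations, the episode-preserving permutation
#' null for the recurrence peak, and a 0.05 significance level for declaring
#' a child's delay peak interpretable.
#'
#' @param window_s LOS-profile half-window, seconds.
#' @param min_line Minimum line length for LAM/TT, seconds.
#' @param n_perm Permutations for every Monte Carlo test.
#' @param seed Base seed; per-child and per-test seeds are derived from it.
#' @param rr_peak_null `"episode_shuffle"` or `"second_shuffle"`.
#' @param alpha Significance level for the RR_peak screen: children whose
#'   peak does not beat chance have `tau_peak` reported missing.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(window_s = 60L, min_line = 2L, n_perm = 1000L,
                            seed = 1L,
                            rr_peak_null = c("episode_shuffle",
                                             "second_shuffle"),
                            alpha = 0.05) {
  structure(list(window_s = as.integer(window_s),
                 min_line = as.integer(min_line),
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 rr_peak_null = match.arg(rr_peak_null),
                 alpha = alpha),
            class = "analysis_config")
}

#' Analyze one child end-to-end
#'
#' Rasterizes both streams to a common duration, builds the tier-matched
#' cross-recurrence plot, and computes: global CRQA measures and asymmetry
#' scores, sensorimotor- and representational-tier restricted measures with
#' their asymmetry scores, the LOS profile and its leader-follower measures,
#' and the RR_peak permutation screen. `tau_peak` is reported missing when
#' the peak does not exceed chance at `config$alpha` — a delay only makes
#' sense if there is a real peak.
#'
#' @param events Events `data.frame` for one child (both streams).
#' @param config An [analysis_config()].
#' @param child_id Identifier; defaults to the one in `events`.
#' @param rr_peak_seed Seed for the RR_peak permutation test (derived from
#'   `config$seed` when `NULL`).
#' @return A list with `row` (one-row `data.frame` of all scalar measures),
#'   `crp`, `profile` and `series`. If one stream has no leveled events the
#'   row carries `NA` measures and a warning is logged.
#' @export
analyze_child <- function(events, config = analysis_config(),
                          child_id = NULL, rr_peak_seed = NULL) {
  if (is.null(child_id)) {
    child_id <- if (nrow(events) > 0) events$child_id[1] else "unknown"
  }
  series <- child_series(events)
  g <- series$gesture$tiers
  s <- series$speech$tiers
  if (all(g == 0) || all(s == 0)) {
    warning("child ", child_id, ": one stream has no leveled events; ",
            "emitting missing measures")
    na_row <- as.data.frame(as.list(stats::setNames(
      rep(NA_real_, length(measure_columns())), measure_columns())))
    return(list(row = cbind(data.frame(child_id = child_id,
                                       n_s = series$duration_s), na_row),
                crp = NULL, profile = NULL, series = series))
  }

  crp <- build_crp(g, s)
  glob <- crqa_measures(crp, config$min_line)
  asym <- asymmetry_scores(glob)
  s_m <- tier_measures(crp, 1L, config$min_line)
  s_a <- asymmetry_scores(s_m)
  r_m <- tier_measures(crp, 2L, config$min_line)
  r_a <- asymmetry_scores(r_m)

  window <- min(config$window_s, series$duration_s - 1L)
  profile <- los_profile(crp, window)
  lm <- los_measures(profile)
  if (is.null(rr_peak_seed)) rr_peak_seed <- config$seed + 7919L
  pk <- rr_peak_test(g, s, window, n_perm = config$n_perm,
                     seed = rr_peak_seed, null = config$rr_peak_null)
  tau_peak <- if (pk$p_value >= config$alpha) NA_integer_ else lm$tau_peak

  row <- data.frame(
    child_id = child_id, n_s = series$duration_s,
    pct_sync = lm$pct_sync, rr_peak = lm$rr_peak,
    rr_peak_p = pk$p_value, tau_peak = tau_peak, q_los = lm$q_los,
    rr = glob$rr, lam_v = glob$lam_v, lam_h = glob$lam_h,
    tt_v = glob$tt_v, tt_h = glob$tt_h,
    maxl_v = glob$maxl_v, maxl_h = glob$maxl_h,
    vh_lam = asym$vh_lam, vh_tt = asym$vh_tt, vh_maxl = asym$vh_maxl,
    s_pct_rr = s_m$pct_rr, s_lam_v = s_m$lam_v, s_lam_h = s_m$lam_h,
    s_tt_v = s_m$tt_v, s_tt_h = s_m$tt_h,
    s_maxl_v = s_m$maxl_v, s_maxl_h = s_m$maxl_h,
    s_vh_lam = s_a$vh_lam, s_vh_tt = s_a$vh_tt, s_vh_maxl = s_a$vh_maxl,
    r_pct_rr = r_m$pct_rr, r_lam_v = r_m$lam_v, r_lam_h = r_m$lam_h,
    r_tt_v = r_m$tt_v, r_tt_h = r_m$tt_h,
    r_maxl_v = r_m$maxl_v, r_maxl_h = r_m$maxl_h,
    r_vh_lam = r_a$vh_lam, r_vh_tt = r_a$vh_tt, r_vh_maxl = r_a$vh_maxl,
    stringsAsFactors = FALSE)
  list(row = row, crp = crp, profile = profile, series = series)
}

measure_columns <- function() {
  c("pct_sync", "rr_peak", "rr_peak_p", "tau_peak", "q_los",
    "rr", "lam_v", "lam_h", "tt_v", "tt_h", "maxl_v", "maxl_h",
    "vh_lam", "vh_tt", "vh_maxl",
    paste0("s_", c("pct_rr", "lam_v", "lam_h", "tt_v", "tt_h",
                   "maxl_v", "maxl_h", "vh_lam", "vh_tt", "vh_maxl")),
    paste0("r_", c("pct_rr", "lam_v", "lam_h", "tt_v", "tt_h",
                   "maxl_v", "maxl_h", "vh_lam", "vh_tt", "vh_maxl")))
}

#' Analyze a cohort and assemble the group-level report
#'
#' Runs [analyze_child()] for every child, then the group-level inference:
#'
#' * temporal relation: `Q_LOS` vs 1, `tau_peak` vs 0, and the KG vs
#'   grade-1 contrasts on both (with Cohen's d);
#' * anisotropy: paired vertical-vs-horizontal tests on LAM, TT and MaxL
#'   (directional: vertical expected higher) with Cohen's d;
#' * tiers: paired sensorimotor-vs-representational comparisons of every
#'   tier measure and asymmetry score, plus KG vs grade-1 contrasts within
#'   each tier;
#' * covariates: permutation correlations of age and the school/test scores
#'   with the LOS measures, tier measures and asymmetry scores.
#'
#' Group contrasts need at least two children per grade; otherwise they are
#' skipped with a warning. Children missing from `meta` are dropped from the
#' correlations only.
#'
#' @param events Events `data.frame` for the whole cohort.
#' @param meta Metadata `data.frame` (see [read_child_meta()]).
#' @param config An [analysis_config()].
#' @return A `cohort_report` list: `per_child`, `group_stats`,
#'   `correlations`, `group_means`, `children` (per-child crp/profile
#'   objects), `config`.
#' @export
analyze_cohort <- function(events, meta = NULL, config = analysis_config()) {
  ids <- sort(unique(events$child_id))
  children <- lapply(seq_along(ids), function(i) {
    analyze_child(events[events$child_id == ids[i], , drop = FALSE], config,
                  child_id = ids[i],
                  rr_peak_seed = config$seed * 1000L + i)
  })
  names(children) <- ids
  per_child <- do.call(rbind, lapply(children, `[[`, "row"))
  rownames(per_child) <- NULL
  if (!is.null(meta)) {
    per_child <- merge(meta[, c("child_id", "grade")], per_child,
                       by = "child_id", all.y = TRUE, sort = TRUE)
  } else {
    per_child <- cbind(data.frame(child_id = per_child$child_id,
                                  grade = NA_character_),
                       per_child[, -1, drop = FALSE])
  }

  seed0 <- config$seed
  np <- config$n_perm
  stats_rows <- list()
  k <- 0L
  add_stat <- function(name, test, d = NA_real_) {
    k <<- k + 1L
    stats_rows[[k]] <<- data.frame(
      comparison = name, observed = test$observed, p_value = test$p_value,
      d = d, n_perm = test$n_perm, sided = test$sided,
      seed = if (is.null(test$seed)) NA_integer_ else test$seed,
      stringsAsFactors = FALSE)
  }

  # temporal relation (Q_LOS, tau_peak)
  add_stat("q_los_vs_1",
           perm_test_vs_value(per_child$q_los, 1, "greater", np, seed0 + 11L))
  if (any(!is.na(per_child$tau_peak))) {
    add_stat("tau_peak_vs_0",
             perm_test_vs_value(per_child$tau_peak, 0, "greater", np,
                                seed0 + 12L))
  }
  grades <- per_child$grade
  two_per_grade <- !is.null(meta) &&
    all(table(factor(grades, levels = c("KG", "1"))) >= 2)
  if (two_per_grade) {
    kg <- grades == "KG"
    for (v in c("q_los", "tau_peak")) {
      a <- per_child[[v]][kg]; b <- per_child[[v]][!kg]
      if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2) {
        add_stat(paste0("kg_vs_1_", v),
                 perm_test_two_groups(a, b, "two", np, seed0 + 20L + nchar(v)),
                 d = cohens_d(a, b))
      }
    }
  } else if (!is.null(meta)) {
    warning("fewer than two children in a grade: grade contrasts skipped")
  }

  # anisotropy: vertical vs horizontal, directional
  for (v in c("lam", "tt", "maxl")) {
    x <- per_child[[paste0(v, "_v")]]
    y <- per_child[[paste0(v, "_h")]]
    add_stat(paste0(v, "_v_vs_h"),
             perm_test_paired(x, y, "greater", np, seed0 + 30L + nchar(v)),
             d = cohens_d(x, y))
  }

  # tiers: sensorimotor vs representational, and grade contrasts per tier
  tier_vars <- c("pct_rr", "lam_v", "lam_h", "tt_v", "tt_h",
                 "maxl_v", "maxl_h", "vh_lam", "vh_tt", "vh_maxl")
  for (v in tier_vars) {
    x <- per_child[[paste0("s_", v)]]
    y <- per_child[[paste0("r_", v)]]
    add_stat(paste0("s_vs_r_", v),
             perm_test_paired(x, y, "two", np, seed0 + 40L + match(v, tier_vars)),
             d = cohens_d(x, y))
  }
  if (two_per_grade) {
    kg <- grades == "KG"
    for (tier in c("s", "r")) {
      for (v in tier_vars) {
        col <- paste0(tier, "_", v)
        a <- per_child[[col]][kg]; b <- per_child[[col]][!kg]
        if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2) {
          add_stat(paste0("kg_vs_1_", col),
                   perm_test_two_groups(a, b, "two", np,
                                        seed0 + 60L + match(v, tier_vars) +
                                          ifelse(tier == "s", 0L, 100L)),
                   d = cohens_d(a, b))
        }
      }
    }
  }
  group_stats <- do.call(rbind, stats_rows)

  # covariate correlations
  correlations <- NULL
  if (!is.null(meta)) {
    covars <- c("age_months", "math_score", "language_score", "avg_past_score")
    meas <- c("pct_sync", "rr_peak", "tau_peak", "q_los",
              paste0("s_", tier_vars), paste0("r_", tier_vars))
    merged <- merge(per_child, meta, by = "child_id")
    rows <- list()
    ci <- 0L
    for (m in meas) {
      for (cv in covars) {
        x <- merged[[cv]]; y <- merged[[m]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 3 || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) next
        ci <- ci + 1L
        ct <- perm_cor(x, y, np, seed0 + 200L + ci)
        rows[[ci]] <- data.frame(measure = m, covariate = cv, r = ct$r,
                                 n = ct$n, p_value = ct$p_value,
                                 stars = ct$stars, stringsAsFactors = FALSE)
      }
    }
    correlations <- do.call(rbind, rows)
  }

  # mean rows per grade and overall, recomputed from the per-child columns
  num_cols <- setdiff(names(per_child), c("child_id", "grade"))
  mean_row <- function(rows, label) {
    m <- vapply(num_cols, function(cn) mean(rows[[cn]], na.rm = TRUE),
                numeric(1))
    cbind(data.frame(child_id = "mean", grade = label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(m)))
  }
  group_means <- rbind(
    if (two_per_grade) mean_row(per_child[grades == "KG", ], "KG"),
    if (two_per_grade) mean_row(per_child[grades == "1", ], "1"),
    mean_row(per_child, "overall"))

  structure(list(per_child = per_child, group_stats = group_stats,
                 correlations = correlations, group_means = group_means,
                 children = children, config = config),
            class = "cohort_report")
}

# table rounding conventions: proportions 3 dp, percentages and TT 1 dp,
# MaxL whole seconds, Q_LOS and asymmetry scores 2 dp
round_report <- function(df) {
  rules <- list(
    `3` = c("rr_peak", "rr", "lam_v", "lam_h", "s_lam_v", "s_lam_h",
            "r_lam_v", "r_lam_h", "rr_peak_p", "vh_lam", "s_vh_lam",
            "r_vh_lam"),
    `1` = c("pct_sync", "tt_v", "tt_h", "s_tt_v", "s_tt_h", "r_tt_v",
            "r_tt_h", "s_pct_rr", "r_pct_rr"),
    `0` = c("maxl_v", "maxl_h", "s_maxl_v", "s_maxl_h", "r_maxl_v",
            "r_maxl_h"),
    `2` = c("q_los", "vh_tt", "vh_maxl", "s_vh_tt", "s_vh_maxl",
            "r_vh_tt", "r_vh_maxl"))
  for (dp in names(rules)) {
    for (cn in intersect(rules[[dp]], names(df))) {
      df[[cn]] <- round(df[[cn]], as.integer(dp))
    }
  }
  df
}

#' Write a cohort report to disk
#'
#' Emits `per_child.csv` (with per-grade and overall mean rows, rounded to
#' the reporting conventions), `per_child_full.json` (full precision),
#' `tier_S.csv` / `tier_R.csv`, `group_stats.json`, `correlations.csv`,
#' `profiles/<child>.csv`, `crp/<child>.csv` and `config.yaml`.
#'
#' @param report An [analyze_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @param crp_sparse Write plots as sparse triplets rather than dense
#'   matrices.
#' @return `out_dir`, invisibly.
#' @export
write_cohort_report <- function(report, out_dir, crp_sparse = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pc <- rbind(report$per_child, report$group_means)
  utils::write.csv(round_report(pc), file.path(out_dir, "per_child.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(report$per_child,
                       file.path(out_dir, "per_child_full.json"),
                       dataframe = "rows", na = "null", digits = NA)
  for (tier in c(S = "s", R = "r")) {
    cols <- c("child_id", "grade",
              grep(paste0("^", tier, "_"), names(report$per_child),
                   value = TRUE))
    nm <- if (tier == "s") "tier_S.csv" else "tier_R.csv"
    utils::write.csv(round_report(report$per_child[, cols]),
                     file.path(out_dir, nm), row.names = FALSE, na = "")
  }
  jsonlite::write_json(report$group_stats,
                       file.path(out_dir, "group_stats.json"),
                       dataframe = "rows", na = "null", digits = NA)
  if (!is.null(report$correlations)) {
    utils::write.csv(report$correlations,
                     file.path(out_dir, "correlations.csv"),
                     row.names = FALSE, na = "")
  }
  dir.create(file.path(out_dir, "profiles"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "crp"), showWarnings = FALSE)
  for (id in names(report$children)) {
    ch <- report$children[[id]]
    if (!is.null(ch$profile)) {
      write_profile(ch$profile,
                    file.path(out_dir, "profiles", paste0(id, ".csv")))
    }
    if (!is.null(ch$crp)) {
      write_crp(ch$crp, file.path(out_dir, "crp", paste0(id, ".csv")),
                sparse = crp_sparse)
    }
  }
  yaml::write_yaml(unclass(report$config), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Bundled reference cohort tables
#'
#' Returns the published per-child measure tables for the original 12-child
#' cohort (five kindergartners, seven first-graders), shipped with the
#' package as plain CSV: child characteristics, the whole-plot LOS/CRQA
#' measures, and the sensorimotor- and representational-tier restricted
#' measures. These support worked examples and recomposition checks (group
#' means, asymmetry scores and correlations recomputed from the printed
#' per-child values).
#'
#' @param table One of `"children"`, `"global"`, `"sensorimotor"`,
#'   `"representational"`.
#' @return A `data.frame`.
#' @export
reference_cohort <- function(table = c("children", "global", "sensorimotor",
                                       "representational")) {
  table <- match.arg(table)
  file <- c(children = "children.csv", global = "measures_global.csv",
            sensorimotor = "measures_sensorimotor.csv",
            representational = "measures_representational.csv")[[table]]
  path <- system.file("extdata", "reference", file, package = "attune")
  if (path == "") stop("reference table not found; is the package installed?")
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(child_id = "character", grade = "character"))
}
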