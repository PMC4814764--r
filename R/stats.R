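# Monte Carlo permutation inference. All tests use the mean difference (not
# a t statistic) as the test statistic and the add-one corrected p-value
# (1 + #extreme) / (1 + n_perm), so p is always in (0, 1] and never exactly 0
# at finite n_perm. Every function is reproducible given (seed, n_perm).

perm_p <- function(null_stats, observed, sided) {
  n <- length(null_stats)
  extreme <- switch(sided,
                    greater = sum(null_stats >= observed),
                    less = sum(null_stats <= observed),
                    two = sum(abs(null_stats) >= abs(observed)),
                    stop("sided must be 'greater', 'less' or 'two'"))
  (1 + extreme) / (1 + n)
}

#' Two-group Monte Carlo permutation test
#'
#' Statistic: `mean(a) - mean(b)`. The null redistributes the pooled values
#' over the two group labels at random, `n_perm` times.
#'
#' @param a,b Numeric vectors (both nonempty; `NA`s dropped).
#' @param sided `"greater"`, `"less"` or `"two"`.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for reproducibility.
#' @return A `perm_test` list: `observed`, `p_value`, `n_perm`, `sided`,
#'   `seed`.
#' @export
perm_test_two_groups <- function(a, b, sided = c("two", "greater", "less"),
                                 n_perm = 1000L, seed = NULL) {
  sided <- match.arg(sided)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  na <- length(a)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), na)
    mean(pool[idx]) - mean(pool[-idx])
  }, numeric(1))
  structure(list(observed = obs, p_value = perm_p(null_stats, obs, sided),
                 n_perm = as.integer(n_perm), sided = sided, seed = seed),
            class = "perm_test")
}

#' Paired Monte Carlo permutation test
#'
#' Statistic: the mean within-pair difference `mean(x - y)`. The null flips
#' the sign of each pair's difference independently with probability 1/2
#' (i.e. swaps the two members of random pairs).
#'
#' @param x,y Paired numeric vectors of equal length (pairs with an `NA`
#'   are dropped).
#' @inheritParams perm_test_two_groups
#' @return A `perm_test` list.
#' @export
perm_test_paired <- function(x, y, sided = c("two", "greater", "less"),
                             n_perm = 1000L, seed = NULL) {
  sided <- match.arg(sided)
  if (length(x) != length(y)) stop("paired vectors differ in length")
  d <- x - y
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("no complete pairs")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(d)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    mean(d * sample(c(-1, 1), length(d), replace = TRUE))
  }, numeric(1))
  structure(list(observed = obs, p_value = perm_p(null_stats, obs, sided),
                 n_perm = as.integer(n_perm), sided = sided, seed = seed),
            class = "perm_test")
}

#' One-sample Monte Carlo permutation test against a reference value
#'
#' Statistic: `mean(x) - ref`. The null flips the signs of the centered
#' deviations `x - ref` at random.
#'
#' @param x Numeric vector (`NA`s dropped).
#' @param ref Reference value.
#' @inheritParams perm_test_two_groups
#' @return A `perm_test` list.
#' @export
perm_test_vs_value <- function(x, ref, sided = c("two", "greater", "less"),
                               n_perm = 1000L, seed = NULL) {
  sided <- match.arg(sided)
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("x must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  dev <- x - ref
  obs <- mean(dev)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    mean(dev * sample(c(-1, 1), length(dev), replace = TRUE))
  }, numeric(1))
  structure(list(observed = obs, p_value = perm_p(null_stats, obs, sided),
                 n_perm = as.integer(n_perm), sided = sided, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Monte Carlo permutation test (%s, %d permutations)\n",
              x$sided, x$n_perm))
  cat(sprintf("  observed = %g, p = %.4g\n", x$observed, x$p_value))
  invisible(x)
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(a) - mean(b)) / s_pooled`, with
#' `s_pooled = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#' As a rule of thumb, d around 0.2 is small, 0.5 medium, 0.8+ large.
#'
#' @param a,b Numeric vectors with at least two values each (`NA`s dropped).
#' @return The effect size, or `NA` when the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  if (sp == 0) return(NA_real_)
  (mean(a) - mean(b)) / sp
}

#' Pearson correlation with permutation significance
#'
#' Pearson r on complete pairs (pairwise deletion of missing values), with a
#' two-sided permutation p-value obtained by shuffling `y`, and significance
#' stars at p < 0.05 (`*`) and p < 0.01 (`**`).
#'
#' @param x,y Numeric vectors of equal length.
#' @inheritParams perm_test_two_groups
#' @return A `cor_test` list: `r`, `n` (complete pairs), `p_value`, `stars`,
#'   `n_perm`, `seed`.
#' @export
perm_cor <- function(x, y, n_perm = 1000L, seed = NULL) {
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (!is.null(seed)) set.seed(seed)
  r <- stats::cor(x, y)
  null_r <- vapply(seq_len(n_perm), function(i) stats::cor(x, sample(y)),
                   numeric(1))
  p <- perm_p(null_r, r, "two")
  structure(list(r = r, n = length(x), p_value = p,
                 stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
                 n_perm = as.integer(n_perm), seed = seed),
            class = "cor_test")
}

#' @export
print.cor_test <- function(x, ...) {
  cat(sprintf("r = %.2f%s (n = %d, permutation p = %.4g)\n",
              x$r, x$stars, x$n, x$p_value))
  invisible(x)
}

#' Permutation test of inter-rater agreement
#'
#' The observed statistic is the percentage of positions at which the two
#' label sequences agree. The null shuffles the order of one sequence
#' `n_perm` times, so agreement under a random ordering of the same codes is
#' the reference distribution.
#'
#' @param codes_a,codes_b Equal-length label vectors.
#' @inheritParams perm_test_two_groups
#' @return A `perm_test` list (`observed` is the agreement percentage).
#' @export
agreement_perm_test <- function(codes_a, codes_b, n_perm = 1000L,
                                seed = NULL) {
  if (length(codes_a) != length(codes_b)) {
    stop("code sequences differ in length")
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- 100 * mean(codes_a == codes_b)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    100 * mean(codes_a == sample(codes_b))
  }, numeric(1))
  structure(list(observed = obs, p_value = perm_p(null_stats, obs, "greater"),
                 n_perm = as.integer(n_perm), sided = "greater", seed = seed),
            class = "perm_test")
}
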