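# ---------------------------------------------------------------------------
# Summary-measure approach (SMA): reduce each subject's profile to a single
# number (least-squares slope for within-subject effects, mean over time for
# the between-subject effect) and apply standard univariate tests.
# ---------------------------------------------------------------------------

#' Test-result container
#'
#' Uniform container returned by every hypothesis test in the package.
#'
#' @param effect one of `"time"`, `"group"`, `"interaction"`.
#' @param method label of the analysis route (e.g. `"sma-t"`, `"uma-wilks"`).
#' @param statistic_name label of the test statistic.
#' @param statistic observed statistic value.
#' @param df_num numerator (or only) degrees of freedom; may be `NA`.
#' @param df_den denominator degrees of freedom; may be `NA`.
#' @param p_value two-sided p-value in \[0, 1\].
#' @param alpha significance level used for the `reject` flag.
#' @return An object of class `trend_test`.
#' @export
trend_test <- function(effect, method, statistic_name, statistic,
                       df_num = NA_real_, df_den = NA_real_,
                       p_value, alpha = 0.05) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(effect = effect, method = method,
                 statistic_name = statistic_name,
                 statistic = as.numeric(statistic),
                 df_num = as.numeric(df_num), df_den = as.numeric(df_den),
                 p_value = as.numeric(p_value), alpha = alpha,
                 reject = p_value <= alpha),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  df <- if (is.na(x$df_den)) sprintf("df = %g", x$df_num)
        else sprintf("df = (%g, %g)", x$df_num, x$df_den)
  cat(sprintf("%s effect [%s]: %s = %.4f, %s, p = %.4g (%s at alpha = %g)\n",
              x$effect, x$method, x$statistic_name, x$statistic, df,
              x$p_value, if (x$reject) "reject" else "retain", x$alpha))
  invisible(x)
}

#' @export
as.data.frame.trend_test <- function(x, ...) {
  data.frame(effect = x$effect, method = x$method,
             statistic_name = x$statistic_name, statistic = x$statistic,
             df_num = x$df_num, df_den = x$df_den, p_value = x$p_value,
             alpha = x$alpha, reject = x$reject, stringsAsFactors = FALSE)
}

#' Per-subject least-squares slope
#'
#' Ordinary least-squares slope of response on time,
#' \eqn{\sum (t - \bar t)(y - \bar y) / \sum (t - \bar t)^2}. For a subject
#' whose profile is linear or at least monotone this summarises the rate of
#' change over time.
#'
#' @param times,responses numeric vectors of equal length; at least two
#'   distinct times are required.
#' @return The slope, in response units per time unit.
#' @examples
#' subject_slope(c(2, 4, 6), c(1, 2, 4)) # 0.75
#' @export
subject_slope <- function(times, responses) {
  if (length(times) != length(responses))
    stop("times and responses must have equal length", call. = FALSE)
  if (length(unique(times)) < 2)
    stop("slope undefined: fewer than two distinct time values", call. = FALSE)
  tc <- times - mean(times)
  sum(tc * (responses - mean(responses))) / sum(tc^2)
}

#' Per-subject mean response
#'
#' @param responses numeric vector with at least one value.
#' @return The arithmetic mean, used as the between-subject summary measure.
#' @export
subject_mean <- function(responses) {
  if (!length(responses)) stop("mean undefined: no responses", call. = FALSE)
  mean(responses)
}

#' Summarise every subject by slope and mean
#'
#' @param ds an [rm_data] dataset.
#' @return A `data.frame` with one row per subject: `subject`, `group`,
#'   `slope` (`NA` when the subject has fewer than two distinct times, flagged
#'   via `slope_defined`), `mean` and `n_points`.
#' @export
summarize_subjects <- function(ds) {
  stopifnot(inherits(ds, "rm_data"))
  subs <- unique(ds[c("subject", "group")])
  idx <- split(seq_len(nrow(ds)), factor(ds$subject, levels = subs$subject))
  res <- lapply(idx, function(ix) {
    tt <- ds$time[ix]; yy <- ds$response[ix]
    ok <- length(unique(tt)) >= 2
    c(slope = if (ok) subject_slope(tt, yy) else NA_real_,
      mean = subject_mean(yy), n_points = length(ix), slope_defined = ok)
  })
  res <- do.call(rbind, res)
  out <- data.frame(subject = subs$subject, group = subs$group,
                    slope = res[, "slope"], mean = res[, "mean"],
                    n_points = as.integer(res[, "n_points"]),
                    slope_defined = as.logical(res[, "slope_defined"]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (any(!out$slope_defined))
    warning(sum(!out$slope_defined),
            " subject(s) with undefined slope (single time point)", call. = FALSE)
  out
}

summaries_of <- function(x) {
  if (inherits(x, "rm_data")) suppressWarnings(summarize_subjects(x)) else x
}

#' SMA time-effect test
#'
#' One-sample t test of the per-subject least-squares slopes against zero,
#' pooled over all groups. Under no time effect the population mean slope is
#' zero.
#'
#' @param x an [rm_data] dataset or the output of [summarize_subjects()].
#' @param alpha significance level.
#' @return A [trend_test()].
#' @export
sma_time_test <- function(x, alpha = 0.05) {
  s <- summaries_of(x)
  sl <- s$slope[s$slope_defined]
  if (length(sl) < 2)
    stop("time test needs at least two subjects with defined slopes", call. = FALSE)
  if (var(sl) == 0)
    stop("degenerate test: zero variance of subject slopes", call. = FALSE)
  tt <- t.test(sl, mu = 0)
  trend_test("time", "sma-t", "t", tt$statistic, df_num = tt$parameter,
             p_value = tt$p.value, alpha = alpha)
}

# Shared engine for the SMA interaction (slopes) and group (means) tests:
# ordinary k-sample tests on the per-subject summary values.
k_sample_test <- function(values, groups, effect, variant, alpha,
                          perm_reps = 9999, seed = NULL) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2)
    stop("k-sample test needs at least two groups", call. = FALSE)
  variant <- match.arg(variant, c("t", "anova", "wilcoxon", "kruskal",
                                  "permutation"))
  if (variant %in% c("t", "wilcoxon") && k != 2)
    stop("variant '", variant, "' requires exactly two groups", call. = FALSE)
  if (variant %in% c("t", "anova")) {
    if (any(tapply(values, groups, length) < 2))
      stop("parametric variants need at least two summaries per group",
           call. = FALSE)
    if (sum(tapply(values, groups, var)) == 0)
      stop("degenerate test: zero pooled variance", call. = FALSE)
  }
  method <- paste0("sma-", variant)
  switch(variant,
    t = {
      sp <- split(values, groups)
      tt <- t.test(sp[[1]], sp[[2]], var.equal = TRUE)
      trend_test(effect, method, "t", tt$statistic, df_num = tt$parameter,
                 p_value = tt$p.value, alpha = alpha)
    },
    anova = {
      a <- anova(lm(values ~ groups))
      trend_test(effect, method, "F", a$`F value`[1], df_num = a$Df[1],
                 df_den = a$Df[2], p_value = a$`Pr(>F)`[1], alpha = alpha)
    },
    wilcoxon = {
      sp <- split(values, groups)
      wt <- suppressWarnings(wilcox.test(sp[[1]], sp[[2]], exact = FALSE,
                                         correct = FALSE))
      trend_test(effect, method, "W", wt$statistic, p_value = wt$p.value,
                 alpha = alpha)
    },
    kruskal = {
      kt <- kruskal.test(values, groups)
      trend_test(effect, method, "chi-squared", kt$statistic,
                 df_num = kt$parameter, p_value = kt$p.value, alpha = alpha)
    },
    permutation = permutation_test(values, groups, effect, alpha,
                                   perm_reps, seed)
  )
}

# Permutation test on the summary values: the group labels are permuted and
# the corresponding parametric statistic recomputed. For two groups the
# statistic is |pooled t| (equivalently, the group-1 sum of values, which is a
# monotone surrogate at fixed margins); for k > 2 it is the one-way F. When
# the number of distinct label assignments does not exceed perm_reps (two
# groups only) all assignments are enumerated and the exact conditional
# p-value is returned; otherwise perm_reps random permutations are drawn and
# p = (1 + #{|T*| >= |T|}) / (1 + B).
permutation_test <- function(values, groups, effect, alpha, perm_reps, seed) {
  if (perm_reps < 1) stop("perm_reps must be >= 1", call. = FALSE)
  groups <- factor(groups)
  k <- nlevels(groups)
  stat_fun <- if (k == 2) {
    g1 <- levels(groups)[1]
    function(g) {
      sp <- split(values, g)
      abs(pooled_t(sp[[1]], sp[[2]]))
    }
  } else {
    function(g) anova(lm(values ~ g))$`F value`[1]
  }
  obs <- stat_fun(groups)
  n <- length(values)
  n1 <- sum(groups == levels(groups)[1])
  n_assign <- if (k == 2) choose(n, n1) else Inf
  eps <- 1e-12
  if (k == 2 && n_assign <= perm_reps) {
    combs <- combn(n, n1)
    stats <- apply(combs, 2, function(ix) {
      g <- factor(replace(rep(levels(groups)[2], n), ix, levels(groups)[1]),
                  levels = levels(groups))
      stat_fun(g)
    })
    p <- mean(stats >= obs - eps)
    b <- ncol(combs)
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats <- vapply(seq_len(perm_reps),
                    function(i) stat_fun(sample(groups)), numeric(1))
    p <- (1 + sum(stats >= obs - eps)) / (1 + perm_reps)
    b <- perm_reps
  }
  out <- trend_test(effect, "sma-permutation",
                    if (k == 2) "|t|" else "F", obs, p_value = p,
                    alpha = alpha)
  out$n_permutations <- b
  out
}

pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) stop("degenerate test: zero pooled variance", call. = FALSE)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

#' SMA interaction-effect test
#'
#' Compares the distribution of per-subject slopes across groups: under no
#' group-by-time interaction, group slope distributions share a common mean.
#' Variants: pooled-variance Student's t (`"t"`, two groups), one-way ANOVA F
#' (`"anova"`), Wilcoxon-Mann-Whitney with midranks and normal approximation
#' (`"wilcoxon"`, two groups), Kruskal-Wallis (`"kruskal"`), and a label
#' permutation test (`"permutation"`).
#'
#' @inheritParams sma_time_test
#' @param variant which k-sample test to apply to the slopes.
#' @param perm_reps number of random permutations (permutation variant); when
#'   two groups admit at most `perm_reps` distinct assignments the exact
#'   enumeration p-value is returned instead.
#' @param seed optional integer seed for the sampled permutation variant.
#' @return A [trend_test()].
#' @export
sma_interaction_test <- function(x, variant = c("t", "anova", "wilcoxon",
                                                "kruskal", "permutation"),
                                 alpha = 0.05, perm_reps = 9999, seed = NULL) {
  s <- summaries_of(x)
  s <- s[s$slope_defined, , drop = FALSE]
  k_sample_test(s$slope, s$group, "interaction", match.arg(variant), alpha,
                perm_reps, seed)
}

#' SMA group-effect test
#'
#' Compares per-subject mean responses (over time) across groups with the
#' same k-sample machinery as [sma_interaction_test()].
#'
#' @inheritParams sma_interaction_test
#' @return A [trend_test()].
#' @export
sma_group_test <- function(x, variant = c("t", "anova", "wilcoxon", "kruskal",
                                          "permutation"),
                           alpha = 0.05, perm_reps = 9999, seed = NULL) {
  s <- summaries_of(x)
  k_sample_test(s$mean, s$group, "group", match.arg(variant), alpha,
                perm_reps, seed)
}
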