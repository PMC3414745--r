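# ---------------------------------------------------------------------------
# Unstructured multivariate approach (UMA, profile analysis): treats the m
# time points as an unordered multivariate response with a common arbitrary
# covariance. Parallelism (interaction) is a one-way MANOVA on contrast-
# transformed responses; the time effect is a one-sample Hotelling T^2 on the
# adjacent differences; the group effect delegates to the SMA mean test.
# ---------------------------------------------------------------------------

#' Adjacent-difference contrast matrix
#'
#' Builds the (m-1) x m matrix whose rows take differences between adjacent
#' measurements: row j has -1 in column j and +1 in column j+1. Any full-rank
#' contrast matrix whose rows sum to zero yields identical test results; the
#' adjacent-difference form is the conventional default.
#'
#' @param m number of time points, at least 2.
#' @return An (m-1) x m numeric matrix of rank m-1 with zero row sums.
#' @export
adjacent_contrast <- function(m) {
  if (m < 2) stop("contrast matrix requires m >= 2 time points", call. = FALSE)
  C <- matrix(0, m - 1, m)
  C[cbind(seq_len(m - 1), seq_len(m - 1))] <- -1
  C[cbind(seq_len(m - 1), seq_len(m - 1) + 1)] <- 1
  C
}

check_contrast <- function(C, m) {
  if (is.null(C)) return(adjacent_contrast(m))
  C <- as.matrix(C)
  if (ncol(C) != m || nrow(C) != m - 1)
    stop("contrast matrix must be (m-1) x m", call. = FALSE)
  if (max(abs(rowSums(C))) > 1e-10)
    stop("contrast rows must sum to zero", call. = FALSE)
  if (qr(C)$rank != m - 1)
    stop("contrast matrix must have rank m-1", call. = FALSE)
  C
}

as_wide_of <- function(x) if (inherits(x, "rm_wide")) x else as_wide(x)

#' UMA parallelism (group-by-time interaction) test
#'
#' Profile-analysis test that the k group mean profiles are parallel, i.e.
#' that the contrast-transformed mean vectors coincide across groups. The
#' m-1 transformed variables enter a one-way MANOVA; Wilks' lambda
#' \eqn{\Lambda = \det(E)/\det(E + H)} is converted to an F statistic by
#' Rao's approximation (exact for k = 2, where the test coincides with a
#' two-sample Hotelling T-squared, or for m - 1 <= 2).
#'
#' Requires balanced complete data with N - k > m - 1 so that the pooled
#' covariance of the transformed responses is nonsingular.
#'
#' @param x an [rm_data] dataset (balanced, complete) or an `rm_wide` object.
#' @param alpha significance level.
#' @param contrast optional (m-1) x m contrast matrix with zero row sums;
#'   results are invariant to this choice.
#' @return A [trend_test()] carrying the Wilks lambda in `$wilks`.
#' @export
uma_parallelism_test <- function(x, alpha = 0.05, contrast = NULL) {
  w <- as_wide_of(x)
  m <- length(w$times)
  N <- nrow(w$values)
  groups <- factor(w$groups)
  k <- nlevels(groups)
  if (k < 2) stop("parallelism test requires at least two groups", call. = FALSE)
  if (N - k <= m - 1)
    stop("infeasible: N - k must exceed m - 1 for a nonsingular covariance ",
         "of the transformed responses (N = ", N, ", k = ", k, ", m = ", m, ")",
         call. = FALSE)
  C <- check_contrast(contrast, m)
  D <- w$values %*% t(C)              # N x (m-1) transformed responses
  p <- m - 1
  gm <- rowsum(D, groups) / as.vector(table(groups))
  overall <- colMeans(D)
  E <- matrix(0, p, p)
  H <- matrix(0, p, p)
  for (g in levels(groups)) {
    Dg <- D[groups == g, , drop = FALSE]
    cg <- sweep(Dg, 2, gm[g, ])
    E <- E + crossprod(cg)
    H <- H + nrow(Dg) * tcrossprod(gm[g, ] - overall)
  }
  detE <- det(E)
  if (!is.finite(detE) || detE <= 0)
    stop("singular within-group cross-product matrix", call. = FALSE)
  lambda <- detE / det(E + H)
  # Rao's F approximation for Wilks' lambda
  vh <- k - 1
  ve <- N - k
  tpar <- if (p^2 + vh^2 - 5 > 0) sqrt((p^2 * vh^2 - 4) / (p^2 + vh^2 - 5)) else 1
  wpar <- ve + vh - (p + vh + 1) / 2
  df1 <- p * vh
  df2 <- wpar * tpar - (p * vh - 2) / 2
  lam_t <- lambda^(1 / tpar)
  Fstat <- (1 - lam_t) / lam_t * df2 / df1
  pval <- pf(Fstat, df1, df2, lower.tail = FALSE)
  out <- trend_test("interaction", "uma-wilks", "F", Fstat, df_num = df1,
                    df_den = df2, p_value = pval, alpha = alpha)
  out$wilks <- lambda
  out
}

#' UMA time-effect test (one-sample Hotelling's T-squared)
#'
#' Tests whether the m elements of the overall mean vector are equal by
#' applying a one-sample Hotelling T-squared test to the m-1 contrast-
#' transformed responses (adjacent differences by default) pooled over all
#' subjects: \eqn{T^2 = N \bar d' S^{-1} \bar d} with S the sample covariance
#' of the differences, converted to F with degrees of freedom
#' (m-1, N-m+1).
#'
#' @inheritParams uma_parallelism_test
#' @return A [trend_test()] carrying the T-squared value in `$t_squared`.
#' @export
uma_time_test <- function(x, alpha = 0.05, contrast = NULL) {
  w <- as_wide_of(x)
  m <- length(w$times)
  N <- nrow(w$values)
  if (N <= m)
    stop("infeasible: need more subjects (", N, ") than time points (", m,
         ") for a stable covariance of the differences", call. = FALSE)
  C <- check_contrast(contrast, m)
  D <- w$values %*% t(C)
  dbar <- colMeans(D)
  S <- cov(D)
  qr_S <- qr(S)
  if (qr_S$rank < m - 1) {
    if (max(abs(D)) < 1e-12) {
      # all profiles flat: no evidence against equal means
      return(trend_test("time", "uma-hotelling", "F", 0, df_num = m - 1,
                        df_den = N - m + 1, p_value = 1, alpha = alpha))
    }
    stop("singular covariance matrix of the transformed responses", call. = FALSE)
  }
  T2 <- N * sum(dbar * solve(qr_S, dbar))
  Fstat <- (N - m + 1) / ((N - 1) * (m - 1)) * T2
  pval <- pf(Fstat, m - 1, N - m + 1, lower.tail = FALSE)
  out <- trend_test("time", "uma-hotelling", "F", Fstat, df_num = m - 1,
                    df_den = N - m + 1, p_value = pval, alpha = alpha)
  out$t_squared <- T2
  out
}

#' UMA group-effect test
#'
#' The multivariate route uses the same strategy as the summary-measure
#' approach for the between-subject comparison: a k-sample test on the
#' per-subject means over time, which is typically more efficient than a
#' MANOVA comparison of the full mean vectors. Delegates to [sma_group_test()].
#'
#' @inheritParams sma_group_test
#' @return A [trend_test()] with method label `"uma-group(sma)"`.
#' @export
uma_group_test <- function(x, variant = c("t", "anova", "wilcoxon", "kruskal",
                                          "permutation"),
                           alpha = 0.05, perm_reps = 9999, seed = NULL) {
  out <- sma_group_test(x, variant = variant, alpha = alpha,
                        perm_reps = perm_reps, seed = seed)
  out$method <- paste0("uma-group(", out$method, ")")
  out
}
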