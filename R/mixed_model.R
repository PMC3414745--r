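# ---------------------------------------------------------------------------
# Linear mixed models: Y_i = X_i beta + Z_i b_i + e_i with a random intercept
# (optionally intercept + slope) and IND / AR(1) / unstructured within-subject
# error covariance, estimated by REML through nlme::lme. Wald F tests use the
# inner-outer denominator degrees of freedom: between-subject terms are tested
# against subject-level df, within-subject terms against observation-level df.
# ---------------------------------------------------------------------------

lmm_structures <- c("ind", "ar1", "uns")
lmm_randoms <- c("intercept", "intercept-slope")

lmm_failure <- function(random, structure, msg) {
  out <- list(converged = FALSE, random = random, structure = structure,
              message = msg)
  class(out) <- "lmm_fit"
  out
}

# Model frame shared by lmm_fit and lmm_design: group as factor with the
# reference level first (lexicographic unless ref_level is given), time
# numeric, plus the position index of each time on the shared grid (used by
# the AR(1) and unstructured correlation structures).
lmm_frame <- function(ds, ref_level = NULL) {
  stopifnot(inherits(ds, "rm_data"))
  levs <- sort(unique(ds$group))
  if (!is.null(ref_level)) {
    if (!ref_level %in% levs) stop("unknown reference level: ", ref_level,
                                   call. = FALSE)
    levs <- c(ref_level, setdiff(levs, ref_level))
  }
  data.frame(subject = factor(ds$subject, levels = unique(ds$subject)),
             group = factor(ds$group, levels = levs),
             time = ds$time,
             time_idx = match(ds$time, sort(unique(ds$time))))
}

#' Per-subject design matrices of the linear-trend mixed model
#'
#' Exposes the fixed- and random-effects design matrices implied by the model
#' `response ~ group * time`: for k groups the fixed part has an intercept,
#' k-1 group indicators (reference = first level), the numeric time value and
#' the k-1 interaction columns. The random part is a column of ones
#' (intercept) or ones plus time (intercept and slope).
#'
#' @param ds an [rm_data] dataset.
#' @param random `"intercept"` or `"intercept-slope"`.
#' @param ref_level optional group reference level (default: first
#'   lexicographically).
#' @return A named list per subject, each element holding matrices `X` and `Z`
#'   whose rows follow the subject's observed times.
#' @export
lmm_design <- function(ds, random = c("intercept", "intercept-slope"),
                       ref_level = NULL) {
  random <- match.arg(random)
  fr <- lmm_frame(ds, ref_level)
  X <- model.matrix(~ group * time, fr)
  Z <- if (random == "intercept") cbind(`(Intercept)` = rep(1, nrow(fr)))
       else cbind(`(Intercept)` = 1, time = fr$time)
  lapply(split(seq_len(nrow(fr)), fr$subject), function(ix) {
    list(X = X[ix, , drop = FALSE], Z = Z[ix, , drop = FALSE])
  })
}

#' Fit a linear-trend mixed model by REML
#'
#' Fits `response ~ group * time` with a subject-level random intercept (or
#' random intercept and slope with unstructured 2 x 2 covariance) and one of
#' three within-subject error covariance structures:
#' \describe{
#'   \item{`"ind"`}{independent errors, \eqn{R_i = \sigma^2 I}. With a random
#'     intercept this implies compound symmetry of the marginal covariance.}
#'   \item{`"ar1"`}{first-order autoregressive on the time-grid position,
#'     \eqn{R_i = \sigma^2 [\rho^{|j-j'|}]}.}
#'   \item{`"uns"`}{unstructured: a general correlation matrix with
#'     heterogeneous variances, indexed by position on the shared time grid;
#'     requires enough complete subjects to identify its m(m+1)/2 parameters.}
#' }
#' Estimation is restricted maximum likelihood via [nlme::lme()], the
#' estimator whose F statistics the inner-outer degrees-of-freedom rule
#' accompanies.
#'
#' @param ds an [rm_data] dataset.
#' @param random random-effects structure, `"intercept"` or
#'   `"intercept-slope"`.
#' @param structure error covariance structure, `"ind"`, `"ar1"` or `"uns"`.
#' @param ref_level optional group reference level.
#' @param alpha significance level forwarded to the F tests.
#' @return An object of class `lmm_fit`: a list with the fitted `lme` object
#'   (`$fit`), fixed-effect estimates (`$beta`), variance components (`$vc`:
#'   random-effects covariance `G`, residual SD `sigma`, structure
#'   parameters), `$reml_loglik`, parameter count `$d`, `$aic`, `$bic`,
#'   `$f_tests` (see [lmm_f_tests()]), `$converged` and the structure labels.
#' @export
lmm_fit <- function(ds, random = c("intercept", "intercept-slope"),
                    structure = c("ind", "ar1", "uns"), ref_level = NULL,
                    alpha = 0.05) {
  random <- match.arg(random)
  structure <- match.arg(structure)
  fr <- lmm_frame(ds, ref_level)
  fr$response <- ds$response
  k <- nlevels(fr$group)
  fixed <- if (k >= 2) response ~ group * time else response ~ time
  m <- length(unique(fr$time_idx))
  if (structure == "uns") {
    cnt <- table(fr$subject)
    if (any(cnt < m))
      stop("infeasible: unstructured error covariance requires every subject ",
           "on the shared time grid; ", sum(cnt < m),
           " subject(s) incomplete", call. = FALSE)
    if (length(cnt) <= m)
      stop("infeasible: unstructured covariance needs more subjects (",
           length(cnt), ") than time points (", m, ")", call. = FALSE)
    n_rpar <- m * (m + 1) / 2
    if (n_rpar >= nrow(fr))
      stop("infeasible: unstructured covariance has ", n_rpar,
           " parameters but only ", nrow(fr), " observations", call. = FALSE)
  }
  corr <- switch(structure,
                 ind = NULL,
                 ar1 = nlme::corAR1(form = ~ time_idx | subject),
                 uns = nlme::corSymm(form = ~ time_idx | subject))
  wts <- if (structure == "uns") nlme::varIdent(form = ~ 1 | time_idx) else NULL
  ranef <- if (random == "intercept") ~ 1 | subject else ~ time | subject
  ctrl <- nlme::lmeControl(maxIter = 200, msMaxIter = 200, niterEM = 50,
                           opt = "optim", returnObject = FALSE)
  fit <- try(nlme::lme(fixed, random = ranef, data = fr,
                       method = "REML", correlation = corr, weights = wts,
                       control = ctrl),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(lmm_failure(random, structure,
                       conditionMessage(attr(fit, "condition"))))
  }
  ll <- logLik(fit)
  G <- nlme::getVarCov(fit, type = "random.effects")
  vc <- list(G = matrix(as.numeric(G), nrow(G), ncol(G),
                        dimnames = dimnames(G)),
             sigma = fit$sigma)
  if (structure == "ar1")
    vc$rho <- as.numeric(coef(fit$modelStruct$corStruct,
                              unconstrained = FALSE))
  if (structure == "uns")
    vc$R <- tryCatch(as.matrix(nlme::getVarCov(fit, type = "conditional",
                                               individuals = 1)[[1]]),
                     error = function(e) NULL)
  d <- attr(ll, "df")
  # BIC with log(N_obs); nlme's REML BIC would use log(N_obs - p) instead
  out <- list(fit = fit, beta = nlme::fixef(fit), vc = vc,
              reml_loglik = as.numeric(ll), d = d,
              aic = -2 * as.numeric(ll) + 2 * d,
              bic = -2 * as.numeric(ll) + d * log(nrow(fr)),
              converged = TRUE, n_obs = nrow(fr),
              random = random, structure = structure)
  class(out) <- "lmm_fit"
  out$f_tests <- lmm_f_tests(out, alpha = alpha)
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Linear mixed model (", x$random, ", ", x$structure,
        "): did not converge\n  ", x$message, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Linear mixed model: random %s, %s errors (REML)\n",
              x$random, toupper(x$structure)))
  cat("Fixed effects:\n"); print(round(x$beta, 4))
  cat(sprintf("sigma = %.4f", x$vc$sigma))
  if (!is.null(x$vc$rho)) cat(sprintf(", rho = %.4f", x$vc$rho))
  cat(sprintf("\nREML logLik = %.2f, d = %d, AIC = %.2f, BIC = %.2f\n",
              x$reml_loglik, x$d, x$aic, x$bic))
  cat("F tests (inner-outer df):\n")
  print(do.call(rbind, lapply(x$f_tests, as.data.frame)))
  invisible(x)
}

#' Wald F tests with inner-outer denominator degrees of freedom
#'
#' Marginal (Type III) Wald F tests for the group, time and group-by-time
#' terms of a fitted model. Denominator degrees of freedom follow the
#' inner-outer rule: terms constant within subjects (group) are tested at the
#' subject level, N minus the between-subject fixed-effect count; terms
#' varying within subjects (time, interaction) at the observation level,
#' N_obs - N minus the within-subject fixed-effect count.
#'
#' @param fit an `lmm_fit` from [lmm_fit()].
#' @param alpha significance level.
#' @return A named list of [trend_test()] objects for effects `group`, `time`
#'   and `interaction`.
#' @export
lmm_f_tests <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged) stop("model did not converge; no F tests", call. = FALSE)
  a <- anova(fit$fit, type = "marginal")
  rn <- rownames(a)
  lab <- paste0("lmm-", fit$structure)
  grab <- function(effect, row) {
    if (!length(row)) return(NULL)
    trend_test(effect, lab, "F", a[row, "F-value"],
               df_num = a[row, "numDF"], df_den = a[row, "denDF"],
               p_value = a[row, "p-value"], alpha = alpha)
  }
  out <- list(group = grab("group", which(rn == "group")),
              time = grab("time", which(rn == "time")),
              interaction = grab("interaction", which(rn == "group:time")))
  out[!vapply(out, is.null, logical(1))]
}

#' Information criteria of a fitted mixed model
#'
#' AIC and BIC of the REML fit: `-2 logLik + 2 d` and
#' `-2 logLik + d log(N_obs)`, where `d` counts the fixed effects plus all
#' free variance-covariance parameters (including the residual SD).
#'
#' @param fit an `lmm_fit`.
#' @return Named numeric vector `c(aic, bic)`.
#' @export
lmm_criteria <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged) stop("model did not converge", call. = FALSE)
  c(aic = fit$aic, bic = fit$bic)
}

#' Fit the six-model menu and rank by AIC/BIC
#'
#' Fits all combinations of random structure (intercept; intercept and slope)
#' and error covariance (IND, AR1, UNS), records infeasible or non-converged
#' cells with a reason instead of failing, and returns a ranked table. The
#' model with the smallest criterion provides the best fit; BIC penalises the
#' heavily parameterised unstructured fits more strongly than AIC.
#'
#' @param ds an [rm_data] dataset.
#' @param alpha significance level forwarded to the per-model F tests.
#' @return A list with `$table` (data.frame: model number, random, structure,
#'   d, AIC, BIC, per-effect p-values, status) ordered as fitted, plus
#'   `$fits` (the `lmm_fit` objects) and `$best` (names of the AIC- and
#'   BIC-preferred models).
#' @export
lmm_menu <- function(ds, alpha = 0.05) {
  grid <- expand.grid(structure = lmm_structures, random = lmm_randoms,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- tryCatch(lmm_fit(ds, random = grid$random[i],
                          structure = grid$structure[i], alpha = alpha),
                  error = function(e) lmm_failure(grid$random[i],
                                                  grid$structure[i],
                                                  conditionMessage(e)))
    fits[[i]] <- f
    p_of <- function(f, eff) if (is.null(f$f_tests[[eff]])) NA_real_
                             else f$f_tests[[eff]]$p_value
    rows[[i]] <- if (f$converged) {
      data.frame(model = i, random = f$random, structure = toupper(f$structure),
                 d = f$d, AIC = f$aic, BIC = f$bic,
                 p_group = p_of(f, "group"),
                 p_time = p_of(f, "time"),
                 p_interaction = p_of(f, "interaction"),
                 status = "ok", stringsAsFactors = FALSE)
    } else {
      data.frame(model = i, random = grid$random[i],
                 structure = toupper(grid$structure[i]),
                 d = NA_integer_, AIC = NA_real_, BIC = NA_real_,
                 p_group = NA_real_, p_time = NA_real_,
                 p_interaction = NA_real_,
                 status = paste0("failed: ", trimws(f$message)),
                 stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- which(tab$status == "ok")
  best <- c(aic = if (length(ok)) ok[which.min(tab$AIC[ok])] else NA,
            bic = if (length(ok)) ok[which.min(tab$BIC[ok])] else NA)
  list(table = tab, fits = fits, best = best)
}
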