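# ---------------------------------------------------------------------------
# Monte Carlo engine: generate linear-trend mixed-model data
#   Y_ij = b0 + b1*X_i + b2*t_j + b3*t_j*X_i + b_0i + e_ij,  t_j = 2j,
# with a normal random intercept and errors drawn jointly normal under an
# IND / AR(1) / unstructured covariance, then estimate empirical rejection
# rates of the SMA, UMA and LMM tests.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Describes one cell of the simulation design: two groups (X = 0, 1) of
#' `n_per_group` subjects, `m` measurements per subject at times t_j = 2j,
#' responses from the linear-trend random-intercept model with coefficients
#' `beta = (b0, b1, b2, b3)` (intercept, group, time, group-by-time), random
#' intercept SD `b0_sd` and errors with the given covariance structure.
#'
#' @param m measurements per subject.
#' @param n_per_group subjects per group.
#' @param beta numeric length-4 vector of fixed effects
#'   (intercept, group, time, interaction). Defaults to the null
#'   `c(2, 0, 0, 0)`.
#' @param b0_sd random-intercept standard deviation (default 0.25).
#' @param sigma2 error variance for the IND and AR1 structures (default 0.5).
#' @param structure true error covariance structure: `"ind"`, `"ar1"` or
#'   `"uns"`.
#' @param rho AR(1) correlation between adjacent measurements (default 0.7;
#'   used only when `structure = "ar1"`).
#' @param uns_R m x m positive-definite error covariance matrix; required for
#'   `structure = "uns"` (see [default_uns_matrix()]).
#' @param alpha nominal significance level (default 0.05).
#' @param label optional cell label.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m, n_per_group, beta = c(2, 0, 0, 0), b0_sd = 0.25,
                       sigma2 = 0.5, structure = c("ind", "ar1", "uns"),
                       rho = 0.7, uns_R = NULL, alpha = 0.05, label = NULL) {
  structure <- match.arg(structure)
  stopifnot(m >= 2, n_per_group >= 2, length(beta) == 4, b0_sd >= 0,
            sigma2 > 0)
  if (structure == "ar1" && abs(rho) >= 1)
    stop("AR(1) correlation must satisfy |rho| < 1", call. = FALSE)
  if (structure == "uns") {
    if (is.null(uns_R)) stop("uns_R is required for structure = 'uns'",
                             call. = FALSE)
    uns_R <- as.matrix(uns_R)
    if (nrow(uns_R) != m || ncol(uns_R) != m)
      stop("uns_R must be m x m", call. = FALSE)
    ev <- eigen(uns_R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("uns_R must be positive definite", call. = FALSE)
  }
  cfg <- list(m = m, n_per_group = n_per_group, beta = as.numeric(beta),
              b0_sd = b0_sd, sigma2 = sigma2, structure = structure,
              rho = rho, uns_R = uns_R, alpha = alpha,
              times = 2 * seq_len(m),
              label = label %||% sprintf("m%d_n%d_%s", m, n_per_group,
                                         structure))
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

error_covariance <- function(cfg) {
  switch(cfg$structure,
         ind = diag(cfg$sigma2, cfg$m),
         ar1 = cfg$sigma2 * cfg$rho^abs(outer(seq_len(cfg$m),
                                              seq_len(cfg$m), "-")),
         uns = cfg$uns_R)
}

# Deterministic substream seed below 2^31 from (root seed, config id, rep);
# keeps replicates reproducible and independent of evaluation order.
derive_seed <- function(seed, config_id, rep_index) {
  s <- (abs(as.numeric(seed)) %% 2147483647)
  s <- (s * 48271 + as.numeric(config_id) * 9973 +
        as.numeric(rep_index) * 7919) %% 2147483629
  as.integer(s + 1)
}

#' Reproducible unstructured error covariance
#'
#' Builds a positive-definite m x m covariance with heterogeneous variances
#' drawn uniformly from \[0.25, 1\] and correlations decaying geometrically
#' with time-point separation (base 0.6). Fixed per `(m, seed)`; the global
#' RNG state is left untouched. This is a synthetic stand-in used as the
#' generating matrix of the unstructured simulation arm.
#'
#' @param m number of time points (>= 2).
#' @param seed integer seed fixing the variances.
#' @return An m x m positive-definite covariance matrix.
#' @export
default_uns_matrix <- function(m, seed = 1) {
  stopifnot(m >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, 0, 0))
  v <- runif(m, 0.25, 1)
  C <- 0.6^abs(outer(seq_len(m), seq_len(m), "-"))
  diag(sqrt(v)) %*% C %*% diag(sqrt(v))
}

#' Generate one dataset from the linear-trend mixed model
#'
#' Draws one replicate from the configured model: random intercepts
#' `Normal(0, b0_sd^2)`, error vectors jointly normal with the structure's
#' covariance (drawn via its Cholesky factor), and the group-specific linear
#' trends added on top. The RNG substream is derived deterministically from
#' `(seed, config_id, rep_index)`, so a replicate can be regenerated in
#' isolation.
#'
#' @param cfg a [sim_config()].
#' @param rep_index replicate number (>= 1).
#' @param seed root integer seed.
#' @param config_id integer identifying the configuration within a study.
#' @return An [rm_data] dataset with groups `"0"` and `"1"`.
#' @export
simulate_trend_data <- function(cfg, rep_index = 1, seed = 1, config_id = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(seed, config_id, rep_index))
  m <- cfg$m
  n <- cfg$n_per_group
  N <- 2 * n
  tj <- cfg$times
  X <- rep(c(0, 1), each = n)
  L <- chol(error_covariance(cfg))
  eps <- matrix(rnorm(N * m), N, m) %*% L
  b0 <- rnorm(N, 0, cfg$b0_sd)
  mu <- cfg$beta[1] + cfg$beta[2] * X + b0
  trend <- outer(X, tj, function(x, t) cfg$beta[3] * t + cfg$beta[4] * t * x)
  Y <- mu + trend + eps
  df <- data.frame(subject = sprintf("s%03d", rep(seq_len(N), each = m)),
                   group = as.character(rep(X, each = m)),
                   time = rep(tj, N),
                   response = as.vector(t(Y)),
                   stringsAsFactors = FALSE)
  class(df) <- c("rm_data", "data.frame")
  df
}

sim_methods <- c("sma", "uma", "lmm-ind", "lmm-ar1", "lmm-uns")

#' Analyse one dataset with the selected methods
#'
#' Applies the selected analysis routes to one dataset and collects p-values
#' for the time, group and interaction effects. Infeasible tests (e.g. the
#' multivariate tests when m exceeds the complete-subject count) and
#' non-converged mixed-model fits are recorded with a reason code and an `NA`
#' p-value, never a fabricated one. The SMA two-group tests use the pooled
#' Student t (for k > 2 groups, one-way ANOVA).
#'
#' @param ds an [rm_data] dataset.
#' @param methods subset of `c("sma", "uma", "lmm-ind", "lmm-ar1",
#'   "lmm-uns")`.
#' @param alpha significance level stored alongside each p-value.
#' @return A `data.frame` with columns `method`, `effect`, `p_value`,
#'   `status` (`"ok"` or a reason code).
#' @export
analyze_replicate <- function(ds, methods = c("sma", "uma"), alpha = 0.05) {
  methods <- match.arg(methods, sim_methods, several.ok = TRUE)
  k <- length(unique(ds$group))
  variant <- if (k == 2) "t" else "anova"
  rows <- list()
  add <- function(method, effect, p, status = "ok") {
    rows[[length(rows) + 1]] <<- data.frame(
      method = method, effect = effect, p_value = p, status = status,
      stringsAsFactors = FALSE)
  }
  p_of <- function(expr, method, effect) {
    r <- tryCatch(expr, error = function(e) e)
    if (inherits(r, "error")) add(method, effect, NA_real_,
                                  trimws(conditionMessage(r)))
    else add(method, effect, r$p_value)
  }
  smry <- suppressWarnings(summarize_subjects(ds))
  if ("sma" %in% methods) {
    p_of(sma_time_test(smry, alpha = alpha), "sma", "time")
    p_of(sma_group_test(smry, variant = variant, alpha = alpha),
         "sma", "group")
    p_of(sma_interaction_test(smry, variant = variant, alpha = alpha),
         "sma", "interaction")
  }
  if ("uma" %in% methods) {
    wide <- tryCatch(as_wide(ds), error = function(e) e)
    if (inherits(wide, "error")) {
      msg <- trimws(conditionMessage(wide))
      add("uma", "time", NA_real_, msg)
      add("uma", "interaction", NA_real_, msg)
    } else {
      p_of(uma_time_test(wide, alpha = alpha), "uma", "time")
      p_of(uma_parallelism_test(wide, alpha = alpha), "uma", "interaction")
    }
    p_of(uma_group_test(smry, variant = variant, alpha = alpha),
         "uma", "group")
  }
  for (st in c("ind", "ar1", "uns")) {
    meth <- paste0("lmm-", st)
    if (!meth %in% methods) next
    f <- tryCatch(lmm_fit(ds, random = "intercept", structure = st,
                          alpha = alpha),
                  error = function(e) lmm_failure("intercept", st,
                                                  conditionMessage(e)))
    if (!f$converged) {
      for (eff in c("time", "group", "interaction"))
        add(meth, eff, NA_real_, paste0("non-convergence: ",
                                        trimws(f$message)))
    } else {
      for (eff in c("time", "group", "interaction"))
        add(meth, eff, f$f_tests[[eff]]$p_value)
    }
  }
  do.call(rbind, rows)
}

#' Empirical rejection rate
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param alpha significance level.
#' @return Fraction of `pvals` at or below `alpha`.
#' @export
empirical_rate <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) stop("no p-values: rate undefined", call. = FALSE)
  stopifnot(all(pvals >= 0 & pvals <= 1))
  mean(pvals <= alpha)
}

#' Run a Monte Carlo rejection-rate study
#'
#' For every configuration, generates `reps` datasets (substreams derived from
#' `seed`), analyses each with the selected methods and tabulates the
#' empirical rejection rate per (configuration, method, effect), computed over
#' the replicates whose test produced a p-value. Failure counts and the most
#' common reason are reported per cell.
#'
#' @param configs a [sim_config()] or list of them.
#' @param methods methods to apply; see [analyze_replicate()].
#' @param reps replicates per configuration (>= 1).
#' @param seed root integer seed.
#' @param progress emit a message per configuration.
#' @return A `data.frame`, one row per (config, method, effect): columns
#'   `config`, `structure`, `m`, `n_per_group`, `beta1`, `beta2`, `beta3`,
#'   `method`, `effect`, `rate`, `n_valid`, `n_failed`, `reason`.
#' @export
run_power_study <- function(configs, methods = c("sma", "uma"), reps = 1000,
                            seed = 1, progress = FALSE) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(reps >= 1)
  out <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    if (progress) message("config ", cfg$label, " (", reps, " reps)")
    ps <- vector("list", reps)
    for (r in seq_len(reps)) {
      ds <- simulate_trend_data(cfg, rep_index = r, seed = seed,
                                config_id = ci)
      ps[[r]] <- analyze_replicate(ds, methods = methods, alpha = cfg$alpha)
    }
    tab <- do.call(rbind, ps)
    cells <- unique(tab[c("method", "effect")])
    for (j in seq_len(nrow(cells))) {
      sel <- tab$method == cells$method[j] & tab$effect == cells$effect[j]
      pv <- tab$p_value[sel]
      ok <- !is.na(pv)
      reasons <- tab$status[sel][!ok]
      out[[length(out) + 1]] <- data.frame(
        config = cfg$label, structure = cfg$structure, m = cfg$m,
        n_per_group = cfg$n_per_group, beta1 = cfg$beta[2],
        beta2 = cfg$beta[3], beta3 = cfg$beta[4],
        method = cells$method[j], effect = cells$effect[j],
        rate = if (any(ok)) empirical_rate(pv[ok], cfg$alpha) else NA_real_,
        n_valid = sum(ok), n_failed = sum(!ok),
        reason = if (length(reasons)) names(sort(table(reasons),
                                                 decreasing = TRUE))[1]
                 else "",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulation grid of the reference study design
#'
#' The factorial design used for the headline comparison: m in (5, 10, 20)
#' measurements, n in (5, 10, 30, 50) subjects per group, IND and AR1 true
#' error structures (plus, optionally, the unstructured arm with the
#' [default_uns_matrix()] stand-in), with the null and the two power settings
#' per effect family. Time/group power rows pair beta1 with an m-adjusted
#' beta2; interaction rows use beta3 alone.
#'
#' @param m,n vectors of measurement counts and per-group sizes.
#' @param structures subset of `c("ind", "ar1", "uns")`.
#' @param effects `"trend"` rows (beta1, beta2 pairs, for the time and group
#'   tests) and/or `"interaction"` rows (beta3 only).
#' @param uns_seed seed for the unstructured generating matrix.
#' @return A list of [sim_config()] objects.
#' @export
trend_study_grid <- function(m = c(5, 10, 20), n = c(5, 10, 30, 50),
                             structures = c("ind", "ar1"),
                             effects = c("trend", "interaction"),
                             uns_seed = 1) {
  structures <- match.arg(structures, c("ind", "ar1", "uns"),
                          several.ok = TRUE)
  effects <- match.arg(effects, c("trend", "interaction"), several.ok = TRUE)
  beta2_of <- function(m, hi) switch(as.character(m),
                                     "5" = if (hi) 0.040 else 0.020,
                                     "10" = if (hi) 0.020 else 0.010,
                                     "20" = if (hi) 0.010 else 0.005)
  beta3_of <- beta2_of  # interaction slopes use the same m-adjusted values
  cfgs <- list()
  for (st in structures) for (mm in m) for (nn in n) {
    R <- if (st == "uns") default_uns_matrix(mm, uns_seed) else NULL
    betas <- list()
    if ("trend" %in% effects) {
      betas <- c(betas, list(c(2, 0, 0, 0),
                             c(2, 0.25, beta2_of(mm, FALSE), 0),
                             c(2, 0.35, beta2_of(mm, TRUE), 0)))
    }
    if ("interaction" %in% effects) {
      b3 <- beta3_of(mm, TRUE)   # 0.040, 0.020, 0.010 for m = 5, 10, 20
      betas <- c(betas, list(c(2, 0, 0, 0), c(2, 0, 0, b3),
                             c(2, 0, 0, 2 * b3)))
    }
    betas <- unique(betas)
    for (b in betas) {
      cfgs[[length(cfgs) + 1]] <- sim_config(
        mm, nn, beta = b, structure = st, uns_R = R,
        label = sprintf("m%d_n%d_%s_b%.2f_%.3f_%.3f", mm, nn, st,
                        b[2], b[3], b[4]))
    }
  }
  cfgs
}
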