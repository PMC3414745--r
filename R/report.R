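# ---------------------------------------------------------------------------
# Combined reports and the command-line entry point (inst/cli/linetrend.R is a
# thin wrapper around lt_main()).
# ---------------------------------------------------------------------------

#' Combined analysis report
#'
#' Runs the six-model mixed-model menu, the SMA and the UMA on one dataset and
#' assembles a single method-by-effect table of p-values plus AIC/BIC for the
#' mixed models — the standard side-by-side summary for a linear-trend
#' repeated-measures analysis. Infeasible entries (e.g. the multivariate tests
#' when m exceeds the complete-subject count) are reported as `NA` with the
#' reason in `status`.
#'
#' @param ds an [rm_data] dataset.
#' @param alpha significance level.
#' @return A `data.frame` with columns `method`, `no`, `structure`,
#'   `p_group`, `p_time`, `p_interaction`, `AIC`, `BIC`, `status`.
#' @export
analysis_report <- function(ds, alpha = 0.05) {
  menu <- lmm_menu(ds, alpha = alpha)
  tab <- menu$table
  lmm_rows <- data.frame(
    method = paste0("LMM random ", tab$random), no = tab$model,
    structure = tab$structure, p_group = tab$p_group, p_time = tab$p_time,
    p_interaction = tab$p_interaction, AIC = tab$AIC, BIC = tab$BIC,
    status = tab$status, stringsAsFactors = FALSE)
  sma_uma <- analyze_replicate(ds, methods = c("sma", "uma"), alpha = alpha)
  pick <- function(meth, eff) {
    r <- sma_uma[sma_uma$method == meth & sma_uma$effect == eff, ]
    list(p = r$p_value[1], status = r$status[1])
  }
  other <- do.call(rbind, lapply(c("sma", "uma"), function(meth) {
    g <- pick(meth, "group"); t <- pick(meth, "time")
    i <- pick(meth, "interaction")
    st <- unique(c(g$status, t$status, i$status))
    st <- if (all(st == "ok")) "ok" else paste(setdiff(st, "ok"),
                                               collapse = "; ")
    data.frame(method = toupper(meth), no = max(lmm_rows$no) +
                 match(meth, c("sma", "uma")),
               structure = "-", p_group = g$p, p_time = t$p,
               p_interaction = i$p, AIC = NA_real_, BIC = NA_real_,
               status = st, stringsAsFactors = FALSE)
  }))
  out <- rbind(lmm_rows, other)
  rownames(out) <- NULL
  out
}

write_manifest <- function(path, args, seed) {
  manifest <- c(sprintf("command: %s", paste(args, collapse = " ")),
                sprintf("seed: %s", format(seed)),
                sprintf("linetrend_version: %s",
                        as.character(utils::packageVersion("linetrend"))),
                sprintf("timestamp: %s", format(Sys.time(), usetz = TRUE)))
  writeLines(manifest, paste0(path, ".manifest"))
  invisible(path)
}

#' Command-line entry point
#'
#' Backs the `linetrend` command shipped in `inst/cli/linetrend.R`.
#' Subcommands: `sma`, `uma` and `lmm` analyse a long-format delimited file
#' (`--input`); `report` writes the combined method-by-effect table;
#' `simulate` runs a Monte Carlo study from a YAML config. Outputs are
#' delimited text accompanied by a `.manifest` file recording the command,
#' seed and package version. Errors abort before any output is written.
#'
#' @param args character vector of command-line arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, 0 on success (invisibly).
#' @export
lt_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop("usage: linetrend <sma|uma|lmm|report|simulate> [options]",
         call. = FALSE)
  cmd <- args[1]
  opts <- parse_cli(args[-1])
  alpha <- as.numeric(opts$alpha %||% 0.05)
  seed <- as.integer(opts$seed %||% 1)
  out_path <- opts$out %||% ""
  emit <- function(df) {
    if (nzchar(out_path)) {
      write.table(df, out_path, sep = ",", row.names = FALSE, quote = FALSE)
      write_manifest(out_path, c(cmd, args[-1]), seed)
      message("written: ", out_path)
    } else {
      print(df)
    }
  }
  read_input <- function() {
    if (is.null(opts$input)) stop("--input is required", call. = FALSE)
    read_rm(opts$input,
            subject_col = opts$`subject-col` %||% "subject",
            group_col = opts$`group-col` %||% "group",
            time_col = opts$`time-col` %||% "time",
            response_col = opts$`response-col` %||% "response",
            sep = opts$sep %||% ",")
  }
  if (cmd %in% c("sma", "uma")) {
    ds <- read_input()
    effect <- opts$effect %||% "all"
    variant <- opts$variant %||% "t"
    perm_reps <- as.integer(opts$`perm-reps` %||% 9999)
    one <- function(eff) {
      if (cmd == "sma") switch(eff,
        time = sma_time_test(ds, alpha = alpha),
        group = sma_group_test(ds, variant = variant, alpha = alpha,
                               perm_reps = perm_reps, seed = seed),
        interaction = sma_interaction_test(ds, variant = variant,
                                           alpha = alpha,
                                           perm_reps = perm_reps,
                                           seed = seed))
      else switch(eff,
        time = uma_time_test(ds, alpha = alpha),
        group = uma_group_test(ds, variant = variant, alpha = alpha,
                               perm_reps = perm_reps, seed = seed),
        interaction = uma_parallelism_test(ds, alpha = alpha))
    }
    effects <- if (effect == "all") c("time", "group", "interaction")
               else effect
    res <- do.call(rbind, lapply(effects, function(e) as.data.frame(one(e))))
    emit(res)
  } else if (cmd == "lmm") {
    ds <- read_input()
    if (isTRUE(opts$menu == "true") || !is.null(opts[["menu"]])) {
      emit(lmm_menu(ds, alpha = alpha)$table)
    } else {
      f <- lmm_fit(ds, random = opts$random %||% "intercept",
                   structure = opts$structure %||% "ind", alpha = alpha)
      if (!f$converged) stop("model did not converge: ", f$message,
                             call. = FALSE)
      print(f)
      emit(do.call(rbind, lapply(f$f_tests, as.data.frame)))
    }
  } else if (cmd == "report") {
    ds <- read_input()
    emit(analysis_report(ds, alpha = alpha))
  } else if (cmd == "simulate") {
    reps <- as.integer(opts$reps %||% 0)
    if (is.na(reps) || reps < 1)
      stop("--reps must be a positive integer", call. = FALSE)
    methods <- strsplit(opts$methods %||% "sma,uma", ",")[[1]]
    cfgs <- if (!is.null(opts$config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is needed for --config files", call. = FALSE)
      lapply(yaml::read_yaml(opts$config), function(cc)
        do.call(sim_config, cc))
    } else if (identical(opts$grid, "paper")) {
      trend_study_grid()
    } else {
      stop("provide --config <file.yaml> or --grid paper", call. = FALSE)
    }
    res <- run_power_study(cfgs, methods = methods, reps = reps, seed = seed,
                           progress = TRUE)
    emit(res)
  } else {
    stop("unknown subcommand: ", cmd, call. = FALSE)
  }
  invisible(0L)
}

# Minimal --key value / --flag parser (long options only).
parse_cli <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      opts[[key]] <- "true"
      i <- i + 1
    }
  }
  opts
}
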