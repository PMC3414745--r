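#' linetrend: analysis of linear-trend repeated measures
#'
#' Compares three routes to testing time, group and group-by-time effects in
#' repeated-measures data with (approximately) linear subject profiles: the
#' summary-measure approach (SMA) built on per-subject least-squares slopes
#' and means, the unstructured multivariate approach (UMA, profile analysis),
#' and REML linear mixed models with selectable within-subject error
#' covariance. A simulation engine estimates empirical type-I error and power
#' for all of them under independent, AR(1) and unstructured error covariance.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova coef cov kruskal.test lm logLik pf rnorm runif
#'   t.test var wilcox.test AIC BIC model.matrix
#' @importFrom utils combn read.table write.table
NULL

# ---------------------------------------------------------------------------
# Repeated-measures dataset: long format is canonical, wide is derived.
# ---------------------------------------------------------------------------

#' Construct a repeated-measures dataset
#'
#' Bundles long-format records (one row per measurement) into a validated
#' dataset used by all analysis routines. Long format is the canonical
#' representation; a wide subject-by-time matrix is derived on demand with
#' [as_wide()].
#'
#' @param subject vector of subject identifiers (coerced to character).
#' @param group vector of group labels, one per row (coerced to character).
#'   Every subject must carry a single group label.
#' @param time numeric measurement times. Times need not be equally spaced.
#' @param response numeric responses.
#' @return An object of class `rm_data`: a `data.frame` with columns
#'   `subject`, `group`, `time`, `response` plus derived attributes; see
#'   [rm_dims()].
#' @examples
#' ds <- rm_data(subject = rep(1:2, each = 2), group = "a",
#'               time = c(1, 2, 1, 2), response = c(3, 4, 5, 6))
#' rm_dims(ds)
#' @export
rm_data <- function(subject, group, time, response) {
  n <- max(length(subject), length(group), length(time), length(response))
  df <- data.frame(subject = as.character(rep_len(subject, n)),
                   group = as.character(rep_len(group, n)),
                   time = as.numeric(rep_len(time, n)),
                   response = as.numeric(rep_len(response, n)),
                   stringsAsFactors = FALSE)
  validate_rm_data(df)
}

validate_rm_data <- function(df) {
  if (anyNA(df$time)) stop("time values must be non-missing numbers", call. = FALSE)
  dup <- duplicated(df[c("subject", "time")])
  if (any(dup)) {
    bad <- unique(df$subject[dup])
    stop("duplicate (subject, time) measurement for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  gps <- unique(df[c("subject", "group")])
  multi <- unique(gps$subject[duplicated(gps$subject)])
  if (length(multi)) {
    stop("subject(s) assigned to more than one group: ",
         paste(multi, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$subject, df$time), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("rm_data", "data.frame")
  df
}

#' Dimensions of a repeated-measures dataset
#'
#' @param ds an `rm_data` object.
#' @return A list with `N` (total subjects), `k` (groups), `n_h` (named
#'   subject counts per group), `m_i` (named measurement counts per subject)
#'   and `times` (sorted union of observed time values).
#' @export
rm_dims <- function(ds) {
  stopifnot(inherits(ds, "rm_data"))
  sub <- unique(ds[c("subject", "group")])
  list(N = nrow(sub),
       k = length(unique(sub$group)),
       n_h = table(sub$group),
       m_i = table(ds$subject),
       times = sort(unique(ds$time)))
}

#' @export
print.rm_data <- function(x, ...) {
  d <- rm_dims(x)
  cat(sprintf("Repeated-measures dataset: %d subjects in %d group(s), %d records\n",
              d$N, d$k, nrow(x)))
  cat("Times:", paste(format(d$times), collapse = " "), "\n")
  NextMethod()
  invisible(x)
}

#' Read a long-format repeated-measures file
#'
#' Reads delimited text (comma by default, tab accepted) with a header row
#' into an [rm_data] dataset. Rows with a missing response are dropped with a
#' message reporting the count.
#'
#' @param path path to the delimited text file.
#' @param subject_col,group_col,time_col,response_col column names holding the
#'   subject identifier, group label, time and response.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return An [rm_data] dataset.
#' @seealso [write_rm()] for the inverse.
#' @export
read_rm <- function(path, subject_col = "subject", group_col = "group",
                    time_col = "time", response_col = "response", sep = ",") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c(subject_col, group_col, time_col, response_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(subject = as.character(df[[subject_col]]),
                    group = as.character(df[[group_col]]),
                    time = suppressWarnings(as.numeric(df[[time_col]])),
                    response = suppressWarnings(as.numeric(df[[response_col]])),
                    stringsAsFactors = FALSE)
  if (anyNA(out$time)) stop("non-numeric time values in ", path, call. = FALSE)
  na_resp <- is.na(out$response)
  if (any(na_resp)) {
    message(sum(na_resp), " row(s) with missing response dropped")
    out <- out[!na_resp, , drop = FALSE]
  }
  validate_rm_data(out)
}

#' Write a repeated-measures dataset as delimited text
#'
#' @param ds an [rm_data] dataset.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_rm <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "rm_data"))
  write.table(as.data.frame(ds), path, sep = sep, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Pivot to a wide subject-by-time matrix
#'
#' Requires balanced, complete data: every subject must have exactly one
#' response at each time in the shared grid. Use [complete_subjects()] first
#' if some subjects have missing cells.
#'
#' @param ds an [rm_data] dataset.
#' @return An object of class `rm_wide`: a list with `values` (N x m response
#'   matrix), `subjects`, `groups` (one label per row) and `times` (strictly
#'   increasing).
#' @export
as_wide <- function(ds) {
  stopifnot(inherits(ds, "rm_data"))
  times <- sort(unique(ds$time))
  m <- length(times)
  subs <- unique(ds[c("subject", "group")])
  cnt <- table(factor(ds$subject, levels = subs$subject))
  bad <- names(cnt)[cnt != m]
  if (length(bad)) {
    stop("data not balanced/complete over the shared time grid; ",
         "subject(s) with missing cells: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow(subs), m,
                 dimnames = list(subs$subject, format(times)))
  idx <- cbind(match(ds$subject, subs$subject), match(ds$time, times))
  vals[idx] <- ds$response
  structure(list(values = vals, subjects = subs$subject,
                 groups = subs$group, times = times),
            class = "rm_wide")
}

#' Restrict to subjects with complete measurements
#'
#' Keeps the subjects observed at every time in the union time grid, the
#' complete-case set on which the multivariate approach (and an unstructured
#' error covariance) can operate. Counts of retained and dropped subjects are
#' reported via `message()`; an empty result triggers a warning.
#'
#' @param ds an [rm_data] dataset.
#' @return An [rm_data] dataset containing only the complete subjects (may be
#'   empty).
#' @export
complete_subjects <- function(ds) {
  stopifnot(inherits(ds, "rm_data"))
  times <- sort(unique(ds$time))
  cnt <- table(ds$subject)
  keep <- names(cnt)[cnt == length(times)]
  dropped <- length(cnt) - length(keep)
  message(length(keep), " subject(s) retained, ", dropped,
          " with incomplete measurements dropped")
  out <- ds[ds$subject %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rm_data", "data.frame")
  if (!nrow(out)) warning("no subject has complete measurements", call. = FALSE)
  out
}
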