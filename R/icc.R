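# Test-retest reliability of spindle event density: variance-component ICC
# with subject-level bootstrap confidence intervals.

# Validate and reshape a (subject, session, density) table into a balanced
# subjects x sessions matrix.
session_matrix <- function(tbl) {
  need <- c("subject_id", "session_id", "density")
  if (!all(need %in% names(tbl))) {
    stop("session table needs columns ", paste(need, collapse = ", "))
  }
  if (any(tbl$density < 0)) stop("densities must be non-negative")
  counts <- table(tbl$subject_id)
  if (length(counts) < 2L) stop("ICC needs at least 2 subjects")
  if (any(counts < 2L)) stop("every subject needs at least 2 sessions")
  if (length(unique(counts)) != 1L) {
    stop("unbalanced design: all subjects must have the same session count")
  }
  tbl <- tbl[order(tbl$subject_id, tbl$session_id), , drop = FALSE]
  matrix(tbl$density, nrow = length(counts), byrow = TRUE,
         dimnames = list(names(counts), NULL))
}

# One-way random-effects ICC from a balanced subjects x sessions matrix
# (method of moments). Closed form keeps the estimator exactly testable.
icc_from_matrix <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  m_i <- rowMeans(x)
  ms_between <- k * stats::var(m_i)
  ms_within <- sum((x - m_i)^2) / (n * (k - 1))
  s2_b <- max(0, (ms_between - ms_within) / k)
  s2_w <- ms_within
  icc <- if (s2_b + s2_w > 0) s2_b / (s2_b + s2_w) else 0
  list(icc = icc, sigma2_between = s2_b, sigma2_within = s2_w)
}

#' Intraclass correlation of event density across sessions
#'
#' Quantifies the test-retest reliability of spindle event density as the
#' proportion of total variance attributable to stable between-subject
#' differences. Between- and within-subject variance components are
#' estimated from the one-way random-effects ANOVA (subject as a random
#' effect): with `k` sessions per subject,
#' `sigma2_within = MS_within`,
#' `sigma2_between = max(0, (MS_between - MS_within) / k)`, and
#' `ICC = sigma2_between / (sigma2_between + sigma2_within)` (0 when both
#' components vanish). Truncating the between component at zero keeps the
#' ICC in `[0, 1]`.
#'
#' @param tbl data.frame with columns `subject_id`, `session_id`, `density`
#'   (events per minute); balanced design with >= 2 subjects and the same
#'   number (>= 2) of sessions per subject.
#' @return object of class `"icc_result"`: list with `icc`,
#'   `sigma2_between`, `sigma2_within`, `n_subjects`, `n_sessions`, and (for
#'   [icc_bootstrap()]) `ci_lo`, `ci_hi`, `n_boot`.
#' @export
icc_estimate <- function(tbl) {
  x <- session_matrix(tbl)
  est <- icc_from_matrix(x)
  structure(c(est, list(ci_lo = NA_real_, ci_hi = NA_real_, n_boot = 0L,
                        n_subjects = nrow(x), n_sessions = ncol(x))),
            class = "icc_result")
}

#' Bootstrap confidence interval for the ICC
#'
#' Resamples subjects (clusters) with replacement `n_boot` times, preserving
#' the within-subject session pairing, and takes the 2.5th and 97.5th
#' percentiles of the bootstrap ICC distribution as the 95% confidence
#' interval, clipped to `[0, 1]`. The point estimate comes from the full
#' table. As with any percentile interval, a heavily skewed bootstrap
#' distribution can in principle place the point estimate outside the
#' interval; the interval is reported as-is rather than widened.
#'
#' @inheritParams icc_estimate
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed for reproducibility.
#' @param conf confidence level (default 0.95).
#' @return an `"icc_result"` (see [icc_estimate()]) with `ci_lo`, `ci_hi`
#'   and `n_boot` filled in.
#' @export
icc_bootstrap <- function(tbl, n_boot = 1000L, seed = NULL, conf = 0.95) {
  x <- session_matrix(tbl)
  est <- icc_from_matrix(x)
  n <- nrow(x)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      icc_from_matrix(x[sample.int(n, n, replace = TRUE), , drop = FALSE])$icc
    }, 0)
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  ci <- pmin(pmax(ci, 0), 1)
  structure(c(est, list(ci_lo = ci[1L], ci_hi = ci[2L],
                        n_boot = as.integer(n_boot),
                        n_subjects = n, n_sessions = ncol(x))),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.3f", x$icc))
  if (x$n_boot > 0) {
    cat(sprintf(" [%.3f, %.3f] (%d bootstrap resamples)", x$ci_lo, x$ci_hi,
                x$n_boot))
  }
  cat(sprintf("\n  sigma2_between = %.4g, sigma2_within = %.4g (%d subjects x %d sessions)\n",
              x$sigma2_between, x$sigma2_within, x$n_subjects, x$n_sessions))
  invisible(x)
}

#' Read a session table from TSV
#'
#' @param path TSV with columns `subject_id`, `session_id`, `density`.
#' @return data.frame.
#' @export
read_sessions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(subject_id = "character",
                                   session_id = "character"))
}
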