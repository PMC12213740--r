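# Multi-run statistical comparison protocol: Shapiro-Wilk normality check
# on the paired differences, then a paired two-sided t-test.

#' Compare two sets of per-run scores
#'
#' Given per-run weighted-F1 scores of two model configurations over the
#' same seeds, first verifies approximate normality of the paired
#' differences with the Shapiro-Wilk test, then runs a paired two-sided
#' t-test. With all-zero-variance differences the t statistic is undefined
#' and a `tf_degenerate_test` error is raised rather than a spurious
#' p-value.
#'
#' @param scores_a,scores_b equal-length numeric vectors (length >= 3).
#' @return A `tf_runstats`: `scores_a`, `scores_b`, `shapiro_p`,
#'   `t_stat`, `t_p`.
#' @export
compare_runs <- function(scores_a, scores_b) {
  stopifnot(is.numeric(scores_a), is.numeric(scores_b))
  if (length(scores_a) != length(scores_b))
    stop("score lists must have equal length")
  if (length(scores_a) < 3L)
    stop("need at least 3 paired runs")
  d <- scores_a - scores_b
  if (stats::var(d) == 0)
    stop_domain(
      "paired differences have zero variance; t statistic is undefined",
      class = "tf_degenerate_test")
  sw <- stats::shapiro.test(d)
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  structure(list(scores_a = scores_a, scores_b = scores_b,
                 shapiro_p = unname(sw$p.value),
                 t_stat = unname(tt$statistic),
                 t_p = unname(tt$p.value)),
            class = "tf_runstats")
}

#' @export
print.tf_runstats <- function(x, ...) {
  cat(sprintf("paired runs: n=%d  mean diff=%.5f\n",
              length(x$scores_a), mean(x$scores_a - x$scores_b)))
  cat(sprintf("Shapiro-Wilk p (differences): %.4g\n", x$shapiro_p))
  cat(sprintf("paired t-test: t=%.4f, two-sided p=%.4g\n", x$t_stat, x$t_p))
  invisible(x)
}
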