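#' Cohort means of per-clone WGS summaries
#'
#' Arithmetic means of genome coverage and unique SNV/indel/SV counts over
#' a clone summary table, reported at full precision together with the
#' one-decimal display rounding used in text.
#'
#' @param records data.frame with columns `coverage`, `n_unique_snv`,
#'   `n_unique_indel`, `n_unique_sv` (see [study_clone_table()]).
#' @return data.frame with columns `metric`, `mean`, `mean_rounded`.
#' @export
cohort_means <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("empty clone table")
  metrics <- c(coverage = "coverage", n_unique_snv = "n_unique_snv",
               n_unique_indel = "n_unique_indel", n_unique_sv = "n_unique_sv")
  m <- vapply(metrics, function(col) mean(records[[col]]), numeric(1))
  data.frame(metric = names(metrics), mean = unname(m),
             mean_rounded = unname(round(m, 1)), stringsAsFactors = FALSE)
}

#' Pooled-variance two-sample t-test
#'
#' Classic equal-variance (Student) two-sample t: the pooled variance is
#' `((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)`, the statistic
#' `(mean(x)-mean(y)) / sqrt(sp2 (1/n1 + 1/n2))` with `n1+n2-2` degrees of
#' freedom, and the two-sided p-value comes from the t distribution tail.
#' Degenerate inputs (zero pooled variance) give `t = 0, p = 1` when the
#' means agree, and `p = 0` with a warning when they do not.
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @param group_labels Optional length-2 character vector naming the groups.
#' @return Object of class `rate_comparison`: a list with `group_labels`,
#'   `group_n`, `group_means`, `t_statistic`, `degrees_of_freedom`,
#'   `p_two_sided`.
#' @examples
#' student_t_two_sample(c(2, 8), c(0, 3, 1, 1, 1, 1, 3, 1, 1, 0, 1, 0, 0, 1))
#' @export
student_t_two_sample <- function(x, y, group_labels = c("x", "y")) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 2L, length(y) >= 2L)
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (delta == 0) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(delta) * Inf; p <- 0
      warning("zero pooled variance with unequal means; p reported as 0")
    }
  } else {
    tstat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tstat), df = df)
  }
  structure(list(group_labels = group_labels,
                 group_n = c(n1, n2),
                 group_means = c(mean(x), mean(y)),
                 t_statistic = tstat,
                 degrees_of_freedom = df,
                 p_two_sided = p),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("Two-sample pooled-variance t-test\n")
  cat(sprintf("  %s: n = %d, mean = %.4g\n", x$group_labels[1], x$group_n[1],
              x$group_means[1]))
  cat(sprintf("  %s: n = %d, mean = %.4g\n", x$group_labels[2], x$group_n[2],
              x$group_means[2]))
  cat(sprintf("  t = %.4g, df = %d, two-sided p = %.6g\n", x$t_statistic,
              x$degrees_of_freedom, x$p_two_sided))
  invisible(x)
}

#' Compare unintended-variant rates between clone groups
#'
#' Splits per-clone unintended-event counts by delivery method
#' (plasmid vs RNP) or Cas protein (Cas9 vs Cas12a) and applies
#' [student_t_two_sample()].
#'
#' @param records Clone table with columns `n_unintended_events` and the
#'   grouping column (`delivery` or `cas_label`).
#' @param grouping `"delivery"` or `"cas_label"`.
#' @return A `rate_comparison` object.
#' @export
rate_comparison <- function(records, grouping = c("delivery", "cas_label")) {
  grouping <- match.arg(grouping)
  stopifnot(is.data.frame(records), "n_unintended_events" %in% names(records),
            grouping %in% names(records))
  g <- records[[grouping]]
  canonical <- if (grouping == "delivery") c("plasmid", "RNP")
               else c("Cas9", "Cas12a")
  levels <- c(canonical[canonical %in% g], setdiff(sort(unique(g)), canonical))
  if (length(levels) != 2L)
    stop("grouping '", grouping, "' must define exactly 2 groups, found: ",
         paste(levels, collapse = ", "))
  x <- records$n_unintended_events[g == levels[1]]
  y <- records$n_unintended_events[g == levels[2]]
  for (k in 1:2) {
    v <- list(x, y)[[k]]
    if (length(v) < 2L)
      stop("group '", levels[k], "' has fewer than 2 clones")
  }
  student_t_two_sample(x, y, group_labels = levels)
}
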