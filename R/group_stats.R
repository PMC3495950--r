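# Case/control statistics on validated peak clusters: Welch t-test and
# Mann-Whitney U on heights/areas, mid-P Fisher exact test on prevalences,
# and the per-cluster significance report.

test_result <- function(test, statistic, p_value, summaries,
                        flag = NULL) {
  structure(list(test = test, statistic = statistic,
                 p_value = min(max(p_value, 0), 1),
                 group_summaries = summaries, flag = flag),
            class = "ClusterTestResult")
}

#' @export
print.ClusterTestResult <- function(x, ...) {
  cat(sprintf("<%s> statistic=%.4g, p=%.4g%s\n", x$test, x$statistic,
              x$p_value, if (is.null(x$flag)) "" else
                paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) two-sided t-test, the safer default when the
#' variant is not prescribed. Group summaries report mean and SEM
#' (`sd/sqrt(n)`). If both groups are constant with equal means the test
#' is degenerate and p = 1 is returned with a flag.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return a `ClusterTestResult`.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  summ <- list(a = c(mean = mean(a), sem = sqrt(va / na), n = na),
               b = c(mean = mean(b), sem = sqrt(vb / nb), n = nb))
  se2 <- va / na + vb / nb
  if (se2 == 0)
    return(test_result("t", 0, 1, summ,
                       flag = if (mean(a) == mean(b)) "degenerate"
                       else "zero variance, unequal means"))
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  test_result("t", tstat, 2 * stats::pt(-abs(tstat), df), summ)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. With no ties and `min(n) <= 8` the exact null
#' distribution of U is used (two-sided p by doubling the smaller tail,
#' capped at 1); otherwise the normal approximation with tie correction
#' and continuity correction.
#'
#' @param a,b numeric vectors (>= 1 value each).
#' @return a `ClusterTestResult` with the U statistic for group `a`.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2   # pairs where a beats b
  ties <- anyDuplicated(c(a, b)) > 0
  summ <- list(a = c(median = stats::median(a), n = na),
               b = c(median = stats::median(b), n = nb))
  if (!ties && min(na, nb) <= 8) {
    p <- 2 * min(stats::pwilcox(U, na, nb),
                 stats::pwilcox(nb * na - U, na, nb))
    return(test_result("mann_whitney", U, min(1, p), summ))
  }
  mu <- na * nb / 2
  tie_tab <- table(c(a, b))
  n <- na + nb
  sig2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sig2 == 0)
    return(test_result("mann_whitney", U, 1, summ, flag = "degenerate"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  test_result("mann_whitney", U, 2 * stats::pnorm(-abs(z)), summ,
              flag = "normal approximation")
}

#' Fisher exact test with mid-P correction
#'
#' For a 2x2 table (rows = groups, columns = present/absent), enumerates
#' the hypergeometric distribution over the fixed margins. The one-tailed
#' mid-P is the probability of strictly more extreme tables in the
#' observed direction plus half the probability of the observed table;
#' the two-sided p doubles it (capped at 1). Mid-P counts only half of
#' the observed outcome and so is less conservative than the ordinary
#' exact test.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins, e.g. `rbind(c(present_cases, absent_cases),
#'   c(present_controls, absent_controls))`.
#' @return a `ClusterTestResult`; the statistic is the observed count in
#'   cell (1,1), summaries give per-group prevalences.
#' @export
fisher_midp <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in 2x2 table")
  a <- tab[1, 1]
  K <- sum(tab[, 1])          # total present
  N <- sum(tab)
  n1 <- sum(tab[1, ])         # group 1 size
  expect <- n1 * K / N
  lower <- stats::phyper(a - 1, K, N - K, n1) +
    0.5 * stats::dhyper(a, K, N - K, n1)
  upper <- stats::phyper(a, K, N - K, n1, lower.tail = FALSE) +
    0.5 * stats::dhyper(a, K, N - K, n1)
  one_tail <- if (a < expect) lower else if (a > expect) upper
    else min(lower, upper)
  summ <- list(prevalence_1 = tab[1, 1] / n1,
               prevalence_2 = tab[2, 1] / sum(tab[2, ]))
  test_result("fisher_midp", a, min(1, 2 * one_tail), summ)
}

#' Per-cluster significance report
#'
#' Runs all five tests on every validated cluster - Welch t and
#' Mann-Whitney U on both peak heights and peak areas of the members
#' present in each group, and the mid-P Fisher exact test on the 2x2
#' present/absent-by-group table - and reports rows with p below `alpha`.
#' No multiple-testing correction is applied (a header warning says so).
#'
#' @param validated list of validated clusters as returned by
#'   [validate_cluster()], each with `$members` containing `spectrum_id`,
#'   `height`, `area`.
#' @param groups named character vector mapping spectrum_id to group
#'   label; exactly two distinct labels.
#' @param alpha significance threshold for inclusion (default 0.05);
#'   `alpha = 1` reports everything.
#' @return data frame with columns `mean_mz`, `test`, `statistic`,
#'   `p_value`, and per-group summary columns, filtered at `p < alpha`
#'   and ordered by p; attribute `"warning"` notes the absence of
#'   multiplicity correction.
#' @export
cluster_report <- function(validated, groups, alpha = 0.05) {
  stopifnot(length(validated) >= 1)
  glev <- unique(groups)
  if (length(glev) != 2) stop("cluster_report requires exactly two groups")
  n_by_group <- table(factor(groups, levels = glev))
  rows <- list()
  for (cl in validated) {
    mem <- cl$members
    g <- if (!is.null(mem)) groups[mem$spectrum_id] else character()
    present <- table(factor(g, levels = glev))
    tab <- rbind(c(present[1], n_by_group[1] - present[1]),
                 c(present[2], n_by_group[2] - present[2]))
    add <- function(res, test_name) {
      rows[[length(rows) + 1]] <<- data.frame(
        mean_mz = cl$mean_mz, test = test_name,
        statistic = res$statistic, p_value = res$p_value,
        summary_1 = paste(signif(unlist(res$group_summaries[1]), 3),
                          collapse = "/"),
        summary_2 = paste(signif(unlist(res$group_summaries[2]), 3),
                          collapse = "/"))
    }
    # prevalence test is uninformative (and undefined) when a
    # present/absent margin is empty, e.g. the cluster is in every spectrum
    if (all(colSums(tab) > 0)) add(fisher_midp(tab), "fisher_midp")
    for (what in c("height", "area")) {
      x <- mem[[what]][g == glev[1]]
      y <- mem[[what]][g == glev[2]]
      if (length(x) >= 2 && length(y) >= 2) {
        add(two_sample_t(x, y), paste0("t_", what))
        add(mann_whitney_u(x, y), paste0("u_", what))
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$p_value < alpha, , drop = FALSE]
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "warning") <-
    "p-values are not corrected for multiple testing"
  out
}
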