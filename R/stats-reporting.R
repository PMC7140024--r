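#' Significance star label for a p-value
#'
#' The usual three-threshold convention: `***` for p < 0.001, `**` for
#' p < 0.01, `*` for p < 0.05, otherwise `ns`. All inequalities are strict.
#'
#' @param p A p-value (or vector of them) in `[0, 1]`.
#' @return Character vector of labels.
#' @examples
#' star_label(c(0.0005, 0.03, 0.05))
#' @export
star_label <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("invalid-p: p must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

new_test_result <- function(method, statistic, p, comparison) {
  structure(
    list(method = method, statistic = unname(statistic),
         p_value = unname(p), comparison = comparison,
         stars = star_label(unname(p))),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4g, p = %.4g (%s)\n",
              x$comparison, x$method, x$statistic, x$p_value, x$stars))
  invisible(x)
}

#' Two-group comparison: Student's t or Mann-Whitney
#'
#' Two-sided comparison of two independent samples. Parametric datasets use
#' Student's t-test (equal variances; set `welch = TRUE` for the
#' unequal-variance form), non-parametric ones the Mann-Whitney U test.
#' The exact U distribution is used when both groups have at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity correction applies.
#'
#' @param a,b Numeric samples, each of length >= 3.
#' @param parametric `TRUE` for Student's t, `FALSE` for Mann-Whitney.
#' @param comparison Label for the reported comparison.
#' @param welch Apply Welch's unequal-variance correction to the t-test.
#' @return A `test_result` with `method`, `statistic`, `p_value`,
#'   `comparison` and `stars`.
#' @examples
#' two_group_test(c(1, 2, 3), c(10, 11, 12), parametric = FALSE)
#' @export
two_group_test <- function(a, b, parametric = FALSE, comparison = "a vs b",
                           welch = FALSE) {
  if (length(a) < 3L || length(b) < 3L) {
    stop("insufficient-n: both samples need >= 3 observations", call. = FALSE)
  }
  if (parametric) {
    tt <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
    new_test_result(if (welch) "welch_t_two_sided" else "t_test_two_sided",
                    tt$statistic, tt$p.value, comparison)
  } else {
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- !ties && length(a) <= 8L && length(b) <= 8L
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = TRUE)
    )
    new_test_result("mann_whitney", wt$statistic, wt$p.value, comparison)
  }
}

#' Multi-group comparison with post-hoc pairwise tests
#'
#' Parametric: one-way ANOVA omnibus followed by pairwise pooled-variance
#' t-tests with Bonferroni correction. Non-parametric: Kruskal-Wallis
#' omnibus followed by Dunn's rank-sum post-hoc z-tests with tie correction
#' and Bonferroni family correction.
#'
#' @param samples A named list of numeric vectors, one per group (>= 3
#'   groups, each of length >= 3).
#' @param parametric `TRUE` for ANOVA/Bonferroni, `FALSE` for
#'   Kruskal-Wallis/Dunn.
#' @return A list with `omnibus` (a `test_result`) and `pairwise` (a
#'   data.frame `group_a, group_b, statistic, p_raw, p_adj, stars`, stars
#'   from the adjusted p).
#' @export
multi_group_test <- function(samples, parametric = FALSE) {
  if (!is.list(samples) || length(samples) < 3L) {
    stop("insufficient-n: need >= 3 groups", call. = FALSE)
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  if (any(vapply(samples, length, 1L) < 3L)) {
    stop("insufficient-n: every group needs >= 3 observations", call. = FALSE)
  }
  values <- unlist(samples, use.names = FALSE)
  grp <- factor(rep(names(samples), vapply(samples, length, 1L)),
                levels = names(samples))
  m <- choose(length(samples), 2L)
  pairs <- utils::combn(names(samples), 2L)

  if (parametric) {
    fit <- stats::aov(values ~ grp)
    an <- stats::anova(fit)
    omnibus <- new_test_result("anova_bonferroni", an[["F value"]][1],
                               an[["Pr(>F)"]][1], "omnibus")
    pt <- stats::pairwise.t.test(values, grp, p.adjust.method = "none",
                                 pool.sd = TRUE)
    pairwise <- do.call(rbind, apply(pairs, 2L, function(gp) {
      praw <- pt$p.value[gp[2], gp[1]]
      if (is.na(praw)) praw <- pt$p.value[gp[1], gp[2]]
      data.frame(group_a = gp[1], group_b = gp[2], statistic = NA_real_,
                 p_raw = praw, p_adj = min(1, praw * m),
                 stringsAsFactors = FALSE)
    }))
  } else {
    kw <- stats::kruskal.test(values, grp)
    omnibus <- new_test_result("kruskal_dunn", kw$statistic, kw$p.value,
                               "omnibus")
    pairwise <- dunn_posthoc(values, grp, pairs, m)
  }
  pairwise$stars <- star_label(pairwise$p_adj)
  rownames(pairwise) <- NULL
  list(omnibus = omnibus, pairwise = pairwise)
}

# Dunn's post hoc: z on mean-rank differences from the pooled ranking, with
# tie correction in the variance; family correction is Bonferroni.
dunn_posthoc <- function(values, grp, pairs, m) {
  N <- length(values)
  r <- rank(values)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  mean_ranks <- tapply(r, grp, mean)
  ns <- tapply(r, grp, length)
  do.call(rbind, apply(pairs, 2L, function(gp) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[gp[1]] + 1 / ns[gp[2]]))
    z <- (mean_ranks[gp[1]] - mean_ranks[gp[2]]) / se
    praw <- 2 * stats::pnorm(-abs(z))
    data.frame(group_a = gp[1], group_b = gp[2], statistic = unname(z),
               p_raw = unname(praw), p_adj = min(1, unname(praw) * m),
               stringsAsFactors = FALSE)
  }))
}

#' Comparisons table in the reporting format
#'
#' Flattens one or more test results into the standard comparisons table
#' with columns `comparison, method, statistic, p, stars`.
#'
#' @param ... `test_result` objects (or lists of them).
#' @return A data.frame.
#' @export
comparisons_table <- function(...) {
  res <- list(...)
  res <- unlist(lapply(res, function(x) {
    if (inherits(x, "test_result")) list(x) else x
  }), recursive = FALSE)
  out <- do.call(rbind, lapply(res, function(x) {
    data.frame(comparison = x$comparison, method = x$method,
               statistic = x$statistic, p = x$p_value, stars = x$stars,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
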