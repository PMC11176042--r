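test_result <- function(test_name, groups, statistic, p_value,
                        adjusted_p = NA_real_, method_detail = "") {
  structure(list(test_name = test_name, groups = groups,
                 statistic = unname(statistic), p_value = unname(p_value),
                 adjusted_p = adjusted_p, method_detail = method_detail),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.6g, p = %.4g%s (%s)\n",
              x$test_name, paste(x$groups, collapse = " vs "),
              x$statistic, x$p_value,
              if (!is.na(x$adjusted_p)) sprintf(", adj. p = %.4g", x$adjusted_p) else "",
              x$method_detail))
  invisible(x)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration when both samples are tie-free and the pooled size is at
#' most 12 (or whenever `mode = "exact"` and no ties are present); otherwise
#' a tie-corrected normal approximation on midranks without continuity
#' correction. The statistic is the Mann-Whitney U for the first sample.
#'
#' @param a,b numeric samples (nonempty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return a `test_result` (`statistic` = U, two-sided `p_value`,
#'   `method_detail` records exact vs approximation and tie handling).
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- switch(mode,
                      exact = !ties,
                      approx = FALSE,
                      auto = !ties && (length(a) + length(b)) <= 12)
  if (use_exact) {
    wt <- stats::wilcox.test(a, b, exact = TRUE)
    detail <- "exact"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    detail <- if (ties) "normal approximation, tie-corrected (midranks)"
              else "normal approximation"
  }
  p <- wt$p.value
  if (!is.finite(p)) { p <- 1; detail <- paste(detail, "(degenerate: all values tied)") }
  test_result("mann_whitney", c("a", "b"), wt$statistic, p, method_detail = detail)
}

#' Kruskal-Wallis test with Dunn's pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis H over all groups, followed by Dunn's
#' pairwise z-tests on the pooled midranks with multiplicity adjustment.
#' With exactly two groups the comparison delegates to [mann_whitney()].
#'
#' @param groups named (or unnamed) list of numeric vectors, all nonempty.
#' @param p_adjust multiplicity adjustment for Dunn's pairwise p-values
#'   (any [stats::p.adjust()] method; default `"bonferroni"`).
#' @return list with `test` (a `test_result` carrying H and its p-value) and
#'   `pairwise` (data.frame: `group1`, `group2`, `z`, `p_value`,
#'   `adjusted_p`). For two groups, `pairwise` is `NULL`.
#' @export
kruskal_wallis_dunn <- function(groups, p_adjust = "bonferroni") {
  if (!is.list(groups) || length(groups) < 2) stop("need a list of >= 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (length(groups) == 2) {
    res <- mann_whitney(groups[[1]], groups[[2]])
    res$groups <- names(groups)
    return(list(test = res, pairwise = NULL))
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  if (diff(range(x)) == 0) {
    test <- test_result("kruskal_wallis", names(groups), 0, 1,
                        method_detail = "degenerate: all values identical")
    pw <- t(utils::combn(names(groups), 2))
    pairwise <- data.frame(group1 = pw[, 1], group2 = pw[, 2],
                           z = 0, p_value = 1, adjusted_p = 1,
                           stringsAsFactors = FALSE)
    return(list(test = test, pairwise = pairwise))
  }
  kw <- stats::kruskal.test(x, g)
  test <- test_result("kruskal_wallis", names(groups), kw$statistic, kw$p.value,
                      method_detail = "tie-corrected H")
  # Dunn's z on pooled midranks
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  tie_counts <- table(x)
  tie_term <- sum(tie_counts^3 - tie_counts) / (12 * (N - 1))
  pw <- t(utils::combn(names(groups), 2))
  z <- numeric(nrow(pw))
  for (i in seq_len(nrow(pw))) {
    g1 <- pw[i, 1]; g2 <- pw[i, 2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[g1]] + 1 / n[[g2]]))
    z[i] <- (rbar[[g1]] - rbar[[g2]]) / se
  }
  p <- 2 * pnorm(-abs(z))
  pairwise <- data.frame(group1 = pw[, 1], group2 = pw[, 2], z = z,
                         p_value = p,
                         adjusted_p = stats::p.adjust(p, method = p_adjust),
                         stringsAsFactors = FALSE)
  list(test = test, pairwise = pairwise)
}

#' Two-proportion Z-test (pooled variance, two-sided)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled proportion
#' `p = (x1 + x2)/(n1 + n2)`; two-sided p from the standard normal. No
#' continuity correction.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return a `test_result` (`statistic` = z). A pooled proportion of 0 or 1
#'   is degenerate: z = 0, p = 1, flagged in `method_detail`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop("n must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stop("x must satisfy 0 <= x <= n")
  p_pool <- (x1 + x2) / (n1 + n2)
  if (p_pool == 0 || p_pool == 1)
    return(test_result("two_proportion_z", c("1", "2"), 0, 1,
                       method_detail = "degenerate: pooled proportion 0 or 1"))
  z <- (x1 / n1 - x2 / n2) / sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  test_result("two_proportion_z", c("1", "2"), z, 2 * pnorm(-abs(z)),
              method_detail = "pooled variance, no continuity correction")
}

#' Implantation outcome table
#'
#' Per-group counts of injected mice, mice carrying embryos, mice with
#' implantation sites (IS), and embryos observed/implanted, validated against
#' the obvious ordering constraints.
#'
#' @param group character vector of group labels.
#' @param n_mice_injected,n_mice_with_embryos,n_mice_with_IS integer vectors.
#' @param n_embryos_total,n_embryos_implanted integer vectors.
#' @return data.frame of class `implantation_table`.
#' @export
implantation_table <- function(group, n_mice_injected, n_mice_with_embryos,
                               n_mice_with_IS, n_embryos_total, n_embryos_implanted) {
  df <- data.frame(group = as.character(group),
                   n_mice_injected = as.integer(n_mice_injected),
                   n_mice_with_embryos = as.integer(n_mice_with_embryos),
                   n_mice_with_IS = as.integer(n_mice_with_IS),
                   n_embryos_total = as.integer(n_embryos_total),
                   n_embryos_implanted = as.integer(n_embryos_implanted),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$group)) stop("duplicate group labels")
  with(df, {
    if (any(n_mice_with_IS > n_mice_with_embryos))
      stop("n_mice_with_IS cannot exceed n_mice_with_embryos")
    if (any(n_mice_with_embryos > n_mice_injected))
      stop("n_mice_with_embryos cannot exceed n_mice_injected")
    if (any(n_embryos_implanted > n_embryos_total))
      stop("implanted embryos cannot exceed total embryos")
    if (any(cbind(n_mice_injected, n_mice_with_embryos, n_mice_with_IS,
                  n_embryos_total, n_embryos_implanted) < 0))
      stop("counts must be nonnegative")
  })
  class(df) <- c("implantation_table", "data.frame")
  df
}

it_row <- function(table, group) {
  i <- match(group, table$group)
  if (is.na(i)) stop("unknown group: ", group)
  table[i, , drop = FALSE]
}

#' Average embryos per mouse carrying embryos
#' @param table an [implantation_table()].
#' @param group group label.
#' @return total embryos divided by the number of mice with embryos.
#' @export
embryos_per_mouse <- function(table, group) {
  r <- it_row(table, group)
  if (r$n_mice_with_embryos < 1) stop("no mice with embryos in group ", group)
  r$n_embryos_total / r$n_mice_with_embryos
}

#' Implantation rescue percentages
#'
#' Mouse-level rescue: mice with implantation sites over mice with embryos.
#' Embryo-level rescue: implanted embryos over embryos observed. Display
#' values are rounded to integer percent; full precision is retained.
#'
#' @param table an [implantation_table()].
#' @param group group label.
#' @return list: `mouse_level_pct`, `embryo_level_pct` (full precision) and
#'   `mouse_level_display`, `embryo_level_display` (integer percent).
#' @export
rescue_percentages <- function(table, group) {
  r <- it_row(table, group)
  if (r$n_mice_with_embryos < 1 || r$n_embryos_total < 1)
    stop("zero denominator in group ", group)
  mouse <- 100 * r$n_mice_with_IS / r$n_mice_with_embryos
  embryo <- 100 * r$n_embryos_implanted / r$n_embryos_total
  list(mouse_level_pct = mouse, embryo_level_pct = embryo,
       mouse_level_display = round(mouse), embryo_level_display = round(embryo))
}
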