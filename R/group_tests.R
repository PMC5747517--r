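#' F-test for equality of variances
#'
#' Two-sided F-test comparing the variances of two samples:
#' `F = s_a^2 / s_b^2` referred to the F distribution with
#' `(n_a - 1, n_b - 1)` degrees of freedom (via [stats::var.test()]).
#' This is the test used to compare the spread of period and acrophase
#' distributions between genotypes.
#'
#' @param a,b numeric samples with at least 2 observations each.
#' @return List with `F`, `df`, `p_value`.
#' @export
variance_f_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations")
  if (stats::var(b) == 0) stop("denominator sample has zero variance")
  vt <- stats::var.test(a, b)
  list(F = unname(vt$statistic), df = unname(vt$parameter),
       p_value = unname(vt$p.value))
}

#' Pairwise group comparisons
#'
#' `method = "t_test"` performs Student's two-sample two-sided t-tests
#' (pooled variance) on every pair of groups. `method = "tukey"` fits a
#' one-way ANOVA and applies Tukey's HSD over all pairs.
#'
#' @param groups named list of numeric vectors, one per group; at least 2
#'   groups with at least 2 observations each.
#' @param method `"t_test"` (default) or `"tukey"`.
#' @return Data frame with one row per comparison: `group1`, `group2`,
#'   `estimate` (mean difference, group2 - group1), `statistic`
#'   (t or Tukey's q via the underlying procedure), `p_value`, `method`.
#' @export
group_compare <- function(groups, method = c("t_test", "tukey")) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L)
    stop("`groups` must be a list of at least 2 samples")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, 0L) < 2L))
    stop("every group needs at least 2 observations")

  if (method == "t_test") {
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      tt <- stats::t.test(groups[[pr[2]]], groups[[pr[1]]],
                          var.equal = TRUE)
      data.frame(group1 = pr[1], group2 = pr[2],
                 estimate = mean(groups[[pr[2]]]) - mean(groups[[pr[1]]]),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 method = "t_test", stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }

  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  hsd <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
  cmp <- strsplit(rownames(hsd), "-", fixed = TRUE)
  data.frame(group1 = vapply(cmp, `[`, "", 2),
             group2 = vapply(cmp, `[`, "", 1),
             estimate = unname(hsd[, "diff"]),
             statistic = NA_real_,
             p_value = unname(hsd[, "p adj"]),
             method = "tukey", stringsAsFactors = FALSE)
}
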