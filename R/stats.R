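#' Welch's t-test between two groups of per-cell medians
#'
#' Two-sided unequal-variance t-test, the comparison used for plasma
#' membrane vs organelle median ratios. A paired t-test on the same cells
#' is available behind `paired = TRUE` for sensitivity analyses.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param paired Use a paired t-test instead (vectors must align by cell).
#' @return A `test_result` list: `method`, `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(group_a, group_b, paired = FALSE) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  if (stats::var(group_a) + stats::var(group_b) <= 0)
    stop("both groups have zero variance: t undefined", call. = FALSE)
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE, paired = paired)
  structure(list(method = if (paired) "paired_t" else "welch_t",
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b)),
            class = "test_result")
}

#' One-way ANOVA with Tukey's HSD pairwise comparisons
#'
#' Fixed-effects one-way ANOVA across labeled groups (here, PM-normalized
#' per-cell medians per organelle), followed by Tukey's honestly
#' significant difference test on all pairs using the studentized-range
#' distribution (Tukey-Kramer correction for unequal group sizes, as
#' implemented by [stats::TukeyHSD()]). Pairwise results are reported
#' regardless of the ANOVA outcome but flagged when the between-group
#' effect is not significant at 0.05.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with `anova` (a `test_result`), `pairwise` (data frame:
#'   `pair`, `diff`, `lwr`, `upr`, `p_value`, `stars`), and
#'   `anova_significant` (logical flag at alpha = 0.05).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named", call. = FALSE)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2))
    stop("group(s) with n < 2: ", paste(names(groups)[ns < 2], collapse = ", "),
         call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  if (sum(vapply(groups, stats::var, double(1))) <= 0)
    stop("zero within-group variance in every group: F undefined", call. = FALSE)
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  anova_res <- structure(list(method = "anova",
                              statistic = an[["F value"]][1],
                              df = c(df_between = an[["Df"]][1],
                                     df_within = an[["Df"]][2]),
                              p_value = an[["Pr(>F)"]][1]),
                         class = "test_result")
  tk <- stats::TukeyHSD(fit)$g
  pairwise <- data.frame(pair = rownames(tk),
                         diff = tk[, "diff"], lwr = tk[, "lwr"],
                         upr = tk[, "upr"], p_value = tk[, "p adj"],
                         row.names = NULL)
  pairwise$stars <- p_stars(pairwise$p_value)
  list(anova = anova_res, pairwise = pairwise,
       anova_significant = anova_res$p_value < 0.05)
}

#' Group summary with the violin-plot statistics
#'
#' n, mean, SD, and median with quartiles (type-7 quantiles, the same
#' convention as [region_stats()]).
#'
#' @param values Non-empty numeric vector.
#' @param label Group label.
#' @return A `group_summary` list.
#' @export
summarize_group <- function(values, label = "group") {
  values <- as.numeric(values)
  if (!length(values)) stop("empty group", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(label = label, n = length(values), mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else 0,
                 median = q[2], q1 = q[1], q3 = q[3]),
            class = "group_summary")
}

#' Significance stars
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001,
#' `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' @export
print.test_result <- function(x, ...) {
  df <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.3g %s\n",
              x$method, x$statistic, df, x$p_value, p_stars(x$p_value)))
  invisible(x)
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, mean = %.4g +/- %.4g, median %.4g [%.4g, %.4g]\n",
              x$label, x$n, x$mean, x$sd, x$median, x$q1, x$q3))
  invisible(x)
}
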