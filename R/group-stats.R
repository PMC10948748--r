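# Group comparison layer: normality-driven two- and three-group tests,
# Bonferroni post hoc comparisons, and covariate-adjusted regression.

shapiro_ok <- function(x, alpha) {
  # Shapiro-Wilk is defined for 3..5000 observations; subsample huge
  # groups, and treat (near-)constant samples as non-normal.
  if (length(unique(x)) < 3) return(FALSE)
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  stats::shapiro.test(x)$p.value > alpha
}

#' Two-group comparison with normality-driven test selection
#'
#' Tests each group for normality (Shapiro-Wilk at `alpha_normal`,
#' applied per group); if both pass, a two-sided two-sample t-test
#' (Welch) is used, otherwise a two-sided Mann-Whitney U test. For the
#' U test, exact enumeration is used for small tieless samples
#' (both n <= 20) and the continuity-corrected normal approximation
#' otherwise.
#'
#' @param values_a,values_b Numeric samples (each n >= 3).
#' @param alpha_normal Normality screening level (default 0.05).
#' @param feature Optional feature label carried into the result.
#' @return List of class `comparison_result`: `feature`, `test_used`
#'   (`"t"` or `"mann_whitney"`), `statistic`, `p`, `p_corrected`
#'   (`NA` here), `group_summaries`, `degenerate`.
#' @export
compare_two_groups <- function(values_a, values_b, alpha_normal = 0.05,
                               feature = NA_character_) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs n >= 3", call. = FALSE)
  degenerate <- stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
    values_a[1] == values_b[1]
  normal <- shapiro_ok(values_a, alpha_normal) &&
    shapiro_ok(values_b, alpha_normal)
  if (degenerate) {
    test_used <- "degenerate"; statistic <- 0; p <- 1
  } else if (normal) {
    ht <- stats::t.test(values_a, values_b)
    test_used <- "t"; statistic <- unname(ht$statistic); p <- ht$p.value
  } else {
    exact <- length(values_a) <= 20 && length(values_b) <= 20 &&
      !any(duplicated(c(values_a, values_b)))
    ht <- stats::wilcox.test(values_a, values_b, exact = exact,
                             correct = TRUE)
    test_used <- "mann_whitney"
    statistic <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(feature = feature, test_used = test_used,
                 statistic = statistic, p = p, p_corrected = NA_real_,
                 group_summaries = data.frame(
                   group = c("a", "b"),
                   n = c(length(values_a), length(values_b)),
                   mean = c(mean(values_a), mean(values_b)),
                   sd = c(stats::sd(values_a), stats::sd(values_b))),
                 degenerate = degenerate),
            class = "comparison_result")
}

#' Three-group comparison with Bonferroni post hoc tests
#'
#' Omnibus test selected by per-group normality: one-way ANOVA when all
#' three groups pass Shapiro-Wilk, Kruskal-Wallis otherwise. Pairwise
#' post hoc tests use the matching two-group test (t or Mann-Whitney)
#' and their p-values are Bonferroni-corrected (multiplied by the number
#' of comparisons, capped at 1).
#'
#' @param control,remitted,nonremitted Numeric samples (each n >= 3).
#' @param alpha_normal Normality screening level.
#' @param feature Optional feature label.
#' @return List of class `comparison_result` with `test_used`
#'   (`"anova"` or `"kruskal_wallis"`), omnibus `statistic` and `p`, and
#'   a `post_hoc` data.frame (pair, raw `p`, `p_corrected`).
#' @export
compare_three_groups <- function(control, remitted, nonremitted,
                                 alpha_normal = 0.05,
                                 feature = NA_character_) {
  groups <- list(control = control, remitted = remitted,
                 non_remitted = nonremitted)
  if (any(vapply(groups, length, integer(1)) < 3))
    stop("each group needs n >= 3", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  normal <- all(vapply(groups, shapiro_ok, logical(1), alpha_normal))
  if (stats::sd(x) == 0) {
    test_used <- "degenerate"; statistic <- 0; p <- 1
  } else if (normal) {
    av <- stats::oneway.test(x ~ g, var.equal = TRUE)
    test_used <- "anova"; statistic <- unname(av$statistic)
    p <- av$p.value
  } else {
    kw <- stats::kruskal.test(x, g)
    test_used <- "kruskal_wallis"; statistic <- unname(kw$statistic)
    p <- kw$p.value
  }
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  post <- do.call(rbind, lapply(pairs, function(pr) {
    cmp <- compare_two_groups(groups[[pr[1]]], groups[[pr[2]]],
                              alpha_normal)
    data.frame(pair = paste(pr, collapse = " vs "), test = cmp$test_used,
               p = cmp$p, p_corrected = min(1, cmp$p * length(pairs)))
  }))
  structure(list(feature = feature, test_used = test_used,
                 statistic = statistic, p = p,
                 p_corrected = NA_real_, post_hoc = post,
                 group_summaries = data.frame(
                   group = names(groups),
                   n = vapply(groups, length, integer(1)),
                   mean = vapply(groups, mean, numeric(1)),
                   sd = vapply(groups, stats::sd, numeric(1)))),
            class = "comparison_result")
}

#' Chi-square test for categorical group differences
#'
#' Pearson chi-square on a contingency table, without continuity
#' correction (the classical formula).
#'
#' @param tab A matrix or table of counts.
#' @return List `statistic`, `df`, `p`.
#' @export
compare_categorical <- function(tab) {
  ht <- stats::chisq.test(as.table(as.matrix(tab)), correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Age- and sex-adjusted group effect on a feature
#'
#' Ordinary least squares of the feature on group indicators plus age
#' and sex, the standard adjustment when groups are not demographically
#' matched. Returns the group coefficients with standard errors,
#' two-sided p-values, and 95% confidence intervals.
#'
#' @param feature Numeric response, one value per subject.
#' @param group Factor/character of group labels (first level is the
#'   reference).
#' @param age Numeric age in years.
#' @param sex Factor/character sex.
#' @return data.frame with one row per non-reference group level:
#'   `term`, `estimate`, `se`, `p`, `ci_lo`, `ci_hi`.
#' @export
adjusted_group_effect <- function(feature, group, age, sex) {
  df <- data.frame(y = feature, group = factor(group), age = age,
                   sex = factor(sex))
  if (nrow(df) <= nlevels(df$group) + nlevels(df$sex) + 1)
    stop("too few observations for the adjusted model", call. = FALSE)
  fit <- stats::lm(y ~ group + age + sex, data = df)
  if (any(is.na(stats::coef(fit))))
    stop("collinear design in adjusted model", call. = FALSE)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  rows <- grep("^group", rownames(sm))
  data.frame(term = rownames(sm)[rows],
             estimate = sm[rows, 1], se = sm[rows, 2],
             p = sm[rows, 4],
             ci_lo = ci[rows, 1], ci_hi = ci[rows, 2],
             row.names = NULL)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s: %s, statistic %.4g, p = %.4g\n",
              if (is.na(x$feature)) "(feature)" else x$feature,
              x$test_used, x$statistic, x$p))
  invisible(x)
}

#' Feature-table group comparison report
#'
#' Runs [compare_two_groups()] on every feature column of a per-subject
#' feature table, producing a report in the familiar two-column
#' (group mean/SD, test, P) layout of case-control feature tables.
#'
#' @param features data.frame of per-subject features (numeric columns).
#' @param group Two-level grouping vector aligned with rows.
#' @param alpha_normal Normality screening level.
#' @return data.frame: feature, per-group mean/sd, test used, P.
#' @export
compare_feature_table <- function(features, group, alpha_normal = 0.05) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2)
  lv <- levels(group)
  rows <- lapply(names(features), function(f) {
    v <- features[[f]]
    ok <- is.finite(v)
    a <- v[ok & group == lv[1]]
    b <- v[ok & group == lv[2]]
    if (length(a) < 3 || length(b) < 3) return(NULL)
    cmp <- compare_two_groups(a, b, alpha_normal, feature = f)
    data.frame(feature = f,
               mean_1 = mean(a), sd_1 = stats::sd(a), n_1 = length(a),
               mean_2 = mean(b), sd_2 = stats::sd(b), n_2 = length(b),
               test = cmp$test_used, p = cmp$p)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  names(out)[2:7] <- c(paste0(c("mean_", "sd_", "n_"), lv[1]),
                       paste0(c("mean_", "sd_", "n_"), lv[2]))
  out
}
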