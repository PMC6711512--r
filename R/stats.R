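#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) skewness z and the Anscombe-Glynn (1983)
#' kurtosis z into the omnibus statistic `K2 = Zs^2 + Zk^2`, referred to a
#' chi-squared distribution with 2 degrees of freedom. Requires n >= 8 for
#' the kurtosis approximation to hold.
#'
#' @param x numeric sample.
#' @return list with `statistic` (K2), `p.value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop_input("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop_input("zero-variance sample")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness: D'Agostino (1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  g2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2,
       p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Normality gate for test dispatch
#'
#' Each group is screened with the Shapiro-Wilk test (n in 3..5000) and the
#' D'Agostino-Pearson omnibus test (n >= 8); under the default `"either"`
#' rule a group is called non-normal when either applicable test rejects at
#' `alpha`. The family verdict is `"nonparametric"` when any group is
#' non-normal or no test could be applied to some group (conservative
#' default), `"parametric"` otherwise.
#'
#' @param groups named list of numeric vectors.
#' @param alpha rejection level for the normality tests (default 0.05).
#' @param rule `"either"` (default: non-normal if either test rejects) or
#'   `"both"` (both applicable tests must reject).
#' @return list with `per_group` (data.frame of verdicts and p values) and
#'   `family` (`"parametric"` or `"nonparametric"`).
#' @export
normality_gate <- function(groups, alpha = 0.05,
                           rule = c("either", "both")) {
  rule <- match.arg(rule)
  stopifnot(is.list(groups), length(groups) >= 1)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    n <- length(x)
    p_sw <- if (n >= 3 && n <= 5000 && stats::sd(x) > 0)
      stats::shapiro.test(x)$p.value else NA_real_
    p_dp <- if (n >= 8 && stats::sd(x) > 0)
      dagostino_test(x)$p.value else NA_real_
    ps <- c(p_sw, p_dp)
    applicable <- !is.na(ps)
    verdict <- if (!any(applicable)) "indeterminate"
    else {
      rej <- ps[applicable] < alpha
      nn <- if (rule == "either") any(rej) else all(rej)
      if (nn) "non-normal" else "normal"
    }
    data.frame(group = g, n = n, shapiro_p = p_sw, dagostino_p = p_dp,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  per_group <- do.call(rbind, rows)
  family <- if (any(per_group$verdict != "normal")) "nonparametric"
  else "parametric"
  list(per_group = per_group, family = family, alpha = alpha, rule = rule)
}

test_report <- function(test_name, statistic, p_value, correction = "none",
                        comparisons = NULL, normality = NULL, alpha = 0.05) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, correction = correction,
                 comparisons = comparisons, normality = normality,
                 alpha = alpha),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (correction: %s)\n",
              x$test_name, x$statistic, x$p_value, x$correction))
  if (!is.null(x$comparisons)) print(x$comparisons)
  invisible(x)
}

#' Two-group comparison under the dispatch policy
#'
#' Runs an unpaired two-sample t test when the family verdict is parametric
#' and a two-sided Mann-Whitney (Wilcoxon rank-sum) test otherwise. When
#' `family` is omitted it is determined by [normality_gate()].
#'
#' @param g1,g2 numeric vectors.
#' @param family `"parametric"`, `"nonparametric"`, or `NULL` to gate.
#' @param alpha reporting level.
#' @param var_equal use the pooled-variance (ordinary) t test (default TRUE).
#' @return a `test_report`.
#' @export
compare_two <- function(g1, g2, family = NULL, alpha = 0.05,
                        var_equal = TRUE) {
  if (length(g1) == 0 || length(g2) == 0)
    stop_input("both groups must be nonempty")
  pooled <- c(g1, g2)
  if (stats::sd(pooled) == 0)
    stop_input("degenerate data: all values identical")
  gate <- NULL
  if (is.null(family)) {
    gate <- normality_gate(list(g1 = g1, g2 = g2), alpha = alpha)
    family <- gate$family
  }
  if (family == "parametric") {
    tt <- stats::t.test(g1, g2, var.equal = var_equal)
    test_report("unpaired t test", unname(tt$statistic), tt$p.value,
                normality = gate, alpha = alpha)
  } else {
    wt <- stats::wilcox.test(g1, g2, exact = FALSE, correct = TRUE)
    test_report("Mann-Whitney test", unname(wt$statistic), wt$p.value,
                normality = gate, alpha = alpha)
  }
}

# Dunn's z test on the pooled ranks, with tie correction
dunn_pairwise <- function(values, labels, pairs) {
  n_total <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_total - 1))
  mean_ranks <- tapply(rk, labels, mean)
  ns <- table(labels)
  do.call(rbind, lapply(pairs, function(p) {
    i <- p[1]; j <- p[2]
    sigma <- sqrt((n_total * (n_total + 1) / 12 - tie_term) *
                    (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (mean_ranks[[i]] - mean_ranks[[j]]) / sigma
    data.frame(group1 = i, group2 = j, statistic = z,
               p_raw = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
}

#' Multi-group comparison under the dispatch policy
#'
#' Parametric branch: one-way ANOVA omnibus, then pairwise pooled-variance t
#' tests (pooled MSE, residual df) among the requested comparisons with
#' Bonferroni correction (family size = number of requested pairs).
#' Nonparametric branch: Kruskal-Wallis omnibus, then Dunn's rank z tests
#' with the same Bonferroni-style family correction. Only explicitly
#' requested pairs are tested — there is no all-pairs default.
#'
#' @param groups named list (length >= 3) of numeric vectors.
#' @param family `"parametric"`, `"nonparametric"`, or `NULL` to gate.
#' @param comparisons list of length-2 character vectors naming the relevant
#'   group pairs; empty list gives the omnibus test only.
#' @param alpha reporting level.
#' @return a `test_report`; `comparisons` holds the pairwise table with raw
#'   and corrected p values.
#' @export
compare_multi <- function(groups, family = NULL, comparisons = list(),
                          alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 3, !is.null(names(groups)))
  bad <- setdiff(unlist(comparisons), names(groups))
  if (length(bad) > 0)
    stop_input("unknown group(s) in comparisons: ", paste(bad, collapse = ", "))
  gate <- NULL
  if (is.null(family)) {
    gate <- normality_gate(groups, alpha = alpha)
    family <- gate$family
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  m <- length(comparisons)

  if (family == "parametric") {
    fit <- stats::aov(values ~ labels)
    an <- summary(fit)[[1]]
    omni_p <- an[["Pr(>F)"]][1]
    omni_f <- an[["F value"]][1]
    cmp <- NULL
    if (m > 0) {
      mse <- an[["Mean Sq"]][2]
      df_res <- an[["Df"]][2]
      ns <- table(labels)
      mus <- tapply(values, labels, mean)
      cmp <- do.call(rbind, lapply(comparisons, function(p) {
        se <- sqrt(mse * (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
        tstat <- (mus[[p[1]]] - mus[[p[2]]]) / se
        praw <- 2 * stats::pt(-abs(tstat), df_res)
        data.frame(group1 = p[1], group2 = p[2], statistic = tstat,
                   p_raw = praw, stringsAsFactors = FALSE)
      }))
      cmp$p_adjusted <- pmin(1, cmp$p_raw * m)
    }
    test_report("one-way ANOVA + Bonferroni", omni_f, omni_p,
                correction = if (m > 0) "Bonferroni" else "none",
                comparisons = cmp, normality = gate, alpha = alpha)
  } else {
    kw <- stats::kruskal.test(values, labels)
    cmp <- NULL
    if (m > 0) {
      cmp <- dunn_pairwise(values, labels, comparisons)
      cmp$p_adjusted <- pmin(1, cmp$p_raw * m)
    }
    test_report("Kruskal-Wallis + Dunn's", unname(kw$statistic), kw$p.value,
                correction = if (m > 0) "Dunn" else "none",
                comparisons = cmp, normality = gate, alpha = alpha)
  }
}

#' One-sample t test against a reference value
#'
#' Used e.g. to ask whether a set of per-trial preference-index differences
#' departs from zero.
#'
#' @param x numeric sample (n >= 2 with nonzero variance).
#' @param mu0 null value (default 0).
#' @param alpha reporting level.
#' @return a `test_report`.
#' @export
one_sample_test <- function(x, mu0 = 0, alpha = 0.05) {
  if (length(x) < 2) stop_input("one-sample test requires n >= 2")
  if (stats::sd(x) == 0) stop_input("degenerate data: zero variance")
  tt <- stats::t.test(x, mu = mu0)
  test_report("one-sample t test", unname(tt$statistic), tt$p.value,
              alpha = alpha)
}
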