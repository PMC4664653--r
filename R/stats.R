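# Normality-gated region comparisons: t-test / Mann-Whitney for two groups,
# one-way ANOVA + Tukey HSD / Kruskal-Wallis + Dunn (Holm) for three or
# more. Alpha is fixed at 0.05 throughout.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe-Glynn 1983) statistics into K2 = Z1^2 + Z2^2, referred to a
#' chi-squared distribution with 2 df. Requires n >= 8.
#'
#' @param x Numeric vector, n >= 8, non-constant.
#' @return List with `statistic` (K2), `p_value`, `n`.
#' @export
dagostino_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) stop("constant sample")
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2

  # skewness component
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * asinh(Y / alpha)

  # kurtosis component
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eb2) / sqrt(Vb2)
  B <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / B * (2 / B + sqrt(1 + 4 / B^2))
  u <- (1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4)))
  Z2 <- ((1 - 2 / (9 * A)) - sign(u) * abs(u)^(1 / 3)) / sqrt(2 / (9 * A))

  K2 <- Z1^2 + Z2^2
  list(statistic = K2,
       p_value = stats::pchisq(K2, df = 2, lower.tail = FALSE), n = n)
}

#' Gaussian-fit gate per group
#'
#' Tests each group for consistency with a Gaussian distribution at alpha =
#' 0.05; the gate decides between the parametric and nonparametric
#' comparison paths. The default test is D'Agostino-Pearson (the convention
#' of interactive graphing software); Shapiro-Wilk is selectable and is also
#' the automatic fallback for 3 <= n < 8, where the D'Agostino-Pearson
#' approximations are unreliable. Groups with n < 3 or constant values fail
#' closed (nonparametric path) with a warning.
#'
#' @param groups Named list of numeric vectors.
#' @param test `"dagostino"` or `"shapiro"`.
#' @param alpha Gate significance level (0.05).
#' @return Data frame: `group`, `n`, `p_value`, `normal`, `test_used`.
#' @export
normality_gate <- function(groups, test = c("dagostino", "shapiro"),
                           alpha = 0.05) {
  test <- match.arg(test)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  rows <- lapply(names(groups), function(nm) {
    x <- groups[[nm]][is.finite(groups[[nm]])]
    n <- length(x)
    if (n < 3L) {
      warning("group '", nm, "' has n < 3; normality gate fails closed")
      return(data.frame(group = nm, n = n, p_value = NA_real_,
                        normal = FALSE, test_used = "none"))
    }
    if (stats::sd(x) == 0) {
      warning("group '", nm, "' is constant; normality gate fails closed")
      return(data.frame(group = nm, n = n, p_value = NA_real_,
                        normal = FALSE, test_used = "none"))
    }
    use <- if (test == "dagostino" && n >= 8L) "dagostino" else "shapiro"
    p <- if (use == "dagostino") dagostino_test(x)$p_value
         else stats::shapiro.test(x)$p.value
    data.frame(group = nm, n = n, p_value = p, normal = p >= alpha,
               test_used = use)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.mann_whitney <- function(a, b) {
  exact <- (length(a) + length(b)) <= 20L &&
    !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
}

#' Compare two groups with a normality-gated test
#'
#' If both groups pass the Gaussian gate, an unpaired two-sided t-test
#' (equal variances) is used; otherwise a two-sided Mann-Whitney test,
#' exact for combined n <= 20 without ties and normal-approximated (with
#' continuity and tie correction) otherwise. The path can be forced via
#' `method`.
#'
#' @param a,b Numeric samples (each n >= 2, non-empty).
#' @param labels Group labels for reporting.
#' @param normality Gate test, see [normality_gate()].
#' @param method `"auto"` (gate decides), `"t"`, or `"mann-whitney"`.
#' @param alpha Significance level (0.05).
#' @return List of class `stat_result`: `test_name`, `groups`, `statistic`,
#'   `p_value`, `alpha`, `gate`.
#' @export
compare_two <- function(a, b, labels = c("A", "B"),
                        normality = c("dagostino", "shapiro"),
                        method = c("auto", "t", "mann-whitney"),
                        alpha = 0.05) {
  method <- match.arg(method)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(a) < 2L || length(b) < 2L) stop("both groups need n >= 2")
  gate <- suppressWarnings(
    normality_gate(stats::setNames(list(a, b), labels),
                   test = match.arg(normality), alpha = alpha))
  use_t <- switch(method, auto = all(gate$normal), t = TRUE,
                  `mann-whitney` = FALSE)
  if (use_t) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(test_name = "t-test", statistic = unname(ht$statistic),
                p_value = ht$p.value)
  } else {
    ht <- .mann_whitney(a, b)
    res <- list(test_name = "Mann-Whitney", statistic = unname(ht$statistic),
                p_value = ht$p.value)
  }
  structure(c(res, list(groups = labels, alpha = alpha, gate = gate)),
            class = "stat_result")
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean pooled ranks with the standard tie
#' correction; two-sided p-values are Holm-adjusted across all pairs.
#'
#' @param groups Named list of numeric vectors.
#' @return Data frame: `comparison`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(groups) {
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    data.frame(comparison = paste(i, "vs", j), z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  rownames(out) <- NULL
  out
}

#' Compare three or more groups with a normality-gated test
#'
#' If every group passes the Gaussian gate, a one-way ANOVA with Tukey HSD
#' pairwise comparisons is used; otherwise a Kruskal-Wallis omnibus test
#' with Dunn's pairwise post hoc (Holm-adjusted). The path can be forced via
#' `method`.
#'
#' @param groups Named list of >= 3 numeric vectors (each n >= 2).
#' @inheritParams compare_two
#' @param method `"auto"`, `"anova"`, or `"kruskal"`.
#' @return List of class `stat_result`: `test_name`, `statistic` (omnibus),
#'   `p_value` (omnibus), `pairwise` (data frame with adjusted p-values),
#'   `alpha`, `gate`.
#' @export
compare_many <- function(groups, normality = c("dagostino", "shapiro"),
                         method = c("auto", "anova", "kruskal"),
                         alpha = 0.05) {
  method <- match.arg(method)
  if (length(groups) < 3L)
    stop("fewer than 3 groups: use compare_two()")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, function(x) x[is.finite(x)])
  if (any(lengths(groups) < 2L)) stop("every group needs n >= 2")
  gate <- suppressWarnings(
    normality_gate(groups, test = match.arg(normality), alpha = alpha))
  use_anova <- switch(method, auto = all(gate$normal), anova = TRUE,
                      kruskal = FALSE)
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups)),
                                  levels = names(groups)))
  if (use_anova) {
    fit <- stats::aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$group
    pairwise <- data.frame(
      comparison = sub("-", " vs ", rownames(tk), fixed = TRUE),
      difference = tk[, "diff"], p_adjusted = tk[, "p adj"])
    rownames(pairwise) <- NULL
    res <- list(test_name = "one-way ANOVA + Tukey",
                statistic = an[["F value"]][1],
                p_value = an[["Pr(>F)"]][1], pairwise = pairwise)
  } else {
    kw <- stats::kruskal.test(value ~ group, data = df)
    res <- list(test_name = "Kruskal-Wallis + Dunn",
                statistic = unname(kw$statistic), p_value = kw$p.value,
                pairwise = dunn_test(groups))
  }
  structure(c(res, list(groups = names(groups), alpha = alpha, gate = gate)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test_name, ": statistic = ", signif(x$statistic, 4),
      ", p = ", format.pval(x$p_value, digits = 3),
      " (alpha = ", x$alpha, ")\n", sep = "")
  if (!is.null(x$pairwise)) {
    cat("Pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
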