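# Classical test selection mirroring the study's decision tree:
#   two groups:  t (normal + homoscedastic) / Welch (normal only) /
#                Mann-Whitney (not normal)
#   > 2 groups:  one-way ANOVA (assumptions met) / Kruskal-Wallis, with
#                pairwise Mann-Whitney follow-up when KW p <= 0.05
#   correlation: Pearson (bivariate normal) / Spearman otherwise
# Homoscedasticity via F test (2 groups) or Bartlett (> 2); when it fails,
# the data are log-transformed and re-checked. Normality was judged from QQ
# plots in the study; the automated default here is per-group Shapiro-Wilk
# at alpha = 0.05, overridable by explicit flags.

test_result <- function(test, statistic, df = NA_real_, p, transform = "none",
                        pairwise = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p = unname(p), transform = transform,
                 pairwise = pairwise),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: stat=%.4g%s, p=%.4g%s\n", x$test,
              x$statistic,
              if (all(is.na(x$df))) "" else
                paste0(", df=", paste(signif(x$df, 4), collapse = ",")),
              x$p,
              if (x$transform != "none") paste0(" (", x$transform, ")") else ""))
  if (!is.null(x$pairwise)) {
    cat("  pairwise Mann-Whitney:\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' Check normality and homoscedasticity for grouped data
#'
#' Normality: Shapiro-Wilk per group at `alpha` (all groups must pass).
#' Homoscedasticity: F test for two groups, Bartlett for more. If variances
#' are heterogeneous and all values are positive, the check is repeated on
#' log-transformed data; when the log scale passes, `transform = "log"` is
#' reported and the flags refer to the log scale.
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 3.
#' @param alpha Significance level for both checks (default 0.05).
#' @param try_log Attempt the log-transform branch (default TRUE).
#' @return List: `normal`, `homoscedastic` (logicals), `transform`
#'   (`"none"`/`"log"`), `log_unavailable` (TRUE when a log rescue was
#'   wanted but non-positive values forbid it).
#' @export
check_assumptions <- function(groups, alpha = 0.05, try_log = TRUE) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("need a list of >= 2 groups")
  if (any(vapply(groups, length, 0L) < 3L))
    stopf("each group needs n >= 3")
  eval_scale <- function(gs) {
    normal <- all(vapply(gs, function(g) shapiro.test(g)$p.value, 0) > alpha)
    hom <- if (length(gs) == 2L) {
      var.test(gs[[1L]], gs[[2L]])$p.value > alpha
    } else {
      bartlett.test(gs)$p.value > alpha
    }
    list(normal = normal, homoscedastic = hom)
  }
  raw <- eval_scale(groups)
  out <- c(raw, list(transform = "none", log_unavailable = FALSE))
  if (!raw$homoscedastic && try_log) {
    if (all(unlist(groups) > 0)) {
      lg <- eval_scale(lapply(groups, log))
      if (lg$homoscedastic)
        out <- c(lg, list(transform = "log", log_unavailable = FALSE))
    } else {
      out$log_unavailable <- TRUE
    }
  }
  out
}

#' Mann-Whitney U with mid-rank ties
#'
#' U for the first sample (pairwise wins plus half-ties, computed from
#' mid-ranks). P-value: exact null distribution (`stats::pwilcox`) when
#' there are no ties and both n <= 20, otherwise the normal approximation
#' with tie-corrected variance and continuity correction. Two-sided.
#'
#' @param x,y Numeric samples.
#' @return A `test_result` with `test = "Mann-Whitney"` and the U statistic.
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stopf("each sample needs n >= 2")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && max(n1, n2) <= 20L) {
    # exact: P(U <= u) symmetric null, two-sided doubling capped at 1
    p_lo <- pwilcox(u, n1, n2)
    p_hi <- 1 - pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    z <- (u - mu - sign(u - mu) * 0.5) / sigma
    p <- 2 * pnorm(-abs(z))
  }
  test_result("Mann-Whitney", statistic = u, p = p)
}

#' Two-group test chosen by the decision tree
#'
#' Student t when normal and homoscedastic, Welch when normal only,
#' Mann-Whitney otherwise. `assumptions` defaults to [check_assumptions()]
#' on the data; pass explicit flags to reproduce a visual-QQ judgement.
#'
#' @param groups List of exactly 2 numeric vectors (each n >= 2).
#' @param assumptions Optional list with `normal`, `homoscedastic`, and
#'   optionally `transform` (`"log"` applies log before parametric tests).
#' @return A `test_result`.
#' @export
two_group_test <- function(groups, assumptions = NULL) {
  if (length(groups) != 2L) stopf("two_group_test needs exactly 2 groups")
  if (any(vapply(groups, length, 0L) < 2L)) stopf("each group needs n >= 2")
  if (is.null(assumptions)) assumptions <- check_assumptions(groups)
  tr <- if (identical(assumptions$transform, "log")) "log" else "none"
  g <- if (tr == "log") lapply(groups, log) else groups
  if (isTRUE(assumptions$normal) && isTRUE(assumptions$homoscedastic)) {
    ht <- t.test(g[[1L]], g[[2L]], var.equal = TRUE)
    test_result("t", ht$statistic, ht$parameter, ht$p.value, tr)
  } else if (isTRUE(assumptions$normal)) {
    ht <- t.test(g[[1L]], g[[2L]], var.equal = FALSE)
    test_result("Welch", ht$statistic, ht$parameter, ht$p.value, tr)
  } else {
    res <- mann_whitney(groups[[1L]], groups[[2L]])  # rank-based: raw scale
    res$transform <- "none"
    res
  }
}

#' Multi-group test chosen by the decision tree
#'
#' One-way ANOVA (equal variances) when normality and homoscedasticity hold,
#' Kruskal-Wallis otherwise; when Kruskal-Wallis gives p <= 0.05, all
#' pairwise Mann-Whitney comparisons are attached.
#'
#' @param groups Named list of >= 3 numeric vectors (each n >= 2); two
#'   groups are rejected (use [two_group_test()]).
#' @param assumptions As in [two_group_test()].
#' @return A `test_result`; `$pairwise` is a data.frame when attached.
#' @export
multi_group_test <- function(groups, assumptions = NULL) {
  if (length(groups) < 3L)
    stopf("multi_group_test needs >= 3 groups (use two_group_test for 2)")
  if (any(vapply(groups, length, 0L) < 2L)) stopf("each group needs n >= 2")
  if (is.null(assumptions)) assumptions <- check_assumptions(groups)
  tr <- if (identical(assumptions$transform, "log")) "log" else "none"
  g <- if (tr == "log") lapply(groups, log) else groups
  if (isTRUE(assumptions$normal) && isTRUE(assumptions$homoscedastic)) {
    y <- unlist(g)
    f <- factor(rep(seq_along(g), lengths(g)))
    ht <- oneway.test(y ~ f, var.equal = TRUE)
    test_result("ANOVA", ht$statistic, ht$parameter, ht$p.value, tr)
  } else {
    ht <- kruskal.test(groups)
    pw <- NULL
    if (ht$p.value <= 0.05) {
      nm <- names(groups)
      if (is.null(nm)) nm <- paste0("g", seq_along(groups))
      cmb <- utils::combn(seq_along(groups), 2L)
      pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
        i1 <- cmb[1, j]; i2 <- cmb[2, j]
        mw <- mann_whitney(groups[[i1]], groups[[i2]])
        data.frame(group_a = nm[i1], group_b = nm[i2],
                   U = mw$statistic, p = mw$p, stringsAsFactors = FALSE)
      }))
    }
    test_result("Kruskal-Wallis", ht$statistic, ht$parameter, ht$p.value,
                "none", pairwise = pw)
  }
}

#' Correlation test chosen by the decision tree
#'
#' Pearson's r with the t-approximation p-value when flagged bivariate
#' normal, otherwise Spearman's rho with its standard approximation
#' (two-sided throughout).
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param bivariate_normal Logical flag (judged externally, e.g. from QQ
#'   plots or marginal Shapiro-Wilk checks).
#' @return A `test_result` (`"Pearson"` or `"Spearman"`).
#' @export
correlation_test <- function(x, y, bivariate_normal = FALSE) {
  if (length(x) != length(y) || length(x) < 4L)
    stopf("x and y must have equal length >= 4")
  if (var(x) == 0 || var(y) == 0) stopf("zero variance input")
  if (isTRUE(bivariate_normal)) {
    ht <- cor.test(x, y, method = "pearson")
    test_result("Pearson", ht$estimate, ht$parameter, ht$p.value)
  } else {
    ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    test_result("Spearman", ht$estimate, p = ht$p.value)
  }
}
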