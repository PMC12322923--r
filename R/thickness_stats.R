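#' Data-driven selection of a group-comparison test
#'
#' Picks the conventional test for a categorical predictor from normality,
#' homoscedasticity, and the number of groups: Shapiro-Wilk per group
#' (alpha 0.05) for normality, median-centred Levene (alpha 0.05) for
#' equality of variances. All groups normal and homoscedastic gives the
#' pooled t-test (2 groups) or one-way ANOVA (> 2); normal but
#' heteroscedastic gives the Welch t-test / Welch ANOVA; any non-normal
#' group falls back to the Kruskal-Wallis H-test. With `paired = TRUE` and
#' two normal groups the paired t-test is used (variance equality is then
#' irrelevant).
#'
#' @param groups List of >= 2 numeric vectors, each with >= 3 observations.
#' @param paired Logical; only meaningful for two groups of equal length.
#' @param alpha Significance level for the assumption checks.
#' @return List with `test` (name), `statistic`, `p.value`, and the
#'   assumption-check details (`normal`, `homoscedastic`).
#' @export
#' @examples
#' set.seed(1)
#' select_group_test(list(rnorm(20), rnorm(20, 1)))
select_group_test <- function(groups, paired = FALSE, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 3L)) stop("every group needs at least 3 observations")
  k <- length(groups)
  if (paired && (k != 2L || sizes[1] != sizes[2]))
    stop("paired comparison requires two groups of equal length")

  normal <- all(vapply(groups, function(g) shapiro.test(g)$p.value,
                       numeric(1)) > alpha)
  y <- unlist(groups)
  g <- factor(rep(seq_len(k), sizes))
  lev <- car::leveneTest(y ~ g, center = stats::median)
  homoscedastic <- lev[["Pr(>F)"]][1] > alpha

  if (!normal) {
    ht <- kruskal.test(y, g)
    res <- list(test = "kruskal-wallis", statistic = unname(ht$statistic),
                p.value = ht$p.value)
  } else if (k == 2L) {
    if (paired) {
      ht <- t.test(groups[[1]], groups[[2]], paired = TRUE)
      res <- list(test = "paired t-test", statistic = unname(ht$statistic),
                  p.value = ht$p.value)
    } else if (homoscedastic) {
      ht <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      res <- list(test = "t-test", statistic = unname(ht$statistic),
                  p.value = ht$p.value)
    } else {
      ht <- t.test(groups[[1]], groups[[2]], var.equal = FALSE)
      res <- list(test = "welch t-test", statistic = unname(ht$statistic),
                  p.value = ht$p.value)
    }
  } else if (homoscedastic) {
    ht <- oneway.test(y ~ g, var.equal = TRUE)
    res <- list(test = "one-way anova", statistic = unname(ht$statistic),
                p.value = ht$p.value)
  } else {
    ht <- oneway.test(y ~ g, var.equal = FALSE)
    res <- list(test = "welch anova", statistic = unname(ht$statistic),
                p.value = ht$p.value)
  }
  c(res, list(normal = normal, homoscedastic = homoscedastic))
}

#' Fit a cortical-thickness OLS model with HC3 robust errors
#'
#' Fits thickness ~ age + sex (+ optional categorical vasculature term) by
#' ordinary least squares, reporting per-term estimates with
#' heteroscedasticity-consistent HC3 standard errors, t-based two-sided
#' p-values, and the adjusted R-squared. Categorical terms use treatment
#' coding; the reference levels follow the reporting convention of the
#' analysis: sex = female, vessel pattern = "3", dominance = "equal".
#'
#' @param data Data frame with columns `thickness_mm`, `age`, `sex`, plus
#'   the vascular column when requested.
#' @param vascular Optional name of a categorical vasculature column (e.g.
#'   `"pattern"`, an ACA or MCA dominance rating column); `NULL` fits the
#'   covariate-only (reduced) model.
#' @param covariates Covariate column names (default `c("age", "sex")`;
#'   `character(0)` gives an intercept-only model).
#' @return An object of class `thickness_fit`: list with `coefficients`
#'   (data frame: estimate, se (HC3), statistic, p.value), `adj_r_squared`,
#'   `n`, `lm` (the underlying fit), `formula`, `vascular`.
#' @export
fit_thickness_model <- function(data, vascular = NULL,
                                covariates = c("age", "sex")) {
  stopifnot(is.data.frame(data), "thickness_mm" %in% names(data))
  terms <- covariates
  if (!is.null(vascular)) {
    if (!vascular %in% names(data)) stop("no column '", vascular, "' in data")
    terms <- c(terms, vascular)
  }
  missing <- setdiff(terms, names(data))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  data <- set_reference_levels(data, c(intersect("sex", terms), vascular))
  if (!is.null(vascular) && nlevels(data[[vascular]]) < 2L)
    stop("vascular term '", vascular, "' has fewer than 2 observed levels")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fm <- stats::as.formula(paste("thickness_mm ~", rhs))
  fit <- lm(fm, data = data)
  if (any(is.na(coef(fit)))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  vc <- sandwich::vcovHC(fit, type = "HC3")
  est <- coef(fit)
  se <- sqrt(diag(vc))
  tval <- est / se
  df <- fit$df.residual
  pval <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), statistic = unname(tval),
                      p.value = unname(pval), stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 adj_r_squared = summary(fit)$adj.r.squared,
                 n = stats::nobs(fit), lm = fit, formula = fm,
                 vascular = vascular, data = data),
            class = "thickness_fit")
}

set_reference_levels <- function(data, cols) {
  refs <- c(sex = "female", pattern = "3")
  for (col in cols) {
    x <- data[[col]]
    if (is.numeric(x) && identical(col, "pattern")) x <- as.character(x)
    if (!is.factor(x)) x <- factor(x)
    ref <- if (col %in% names(refs)) refs[[col]] else
      if ("equal" %in% levels(x)) "equal" else levels(x)[1]
    if (ref %in% levels(x)) x <- stats::relevel(x, ref = ref)
    data[[col]] <- x
  }
  data
}

#' @export
print.thickness_fit <- function(x, ...) {
  cat(sprintf("<thickness_fit> %s  (n = %d)\n", deparse(x$formula), x$n))
  printable <- x$coefficients
  printable$estimate <- signif(printable$estimate, 4)
  printable$se <- signif(printable$se, 4)
  printable$statistic <- signif(printable$statistic, 4)
  printable$p.value <- signif(printable$p.value, 4)
  print(printable, row.names = FALSE)
  cat(sprintf("adjusted R-squared: %.4f   (HC3 robust standard errors)\n",
              x$adj_r_squared))
  invisible(x)
}

#' Compare nested thickness models by partial F-test
#'
#' Tests whether adding the vasculature term to the covariate-only model
#' significantly improves fit: the classic ANOVA comparison
#' `F = ((RSS_r - RSS_f) / (df_r - df_f)) / (RSS_f / df_f)` with the
#' corresponding F reference distribution. The reduced model's terms must
#' be a subset of the full model's, on the same rows.
#'
#' @param full,reduced `thickness_fit` objects from [fit_thickness_model()].
#' @return An object of class `thickness_comparison`: list with
#'   `F.statistic`, `df` (pair), `p.value`, and both adjusted R-squared
#'   values.
#' @export
compare_models <- function(full, reduced) {
  stopifnot(inherits(full, "thickness_fit"),
            inherits(reduced, "thickness_fit"))
  t_full <- attr(terms(full$lm), "term.labels")
  t_red <- attr(terms(reduced$lm), "term.labels")
  if (!all(t_red %in% t_full))
    stop("models are not nested: reduced terms must be a subset of full terms")
  if (full$n != reduced$n)
    stop("models were fitted on different numbers of rows")
  rss_f <- sum(residuals(full$lm)^2)
  rss_r <- sum(residuals(reduced$lm)^2)
  df_f <- full$lm$df.residual
  df_r <- reduced$lm$df.residual
  ddf <- df_r - df_f
  if (ddf == 0L) {
    fstat <- 0; p <- 1
  } else {
    fstat <- ((rss_r - rss_f) / ddf) / (rss_f / df_f)
    fstat <- max(fstat, 0)
    p <- pf(fstat, ddf, df_f, lower.tail = FALSE)
  }
  structure(list(F.statistic = fstat, df = c(ddf, df_f), p.value = p,
                 adj_r_squared_full = full$adj_r_squared,
                 adj_r_squared_reduced = reduced$adj_r_squared),
            class = "thickness_comparison")
}

#' @export
print.thickness_comparison <- function(x, ...) {
  cat(sprintf("<thickness_comparison> F(%d, %d) = %.3f, p = %.4f\n",
              x$df[1], x$df[2], x$F.statistic, x$p.value))
  cat(sprintf("adjusted R-squared: reduced %.3f, full %.3f\n",
              x$adj_r_squared_reduced, x$adj_r_squared_full))
  invisible(x)
}

#' Covariate-adjusted thickness values
#'
#' Removes linear covariate effects while preserving the baseline level:
#' each observation becomes the reduced-model intercept plus its residual.
#' The mean of the adjusted values equals the intercept, and the residual
#' variance is untouched, so group comparisons on the adjusted values
#' reflect what the covariate-adjusted model sees.
#'
#' @param fit A `thickness_fit` (normally the reduced, covariate-only
#'   model).
#' @return Numeric vector of adjusted thickness values, one per row of the
#'   fitted data.
#' @export
adjust_thickness <- function(fit) {
  stopifnot(inherits(fit, "thickness_fit"))
  unname(coef(fit$lm)[["(Intercept)"]] + residuals(fit$lm))
}
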