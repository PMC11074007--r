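#' Fit per-peptide linear models for a two-group contrast
#'
#' Ordinary least squares per peptide on its observed samples only, with a
#' model of intercept + group (+ optional additive covariates from the
#' design). The reported effect is the group coefficient, i.e. the log2
#' fold change test minus reference.
#'
#' Peptides observable in fewer than 2 samples per group, or with fewer
#' residual degrees of freedom than 1, are flagged (`ok = FALSE`) rather
#' than silently dropped; flagged peptides carry `NA` effects and are
#' excluded from downstream sets and backgrounds.
#'
#' @param table a [peptide_quant_table()].
#' @param design a [design_spec()] covering every sample of `table`.
#' @return object of class `PeptideFitResult`: a list with per-peptide
#'   vectors `effect`, `sigma2`, `df_resid`, `se_unscaled` (the
#'   design-dependent standard-error factor so that
#'   `se = se_unscaled * sigma`), logical `ok`, plus `peptide_ids`,
#'   `protein_map` and the `design` used.
#' @export
fit_peptides <- function(table, design) {
  stopifnot(inherits(table, "PeptideQuantTable"),
            inherits(design, "DesignSpec"))
  Y <- table$abundance
  X <- design_matrix(design, colnames(Y))
  fit <- fit_matrix(Y, X)
  structure(
    c(fit,
      list(peptide_ids = rownames(Y),
           protein_map = table$protein_map,
           design = design)),
    class = "PeptideFitResult")
}

#' @export
print.PeptideFitResult <- function(x, ...) {
  cat(sprintf("PeptideFitResult: %d peptides (%d estimable)",
              length(x$effect), sum(x$ok)))
  if (!is.null(x$d0))
    cat(sprintf(", prior df %.3g, prior variance %.3g",
                x$d0, if (length(x$s0_2) == 1L) x$s0_2 else mean(x$s0_2)))
  cat("\n")
  invisible(x)
}

# OLS of every row of Y on design matrix X (observed cells only).
# Shared by the peptide-level and the aggregated protein-level fits.
# Fast vectorized branch for the ubiquitous intercept+group model;
# row-wise lm fallback when covariates are present.
fit_matrix <- function(Y, X) {
  p <- ncol(X)
  g <- X[, "group"]
  obs <- !is.na(Y)
  n1 <- rowSums(obs[, g == 1, drop = FALSE])
  n0 <- rowSums(obs[, g == 0, drop = FALSE])
  n <- n0 + n1
  ok <- n0 >= 2L & n1 >= 2L & (n - p) >= 1L
  eff <- s2 <- u <- rep(NA_real_, nrow(Y))
  df <- rep(0, nrow(Y))
  if (p == 2L) {
    m1 <- rowMeans(Y[, g == 1, drop = FALSE], na.rm = TRUE)
    m0 <- rowMeans(Y[, g == 0, drop = FALSE], na.rm = TRUE)
    rss <- rowSums((Y[, g == 1, drop = FALSE] - m1)^2, na.rm = TRUE) +
      rowSums((Y[, g == 0, drop = FALSE] - m0)^2, na.rm = TRUE)
    eff[ok] <- (m1 - m0)[ok]
    df[ok] <- (n - 2L)[ok]
    s2[ok] <- (rss / pmax(n - 2L, 1L))[ok]
    u[ok] <- sqrt(1 / n0 + 1 / n1)[ok]
  } else {
    for (i in which(ok)) {
      sel <- obs[i, ]
      Xi <- X[sel, , drop = FALSE]
      q <- qr(Xi)
      if (q$rank < p || (sum(sel) - p) < 1L) {
        ok[i] <- FALSE
        next
      }
      f <- stats::lm.fit(Xi, Y[i, sel])
      eff[i] <- f$coefficients["group"]
      df[i] <- f$df.residual
      s2[i] <- sum(f$residuals^2) / f$df.residual
      XtXinv <- chol2inv(qr.R(q))
      u[i] <- sqrt(XtXinv[match("group", colnames(Xi)),
                          match("group", colnames(Xi))])
    }
  }
  list(effect = eff, sigma2 = s2, df_resid = df, se_unscaled = u, ok = ok)
}

#' Empirical-Bayes shrinkage of residual variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_2`
#' of the scaled inverse chi-square prior by matching the first two
#' moments of `log(sigma2)` to its scaled-F sampling model
#' (digamma/trigamma matching), then forms the posterior variance
#' `s2_post = (d0 * s0_2 + df * sigma2) / (d0 + df)`.
#'
#' With `trend_covariate` (used by the aggregation comparators, where the
#' covariate is the log peptide count per protein) the prior variance
#' becomes a smooth lowess function of the covariate.
#'
#' When the variance of the log variances falls below its pure sampling
#' value, `d0` is reported as `Inf` and every posterior variance equals the
#' common prior value.
#'
#' @param fit a `PeptideFitResult` from [fit_peptides()], or any list with
#'   numeric `sigma2`, `df_resid` and logical `ok`.
#' @param trend_covariate optional numeric covariate (same length as
#'   `sigma2`) for a lowess-smoothed prior variance.
#' @param prior_df optional forced value of `d0` (0 recovers the classical
#'   unmoderated t; `Inf` fully pools).
#' @param prior_var optional forced value of `s0_2` (scalar or
#'   per-peptide), used with `prior_df` to bypass estimation entirely.
#' @param span lowess span for the trend fit.
#' @return `fit` augmented with `d0`, `s0_2` (scalar, or per-unit under
#'   trend) and `s2_post`.
#' @export
empirical_bayes <- function(fit, trend_covariate = NULL, prior_df = NULL,
                            prior_var = NULL, span = 0.5) {
  sigma2 <- fit$sigma2
  df <- fit$df_resid
  use <- fit$ok & !is.na(sigma2) & df >= 1 & sigma2 > 0
  if (sum(use) < 2L)
    stop("empirical Bayes requires at least 2 peptides with positive ",
         "residual df")
  z <- log(sigma2[use])
  e <- z - digamma(df[use] / 2) + log(df[use] / 2)
  if (!is.null(trend_covariate)) {
    stopifnot(length(trend_covariate) == length(sigma2))
    # a degenerate covariate carries no trend information
    if (stats::var(trend_covariate[use]) == 0) trend_covariate <- NULL
  }
  if (is.null(trend_covariate)) {
    emean <- rep(mean(e), length(sigma2))
  } else {
    cv <- trend_covariate[use]
    {
      lo <- stats::lowess(cv, e, f = span)
      emean_use <- stats::approx(lo$x, lo$y, xout = cv, rule = 2, ties = mean)$y
      emean <- rep(NA_real_, length(sigma2))
      emean[use] <- emean_use
      # flagged units still need a prior: extrapolate flat
      if (any(!use))
        emean[!use] <- stats::approx(lo$x, lo$y, xout = trend_covariate[!use],
                                     rule = 2, ties = mean)$y
    }
  }
  if (!is.null(prior_df)) {
    d0 <- prior_df
    s0_2 <- if (!is.null(prior_var)) prior_var
            else if (is.finite(d0) && d0 > 0)
              exp(emean + digamma(d0 / 2) - log(d0 / 2))
            else if (is.finite(d0)) exp(emean)
            else rep(mean(sigma2[use]), length(sigma2))
  } else {
    n <- length(e)
    evar <- mean((e - emean[use])^2) * n / (n - 1) - mean(trigamma(df[use] / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # degenerate spread: variances carry no extra information beyond
      # their common value
      d0 <- Inf
      s0_2 <- if (is.null(trend_covariate)) rep(mean(sigma2[use]),
                                                length(sigma2))
              else exp(emean)
    }
  }
  if (length(unique(s0_2)) == 1L) s0_2 <- s0_2[1L]
  s0_vec <- rep_len(s0_2, length(sigma2))
  if (is.finite(d0)) {
    s2_post <- (d0 * s0_vec + df * ifelse(is.na(sigma2), 0, sigma2)) /
      (d0 + df)
    if (d0 == 0) s2_post <- sigma2
  } else {
    s2_post <- s0_vec
  }
  fit$d0 <- d0
  fit$s0_2 <- s0_2
  fit$s2_post <- s2_post
  fit
}

# Solve trigamma(x) = y by Newton iteration (monotone decreasing, convex).
# Tolerance 1e-8 on the step.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) break
  }
  x
}

#' Moderated t-statistics and p-values
#'
#' `t = effect / (se_unscaled * sqrt(s2_post))`, referred to a Student t
#' distribution on `d0 + df_resid` degrees of freedom (normal in the
#' `d0 = Inf` limit). Flagged peptides get `NA`.
#'
#' @param fit a `PeptideFitResult` that went through [empirical_bayes()].
#' @return `fit` augmented with `t_mod`, `df_total` and two-sided `p`.
#' @export
moderated_t <- function(fit) {
  if (is.null(fit$s2_post))
    stop("run empirical_bayes() before moderated_t()")
  t_mod <- fit$effect / (fit$se_unscaled * sqrt(fit$s2_post))
  t_mod[!fit$ok] <- NA_real_
  df_total <- fit$d0 + fit$df_resid
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[!fit$ok] <- NA_real_
  fit$t_mod <- t_mod
  fit$df_total <- df_total
  fit$p <- p
  fit
}

#' Export per-peptide results as a data.frame
#'
#' @param fit a fitted, moderated `PeptideFitResult`.
#' @return data.frame with peptide, proteins, logFC, t and p columns.
#' @export
peptide_results <- function(fit) {
  data.frame(
    peptide = fit$peptide_ids,
    protein = vapply(fit$protein_map, paste, "", collapse = ";"),
    logFC = fit$effect,
    t = fit$t_mod,
    p = fit$p,
    row.names = NULL, stringsAsFactors = FALSE)
}
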