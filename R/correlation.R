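#' Mixed-model estimate of the inter-peptide correlation
#'
#' Fits the linear mixed model `y_ij = X_j beta_i + r_j + e_ij` to the
#' peptides of one protein: peptide-specific fixed effects for every
#' design column (each peptide gets its own intercept and group effect), a
#' random intercept `r_j` per sample, and i.i.d. Gaussian errors. The
#' common inter-peptide correlation is the intraclass correlation
#' `rho = sigma_r2 / (sigma_r2 + sigma_e2)`, which is non-negative by
#' construction.
#'
#' Estimation is REML. For complete matrices the balanced-design
#' closed-form (ANOVA) estimator is used, which coincides with REML; with
#' missing cells (missing-at-random assumption) the REML criterion is
#' profiled down to the single variance ratio `lambda = sigma_r2 /
#' sigma_e2` and optimized on the log scale.
#'
#' @param x a `PeptideQuantTable` restricted to one protein, or a numeric
#'   matrix (peptides x samples) of log2 abundances.
#' @param design a [design_spec()]; `NULL` fits peptide means only.
#' @param protein_id accession recorded in the result.
#' @return object of class `CorrelationEstimate`: list with `protein_id`,
#'   `rho`, `sigma_r2`, `sigma_e2`, `n_peptides`, `method = "mixed"`,
#'   `converged`, `flag`.
#' @export
estimate_rho_mixed <- function(x, design = NULL, protein_id = NA_character_) {
  Y <- if (inherits(x, "PeptideQuantTable")) x$abundance else as.matrix(x)
  m <- nrow(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("s", seq_len(ncol(Y)))
  if (m < 2L)
    return(correlation_estimate(protein_id, rho = 0, sigma_r2 = 0,
                                sigma_e2 = NA_real_, n_peptides = m,
                                method = "mixed", converged = FALSE,
                                flag = "single_peptide"))
  X <- if (is.null(design)) {
    matrix(1, ncol(Y), 1L, dimnames = list(colnames(Y), "intercept"))
  } else {
    design_matrix(design, colnames(Y))
  }
  # drop samples with no observed peptide
  keep <- colSums(!is.na(Y)) > 0L
  Y <- Y[, keep, drop = FALSE]
  X <- X[keep, , drop = FALSE]
  if (!anyNA(Y)) {
    est <- rho_mixed_balanced(Y, X)
    return(correlation_estimate(protein_id, est$rho, est$sigma_r2,
                                est$sigma_e2, m, "mixed",
                                converged = TRUE, flag = est$flag))
  }
  est <- rho_mixed_reml(Y, X)
  correlation_estimate(protein_id, est$rho, est$sigma_r2, est$sigma_e2,
                       m, "mixed", converged = est$converged, flag = est$flag)
}

correlation_estimate <- function(protein_id, rho, sigma_r2, sigma_e2,
                                 n_peptides, method, converged, flag = "") {
  structure(list(protein_id = protein_id, rho = rho, sigma_r2 = sigma_r2,
                 sigma_e2 = sigma_e2, n_peptides = n_peptides,
                 method = method, converged = converged, flag = flag),
            class = "CorrelationEstimate")
}

#' @export
print.CorrelationEstimate <- function(x, ...) {
  cat(sprintf(
    "CorrelationEstimate (%s): rho = %.4f (sigma_r2 = %.4g, sigma_e2 = %.4g), m = %d%s\n",
    x$method, x$rho, x$sigma_r2, x$sigma_e2, x$n_peptides,
    if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

# Balanced complete-data REML: classic ANOVA decomposition.
# P projects out the (shared) sample design; the between-sample mean
# square of peptide-averaged residuals estimates sigma_e2 + m * sigma_r2,
# the within mean square estimates sigma_e2.
rho_mixed_balanced <- function(Y, X) {
  m <- nrow(Y)
  qx <- qr(X)
  p <- qx$rank
  dfp <- ncol(Y) - p
  if (dfp < 1L)
    return(list(rho = 0, sigma_r2 = 0, sigma_e2 = NA_real_,
                flag = "no_residual_df"))
  R <- t(qr.resid(qx, t(Y)))                 # peptide x sample residuals
  rbar2 <- colMeans(R)^2
  ss_bar <- m * sum(rbar2)                   # m * ||P ybar||^2
  ss_tot <- sum(R^2)
  ssw <- ss_tot - ss_bar
  sigma_e2 <- ssw / (dfp * (m - 1))
  ms1 <- ss_bar / dfp
  sigma_r2 <- (ms1 - sigma_e2) / m
  flag <- ""
  if (sigma_r2 <= 0) {                       # boundary: refit with rho = 0
    sigma_r2 <- 0
    sigma_e2 <- ss_tot / (dfp * m)
    flag <- "boundary"
  }
  list(rho = sigma_r2 / (sigma_r2 + sigma_e2), sigma_r2 = sigma_r2,
       sigma_e2 = sigma_e2, flag = flag)
}

# Generic profiled REML for incomplete data. Fixed-effect design is the
# full peptide x design interaction; the covariance of sample block j
# (the k_j observed peptides of sample j) is sigma_e2 * (I + lambda * J).
# For a given lambda the model is whitened blockwise with
# (I + lambda J)^(-1/2) = I - c J, c = (1 - 1/sqrt(1 + lambda k)) / k,
# and the criterion log|V| + log|X' V^-1 X| + (n - p) log RSS is
# minimized over log(lambda).
rho_mixed_reml <- function(Y, X) {
  m <- nrow(Y)
  N <- ncol(Y)
  p <- ncol(X)
  obs <- which(!is.na(Y), arr.ind = TRUE)
  y <- Y[obs]
  pep <- obs[, 1L]
  smp <- obs[, 2L]
  n <- length(y)
  # fixed-effect matrix: one block of design columns per peptide
  Fmat <- matrix(0, n, m * p)
  for (k in seq_len(p))
    Fmat[cbind(seq_len(n), (pep - 1L) * p + k)] <- X[smp, k]
  ord <- order(smp)
  y <- y[ord]; Fmat <- Fmat[ord, , drop = FALSE]; smp <- smp[ord]
  ksz <- tabulate(smp, nbins = N)
  ksz <- ksz[ksz > 0L]
  starts <- cumsum(c(1L, ksz[-length(ksz)]))
  crit <- function(loglam) {
    lam <- exp(loglam)
    yt <- y
    Ft <- Fmat
    logdetV <- 0
    for (b in seq_along(ksz)) {
      k <- ksz[b]
      idx <- starts[b]:(starts[b] + k - 1L)
      cc <- (1 - 1 / sqrt(1 + lam * k)) / k
      yt[idx] <- yt[idx] - cc * sum(y[idx])
      Ft[idx, ] <- Ft[idx, , drop = FALSE] -
        cc * matrix(colSums(Fmat[idx, , drop = FALSE]), k, ncol(Fmat),
                    byrow = TRUE)
      logdetV <- logdetV + log1p(lam * k)
    }
    q <- qr(Ft)
    r <- q$rank
    rss <- sum(qr.resid(q, yt)^2)
    dg <- abs(diag(qr.R(q))[seq_len(r)])
    if (rss <= 0 || n - r < 1L) return(Inf)
    logdetV + 2 * sum(log(dg)) + (n - r) * log(rss)
  }
  lo <- log(1e-9); hi <- log(1e5)
  opt <- stats::optimize(crit, c(lo, hi), tol = 1e-10)
  conv <- TRUE
  loglam <- opt$minimum
  # boundary check: compare against lambda -> 0
  if (crit(lo) <= opt$objective + 1e-10 || loglam < lo + 1e-6) {
    loglam <- -Inf
  } else if (loglam > hi - 1e-6) {
    conv <- FALSE
  }
  lam <- exp(loglam)
  # recover sigma_e2 at the optimum
  rss_df <- local({
    yt <- y; Ft <- Fmat
    for (b in seq_along(ksz)) {
      k <- ksz[b]
      idx <- starts[b]:(starts[b] + k - 1L)
      cc <- if (is.finite(lam)) (1 - 1 / sqrt(1 + lam * k)) / k else 0
      yt[idx] <- yt[idx] - cc * sum(y[idx])
      Ft[idx, ] <- Ft[idx, , drop = FALSE] -
        cc * matrix(colSums(Fmat[idx, , drop = FALSE]), k, ncol(Fmat),
                    byrow = TRUE)
    }
    q <- qr(Ft)
    c(sum(qr.resid(q, yt)^2), length(yt) - q$rank)
  })
  sigma_e2 <- rss_df[1L] / rss_df[2L]
  sigma_r2 <- if (is.finite(lam)) lam * sigma_e2 else 0
  list(rho = if (is.finite(lam)) lam / (1 + lam) else 0,
       sigma_r2 = sigma_r2, sigma_e2 = sigma_e2,
       converged = conv,
       flag = if (!is.finite(lam) || lam < 1e-8) "boundary" else "")
}

# Vectorized balanced estimator across many proteins at once (the
# simulation fast path): R is the peptide x sample residual matrix (the
# design already projected out), f the protein factor per row.
rho_mixed_balanced_all <- function(R, f, df_proj) {
  f <- factor(f)
  m <- as.vector(table(f))
  S <- rowsum(R, f, reorder = TRUE)
  ss_bar <- rowSums(S^2) / m
  ss_tot <- rowsum(rowSums(R^2), f, reorder = TRUE)[, 1L]
  ssw <- ss_tot - ss_bar
  sigma_e2 <- ssw / (df_proj * pmax(m - 1, 1))
  ms1 <- ss_bar / df_proj
  sigma_r2 <- pmax((ms1 - sigma_e2) / m, 0)
  at_bound <- sigma_r2 == 0
  sigma_e2[at_bound] <- ss_tot[at_bound] / (df_proj * m[at_bound])
  rho <- ifelse(m >= 2, sigma_r2 / (sigma_r2 + sigma_e2), 0)
  names(rho) <- levels(f)
  rho
}

#' Wu-style moment estimator of the inter-peptide correlation
#'
#' The mean pairwise correlation among the peptides of one protein,
#' estimated from the variance of the standardized residual row-mean
#' statistic: data are rotated into the residual space of the design,
#' each peptide's residual vector is standardized to unit mean square, and
#' the variance inflation of their mean yields
#' `rho = (VIF - 1) / (m - 1)`, clamped to `[0, 1]` (negative raw
#' estimates are set to zero).
#'
#' This estimator requires a complete matrix; missing values raise an
#' error directing the caller to the mixed-model method, which tolerates
#' them.
#'
#' @param x numeric matrix (peptides x samples) of log2 abundances, or a
#'   `PeptideQuantTable` restricted to one protein.
#' @param design a [design_spec()]; `NULL` removes only the per-peptide
#'   mean.
#' @param protein_id accession recorded in the result.
#' @return a `CorrelationEstimate` with `method = "wu"` (`sigma_r2`,
#'   `sigma_e2` are `NA`: this route does not decompose variances).
#' @export
estimate_rho_wu <- function(x, design = NULL, protein_id = NA_character_) {
  Y <- if (inherits(x, "PeptideQuantTable")) x$abundance else as.matrix(x)
  if (anyNA(Y))
    stop("the Wu-style estimator does not allow missing values; ",
         "use estimate_rho_mixed() instead")
  m <- nrow(Y)
  if (m < 2L)
    return(correlation_estimate(protein_id, 0, NA_real_, NA_real_, m,
                                "wu", FALSE, "single_peptide"))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("s", seq_len(ncol(Y)))
  X <- if (is.null(design)) {
    matrix(1, ncol(Y), 1L)
  } else {
    design_matrix(design, colnames(Y))
  }
  qx <- qr(X)
  U <- qr.qty(qx, t(Y))[-seq_len(qx$rank), , drop = FALSE]  # resid coords x m
  rms <- sqrt(colMeans(U^2))
  if (any(rms == 0))
    return(correlation_estimate(protein_id, 0, NA_real_, NA_real_, m,
                                "wu", FALSE, "degenerate"))
  U <- sweep(U, 2L, rms, "/")
  vif <- m * mean(rowMeans(U)^2)
  rho <- (vif - 1) / (m - 1)
  rho <- min(max(rho, 0), 1)
  correlation_estimate(protein_id, rho, NA_real_, NA_real_, m, "wu", TRUE)
}

#' Estimate inter-peptide correlations for every protein of a table
#'
#' @param table a `PeptideQuantTable`.
#' @param design a `DesignSpec`.
#' @param method `"mixed"` (default, tolerates missing data) or `"wu"`.
#' @return data.frame with columns protein, n_peptides, rho, method,
#'   converged, flag.
#' @export
estimate_rho_all <- function(table, design, method = c("mixed", "wu")) {
  method <- match.arg(method)
  idx <- protein_index(table)
  est <- lapply(names(idx), function(pr) {
    sub <- table$abundance[idx[[pr]], , drop = FALSE]
    if (method == "mixed") estimate_rho_mixed(sub, design, pr)
    else estimate_rho_wu(sub, design, pr)
  })
  data.frame(
    protein = names(idx),
    n_peptides = vapply(est, `[[`, 0L, "n_peptides"),
    rho = vapply(est, `[[`, 0, "rho"),
    method = method,
    converged = vapply(est, `[[`, TRUE, "converged"),
    flag = vapply(est, `[[`, "", "flag"),
    row.names = NULL, stringsAsFactors = FALSE)
}
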