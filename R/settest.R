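#' Normal-consistent scaled median absolute deviation
#'
#' `1.4826 * median(|x - median(x)|)`. The constant is the conventional
#' 4-decimal rounding of `1 / qnorm(3/4)`, which makes the estimator
#' consistent for the standard deviation under normality.
#'
#' @param x numeric vector with at least 2 finite values.
#' @return the robust scale estimate; 0 (with a warning) when all values
#'   are equal.
#' @export
scaled_mad <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("scaled_mad() needs at least 2 finite values")
  s <- 1.4826 * stats::median(abs(x - stats::median(x)))
  if (s == 0) warning("scaled MAD is zero: more than half the values are equal")
  s
}

#' Correlation-adjusted competitive set test for one protein
#'
#' Tests whether the mean moderated t-statistic of the peptides mapped to
#' a protein of interest differs from that of the rest of the peptidome.
#' The two means are compared with a two-sample t-statistic whose set-side
#' variance contribution is inflated by the variance inflation factor
#' `VIF = 1 + (m - 1) * rho` to account for inter-peptide correlation:
#'
#' `T = (mean(t_set) - center_bg) / sqrt(s2_pool * (VIF/m1 + 1/m2))`
#'
#' with `m1 = |set|`, `m2 = |background|`, pooled variance
#' `s2_pool = ((m1-1) * var(t_set) + (m2-1) * scale_bg^2) / (m1+m2-2)`,
#' and `m1 + m2 - 2` degrees of freedom. With `scale_method = "sd"` the
#' background center/scale are the sample mean and SD, and the `rho = 0`
#' path reduces exactly to the ordinary pooled two-sample t-test; with
#' `"mad"` the background is robustified to the median and the
#' 1.4826-scaled MAD (the set side keeps its sample mean and SD).
#'
#' @param t_stats numeric vector of per-peptide moderated t-statistics for
#'   the whole peptidome (non-finite entries are dropped from both set and
#'   background).
#' @param set_index indices (into `t_stats`) of the peptides of the
#'   protein of interest.
#' @param rho inter-peptide correlation used in the VIF; negative values
#'   are clamped to 0. Ignored (VIF = 1) for single-peptide sets.
#' @param scale_method `"sd"` or `"mad"` background scale.
#' @param protein_id accession copied into the result.
#' @param mean_logFC average peptide log2 fold change, copied into the
#'   result.
#' @return one-row data.frame of class contribution: protein, m, rho,
#'   T_set, df, p, mean_logFC, direction.
#' @export
competitive_set_test <- function(t_stats, set_index, rho = 0,
                                 scale_method = c("sd", "mad"),
                                 protein_id = NA_character_,
                                 mean_logFC = NA_real_) {
  scale_method <- match.arg(scale_method)
  finite <- is.finite(t_stats)
  in_set <- logical(length(t_stats))
  in_set[set_index] <- TRUE
  tset <- t_stats[in_set & finite]
  tbg <- t_stats[!in_set & finite]
  m1 <- length(tset)
  m2 <- length(tbg)
  if (m1 == 0L) return(NULL)
  if (m2 < 2L || sum(is.finite(tbg)) < 2L)
    stop("background needs at least 2 finite t-statistics")
  rho <- max(rho, 0)
  vif <- if (m1 >= 2L) 1 + (m1 - 1) * rho else 1
  if (scale_method == "sd") {
    center_bg <- mean(tbg)
    scale_bg <- stats::sd(tbg)
  } else {
    center_bg <- stats::median(tbg)
    scale_bg <- suppressWarnings(scaled_mad(tbg))
  }
  if (scale_bg <= 0)
    stop("zero background scale: background t-statistics are all identical")
  var_set <- if (m1 >= 2L) stats::var(tset) else 0
  s2_pool <- ((m1 - 1) * var_set + (m2 - 1) * scale_bg^2) / (m1 + m2 - 2)
  delta <- mean(tset) - center_bg
  T_set <- delta / sqrt(s2_pool * (vif / m1 + 1 / m2))
  df <- m1 + m2 - 2
  p <- 2 * stats::pt(-abs(T_set), df = df)
  data.frame(protein = protein_id, m = m1, rho = rho, T_set = T_set,
             df = df, p = p, mean_logFC = mean_logFC,
             direction = sign(delta), stringsAsFactors = FALSE)
}

#' Adjust p-values for multiple testing (step-up)
#'
#' Hand-rolled Benjamini-Hochberg / Benjamini-Yekutieli step-up: sort p
#' ascending, multiply `p_(i)` by `n/i` (BH) or additionally by the
#' harmonic number `sum(1/(1:n))` (BY), enforce monotonicity from the
#' largest down, cap at 1. `NA` entries are ignored and returned as `NA`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` or `"BY"`.
#' @return adjusted p-values in the original order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  n <- length(idx)
  if (n == 0L) return(out)
  pv <- p[idx]
  o <- order(pv, decreasing = TRUE)      # largest first
  cfac <- if (method == "BY") sum(1 / seq_len(n)) else 1
  adj <- pmin(1, cummin(cfac * n / (n:1) * pv[o]))
  out[idx[o]] <- adj
  out
}

#' Run the competitive peptide set test over a whole peptide table
#'
#' The full pipeline on already filtered/normalized data: per-peptide
#' linear models and empirical-Bayes moderated t-statistics, an
#' inter-peptide correlation estimate per protein, and the
#' correlation-adjusted competitive set test of each protein's peptides
#' against all other fitted peptides, followed by multiplicity adjustment
#' across proteins. Shared peptides count towards every protein they map
#' to and never appear in that protein's own background.
#'
#' @param table a [peptide_quant_table()] (filter/normalize first; see
#'   [filter_missing()] and [normalize_columns()]).
#' @param design a [design_spec()].
#' @param cor_method `"mixed"` (REML variance components, default),
#'   `"wu"` (moment estimator, complete data only) or `"none"`
#'   (assume `rho = 0`).
#' @param scale_method background scale, `"mad"` (robust default) or
#'   `"sd"`.
#' @param adjust `"BH"` (default) or `"BY"`.
#' @param min_set_size proteins with fewer fitted peptides are skipped
#'   (default 1: single-peptide proteins are tested with VIF = 1 and
#'   flagged by their `m`).
#' @return data.frame with one row per tested protein (protein, m, rho,
#'   T_set, df, p, p_adj, mean_logFC, direction), ordered by p then
#'   accession. The fitted `PeptideFitResult` is attached as attribute
#'   `"fit"`, run parameters as `"params"`.
#' @export
run_pepsettest <- function(table, design,
                           cor_method = c("mixed", "wu", "none"),
                           scale_method = c("mad", "sd"),
                           adjust = c("BH", "BY"),
                           min_set_size = 1L) {
  cor_method <- match.arg(cor_method)
  scale_method <- match.arg(scale_method)
  adjust <- match.arg(adjust)
  fit <- moderated_t(empirical_bayes(fit_peptides(table, design)))
  res <- settest_from_fit(table, design, fit, cor_method, scale_method,
                          adjust, min_set_size)
  attr(res, "fit") <- fit
  attr(res, "params") <- list(cor_method = cor_method,
                              scale_method = scale_method, adjust = adjust)
  res
}

# Set tests for every protein given a fitted peptide model. Fully
# vectorized: background moments for the "sd" scale come from peptidome
# totals (one pass); "mad" recomputes the background median/MAD per
# protein. Correlations are estimated per protein on the full peptide
# submatrix; for complete tables with single-valued protein maps the
# balanced REML closed form is computed for all proteins at once.
settest_from_fit <- function(table, design, fit, cor_method, scale_method,
                             adjust, min_set_size = 1L) {
  t_all <- fit$t_mod
  finite <- is.finite(t_all)
  if (sum(finite) < 3L) {
    warning("fewer than 3 finite peptide t-statistics; nothing to test")
    return(empty_settest_result())
  }
  idx_all <- protein_index(table)
  idx <- lapply(idx_all, function(ii) ii[finite[ii]])
  keep <- lengths(idx) >= max(1L, min_set_size)
  idx_all <- idx_all[keep]
  idx <- idx[keep]
  if (length(idx) == 0L) {
    warning("zero testable proteins")
    return(empty_settest_result())
  }
  proteins <- names(idx)
  m1 <- lengths(idx)
  G <- sum(finite)
  m2 <- G - m1
  testable <- m2 >= 2L
  rho <- stats::setNames(numeric(length(idx)), proteins)
  multi <- m1 >= 2L
  if (cor_method != "none" && any(multi)) {
    Y <- table$abundance
    unique_map <- all(lengths(table$protein_map) == 1L)
    if (cor_method == "mixed" && unique_map && !anyNA(Y)) {
      X <- design_matrix(design, colnames(Y))
      qx <- qr(X)
      R <- t(qr.resid(qx, t(Y)))
      f <- vapply(table$protein_map, `[`, "", 1L)
      rho_vec <- rho_mixed_balanced_all(R, f, ncol(Y) - qx$rank)
      rho[] <- rho_vec[proteins]
      rho[!multi] <- 0
    } else {
      for (k in which(multi)) {
        sub <- Y[idx_all[[k]], , drop = FALSE]
        est <- if (cor_method == "mixed")
          estimate_rho_mixed(sub, design, proteins[k])
        else estimate_rho_wu(sub, design, proteins[k])
        rho[k] <- est$rho
      }
    }
  }
  rho <- pmax(rho, 0)
  S <- sum(t_all[finite])
  Q <- sum(t_all[finite]^2)
  sum_set <- vapply(idx, function(ii) sum(t_all[ii]), 0)
  sumsq_set <- vapply(idx, function(ii) sum(t_all[ii]^2), 0)
  mean_lfc <- vapply(idx, function(ii) mean(fit$effect[ii]), 0)
  vif <- ifelse(multi, 1 + (m1 - 1) * rho, 1)
  var_set <- ifelse(multi,
                    pmax(sumsq_set - sum_set^2 / m1, 0) / pmax(m1 - 1, 1),
                    0)
  if (scale_method == "sd") {
    center_bg <- (S - sum_set) / m2
    scale2_bg <- pmax((Q - sumsq_set - m2 * center_bg^2) / (m2 - 1), 0)
  } else {
    tfin <- t_all[finite]
    posmap <- integer(length(t_all))
    posmap[which(finite)] <- seq_len(G)
    center_bg <- scale2_bg <- numeric(length(idx))
    for (k in seq_along(idx)) {
      if (!testable[k]) next
      tbg <- tfin[-posmap[idx[[k]]]]
      center_bg[k] <- stats::median(tbg)
      scale2_bg[k] <- suppressWarnings(scaled_mad(tbg))^2
    }
  }
  if (any(scale2_bg[testable] <= 0))
    stop("zero background scale for protein ",
         proteins[testable & scale2_bg <= 0][1L])
  s2_pool <- ((m1 - 1) * var_set + (m2 - 1) * scale2_bg) / (m1 + m2 - 2)
  delta <- sum_set / m1 - center_bg
  T_set <- delta / sqrt(s2_pool * (vif / m1 + 1 / m2))
  df <- m1 + m2 - 2
  res <- data.frame(
    protein = proteins, m = as.integer(m1), rho = rho, T_set = T_set,
    df = df, p = 2 * stats::pt(-abs(T_set), df = df),
    mean_logFC = mean_lfc, direction = sign(delta),
    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[testable, , drop = FALSE]
  res$p_adj <- adjust_pvalues(res$p, adjust)
  res <- res[order(res$p, res$protein), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_settest_result <- function() {
  data.frame(protein = character(), m = integer(), rho = numeric(),
             T_set = numeric(), df = numeric(), p = numeric(),
             mean_logFC = numeric(), direction = numeric(),
             p_adj = numeric(), stringsAsFactors = FALSE)
}

#' Write set-test (or comparator) results as TSV with a YAML header
#'
#' @param results data.frame as returned by [run_pepsettest()] or
#'   [protein_level_test()].
#' @param path output path.
#' @param params named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(yaml_header(c(list(format = "pepset/results"), params)), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
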