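test_that("OLS per peptide: exact values on symmetric data", {
  ab <- rbind(pep1 = c(1, 2, 3, 3, 4, 5),
              pep2 = c(2, 2, 2, 2, 2, 2))
  colnames(ab) <- paste0("s", sprintf("%02d", 1:6))
  tab <- peptide_quant_table(ab, list("A", "B"))
  fit <- fit_peptides(tab, two_group_design(6))
  expect_equal(fit$effect[1], 2)
  expect_equal(fit$sigma2[1], 1)
  expect_equal(fit$df_resid[1], 4)
  expect_equal(fit$se_unscaled[1], sqrt(2 / 3))
  # identical groups: zero effect
  expect_equal(fit$effect[2], 0)
})

test_that("covariate models match a brute-force normal-equations solve", {
  set.seed(201)
  N <- 8
  samples <- data.frame(sample = paste0("s", sprintf("%02d", 1:N)),
                        group = rep(c("A", "B"), each = 4),
                        age = c(31, 45, 52, 38, 41, 60, 29, 55))
  des <- design_spec(samples, contrast = c("B", "A"), covariates = "age")
  ab <- matrix(rnorm(3 * N, 20), 3, N,
               dimnames = list(paste0("pep", 1:3), samples$sample))
  ab[2, 5] <- NA
  tab <- peptide_quant_table(ab, as.list(c("A", "B", "C")))
  fit <- fit_peptides(tab, des)
  for (i in 1:3) {
    sel <- !is.na(ab[i, ])
    X <- cbind(1, as.numeric(samples$group == "B"), samples$age)[sel, ]
    y <- ab[i, sel]
    beta <- solve(t(X) %*% X, t(X) %*% y)      # normal equations oracle
    r <- y - X %*% beta
    expect_equal(fit$effect[i], beta[2], tolerance = 1e-10)
    expect_equal(fit$sigma2[i],
                 sum(r^2) / (sum(sel) - 3), tolerance = 1e-10)
    expect_equal(fit$df_resid[i], sum(sel) - 3)
    expect_equal(fit$se_unscaled[i], sqrt(solve(t(X) %*% X)[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("peptides without 2 observations per group are flagged", {
  ab <- rbind(pep1 = c(1, 2, NA, NA, NA, 5),
              pep2 = c(1, 2, 3, 4, 5, 6))
  colnames(ab) <- paste0("s", sprintf("%02d", 1:6))
  tab <- peptide_quant_table(ab, list("A", "B"))
  fit <- fit_peptides(tab, two_group_design(6))
  expect_false(fit$ok[1])
  expect_true(is.na(fit$effect[1]))
  expect_true(fit$ok[2])
})

test_that("empirical Bayes recovers generating hyperparameters", {
  set.seed(202)
  n <- 5000; d0 <- 4; s0 <- 1; df <- 4
  # residual variances from the scaled-F sampling model
  s2 <- s0 * (rchisq(n, df) / df) / (rchisq(n, d0) / d0)
  fit <- list(sigma2 = s2, df_resid = rep(df, n), ok = rep(TRUE, n))
  eb <- empirical_bayes(fit)
  expect_lt(abs(eb$d0 - d0) / d0, 0.1)
  expect_lt(abs(eb$s0_2 - s0) / s0, 0.1)
  # independent implementation agrees
  sq <- limma::squeezeVar(s2, df = df)
  expect_equal(eb$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(eb$s0_2, sq$var.prior, tolerance = 1e-6)
  expect_equal(eb$s2_post, sq$var.post, tolerance = 1e-8)
})

test_that("degenerate and forced prior-df limits behave as specified", {
  fit <- list(sigma2 = rep(2, 50), df_resid = rep(4, 50), ok = rep(TRUE, 50),
              effect = rep(1, 50), se_unscaled = rep(1, 50))
  eb <- empirical_bayes(fit)
  expect_identical(eb$d0, Inf)
  expect_equal(eb$s0_2, 2)                  # the common value
  expect_true(all(eb$s2_post == 2))
  # d0 = 0: classical t
  set.seed(203)
  fx <- make_table(c(5, 5), 6)
  f0 <- moderated_t(empirical_bayes(fit_peptides(fx$table, fx$design),
                                    prior_df = 0))
  t_classic <- f0$effect / (f0$se_unscaled * sqrt(f0$sigma2))
  expect_equal(f0$t_mod, t_classic, tolerance = 1e-12)
  # d0 = Inf: all t computed with the pooled prior variance
  fInf <- moderated_t(empirical_bayes(fit_peptides(fx$table, fx$design),
                                      prior_df = Inf))
  expect_equal(fInf$t_mod,
               fInf$effect / (fInf$se_unscaled * sqrt(mean(fInf$sigma2))),
               tolerance = 1e-12)
})

test_that("shrinkage arithmetic and posterior-variance bounds hold", {
  fit <- list(sigma2 = 3, df_resid = 4, ok = TRUE,
              effect = 1, se_unscaled = 1)
  eb <- suppressWarnings(
    empirical_bayes(list(sigma2 = c(3, 2), df_resid = c(4, 4),
                         ok = c(TRUE, TRUE)),
                    prior_df = 2, prior_var = 1))
  expect_equal(eb$s2_post[1], (2 * 1 + 4 * 3) / 6)
  # s2_post always between sigma2 and s0_2
  set.seed(204)
  fx <- make_table(c(10, 10, 10), 8)
  ebf <- empirical_bayes(fit_peptides(fx$table, fx$design))
  lo <- pmin(ebf$sigma2, rep_len(ebf$s0_2, length(ebf$sigma2)))
  hi <- pmax(ebf$sigma2, rep_len(ebf$s0_2, length(ebf$sigma2)))
  expect_true(all(ebf$s2_post >= lo - 1e-12 & ebf$s2_post <= hi + 1e-12))
})

test_that("trend prior follows the covariate (limma parity)", {
  set.seed(205)
  n <- 2000; d0 <- 4; df <- 4
  cv <- runif(n, 1, 4)
  s2 <- exp(0.5 * cv) * (rchisq(n, df) / df) / (rchisq(n, d0) / d0)
  fit <- list(sigma2 = s2, df_resid = rep(df, n), ok = rep(TRUE, n))
  eb <- empirical_bayes(fit, trend_covariate = cv)
  sq <- limma::squeezeVar(s2, df = df, covariate = cv)
  expect_equal(eb$d0, sq$df.prior, tolerance = 0.05)
  expect_gt(cor(eb$s2_post, sq$var.post), 0.999)
  # prior variance increases with the covariate here
  expect_gt(cor(eb$s0_2, cv), 0.95)
})

test_that("moderated t: null distribution, symmetry, shift invariance", {
  set.seed(206)
  fx <- make_table(rep(3, 300), 6)       # 900 null peptides
  fit <- moderated_t(empirical_bayes(fit_peptides(fx$table, fx$design)))
  # zero effect => t = 0, p = 1
  ab0 <- fx$table$abundance
  ab0[1, 4:6] <- ab0[1, 1:3]
  tab0 <- peptide_quant_table(ab0, fx$table$protein_map)
  f0 <- moderated_t(empirical_bayes(fit_peptides(tab0, fx$design)))
  expect_equal(f0$t_mod[1], 0)
  expect_equal(f0$p[1], 1)
  # null t consistent with Student t on d0 + df_resid df
  ks <- stats::ks.test(fit$t_mod, stats::pt,
                       df = fit$d0 + fit$df_resid[1])
  expect_gt(ks$p.value, 0.01)
  # a global abundance shift is absorbed by the intercept; swapping
  # group labels negates every effect and t
  ab <- fx$table$abundance + 7
  fshift <- moderated_t(empirical_bayes(
    fit_peptides(peptide_quant_table(ab, fx$table$protein_map),
                 fx$design)))
  expect_equal(fshift$t_mod, fit$t_mod, tolerance = 1e-9)
  des_swapped <- design_spec(fx$design$samples, contrast = c("A", "B"))
  fswap <- moderated_t(empirical_bayes(fit_peptides(fx$table, des_swapped)))
  expect_equal(fswap$t_mod, -fit$t_mod, tolerance = 1e-12)
  expect_equal(fswap$effect, -fit$effect, tolerance = 1e-12)
})
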