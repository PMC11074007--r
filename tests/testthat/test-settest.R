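test_that("scaled MAD: hand values, consistency constant, degenerate", {
  expect_equal(scaled_mad(c(1, 2, 3, 4, 5)), 1.4826)
  expect_warning(s <- scaled_mad(rep(3, 10)), "zero")
  expect_identical(s, 0)
  expect_error(scaled_mad(2), "2 finite")
  # 1.4826 reproduces 1/qnorm(3/4) to 4 decimals
  expect_equal(1.4826, 1 / qnorm(0.75), tolerance = 5e-5)
})

test_that("centered set with rho 0 gives T = 0, p = 1", {
  t_stats <- c(1, -1, 2, -2, 0, 3, -3, 0.5, -0.5, 0)
  # set mean == background mean == 0
  r <- competitive_set_test(t_stats, c(5, 10), rho = 0,
                            scale_method = "sd")
  expect_equal(r$T_set, 0)
  expect_equal(r$p, 1)
})

test_that("rho 0 + sd path equals the pooled two-sample t oracle", {
  set.seed(401)
  for (i in 1:25) {
    G <- sample(20:200, 1)
    m <- sample(2:10, 1)
    t_stats <- rnorm(G, sd = runif(1, 0.5, 2))
    r <- competitive_set_test(t_stats, seq_len(m), rho = 0,
                              scale_method = "sd")
    ora <- pooled_t_oracle(t_stats[seq_len(m)], t_stats[-seq_len(m)])
    expect_equal(r$T_set, ora$t, tolerance = 1e-12)
    expect_equal(r$p, ora$p, tolerance = 1e-12)
    # and stats::t.test agrees too
    tt <- t.test(t_stats[seq_len(m)], t_stats[-seq_len(m)],
                 var.equal = TRUE)
    expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("the VIF enters the denominator as 1 + (m-1) rho", {
  set.seed(402)
  t_stats <- rnorm(500)
  set_idx <- 1:10
  r0 <- competitive_set_test(t_stats, set_idx, rho = 0, "sd")
  r5 <- competitive_set_test(t_stats, set_idx, rho = 0.05, "sd")
  vif <- 1 + 9 * 0.05
  expect_equal(vif, 1.45)
  m1 <- 10; m2 <- 490
  expect_equal(r5$T_set / r0$T_set,
               sqrt((1 / m1 + 1 / m2) / (vif / m1 + 1 / m2)),
               tolerance = 1e-12)
  # p non-decreasing in rho
  rhos <- seq(0, 0.9, by = 0.1)
  ps <- vapply(rhos, function(r)
    competitive_set_test(t_stats, set_idx, r, "sd")$p, 0)
  expect_true(all(diff(ps) >= -1e-15))
  # negative rho treated as 0
  expect_equal(competitive_set_test(t_stats, set_idx, -0.3, "sd")$T_set,
               r0$T_set)
})

test_that("mad variant robustifies only the background side", {
  set.seed(403)
  t_stats <- c(rnorm(5, 3), rnorm(200))
  r <- competitive_set_test(t_stats, 1:5, rho = 0, "mad")
  tbg <- t_stats[-(1:5)]
  s_bg <- 1.4826 * median(abs(tbg - median(tbg)))
  s2 <- (4 * var(t_stats[1:5]) + 199 * s_bg^2) / 203
  expect_equal(r$T_set,
               (mean(t_stats[1:5]) - median(tbg)) /
                 sqrt(s2 * (1 / 5 + 1 / 200)),
               tolerance = 1e-12)
  expect_equal(r$df, 203)
})

test_that("background permutation and contrast inversion invariances", {
  set.seed(404)
  t_stats <- rnorm(100)
  r <- competitive_set_test(t_stats, 1:4, 0.1, "sd")
  perm <- c(1:4, 4 + sample(96))
  rp <- competitive_set_test(t_stats[perm], 1:4, 0.1, "sd")
  expect_equal(rp$p, r$p, tolerance = 1e-12)
  rn <- competitive_set_test(-t_stats, 1:4, 0.1, "sd")
  expect_equal(rn$T_set, -r$T_set, tolerance = 1e-12)
  expect_equal(rn$p, r$p, tolerance = 1e-12)
  expect_equal(rn$direction, -r$direction)
})

test_that("degenerate backgrounds raise errors", {
  expect_error(competitive_set_test(c(1, 2, rep(0, 10)), 1:2, 0, "sd"),
               "identical")
  expect_error(competitive_set_test(c(1, 2, 3), 1:2, 0, "sd"),
               "at least 2")
})

test_that("step-up adjustment: hand cases and p.adjust oracle", {
  # BH on an arithmetic grid collapses to the largest
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  # BY multiplies by the harmonic number 25/12
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BY"),
               rep(1 / 12, 4))
  expect_equal(sum(1 / (1:4)), 25 / 12)
  # single p: identity
  expect_identical(adjust_pvalues(0.37, "BH"), 0.37)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  set.seed(405)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    bh <- adjust_pvalues(p, "BH")
    by <- adjust_pvalues(p, "BY")
    expect_equal(bh, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(by, p.adjust(p, "BY"), tolerance = 1e-12)
    expect_true(all(by >= bh - 1e-15))
  }
})

test_that("run_pepsettest agrees with the single-protein function", {
  set.seed(406)
  for (scale in c("sd", "mad")) {
    fx <- make_table(c(4, 3, 2, 1, 6), 10, miss = 0.05)
    res <- run_pepsettest(fx$table, fx$design, cor_method = "mixed",
                          scale_method = scale)
    fit <- attr(res, "fit")
    idx <- protein_index(fx$table)
    for (pr in res$protein) {
      rho <- res$rho[res$protein == pr]
      single <- competitive_set_test(fit$t_mod, idx[[pr]], rho = rho,
                                     scale_method = scale)
      expect_equal(res$T_set[res$protein == pr], single$T_set,
                   tolerance = 1e-10)
      expect_equal(res$p[res$protein == pr], single$p, tolerance = 1e-10)
    }
    # sorted by p then accession; p_adj >= p
    expect_false(is.unsorted(res$p))
    expect_true(all(res$p_adj >= res$p - 1e-15))
  }
})

test_that("a strongly spiked protein attains the smallest p", {
  set.seed(407)
  fx <- make_table(rep(3, 40), 6)
  spike <- protein_index(fx$table)[["P7"]]
  ab <- fx$table$abundance
  ab[spike, 4:6] <- ab[spike, 4:6] + 5
  tab <- peptide_quant_table(ab, fx$table$protein_map)
  res <- run_pepsettest(tab, fx$design, cor_method = "mixed",
                        scale_method = "mad")
  expect_identical(res$protein[1], "P7")
  expect_identical(res$direction[1], 1)
  expect_gt(res$mean_logFC[res$protein == "P7"], 3)
})

test_that("shared peptides join every mapped set, never their background", {
  set.seed(408)
  ab <- matrix(rnorm(5 * 6, 20), 5, 6,
               dimnames = list(paste0("pep", 1:5),
                               paste0("s", sprintf("%02d", 1:6))))
  tab <- peptide_quant_table(ab, list("A", "A", "A;B", "B", "C"))
  des <- two_group_design(6)
  res <- run_pepsettest(tab, des, cor_method = "none", scale_method = "sd")
  expect_identical(res$m[res$protein == "A"], 3L)
  expect_identical(res$m[res$protein == "B"], 2L)
  fit <- attr(res, "fit")
  # background of A excludes the shared peptide 3
  manual <- competitive_set_test(fit$t_mod, 1:3, 0, "sd")
  expect_equal(res$p[res$protein == "A"], manual$p, tolerance = 1e-12)
})

test_that("wu and none correlation routes run end to end", {
  set.seed(409)
  fx <- make_table(c(4, 4, 4), 10)
  r_wu <- run_pepsettest(fx$table, fx$design, cor_method = "wu",
                         scale_method = "sd")
  r_no <- run_pepsettest(fx$table, fx$design, cor_method = "none",
                         scale_method = "sd")
  expect_true(all(r_no$rho == 0))
  expect_true(all(r_wu$rho >= 0 & r_wu$rho <= 1))
})
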