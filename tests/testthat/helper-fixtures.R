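# Fixture builders shared across test files. Everything is generated in
# code; no binary data.

# Random peptide table: `sizes[i]` peptides for protein i, optional
# missingness fraction, N samples split into two groups.
make_table <- function(sizes = c(3, 2, 1), n_samples = 6, miss = 0,
                       rho = 0, effect = 0, sd = 1, mean = 20) {
  m <- sum(sizes)
  prot <- rep(paste0("P", seq_along(sizes)), sizes)
  group <- rep(c("A", "B"), each = n_samples / 2)
  z <- matrix(stats::rnorm(length(sizes) * n_samples), length(sizes))
  ab <- mean + stats::rnorm(m) +
    sqrt(rho) * z[rep(seq_along(sizes), sizes), , drop = FALSE] * sd +
    sqrt(1 - rho) * matrix(stats::rnorm(m * n_samples, sd = sd), m)
  ab[, group == "B"] <- ab[, group == "B"] + effect
  dimnames(ab) <- list(sprintf("pep%03d", seq_len(m)),
                       sprintf("s%02d", seq_len(n_samples)))
  if (miss > 0)
    ab[sample(length(ab), round(miss * length(ab)))] <- NA
  list(table = peptide_quant_table(ab, as.list(prot)),
       design = design_spec(
         data.frame(sample = colnames(ab), group = group),
         contrast = c("B", "A")))
}

# Equicorrelated peptide block for one protein (complete data).
make_block <- function(m, N, rho, mu = 0) {
  z <- stats::rnorm(N)
  Y <- matrix(stats::rnorm(m * N, sd = sqrt(1 - rho)), m, N) +
    rep(sqrt(rho) * z, each = m) + stats::rnorm(m) + mu
  dimnames(Y) <- list(paste0("p", seq_len(m)),
                      paste0("s", sprintf("%02d", seq_len(N))))
  Y
}

two_group_design <- function(N) {
  design_spec(data.frame(sample = paste0("s", sprintf("%02d", seq_len(N))),
                         group = rep(c("A", "B"), each = N / 2)),
              contrast = c("B", "A"))
}

# Independently coded pooled two-sample t-test (textbook formula), the
# oracle for the rho = 0 / sd path of the set test.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vx <- if (n1 > 1) stats::var(x) else 0
  sp2 <- ((n1 - 1) * vx + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n1 + n2 - 2))
}

# Write a generic-dialect TSV of raw (non-log) intensities.
write_generic_tsv <- function(path, peptide, protein, intensities) {
  df <- data.frame(peptide = peptide, protein = protein,
                   intensities, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
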