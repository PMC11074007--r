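#' Define a peptidome simulation scenario
#'
#' The stated world of the simulation study: log2 peptide expression is
#' multivariate normal with peptide means drawn standard normal, unit
#' peptide variances, and an equicorrelated covariance block (correlation
#' `rho`) within each protein, zero across proteins. A fraction of
#' proteins is differentially expressed, half shifted by `+effect` and
#' half by `-effect` in the test group.
#'
#' @param proteome list of `c(n_proteins, peptides_per_protein)` blocks.
#'   The default is the mixture proteome of 1400 3-peptide, 360
#'   10-peptide and 40 30-peptide proteins (9000 peptides, 1800
#'   proteins), mimicking a real-world label-free dataset.
#' @param rho common inter-peptide correlation, in `[0, 1)`.
#' @param n_samples total number of samples `N` (even, at least 4);
#'   `N/2` per group.
#' @param de_fraction fraction of differentially expressed proteins, in
#'   `[0, 0.5]`.
#' @param effect absolute mean group difference (log2 units) given to DE
#'   proteins; default 0.5.
#' @param n_reps number of simulation replicates; default 1000.
#' @param seed master seed; every replicate derives its own seed as
#'   `seed + replicate`.
#' @param methods workflows to benchmark: subset of `"pepsettest_sd"`,
#'   `"pepsettest_mad"`, `"sum_limma"`, `"robust_limma"`.
#' @param alpha decision threshold (raw p for Type I error and power,
#'   adjusted p for FDR/TPR); default 0.05.
#' @return object of class `SimConfig`.
#' @export
sim_config <- function(proteome = list(c(1400, 3), c(360, 10), c(40, 30)),
                       rho = 0, n_samples = 30, de_fraction = 0,
                       effect = 0.5, n_reps = 1000, seed = 1,
                       methods = c("pepsettest_sd", "pepsettest_mad",
                                   "sum_limma", "robust_limma"),
                       alpha = 0.05) {
  proteome <- lapply(proteome, as.integer)
  if (!length(proteome) ||
      !all(vapply(proteome, function(b)
        length(b) == 2L && all(b >= 1L), TRUE)))
    stop("'proteome' must be a list of c(n_proteins, peptides_per_protein)")
  if (rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1) for a positive-definite equicorrelation")
  n_samples <- as.integer(n_samples)
  if (n_samples < 4L || n_samples %% 2L != 0L)
    stop("'n_samples' must be an even integer >= 4")
  if (de_fraction < 0 || de_fraction > 0.5)
    stop("'de_fraction' must lie in [0, 0.5]")
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(proteome = proteome, rho = rho, n_samples = n_samples,
                 de_fraction = de_fraction, effect = effect,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 methods = methods, alpha = alpha),
            class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  blocks <- vapply(x$proteome, function(b) sprintf("%dx%d", b[1], b[2]), "")
  cat(sprintf(
    "SimConfig: proteome %s, rho = %g, N = %d, DE %g%% at effect %g, %d reps\n",
    paste(blocks, collapse = " + "), x$rho, x$n_samples,
    100 * x$de_fraction, x$effect, x$n_reps))
  invisible(x)
}

#' Simulate one peptidome replicate
#'
#' Draws peptide means from a standard normal, then log2 expression with
#' unit variance and within-protein equicorrelation `rho`, sampled by the
#' one-factor construction (a shared `sqrt(rho)`-weighted protein-sample
#' factor plus `sqrt(1-rho)`-weighted independent noise), which realizes
#' the equicorrelated block covariance exactly in O(peptides) per sample.
#' DE proteins are drawn without replacement, stratified across proteome
#' blocks (largest-remainder apportionment) so that mixture scenarios
#' contain DE proteins of every size; alternating signs split them into
#' up- and down-regulated halves. The shift is applied to every peptide
#' of the protein in the test group.
#'
#' @param config a [sim_config()].
#' @param rep_seed integer seed for this replicate.
#' @return list with `table` (a [peptide_quant_table()]), `design` (a
#'   [design_spec()], contrast test "B" minus reference "A"), `de`
#'   (named vector per protein: +1 up, -1 down, 0 null) and `protein`
#'   (accession per peptide row).
#' @export
simulate_peptidome <- function(config, rep_seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(rep_seed)
  sizes <- unlist(lapply(config$proteome, function(b) rep(b[2L], b[1L])))
  J <- length(sizes)
  P <- sum(sizes)
  N <- config$n_samples
  prot_ids <- sprintf("prot%05d", seq_len(J))
  pep_prot <- rep.int(seq_len(J), sizes)
  pep_ids <- sprintf("pep%05d", seq_len(P))
  group <- rep(c("A", "B"), each = N %/% 2L)
  sample_ids <- sprintf("%s%02d", group, c(seq_len(N %/% 2L),
                                           seq_len(N %/% 2L)))
  de <- stats::setNames(numeric(J), prot_ids)
  n_de <- round(config$de_fraction * J)
  if (n_de > 0L) {
    block_J <- vapply(config$proteome, `[`, 0L, 1L)
    alloc <- largest_remainder(config$de_fraction * block_J, n_de)
    offset <- cumsum(c(0L, block_J[-length(block_J)]))
    chosen <- unlist(lapply(seq_along(alloc), function(k) {
      if (alloc[k] == 0L) return(integer())
      offset[k] + sample.int(block_J[k], alloc[k])
    }))
    signs <- rep_len(c(1, -1), length(chosen))
    de[chosen] <- signs
  }
  mu <- stats::rnorm(P)
  z <- matrix(stats::rnorm(J * N), J, N)
  eps <- matrix(stats::rnorm(P * N), P, N)
  Y <- mu + sqrt(config$rho) * z[pep_prot, , drop = FALSE] +
    sqrt(1 - config$rho) * eps
  shift <- de[pep_prot] * config$effect
  Y[, group == "B"] <- Y[, group == "B"] + shift
  dimnames(Y) <- list(pep_ids, sample_ids)
  table <- peptide_quant_table(Y, as.list(prot_ids[pep_prot]))
  design <- design_spec(data.frame(sample = sample_ids, group = group),
                        contrast = c("B", "A"))
  list(table = table, design = design, de = de,
       protein = prot_ids[pep_prot])
}

# Integer apportionment: floor the quotas, hand out the remaining units
# by largest fractional remainder.
largest_remainder <- function(quota, total) {
  fl <- floor(quota)
  rem <- total - sum(fl)
  if (rem > 0L) {
    extra <- order(quota - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1L
  }
  as.integer(fl)
}

#' Run a factorial simulation study
#'
#' For each replicate, simulates a peptidome, runs every requested
#' workflow on the identical data (guaranteeing paired comparisons), and
#' tallies calls at `alpha`: raw p-values for the Type I error rate and
#' power, BH-adjusted p-values for FDR and TPR. Replicates on which a
#' method fails are recorded, excluded from that method's averages, and
#' counted.
#'
#' @param config a [sim_config()].
#' @param progress print a dot every 10 replicates.
#' @return object of class `SimMetrics`: data.frame (method, metric,
#'   value, mc_se) with attributes `replicates` (per-replicate tidy
#'   results, for paired analyses), `config` and `n_failed`.
#' @export
run_simulation <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "SimConfig"))
  per_rep <- vector("list", config$n_reps)
  n_failed <- stats::setNames(integer(length(config$methods)),
                              config$methods)
  for (r in seq_len(config$n_reps)) {
    sim <- simulate_peptidome(config, rep_seed = config$seed + r)
    is_de <- sim$de != 0
    rows <- lapply(config$methods, function(meth) {
      res <- tryCatch(run_sim_method(meth, sim$table, sim$design),
                      error = function(e) NULL)
      if (is.null(res)) {
        n_failed[[meth]] <<- n_failed[[meth]] + 1L
        return(data.frame(rep = r, method = meth, failed = TRUE,
                          type1 = NA, power = NA, fdr = NA, tpr = NA))
      }
      p_raw <- res$p[match(names(sim$de), res$protein)]
      p_adj <- res$p_adj[match(names(sim$de), res$protein)]
      disc <- !is.na(p_adj) & p_adj < config$alpha
      cm <- confusion_metrics(disc, is_de)
      data.frame(
        rep = r, method = meth, failed = FALSE,
        type1 = if (any(!is_de))
          mean(p_raw[!is_de] < config$alpha, na.rm = TRUE) else NA_real_,
        power = if (any(is_de))
          mean(p_raw[is_de] < config$alpha, na.rm = TRUE) else NA_real_,
        fdr = cm$fdr,
        tpr = if (any(is_de)) cm$tpr else NA_real_)
    })
    per_rep[[r]] <- do.call(rbind, rows)
    if (progress && r %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  reps <- do.call(rbind, per_rep)
  metrics <- do.call(rbind, lapply(split(reps, reps$method), function(d) {
    d <- d[!d$failed, , drop = FALSE]
    do.call(rbind, lapply(c("type1", "power", "fdr", "tpr"), function(met) {
      v <- d[[met]]
      v <- v[!is.na(v)]
      if (!length(v)) return(NULL)
      data.frame(method = d$method[1L], metric = met, value = mean(v),
                 mc_se = stats::sd(v) / sqrt(length(v)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(metrics) <- NULL
  structure(metrics, class = c("SimMetrics", "data.frame"),
            replicates = reps, config = config, n_failed = n_failed)
}

# One benchmark workflow on one simulated dataset. Aggregation
# comparators use the limma-trend-style log-peptide-count covariate
# whenever the proteome mixes set sizes.
run_sim_method <- function(method, table, design) {
  switch(method,
    pepsettest_sd = run_pepsettest(table, design, cor_method = "mixed",
                                   scale_method = "sd", adjust = "BH"),
    pepsettest_mad = run_pepsettest(table, design, cor_method = "mixed",
                                    scale_method = "mad", adjust = "BH"),
    sum_limma = {
      agg <- aggregate_sum(table)
      protein_level_test(agg, design,
                         trend = length(unique(agg$n_peptides)) > 1L)
    },
    robust_limma = {
      agg <- aggregate_robust(table)
      protein_level_test(agg, design,
                         trend = length(unique(agg$n_peptides)) > 1L)
    },
    stop("unknown method: ", method))
}

#' Empirical confusion metrics of a set of calls
#'
#' @param called logical vector: protein declared differentially
#'   expressed.
#' @param truth logical vector: protein truly differentially expressed.
#' @return list with tp, fp, fn, tn, fdr (0 when there are no
#'   discoveries) and tpr (NA when there are no true positives to find).
#' @export
confusion_metrics <- function(called, truth) {
  stopifnot(length(called) == length(truth))
  tp <- sum(called & truth)
  fp <- sum(called & !truth)
  fn <- sum(!called & truth)
  tn <- sum(!called & !truth)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Write simulation metrics as tidy TSV with a YAML header
#'
#' @param metrics a `SimMetrics` object.
#' @param path output path.
#' @param params extra named values for the header.
#' @return `path`, invisibly.
#' @export
write_sim_metrics <- function(metrics, path, params = list()) {
  cfg <- attr(metrics, "config")
  hdr <- c(list(format = "pepset/sim-metrics",
                proteome = vapply(cfg$proteome, paste, "", collapse = "x"),
                rho = cfg$rho, n_samples = cfg$n_samples,
                de_fraction = cfg$de_fraction, effect = cfg$effect,
                n_reps = cfg$n_reps, seed = cfg$seed, alpha = cfg$alpha),
           params)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(yaml_header(hdr), con)
  utils::write.table(as.data.frame(metrics), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simulation scenario from YAML
#'
#' Fields mirror the arguments of [sim_config()]; `proteome` is a list of
#' two-integer arrays.
#'
#' @param path YAML file.
#' @return a `SimConfig`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("proteome", "rho", "n_samples", "de_fraction", "effect",
             "n_reps", "seed", "methods", "alpha")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown simulation config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$proteome))
    raw$proteome <- lapply(raw$proteome, unlist)
  do.call(sim_config, raw)
}
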