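#' Construct a two-group sample design
#'
#' Describes the comparison: which sample belongs to which group, the
#' contrast direction (test minus reference), and optional additive
#' covariates entering the per-peptide linear models.
#'
#' @param samples data.frame with at least columns `sample` and `group`;
#'   any further columns are treated as covariates when named in
#'   `covariates`.
#' @param contrast character of length 2, `c(test, reference)`. Effects are
#'   reported as test minus reference. Defaults to the second versus first
#'   sorted group label.
#' @param covariates character vector of covariate column names (numeric or
#'   factor) to adjust for; default none.
#' @return object of class `DesignSpec`.
#' @export
design_spec <- function(samples, contrast = NULL, covariates = character()) {
  if (!is.data.frame(samples) || !all(c("sample", "group") %in% names(samples)))
    stop("'samples' must be a data.frame with columns 'sample' and 'group'")
  samples$sample <- as.character(samples$sample)
  samples$group <- as.character(samples$group)
  if (anyDuplicated(samples$sample))
    stop("duplicate sample ids in design")
  lev <- sort(unique(samples$group))
  if (length(lev) != 2L)
    stop("exactly two group levels are required for a contrast; found: ",
         paste(lev, collapse = ", "))
  if (is.null(contrast)) contrast <- c(lev[2L], lev[1L])
  if (length(contrast) != 2L || !all(contrast %in% lev) ||
      contrast[1L] == contrast[2L])
    stop("'contrast' must name two distinct group levels as c(test, reference)")
  if (!all(covariates %in% names(samples)))
    stop("covariate column(s) not found in design: ",
         paste(setdiff(covariates, names(samples)), collapse = ", "))
  structure(
    list(samples = samples, contrast = contrast,
         covariates = as.character(covariates)),
    class = "DesignSpec")
}

#' @export
print.DesignSpec <- function(x, ...) {
  tab <- table(x$samples$group)
  cat(sprintf("DesignSpec: %d samples (%s), contrast %s - %s\n",
              nrow(x$samples),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$contrast[1L], x$contrast[2L]))
  if (length(x$covariates))
    cat("covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Read a sample design table
#'
#' TSV with columns `sample`, `group` and optional covariate columns.
#'
#' @param path file path.
#' @param contrast,covariates passed to [design_spec()].
#' @return a `DesignSpec`.
#' @export
read_design <- function(path, contrast = NULL, covariates = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  design_spec(df, contrast = contrast, covariates = covariates)
}

# Model matrix for a design, rows in the order of `sample_ids`:
# intercept, 0/1 test-group indicator, then covariate columns.
# The group coefficient is therefore the test-minus-reference effect.
design_matrix <- function(design, sample_ids) {
  stopifnot(inherits(design, "DesignSpec"))
  idx <- match(sample_ids, design$samples$sample)
  if (anyNA(idx))
    stop("samples missing from design: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  df <- design$samples[idx, , drop = FALSE]
  g <- as.numeric(df$group == design$contrast[1L])
  X <- cbind(intercept = 1, group = g)
  for (cv in design$covariates) {
    v <- df[[cv]]
    if (is.numeric(v)) {
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- cv
    } else {
      mm <- stats::model.matrix(~f, data.frame(f = factor(v)))[, -1L, drop = FALSE]
      colnames(mm) <- paste0(cv, colnames(mm))
      X <- cbind(X, mm)
    }
  }
  rownames(X) <- sample_ids
  X
}
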